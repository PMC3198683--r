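# Fluorescence vessel morphometry: the mural-cell chain (background
# subtraction, blur, auto-levels, common threshold, dilation, small-object
# rejection, hole filling, inscribed-radius statistics) and the perfusion
# chain (threshold, erosion, skeletonization, branch/endpoint/length
# metrics). Pixel-level primitives come from EBImage; thinning is implemented
# here (Guo-Hall) since no installed package provides it.

as_mask <- function(x) {
  m <- as.matrix(x) > 0.5
  storage.mode(m) <- "logical"
  m
}

disc_brush <- function(radius_px) EBImage::makeBrush(2L * radius_px + 1L, "disc")

#' Preprocess a fluorescence micrograph
#'
#' Three steps mirroring the standard acquisition cleanup: (1) dark-level
#' subtraction -- the image's low-percentile intensity is subtracted and
#' negatives clipped to zero; (2) Gaussian smoothing of electronic noise;
#' (3) linear auto-levels -- the low/high percentiles are mapped to the full
#' `[0, 1]` range. A constant image is returned unchanged with a warning
#' recorded in the provenance attribute.
#'
#' @param img numeric intensity matrix.
#' @param dark_percentile percentile defining the dark level (default 0.01,
#'   i.e. the 1st percentile).
#' @param blur_sigma Gaussian blur SD in pixels (default 1.0).
#' @param level_percentiles low/high percentiles stretched to `[0, 1]`.
#' @return Preprocessed matrix with a `provenance` attribute recording the
#'   applied operators and parameters.
#' @export
preprocess_image <- function(img, dark_percentile = 0.01, blur_sigma = 1.0,
                             level_percentiles = c(0.01, 0.99)) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  prov <- list(dark_percentile = dark_percentile, blur_sigma = blur_sigma,
               level_percentiles = level_percentiles, warnings = character(0L))
  if (diff(range(img)) == 0) {
    prov$warnings <- "constant image: preprocessing skipped"
    return(structure(img, provenance = prov))
  }
  dark <- stats::quantile(img, dark_percentile, names = FALSE)
  out <- pmax(img - dark, 0)
  if (blur_sigma > 0) out <- as.matrix(EBImage::gblur(EBImage::Image(out), sigma = blur_sigma))
  lo <- stats::quantile(out, level_percentiles[1L], names = FALSE)
  hi <- stats::quantile(out, level_percentiles[2L], names = FALSE)
  if (hi <= lo) {
    prov$warnings <- "degenerate intensity range: levels not expanded"
    return(structure(out, provenance = prov))
  }
  structure(pmin(pmax((out - lo) / (hi - lo), 0), 1), provenance = prov)
}

#' Segment vessels from a preprocessed image
#'
#' A common threshold (a fixed fraction of the rescaled intensity range, so
#' that the same cutoff applies across experimental groups) produces a binary
#' mask; the mask is then dilated to close small gaps, connected components
#' below a size cutoff are rejected as background particles, and enclosed
#' holes are filled. Vessels are foreground throughout -- display-polarity
#' inversion is never applied.
#'
#' @param img preprocessed intensity matrix in `[0, 1]`.
#' @param threshold intensity fraction in (0, 1); the default 0.5 is the
#'   midpoint of the rescaled range, where a symmetrically blurred edge
#'   crosses at the true object boundary.
#' @param min_object_px reject components smaller than this (default 50).
#' @param dilate_radius_px disc radius for gap-closing dilation (default 1;
#'   0 skips).
#' @param fill_holes logical, fill enclosed background holes (default TRUE).
#' @return Logical vessel mask with a `provenance` attribute.
#' @export
segment_vessels <- function(img, threshold = 0.5, min_object_px = 50L,
                            dilate_radius_px = 1L, fill_holes = TRUE) {
  stopifnot(is.matrix(img))
  prov <- list(threshold = threshold, min_object_px = min_object_px,
               dilate_radius_px = dilate_radius_px, fill_holes = fill_holes,
               warnings = character(0L))
  mask <- img >= threshold
  if (any(mask) && dilate_radius_px > 0L) {
    mask <- as_mask(EBImage::dilate(EBImage::Image(mask * 1), disc_brush(dilate_radius_px)))
  }
  if (any(mask) && min_object_px > 0L) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_object_px])
    mask <- matrix(as.vector(lab) %in% keep, nrow(img))
  }
  if (any(mask) && fill_holes) {
    mask <- as_mask(EBImage::fillHull(EBImage::Image(mask * 1)))
  }
  if (!any(mask)) prov$warnings <- "empty foreground after segmentation"
  structure(mask, provenance = prov)
}

#' Inscribed-radius statistics of a vessel mask
#'
#' Per connected component, the inscribed radius is the maximum of the
#' Euclidean distance-to-background transform within the component, scaled to
#' micrometres -- the radius of the largest disc fitting inside the object.
#' An isolated single pixel has distance 1 to the adjacent background, hence
#' radius `pixel_size` by convention.
#'
#' @param mask logical vessel mask.
#' @param pixel_size micrometres per pixel.
#' @param radius_cutoff_um cutoff for the large-vessel fraction (default 10).
#' @return List with `object_radii` (micrometres, one per component),
#'   `mean_inscribed_radius` and `fraction_gt_cutoff` (`NA` for an empty
#'   mask).
#' @export
inscribed_radius <- function(mask, pixel_size, radius_cutoff_um = 10) {
  stopifnot(is.matrix(mask))
  check_positive(pixel_size, "pixel_size")
  if (!any(mask)) {
    return(list(object_radii = numeric(0L), mean_inscribed_radius = NA_real_,
                fraction_gt_cutoff = NA_real_))
  }
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"))
  radii <- tapply(dm[lab > 0], lab[lab > 0], max) * pixel_size
  radii <- as.numeric(radii)
  list(object_radii = radii, mean_inscribed_radius = mean(radii),
       fraction_gt_cutoff = mean(radii > radius_cutoff_um))
}

#' Microvessel density (positive-pixel fraction)
#'
#' @param mask logical vessel mask.
#' @return Fraction of foreground pixels in `[0, 1]`.
#' @export
vessel_density <- function(mask) {
  stopifnot(is.matrix(mask))
  mean(mask)
}

#' Skeletonize a binary mask by Guo-Hall thinning
#'
#' Iterative two-subiteration boundary peeling that reduces the mask to
#' 8-connected one-pixel centerlines while preserving topology. The Guo-Hall
#' deletion rules avoid the two-pixel diagonal staircases that simpler
#' thinning schemes leave behind, so branch-point classification by neighbor
#' count stays reliable.
#'
#' @param mask logical matrix.
#' @return Logical skeleton matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(m, -1L, 0L); p3 <- shift(m, -1L, 1L); p4 <- shift(m, 0L, 1L)
      p5 <- shift(m, 1L, 1L);  p6 <- shift(m, 1L, 0L);  p7 <- shift(m, 1L, -1L)
      p8 <- shift(m, 0L, -1L); p9 <- shift(m, -1L, -1L)
      cnum <- ((1L - p2) * pmax(p3, p4)) + ((1L - p4) * pmax(p5, p6)) +
              ((1L - p6) * pmax(p7, p8)) + ((1L - p8) * pmax(p9, p2))
      n1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      n2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      nmin <- pmin(n1, n2)
      mcond <- if (pass == 1L) {
        pmax(pmax(p6, p7), 1L - p9) * p8
      } else {
        pmax(pmax(p2, p3), 1L - p5) * p4
      }
      del <- m == 1L & cnum == 1L & nmin >= 2L & nmin <= 3L & mcond == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-neighbor count of each skeleton pixel.
neighbor_count <- function(skel) {
  s <- skel * 1L
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- s
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  acc
}

#' Skeleton-based vessel architecture metrics
#'
#' Erodes the mask (pruning the thinnest structures, as in the original
#' operator chain), thins it to one-pixel centerlines, and classifies
#' skeleton pixels by their 8-neighbor count: one neighbor marks an endpoint,
#' three or more a branch point. Adjacent branch pixels (within one pixel)
#' are merged into single junctions. Total centerline length sums one
#' `pixel_size` per orthogonal skeleton step and `sqrt(2) * pixel_size` per
#' diagonal step; a diagonal step that merely shortcuts two orthogonal steps
#' is not double-counted.
#'
#' @param mask logical vessel mask.
#' @param pixel_size micrometres per pixel.
#' @param erode_radius_px disc radius of the pre-skeleton erosion (default 1;
#'   0 skips).
#' @param diagonal_correction logical; `FALSE` counts every skeleton step as
#'   one `pixel_size`.
#' @return List with `n_nodes`, `n_endpoints`, `total_length` (micrometres)
#'   and the logical `skeleton` matrix. All zeros (with a warning) if the
#'   mask is empty after erosion.
#' @export
skeleton_metrics <- function(mask, pixel_size, erode_radius_px = 1L,
                             diagonal_correction = TRUE) {
  stopifnot(is.matrix(mask))
  check_positive(pixel_size, "pixel_size")
  m <- mask
  if (erode_radius_px > 0L && any(m)) {
    m <- as_mask(EBImage::erode(EBImage::Image(m * 1), disc_brush(erode_radius_px)))
  }
  if (!any(m)) {
    warning("mask empty after erosion; skeleton metrics are zero")
    return(list(n_nodes = 0L, n_endpoints = 0L, total_length = 0,
                skeleton = m))
  }
  skel <- skeletonize(m)
  nb <- neighbor_count(skel)
  endpoints <- skel & nb == 1L
  # isolated single pixels count as objects with two "ends" collapsed: skip
  nodes_px <- skel & nb >= 3L
  n_nodes <- 0L
  if (any(nodes_px)) {
    merged <- EBImage::dilate(EBImage::Image(nodes_px * 1), disc_brush(1L))
    n_nodes <- max(as.matrix(EBImage::bwlabel(merged)))
  }
  s <- skel
  nr <- nrow(s); nc <- ncol(s)
  horiz <- sum(s[, -nc] & s[, -1L])
  vert <- sum(s[-nr, ] & s[-1L, ])
  dr_diag <- s[-nr, -nc] & s[-1L, -1L] & !s[-1L, -nc] & !s[-nr, -1L]
  dl_diag <- s[-nr, -1L] & s[-1L, -nc] & !s[-1L, -1L] & !s[-nr, -nc]
  diag_n <- sum(dr_diag) + sum(dl_diag)
  step_diag <- if (diagonal_correction) sqrt(2) else 1
  total_length <- (horiz + vert + diag_n * step_diag) * pixel_size
  list(n_nodes = as.integer(n_nodes), n_endpoints = as.integer(sum(endpoints)),
       total_length = total_length, skeleton = skel)
}

#' Compare two groups of inscribed radii at a size cutoff
#'
#' Dichotomizes each group's per-vessel radii at the cutoff and tests the
#' above/below counts with Fisher's exact test.
#'
#' @param group_a_radii,group_b_radii numeric vectors of radii (micrometres).
#' @param threshold_um dichotomization cutoff (default 10).
#' @param alternative passed to [fisher_exact_2x2()].
#' @return List with `fraction_a`, `fraction_b`, the 2x2 `table` and
#'   `p.value`.
#' @export
radius_distribution_compare <- function(group_a_radii, group_b_radii,
                                        threshold_um = 10,
                                        alternative = "two.sided") {
  if (!length(group_a_radii) || !length(group_b_radii)) {
    stop_param("both radius groups must be nonempty")
  }
  a_gt <- sum(group_a_radii > threshold_um)
  b_gt <- sum(group_b_radii > threshold_um)
  tab <- matrix(c(a_gt, length(group_a_radii) - a_gt,
                  b_gt, length(group_b_radii) - b_gt), 2L, byrow = TRUE)
  ft <- fisher_exact_2x2(tab, alternative)
  list(fraction_a = a_gt / length(group_a_radii),
       fraction_b = b_gt / length(group_b_radii),
       table = tab, p.value = ft$p.value)
}

#' Full morphometry of one calibrated vessel image
#'
#' Runs preprocessing, segmentation, inscribed-radius morphometry, vessel
#' density and skeleton metrics in sequence.
#'
#' @param img raw intensity matrix.
#' @param pixel_size micrometres per pixel.
#' @param threshold,min_object_px,dilate_radius_px segmentation parameters,
#'   see [segment_vessels()].
#' @param erode_radius_px pre-skeleton erosion radius.
#' @param radius_cutoff_um large-vessel cutoff (default 10).
#' @param ... further arguments to [preprocess_image()].
#' @return Object of class `morphometry_result`: `mvd`, `object_radii`,
#'   `mean_inscribed_radius`, `fraction_gt_cutoff`, `n_nodes`, `n_endpoints`,
#'   `total_length`, plus the `mask` and `skeleton` and the parameter
#'   provenance.
#' @export
analyze_vessel_image <- function(img, pixel_size, threshold = 0.5,
                                 min_object_px = 50L, dilate_radius_px = 1L,
                                 erode_radius_px = 1L, radius_cutoff_um = 10,
                                 ...) {
  pre <- preprocess_image(img, ...)
  mask <- segment_vessels(pre, threshold = threshold,
                          min_object_px = min_object_px,
                          dilate_radius_px = dilate_radius_px)
  # the perfusion (density) chain applies no gap-closing dilation: MVD comes
  # from the plain thresholded mask so the positive-pixel fraction is unbiased
  mask_mvd <- segment_vessels(pre, threshold = threshold,
                              min_object_px = min_object_px,
                              dilate_radius_px = 0L)
  ir <- inscribed_radius(mask, pixel_size, radius_cutoff_um)
  sk <- skeleton_metrics(mask, pixel_size, erode_radius_px)
  structure(list(mvd = vessel_density(mask_mvd),
                 object_radii = ir$object_radii,
                 mean_inscribed_radius = ir$mean_inscribed_radius,
                 fraction_gt_cutoff = ir$fraction_gt_cutoff,
                 radius_cutoff_um = radius_cutoff_um,
                 n_nodes = sk$n_nodes, n_endpoints = sk$n_endpoints,
                 total_length = sk$total_length,
                 mask = mask, skeleton = sk$skeleton,
                 provenance = list(preprocess = attr(pre, "provenance"),
                                   segment = attr(mask, "provenance"),
                                   pixel_size = pixel_size,
                                   erode_radius_px = erode_radius_px)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("Vessel morphometry\n")
  cat(sprintf("  MVD (positive-pixel fraction): %.4f\n", x$mvd))
  cat(sprintf("  objects: %d, mean inscribed radius: %.2f um, fraction > %g um: %.3f\n",
              length(x$object_radii), x$mean_inscribed_radius,
              x$radius_cutoff_um, x$fraction_gt_cutoff))
  cat(sprintf("  skeleton: %d nodes, %d endpoints, total length %.1f um\n",
              x$n_nodes, x$n_endpoints, x$total_length))
  invisible(x)
}
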