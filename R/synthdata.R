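# Seeded generators for every input the pipeline consumes, each paired with
# the ground truth a downstream estimator should recover: a 4-arm xenograft
# cohort, a small two-condition expression bundle with planted gene sets, a
# reference/target qPCR plate, and rendered 2-D vessel trees.

#' Specify a synthetic xenograft cohort
#'
#' @param arms data frame with columns `arm` (unique names), `n` (animals per
#'   arm), `metastasis_prob` (per-arm Bernoulli probability) and
#'   `weight_scale` (multiplicative mean tumor weight relative to control).
#' @param weight_noise_cv coefficient of variation of tumor weights within an
#'   arm (weights are log-normal).
#' @param control_weight mean tumor weight of the control arm, grams.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(arms, weight_noise_cv = 0.3, control_weight = 1.0, seed = 1L) {
  stopifnot(is.data.frame(arms),
            all(c("arm", "n", "metastasis_prob", "weight_scale") %in% names(arms)))
  if (anyDuplicated(arms$arm)) stop_param("arm names must be unique")
  if (any(arms$n < 1) || any(arms$n != round(arms$n))) {
    stop_param("n_animals must be a positive integer")
  }
  check_prob(arms$metastasis_prob, "metastasis_prob")
  check_positive(arms$weight_scale, "weight_scale")
  check_positive(weight_noise_cv, "weight_noise_cv")
  check_positive(control_weight, "control_weight")
  structure(list(arms = arms, weight_noise_cv = weight_noise_cv,
                 control_weight = control_weight, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The default study cohort design
#'
#' Four arms -- control, COX-2 inhibitor (SC236), anti-VEGF antibody (BV) and
#' the combination -- with arm sizes 13/17/17/15, per-arm metastasis
#' probabilities 12/13, 11/17, 8/17 and 2/15, and mean tumor weights scaled to
#' 100%, 61%, 24% and 26% of control.
#'
#' @param weight_noise_cv within-arm weight coefficient of variation.
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(weight_noise_cv = 0.3, seed = 1L) {
  cohort_spec(data.frame(
    arm = c("control", "SC236", "BV", "BV+SC236"),
    n = c(13L, 17L, 17L, 15L),
    metastasis_prob = c(12 / 13, 11 / 17, 8 / 17, 2 / 15),
    weight_scale = c(1.0, 0.61, 0.24, 0.26)),
    weight_noise_cv = weight_noise_cv, seed = seed)
}

#' Generate a synthetic cohort table
#'
#' Metastasis outcomes are Bernoulli draws at the arm's probability; tumor
#' weights are log-normal with mean `control_weight * weight_scale` and the
#' specified coefficient of variation.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `synth_cohort` with `cohort` (data frame:
#'   `animal_id`, `arm`, `tumor_weight`, `metastasis`) and `truth` (per-arm
#'   design parameters).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cv <- spec$weight_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(seq_len(nrow(spec$arms)), function(i) {
    a <- spec$arms[i, ]
    mu <- spec$control_weight * a$weight_scale
    data.frame(
      animal_id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", a$arm), seq_len(a$n)),
      arm = a$arm,
      tumor_weight = stats::rlnorm(a$n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog),
      metastasis = stats::runif(a$n) < a$metastasis_prob)
  })
  truth <- spec$arms
  truth$mean_weight <- spec$control_weight * truth$weight_scale
  structure(list(cohort = do.call(rbind, rows), truth = truth, spec = spec),
            class = "synth_cohort")
}

#' Specify a planted gene set
#'
#' @param set_id set name.
#' @param set_size number of member genes.
#' @param effect mean log-expression shift applied to member genes in the
#'   second class; its sign must agree with `direction`.
#' @param direction `"up"` or `"down"` (sign of the shift in class 2).
#' @return An object of class `planted_set_spec`.
#' @export
planted_set_spec <- function(set_id, set_size, effect,
                             direction = if (effect >= 0) "up" else "down") {
  direction <- match.arg(direction, c("up", "down"))
  if (set_size < 1 || set_size != round(set_size)) stop_param("set_size must be a positive integer")
  if ((direction == "up" && effect < 0) || (direction == "down" && effect > 0)) {
    stop_param("effect sign inconsistent with direction")
  }
  structure(list(set_id = set_id, set_size = as.integer(set_size),
                 effect = effect, direction = direction),
            class = "planted_set_spec")
}

#' Generate a two-condition expression bundle with planted gene sets
#'
#' Log-scale expression is Gaussian noise around zero; member genes of each
#' planted set are shifted by the set's `effect` in the second class. Planted
#' sets are disjoint, and decoy sets are drawn uniformly from the remaining
#' (unshifted) genes so that they are exact nulls.
#'
#' @param n_genes universe size.
#' @param group_sizes integer pair of per-class sample counts (default `c(3, 4)`,
#'   the two treated arms profiled in the study design this emulates).
#' @param planted list of [planted_set_spec()] objects.
#' @param n_decoy_sets number of null decoy sets.
#' @param decoy_size_range inclusive range decoy sizes are drawn from.
#' @param noise_sd Gaussian noise standard deviation (log-expression units).
#' @param class_labels length-2 character vector of class names.
#' @param seed integer seed.
#' @return List of class `expression_bundle` with `exprs` (genes x samples),
#'   `classes`, `genesets` (named list), and `truth` (planted ids, directions,
#'   effects).
#' @export
gen_expression <- function(n_genes = 10000L, group_sizes = c(3L, 4L),
                           planted = list(), n_decoy_sets = 62L,
                           decoy_size_range = c(30L, 80L), noise_sd = 1.0,
                           class_labels = c("BV", "BV+SC236"), seed = 1L) {
  stopifnot(length(group_sizes) == 2L, all(group_sizes >= 2L))
  check_positive(noise_sd, "noise_sd")
  planted_sizes <- vapply(planted, function(p) p$set_size, integer(1L))
  if (sum(planted_sizes) > n_genes) stop_param("planted sets exceed the gene universe")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_samp <- sum(group_sizes)
  exprs <- matrix(stats::rnorm(n_genes * n_samp, sd = noise_sd), n_genes, n_samp,
                  dimnames = list(genes, sprintf("s%02d", seq_len(n_samp))))
  classes <- rep(class_labels, group_sizes)
  grp2 <- which(classes == class_labels[2L])

  pool <- sample(genes)  # random disjoint allocation of planted members
  genesets <- list(); used <- 0L
  for (p in planted) {
    members <- pool[used + seq_len(p$set_size)]
    used <- used + p$set_size
    exprs[members, grp2] <- exprs[members, grp2] + p$effect
    genesets[[p$set_id]] <- sort(members)
  }
  decoy_pool <- setdiff(genes, unlist(genesets))
  for (i in seq_len(n_decoy_sets)) {
    sz <- sample(decoy_size_range[1L]:decoy_size_range[2L], 1L)
    genesets[[sprintf("DECOY_%03d", i)]] <- sort(sample(decoy_pool, sz))
  }
  truth <- data.frame(
    set_id = names(genesets),
    planted = names(genesets) %in% vapply(planted, `[[`, character(1L), "set_id"),
    effect = c(vapply(planted, `[[`, numeric(1L), "effect"), rep(0, n_decoy_sets)),
    direction = c(vapply(planted, `[[`, character(1L), "direction"),
                  rep("null", n_decoy_sets)))
  structure(list(exprs = exprs, classes = classes, genesets = genesets,
                 truth = truth, noise_sd = noise_sd),
            class = "expression_bundle")
}

#' Write an expression bundle as GCT + CLS + GMT
#'
#' @param bundle an `expression_bundle`.
#' @param prefix file-path prefix; writes `<prefix>.gct`, `<prefix>.cls`,
#'   `<prefix>.gmt` and `<prefix>_truth.json`.
#' @return Invisibly, the named vector of paths written.
#' @export
write_expression_bundle <- function(bundle, prefix) {
  paths <- c(gct = paste0(prefix, ".gct"), cls = paste0(prefix, ".cls"),
             gmt = paste0(prefix, ".gmt"), truth = paste0(prefix, "_truth.json"))
  write_gct(bundle$exprs, paths[["gct"]])
  write_cls(bundle$classes, paths[["cls"]])
  write_gmt(bundle$genesets, paths[["gmt"]])
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Default gene names for the qPCR plate: the six housekeeping references and
# the seven lung-metastasis signature genes assayed in the study design.
.reference_genes <- c("ACTB", "HMBS", "UBC", "GAPD", "HPRT", "PPIA")
.target_genes <- c("COL6A1", "CSF2RA", "CXCR4", "KRT81", "MATN2", "SPARC", "TNC")

#' Generate a synthetic qPCR Cq plate
#'
#' Each Cq value is a fixed gene baseline plus a shared per-sample loading
#' factor plus gene-specific Gaussian jitter whose standard deviation controls
#' that gene's stability (larger jitter = less stable reference). An optional
#' planted log2 fold change shifts target genes in the second sample group
#' (one cycle of Cq per doubling).
#'
#' @param n_reference,n_target numbers of reference and target genes (defaults
#'   6 and 7; names follow the housekeeping/signature panels up to those
#'   counts, then generic labels).
#' @param n_samples number of samples.
#' @param stability_sds per-gene Cq jitter SDs, length `n_reference +
#'   n_target` (recycled if length 1).
#' @param sample_factor_sd SD of the shared per-sample loading factor
#'   (cycles).
#' @param target_log2fc planted log2 fold change of every target gene in the
#'   second group (0 = none).
#' @param group_sizes optional integer pair splitting samples into two groups
#'   (required when `target_log2fc != 0`).
#' @param seed integer seed.
#' @return List of class `synth_qpcr` with `cq` (matrix genes x samples),
#'   `roles`, `truth` (jitter SDs, ascending-stability order, planted fold
#'   change) and `group` (per-sample labels or NULL).
#' @export
gen_qpcr <- function(n_reference = 6L, n_target = 7L, n_samples = 8L,
                     stability_sds = 0.15, sample_factor_sd = 1.0,
                     target_log2fc = 0, group_sizes = NULL, seed = 1L) {
  n_genes <- n_reference + n_target
  if (length(stability_sds) == 1L) stability_sds <- rep(stability_sds, n_genes)
  if (length(stability_sds) != n_genes) stop_param("stability_sds must have one SD per gene")
  if (any(stability_sds < 0)) stop_param("stability_sds must be >= 0")
  if (target_log2fc != 0 && is.null(group_sizes)) {
    stop_param("group_sizes is required when a target fold change is planted")
  }
  if (!is.null(group_sizes) && sum(group_sizes) != n_samples) {
    stop_param("group_sizes must sum to n_samples")
  }
  ref_names <- c(.reference_genes, sprintf("REF%02d", seq_len(max(0, n_reference - 6L))))[seq_len(n_reference)]
  tgt_names <- c(.target_genes, sprintf("TGT%02d", seq_len(max(0, n_target - 7L))))[seq_len(n_target)]
  genes <- c(ref_names, tgt_names)
  roles <- rep(c("reference", "target"), c(n_reference, n_target))
  set.seed(seed)
  baseline <- 18 + 8 * seq(0, 1, length.out = n_genes)  # spread over 18-26 cycles
  sample_factor <- stats::rnorm(n_samples, sd = sample_factor_sd)
  cq <- outer(baseline, sample_factor, `+`) +
    matrix(stats::rnorm(n_genes * n_samples), n_genes) * stability_sds
  dimnames(cq) <- list(genes, sprintf("s%02d", seq_len(n_samples)))
  group <- NULL
  if (!is.null(group_sizes)) {
    group <- rep(c("group1", "group2"), group_sizes)
    if (target_log2fc != 0) {
      # one Cq cycle per doubling: higher expression -> lower Cq
      cq[roles == "target", group == "group2"] <-
        cq[roles == "target", group == "group2"] - target_log2fc
    }
  }
  truth <- list(stability_sds = stats::setNames(stability_sds, genes),
                stability_order = genes[roles == "reference"][
                  order(stability_sds[roles == "reference"])],
                target_log2fc = target_log2fc)
  structure(list(cq = cq, roles = roles, truth = truth, group = group),
            class = "synth_qpcr")
}

#' Specify a synthetic vessel tree image
#'
#' Segments are straight capsules (all points within `radius` of the
#' centerline) in micrometre coordinates; the rendered image is blurred first
#' (optics), then background and Gaussian sensor noise are added.
#'
#' @param segments data frame with columns `x0`, `y0`, `x1`, `y1`, `radius`
#'   (all micrometres).
#' @param pixel_size micrometres per pixel.
#' @param image_shape integer pair `(rows, cols)` in pixels.
#' @param background_level background intensity in `[0, 1)`.
#' @param noise_sd Gaussian sensor-noise SD (intensity units).
#' @param blur_sigma optical blur SD in pixels.
#' @param seed integer seed.
#' @return An object of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(segments, pixel_size = 1.0, image_shape = c(256L, 256L),
                             background_level = 0.05, noise_sd = 0.02,
                             blur_sigma = 1.0, seed = 1L) {
  stopifnot(is.data.frame(segments),
            all(c("x0", "y0", "x1", "y1", "radius") %in% names(segments)))
  check_positive(segments$radius, "segment radius")
  check_positive(pixel_size, "pixel_size")
  extent <- image_shape * pixel_size  # (rows -> y, cols -> x)
  xs <- c(segments$x0, segments$x1); ys <- c(segments$y0, segments$y1)
  r2 <- rep(segments$radius, 2L)
  if (any(xs - r2 < 0) || any(xs + r2 > extent[2L]) ||
      any(ys - r2 < 0) || any(ys + r2 > extent[1L])) {
    stop_param("segment (including its radius) falls outside the image bounds")
  }
  structure(list(segments = segments, pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 background_level = background_level, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "vessel_tree_spec")
}

# Exact capsule-union mask of a vessel tree: pixel centers within `radius` of
# any segment's centerline. Works per-segment on local bounding boxes.
capsule_mask <- function(spec) {
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]; px <- spec$pixel_size
  mask <- matrix(FALSE, nr, nc)
  xc <- (seq_len(nc) - 0.5) * px  # pixel-center x by column
  yc <- (seq_len(nr) - 0.5) * px  # pixel-center y by row
  for (i in seq_len(nrow(spec$segments))) {
    s <- spec$segments[i, ]
    rows <- which(yc >= min(s$y0, s$y1) - s$radius - px &
                  yc <= max(s$y0, s$y1) + s$radius + px)
    cols <- which(xc >= min(s$x0, s$x1) - s$radius - px &
                  xc <= max(s$x0, s$x1) + s$radius + px)
    if (!length(rows) || !length(cols)) next
    gx <- matrix(xc[cols], length(rows), length(cols), byrow = TRUE)
    gy <- matrix(yc[rows], length(rows), length(cols))
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      d2 <- (gx - s$x0)^2 + (gy - s$y0)^2
    } else {
      t_ <- pmin(pmax(((gx - s$x0) * dx + (gy - s$y0) * dy) / len2, 0), 1)
      d2 <- (gx - (s$x0 + t_ * dx))^2 + (gy - (s$y0 + t_ * dy))^2
    }
    mask[rows, cols] <- mask[rows, cols] | (d2 <= s$radius^2)
  }
  mask
}

# Topology of a segment tree from coincident endpoints: nodes are junction
# points where >= 3 segment ends meet; free ends (degree 1) are endpoints.
tree_topology <- function(segments, tol = 1e-6) {
  pts <- rbind(as.matrix(segments[, c("x0", "y0")]),
               as.matrix(segments[, c("x1", "y1")]))
  key <- paste(round(pts[, 1L] / tol), round(pts[, 2L] / tol))
  degree <- table(key)
  list(n_nodes = sum(degree >= 3L), n_endpoints = sum(degree == 1L),
       total_length = sum(sqrt((segments$x1 - segments$x0)^2 +
                               (segments$y1 - segments$y0)^2)))
}

#' Render a synthetic vessel image with ground truth
#'
#' @param spec a [vessel_tree_spec()].
#' @return List of class `synth_vessel_image` with `image` (matrix in
#'   `[0, 1]`), `mask` (exact noiseless capsule-union mask), and `truth`
#'   (per-segment radii, branch/endpoint counts, total centerline length in
#'   micrometres, noiseless positive-pixel fraction).
#' @export
gen_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_tree_spec"))
  mask <- capsule_mask(spec)
  img <- matrix(0, nrow(mask), ncol(mask))
  img[mask] <- 1
  if (spec$blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = spec$blur_sigma))
  }
  img <- spec$background_level + (1 - spec$background_level) * img
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd), nrow(img))
  }
  img <- pmin(pmax(img, 0), 1)
  topo <- tree_topology(spec$segments)
  truth <- list(radii = spec$segments$radius, n_nodes = topo$n_nodes,
                n_endpoints = topo$n_endpoints, total_length = topo$total_length,
                positive_fraction = mean(mask))
  structure(list(image = img, mask = mask, truth = truth, spec = spec),
            class = "synth_vessel_image")
}

#' Lay out disjoint vessel segments on a grid
#'
#' Convenience builder for recovery experiments: each segment is placed in its
#' own grid cell with a random orientation, so connected components map one to
#' one onto segments.
#'
#' @param radii vector of segment radii (micrometres); one segment per entry.
#' @param seg_length segment centerline length (micrometres).
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @param ... further arguments passed to [vessel_tree_spec()]
#'   (`background_level`, `noise_sd`, `blur_sigma`).
#' @return A `vessel_tree_spec` whose `image_shape` is sized to fit the grid.
#' @export
gen_vessel_field <- function(radii, seg_length = 40, pixel_size = 1.0, seed = 1L, ...) {
  n <- length(radii)
  check_positive(radii, "radii")
  ncell <- ceiling(sqrt(n))
  cell <- seg_length + 2 * (max(radii) + 4 * pixel_size)  # segment + clearance
  shape <- rep(ceiling(ncell * cell / pixel_size), 2L)
  set.seed(seed)
  theta <- stats::runif(n, 0, pi)
  idx <- seq_len(n) - 1L
  cx <- (idx %% ncell + 0.5) * cell
  cy <- (idx %/% ncell + 0.5) * cell
  segments <- data.frame(
    x0 = cx - cos(theta) * seg_length / 2, y0 = cy - sin(theta) * seg_length / 2,
    x1 = cx + cos(theta) * seg_length / 2, y1 = cy + sin(theta) * seg_length / 2,
    radius = radii)
  vessel_tree_spec(segments, pixel_size = pixel_size, image_shape = shape,
                   seed = seed, ...)
}
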