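test_that("preprocessing is offset-invariant and guards constant images", {
  const <- matrix(0.3, 20, 20)
  out <- preprocess_image(const)
  expect_equal(unclass(out), unclass(const), ignore_attr = TRUE)
  expect_match(attr(out, "provenance")$warnings, "constant")

  set.seed(2)
  clean <- matrix(runif(900), 30, 30)
  shifted <- preprocess_image(clean + 0.17)
  expect_equal(unclass(preprocess_image(clean)), unclass(shifted),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("segmentation rejects specks, fills holes, and handles empty fields", {
  empty <- segment_vessels(matrix(0, 30, 30))
  expect_false(any(empty))
  expect_match(attr(empty, "provenance")$warnings, "empty")

  img <- matrix(0, 60, 120)
  img[30:33, 5:7] <- 1          # 12-px speck
  img[50:52, 100:102] <- 1      # 9-px speck
  img[10:19, 10:59] <- 1        # 500-px vessel
  mask <- segment_vessels(img, threshold = 0.5, min_object_px = 50,
                          dilate_radius_px = 0)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(lab), 1)     # only the vessel survives
  expect_false(any(mask[28:35, 3:9]))

  ring <- matrix(0, 40, 40)
  ring[10:30, 10:30] <- 1; ring[15:25, 15:25] <- 0
  filled <- segment_vessels(ring, threshold = 0.5, min_object_px = 10,
                            dilate_radius_px = 0)
  expect_true(all(filled[16:24, 16:24]))  # interior filled
})

test_that("inscribed radius recovers disk and capsule radii from the distance transform", {
  d20 <- disk_mask(20L)
  ir <- inscribed_radius(d20, pixel_size = 0.5)
  expect_lt(abs(ir$mean_inscribed_radius - 10), 0.5)  # within one pixel

  two <- disk_mask(10L, pad = 30L, center_offset = c(-18, -18)) |
         disk_mask(30L, pad = 10L, center_offset = c(18, 18))
  ir2 <- inscribed_radius(two, pixel_size = 0.5)     # radii 5 and 15 um
  expect_equal(sort(ir2$object_radii), c(5, 15), tolerance = 0.6)
  expect_equal(ir2$fraction_gt_cutoff, 0.5)

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(inscribed_radius(single, 2)$object_radii, 2)  # 1-px convention
  expect_true(is.na(inscribed_radius(matrix(FALSE, 5, 5), 1)$mean_inscribed_radius))

  # noiseless rendered capsules across the radius range, distance-transform oracle
  for (r in c(3, 8, 14, 20, 25)) {
    spec <- vessel_tree_spec(data.frame(x0 = r + 6, y0 = r + 6, x1 = r + 66,
                                        y1 = r + 6, radius = r),
                             image_shape = rep(ceiling(2 * r + 80), 2),
                             noise_sd = 0, blur_sigma = 0)
    m <- gen_vessel_image(spec)
    est <- inscribed_radius(m$mask, 1)$mean_inscribed_radius
    expect_lt(abs(est - r), 1.5)
  }
})

test_that("vessel density is the positive-pixel fraction", {
  expect_equal(vessel_density(matrix(FALSE, 10, 10)), 0)
  expect_equal(vessel_density(matrix(TRUE, 10, 10)), 1)
  spec <- gen_vessel_field(c(4, 6, 9, 5), seed = 3, noise_sd = 0.02)
  vi <- gen_vessel_image(spec)
  m <- analyze_vessel_image(vi$image, pixel_size = 1)
  expect_lt(abs(m$mvd - vi$truth$positive_fraction), 0.02)
})

test_that("skeleton metrics recover tree topology and length", {
  bar <- vessel_tree_spec(data.frame(x0 = 10, y0 = 30, x1 = 110, y1 = 30,
                                     radius = 5),
                          image_shape = c(60L, 120L), noise_sd = 0.02)
  bm <- analyze_vessel_image(gen_vessel_image(bar)$image, pixel_size = 1)
  expect_equal(bm$n_nodes, 0)
  expect_equal(bm$n_endpoints, 2)
  expect_lt(abs(bm$total_length - 100) / 100, 0.05)

  ytree <- vessel_tree_spec(data.frame(x0 = c(50, 50, 50), y0 = c(50, 50, 50),
                                       x1 = c(50, 20, 80), y1 = c(10, 85, 85),
                                       radius = 4),
                            image_shape = c(100L, 100L), noise_sd = 0.02)
  ym <- analyze_vessel_image(gen_vessel_image(ytree)$image, pixel_size = 1)
  expect_equal(ym$n_nodes, 1)
  expect_equal(ym$n_endpoints, 3)

  cross <- vessel_tree_spec(data.frame(x0 = c(15, 15), y0 = c(15, 85),
                                       x1 = c(85, 85), y1 = c(85, 15), radius = 4),
                            image_shape = c(100L, 100L), noise_sd = 0.02)
  cm <- analyze_vessel_image(gen_vessel_image(cross)$image, pixel_size = 1)
  expect_equal(cm$n_nodes, 1)   # adjacent branch pixels merge to one junction
  expect_equal(cm$n_endpoints, 4)

  expect_warning(empty <- skeleton_metrics(matrix(FALSE, 10, 10), 1), "empty")
  expect_equal(empty$total_length, 0)
})

test_that("the morphometry chain tolerates rotation and recovers noisy fields", {
  spec <- gen_vessel_field(c(5, 12, 8, 15), seed = 2, noise_sd = 0.02)
  vi <- gen_vessel_image(spec)
  m <- analyze_vessel_image(vi$image, pixel_size = 1)
  expect_equal(m$n_nodes, vi$truth$n_nodes)
  expect_equal(m$n_endpoints, vi$truth$n_endpoints)

  rot <- t(vi$image)[ncol(vi$image):1, ]  # 90 degree rotation
  mr <- analyze_vessel_image(rot, pixel_size = 1)
  expect_equal(mr$n_nodes, m$n_nodes)
  expect_equal(mr$n_endpoints, m$n_endpoints)
  expect_lt(abs(mr$total_length - m$total_length) / m$total_length, 0.05)

  # Jaccard of the noisy segmentation against the noiseless truth; the
  # gap-closing dilation is skipped because it inflates boundaries by design
  noisy <- gen_vessel_field(c(5, 12, 8, 15), seed = 2, noise_sd = 0.10)
  nv <- gen_vessel_image(noisy)
  nmask <- segment_vessels(preprocess_image(nv$image), dilate_radius_px = 0)
  jac <- sum(nmask & nv$mask) / sum(nmask | nv$mask)
  expect_gte(jac, 0.9)
})

test_that("radius-distribution comparison dichotomizes and tests correctly", {
  same <- radius_distribution_compare(c(4, 12, 15), c(4, 12, 15))
  expect_equal(same$p.value, 1)
  cmp <- radius_distribution_compare(c(12, 14, 15), c(4, 5, 6))
  expect_equal(cmp$fraction_a, 1)
  expect_equal(cmp$fraction_b, 0)
  expect_error(radius_distribution_compare(numeric(0), 1:3), "nonempty")
})
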