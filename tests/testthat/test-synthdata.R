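test_that("cohort generator honours the design and is reproducible", {
  sc <- gen_cohort(default_cohort_spec(seed = 3))
  expect_equal(nrow(sc$cohort), 62)  # 13 + 17 + 17 + 15 animals
  expect_false(anyDuplicated(sc$cohort$animal_id) > 0)
  expect_identical(gen_cohort(default_cohort_spec(seed = 3)), sc)
  expect_false(identical(gen_cohort(default_cohort_spec(seed = 4)), sc))

  none <- cohort_spec(data.frame(arm = c("a", "b"), n = c(5L, 6L),
                                 metastasis_prob = 0, weight_scale = 1),
                      seed = 1)
  expect_false(any(gen_cohort(none)$cohort$metastasis))
  expect_error(cohort_spec(data.frame(arm = "a", n = 0L, metastasis_prob = 0.5,
                                      weight_scale = 1)), "positive integer")
  expect_error(cohort_spec(data.frame(arm = "a", n = 2L, metastasis_prob = 0.5,
                                      weight_scale = 1), weight_noise_cv = -1),
               "positive")
})

test_that("cohort outcomes follow the Bernoulli/log-normal model", {
  ctrl <- cohort_spec(data.frame(arm = "control", n = 13L,
                                 metastasis_prob = 12 / 13, weight_scale = 1),
                      weight_noise_cv = 0.3, seed = 1)
  draws <- lapply(1:3000, function(s) {
    ctrl$seed <- s
    gen_cohort(ctrl)$cohort
  })
  met <- unlist(lapply(draws, `[[`, "metastasis"))
  p <- 12 / 13
  se <- sqrt(p * (1 - p) / length(met))
  expect_lt(abs(mean(met) - p), 3 * se)
  w <- unlist(lapply(draws, `[[`, "tumor_weight"))
  expect_lt(abs(mean(w) - 1), 3 * stats::sd(w) / sqrt(length(w)))
  expect_lt(abs(stats::sd(w) / mean(w) - 0.3), 0.01)  # target CV
})

test_that("expression generator plants sets with the requested shift", {
  planted <- list(planted_set_spec("DOWN_A", 50L, -1.0))
  b <- gen_expression(n_genes = 800L, planted = planted, n_decoy_sets = 66L,
                      noise_sd = 1.0, seed = 5)
  expect_equal(length(b$genesets), 67)
  expect_equal(dim(b$exprs), c(800L, 7L))
  expect_identical(gen_expression(n_genes = 800L, planted = planted,
                                  n_decoy_sets = 66L, seed = 5)$exprs, b$exprs)

  # planted member group difference is `effect` in expectation, decoys 0
  grp2 <- b$classes == "BV+SC236"
  diffs <- rowMeans(b$exprs[, grp2]) - rowMeans(b$exprs[, !grp2])
  members <- b$genesets[["DOWN_A"]]
  expect_lt(abs(mean(diffs[members]) + 1), 3 * sqrt(1 / 3 + 1 / 4) / sqrt(50))
  decoy_genes <- unique(unlist(b$genesets[names(b$genesets) != "DOWN_A"]))
  expect_lt(abs(mean(diffs[decoy_genes])), 0.15)

  # the planted down-shifted set sits lowest in the ranking
  scores <- rank_genes(b$exprs, b$classes)
  mean_rank <- vapply(b$genesets, function(g) mean(match(g, names(scores))),
                      numeric(1))
  expect_equal(names(which.max(mean_rank)), "DOWN_A")  # largest rank = most down
  expect_gt(mean_rank[["DOWN_A"]], length(scores) / 2)

  expect_error(gen_expression(n_genes = 40L,
                              planted = list(planted_set_spec("x", 50L, -1))),
               "exceed")
  zero <- gen_expression(n_genes = 200L, planted = list(), n_decoy_sets = 10L,
                         seed = 2)
  expect_true(all(!zero$truth$planted))
})

test_that("qPCR generator produces the 13-gene plate with controlled stability", {
  qp <- gen_qpcr(seed = 9)
  expect_equal(dim(qp$cq), c(13L, 8L))
  expect_equal(rownames(qp$cq)[1:6], c("ACTB", "HMBS", "UBC", "GAPD", "HPRT", "PPIA"))
  expect_equal(sum(qp$roles == "target"), 7)
  expect_error(gen_qpcr(stability_sds = -0.1), ">= 0")

  # zero jitter: every reference pair has a constant log-ratio, all M = 0
  calm <- gen_qpcr(stability_sds = 0, seed = 1)
  rq <- relative_quantity(calm$cq[calm$roles == "reference", ])
  expect_equal(unname(pairwise_stability(rq)), rep(0, 6), tolerance = 1e-12)

  # planted fold change moves target Cq by -log2fc cycles in group 2
  fc <- gen_qpcr(stability_sds = 0, target_log2fc = 1, group_sizes = c(4L, 4L),
                 seed = 1)
  base <- gen_qpcr(stability_sds = 0, target_log2fc = 0, group_sizes = c(4L, 4L),
                   seed = 1)
  delta <- fc$cq - base$cq
  expect_equal(unname(delta[fc$roles == "target", fc$group == "group2"]),
               matrix(-1, 7, 4), tolerance = 1e-12)
  expect_equal(sum(abs(delta[fc$roles == "reference", ])), 0)
})

test_that("vessel renderer matches the analytic capsule union and tree topology", {
  spec <- vessel_tree_spec(data.frame(x0 = 8, y0 = 10, x1 = 32, y1 = 25,
                                      radius = 4),
                           image_shape = c(40L, 40L), noise_sd = 0, blur_sigma = 0)
  vi <- gen_vessel_image(spec)
  # independent per-pixel membership: distance from pixel center to segment
  seg <- spec$segments
  ref <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (cc in 1:40) {
    px <- c(cc - 0.5, r - 0.5)
    v <- c(seg$x1 - seg$x0, seg$y1 - seg$y0)
    t_ <- min(max(sum((px - c(seg$x0, seg$y0)) * v) / sum(v^2), 0), 1)
    ref[r, cc] <- sqrt(sum((px - (c(seg$x0, seg$y0) + t_ * v))^2)) <= seg$radius
  }
  expect_identical(vi$mask, ref)
  expect_equal(vi$truth$n_nodes, 0)
  expect_equal(vi$truth$n_endpoints, 2)
  expect_equal(vi$truth$positive_fraction, mean(ref))

  ytree <- vessel_tree_spec(data.frame(x0 = c(50, 50, 50), y0 = c(50, 50, 50),
                                       x1 = c(50, 20, 80), y1 = c(10, 85, 85),
                                       radius = 3),
                            image_shape = c(100L, 100L))
  yt <- gen_vessel_image(ytree)$truth
  expect_equal(yt$n_nodes, 1)
  expect_equal(yt$n_endpoints, 3)
  expect_equal(yt$total_length, 40 + 2 * sqrt(30^2 + 35^2), tolerance = 1e-12)

  expect_error(vessel_tree_spec(data.frame(x0 = -5, y0 = 10, x1 = 20, y1 = 10,
                                           radius = 2),
                                image_shape = c(30L, 30L)), "outside")
  # same spec, same seed: bit-identical noisy image
  noisy <- vessel_tree_spec(data.frame(x0 = 8, y0 = 10, x1 = 32, y1 = 25,
                                       radius = 4),
                            image_shape = c(40L, 40L), seed = 5)
  expect_identical(gen_vessel_image(noisy)$image, gen_vessel_image(noisy)$image)
})
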