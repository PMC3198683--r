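test_that("ranking metrics follow their closed forms with deterministic ties", {
  # two samples per class with exact means (2, 0) and SDs (1, 1)
  a <- 2 + c(-1, 1) / sqrt(2); b <- c(-1, 1) / sqrt(2)
  exprs <- rbind(g1 = c(a, b), g2 = c(b, a))
  cls <- c("A", "A", "B", "B")
  s <- rank_genes(exprs, cls, positive_class = "A")
  expect_equal(unname(s[["g1"]]), 1.0, tolerance = 1e-12)
  expect_equal(unname(s[["g2"]]), -1.0, tolerance = 1e-12)

  # all-zero contrasts: scores 0, order lexicographic by gene id
  flat <- matrix(1, 4, 4, dimnames = list(c("d", "b", "a", "c"), NULL))
  expect_equal(names(rank_genes(flat, cls)), c("a", "b", "c", "d"))

  # t statistic agrees with the pooled t-test per gene
  set.seed(8)
  m <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  cls2 <- rep(c("x", "y"), each = 4)
  ts <- rank_genes(m, cls2, metric = "t_statistic", positive_class = "x",
                   clamp_sd = FALSE)
  for (g in rownames(m)) {
    expect_equal(unname(ts[[g]]), two_sample_t(m[g, 1:4], m[g, 5:8])$t,
                 tolerance = 1e-10)
  }
})

test_that("enrichment score matches the hand-worked 4-gene walk", {
  scores <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1)
  es <- enrichment_score(scores, c("g1", "g3"), weight_p = 1)
  # walk: +3/4, -1/2, +1/4, -1/2 -> (0.75, 0.25, 0.5, 0)
  expect_equal(es$running_sum, c(0.75, 0.25, 0.5, 0), tolerance = 1e-12)
  expect_equal(es$es, 0.75)
  expect_equal(es$extremum_pos, 1L)
  le <- leading_edge(es)
  expect_equal(le$hits_before, 1)
  expect_equal(le$misses_before, 0)
  expect_equal(le$hits_after, 1)
  expect_equal(le$misses_after, 2)

  # set occupying the top of the list attains ES = 1 exactly
  top <- enrichment_score(c(a = 5, b = 4, c = 3, d = 2, e = 1), c("a", "b"))
  expect_equal(top$es, 1)
  expect_error(enrichment_score(scores, c("zz")), "intersect")
  expect_error(enrichment_score(scores, names(scores)), "whole universe")
})

test_that("fast ES equals the literal running-sum walk on random cases", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", seq_len(n))
    k <- sample(2:min(20, n - 1), 1)
    setg <- sample(names(scores), k)
    p <- sample(c(0, 1, 1.5), 1)
    es <- enrichment_score(scores, setg, weight_p = p)
    expect_equal(es$es, oracle_es(scores, setg, p), tolerance = 1e-12)
    expect_true(es$es >= -1 && es$es <= 1)
    expect_lt(abs(es$running_sum[n]), 1e-9)  # walk terminates at zero
    # reversing the list negates the score
    rev_scores <- rev(-scores)
    expect_equal(enrichment_score(rev_scores, setg, weight_p = p)$es, -es$es,
                 tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  scores <- sort(rnorm(300), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:300)
  for (k in c(5, 20, 60)) {
    setg <- sample(names(scores), k)
    ours <- enrichment_score(scores, setg, weight_p = 1)$es
    theirs <- fgsea::calcGseaStat(scores, selectedStats = match(setg, names(scores)),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("gene-permutation null is seeded and matches exhaustive enumeration", {
  scores <- c(a = 2.5, b = 1.5, c = 0.8, d = -0.3, e = -1.1, f = -2.0)
  n1 <- permutation_null(scores, 2, n_perm = 500, seed = 99)
  expect_identical(n1, permutation_null(scores, 2, n_perm = 500, seed = 99))
  expect_error(permutation_null(scores, 0, 10), "set_size")
  expect_error(permutation_null(scores, 2, 0), "n_perm")

  exact <- oracle_es_null_exhaustive(scores, 2)  # all 15 sets
  big <- permutation_null(scores, 2, n_perm = 5000, seed = 7)
  # each distinct exhaustive value appears at its uniform frequency
  for (v in unique(round(exact, 10))) {
    p_true <- mean(round(exact, 10) == v)
    p_hat <- mean(abs(big - v) < 1e-9)
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))
  }
})

test_that("NES and nominal p behave under normalization conventions", {
  null_es <- c(0.2, 0.4, 0.6, -0.3, -0.5)
  nt <- normalize_and_test(0.4, null_es)
  expect_equal(nt$nes, 0.4 / mean(c(0.2, 0.4, 0.6)))
  expect_equal(nt$nominal_p, 2 / 3)  # null values 0.4 and 0.6 are as extreme
  expect_equal(normalize_and_test(mean(c(0.2, 0.4, 0.6)), null_es)$nes, 1)
  expect_equal(normalize_and_test(0.9, null_es)$nominal_p, 0)  # beyond all nulls
  flg <- normalize_and_test(0.5, c(-0.1, -0.2))
  expect_true(flg$flagged)
  expect_equal(flg$nominal_p, 1 / 3)
  # antisymmetry under sign flip of a symmetric null
  sym <- c(-0.6, -0.4, -0.2, 0.2, 0.4, 0.6)
  expect_equal(normalize_and_test(0.5, sym)$nes, -normalize_and_test(-0.5, sym)$nes)
})

test_that("odds-ratio filter arithmetic, degenerate cells and invariances", {
  expect_equal(leading_edge_odds_ratio(5, 10, 5, 10)$odds_ratio, 1)
  expect_equal(leading_edge_odds_ratio(10, 5, 2, 8)$odds_ratio, 8)
  z <- leading_edge_odds_ratio(3, 7, 0, 12)
  expect_true(z$degenerate)
  expect_equal(z$haldane, (3.5 / 7.5) / (0.5 / 12.5), tolerance = 1e-12)
  expect_error(leading_edge_odds_ratio(0, 0, 0, 0), "zero")
  # scaling both sides by the same factor leaves the OR unchanged
  expect_equal(leading_edge_odds_ratio(20, 10, 4, 16)$odds_ratio,
               leading_edge_odds_ratio(5, 2.5, 1, 4)$odds_ratio)

  df <- data.frame(name = c("p1", "n1", "n2"), NES = c(1.2, -1.5, -2.1),
                   odds_ratio = c(1, 1, 1))
  expect_false(any(filter_results(df)$or_pass))
  expect_true(all(filter_results(df, or_threshold = 0)$or_pass))
  expect_equal(filter_results(df)$name, c("p1", "n2", "n1"))  # NES ordering
})

test_that("run_gsea recovers a planted repressed set on a small bundle", {
  b <- gen_expression(n_genes = 600L, planted = list(planted_set_spec("DOWN", 40L, -1.5)),
                      n_decoy_sets = 20L, decoy_size_range = c(20L, 50L), seed = 11)
  res <- run_gsea(b$exprs, b$classes, b$genesets, n_perm = 400, seed = 3)
  expect_s3_class(res, "gsea_result")
  expect_equal(nrow(res), 21)
  down <- res[res$name == "DOWN", ]
  expect_lt(down$ES, 0)
  expect_equal(res$name[which.min(res$NES)], "DOWN")
  expect_lt(down$FDR_q, 0.05)
  # q-values monotone non-increasing with |NES| within each sign
  neg <- res[!is.na(res$NES) & res$NES < 0, ]
  neg <- neg[order(-abs(neg$NES)), ]
  expect_true(all(diff(neg$FDR_q) >= -1e-12))
  # counts partition the set and the leading edge is inside the set
  expect_equal(down$hits_before + down$hits_after, down$size)
  le <- attr(res, "leading_edge")[["DOWN"]]
  expect_true(all(le %in% b$genesets[["DOWN"]]))
  # determinism of the full run
  res2 <- run_gsea(b$exprs, b$classes, b$genesets, n_perm = 400, seed = 3)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})
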