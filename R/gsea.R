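# Gene-set enrichment with a gene-permutation null and a leading-edge
# odds-ratio filter. The running-sum enrichment score follows the classic
# weighted construction (hit increments proportional to |score|^p, miss
# decrements 1/(N - Nh)); the null is built by drawing random gene sets of
# matched size from the ranked universe, the mode recommended when per-class
# sample counts are too small for phenotype permutation. Each set's result
# additionally carries the odds of set membership before versus after the
# leading-edge boundary, the post-hoc filter applied at OR > 2.

#' Rank genes by differential expression between two classes
#'
#' Scores are oriented so that a positive score means higher expression in
#' `positive_class` (by default the second class label, i.e. the treatment
#' group); sets repressed in that class therefore accumulate negative
#' enrichment. Ties are broken lexicographically by gene identifier so the
#' ranking is deterministic.
#'
#' @param exprs log-scale expression matrix, genes x samples.
#' @param classes per-sample class labels (exactly two distinct).
#' @param metric `"signal_to_noise"` (`(m1 - m2) / (s1 + s2)`),
#'   `"t_statistic"` (pooled-variance t) or `"log2_ratio"` (difference of
#'   class means on the log scale).
#' @param positive_class class whose higher expression maps to positive
#'   scores.
#' @param clamp_sd logical; floor each class SD at `0.2 * |class mean|` (0.2
#'   when the mean is 0), the usual small-sample variance guard for the
#'   signal-to-noise metric.
#' @return Named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(exprs, classes,
                       metric = c("signal_to_noise", "t_statistic", "log2_ratio"),
                       positive_class = NULL, clamp_sd = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(exprs), ncol(exprs) == length(classes))
  lev <- unique(as.character(classes))
  if (length(lev) != 2L) stop_param("need exactly two classes")
  positive_class <- positive_class %||% lev[2L]
  if (!positive_class %in% lev) stop_param("positive_class not among class labels")
  i1 <- which(classes == positive_class)
  i2 <- which(classes != positive_class)
  if (metric != "log2_ratio" && (length(i1) < 2L || length(i2) < 2L) && !clamp_sd) {
    stop_param("SD-based metrics need >= 2 samples per class (or clamp_sd = TRUE)")
  }
  m1 <- rowMeans(exprs[, i1, drop = FALSE])
  m2 <- rowMeans(exprs[, i2, drop = FALSE])
  row_sd <- function(x) {
    if (ncol(x) < 2L) return(rep(NA_real_, nrow(x)))
    sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L))
  }
  s1 <- row_sd(exprs[, i1, drop = FALSE])
  s2 <- row_sd(exprs[, i2, drop = FALSE])
  if (clamp_sd) {
    floor1 <- ifelse(m1 == 0, 0.2, 0.2 * abs(m1))
    floor2 <- ifelse(m2 == 0, 0.2, 0.2 * abs(m2))
    s1 <- pmax(ifelse(is.na(s1), 0, s1), floor1)
    s2 <- pmax(ifelse(is.na(s2), 0, s2), floor2)
  }
  score <- switch(metric,
    signal_to_noise = (m1 - m2) / (s1 + s2),
    t_statistic = {
      n1 <- length(i1); n2 <- length(i2)
      sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
      sp <- pmax(sp, 1e-12)
      (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    },
    log2_ratio = m1 - m2)
  names(score) <- rownames(exprs)
  score[order(-score, names(score))]
}

# Core enrichment-score statistic from sorted hit positions only. Between
# hits the running sum falls linearly, so its extrema occur either just after
# a hit (R) or just before one (L); scanning those 2k candidates gives the
# exact extremum of the full N-step walk in O(k).
es_stat <- function(pos, w, n_universe) {
  k <- length(pos)
  w <- unname(w)
  tot <- sum(w)
  if (tot <= 0) { w <- rep(1, k); tot <- k }
  cw <- cumsum(w) / tot
  d <- 1 / (n_universe - k)
  drift <- (pos - seq_len(k)) * d
  upper <- cw - drift                 # value just after hit i
  lower <- c(0, cw[-k]) - drift       # value just before hit i
  i_max <- which.max(upper); i_min <- which.min(lower)
  # an exact tie between the two extrema resolves to the positive side; the
  # tolerance keeps the choice stable under floating-point summation order
  if (upper[i_max] >= -lower[i_min] - 1e-12) {
    list(es = upper[i_max], i_star = i_max, positive = TRUE)
  } else {
    list(es = lower[i_min], i_star = i_min, positive = FALSE)
  }
}

#' Running-sum enrichment score of a gene set
#'
#' @param scores named numeric vector of ranking scores, sorted descending
#'   (as returned by [rank_genes()]).
#' @param gene_set character vector of member genes.
#' @param weight_p hit-weight exponent p (>= 0); 0 gives the unweighted
#'   Kolmogorov-Smirnov walk, 1 the classic weighted statistic.
#' @return List of class `enrichment_score`: `es`, `extremum_pos` (list
#'   position of the signed extremum), `hit_positions`, `running_sum` (full
#'   length-N walk) and `n_universe`.
#' @export
enrichment_score <- function(scores, gene_set, weight_p = 1) {
  stopifnot(!is.null(names(scores)), weight_p >= 0)
  n <- length(scores)
  pos <- sort(match(unique(gene_set), names(scores)))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) stop_param("gene set does not intersect the ranked universe")
  if (length(pos) == n) stop_param("gene set covers the whole universe (no misses)")
  w <- abs(scores[pos])^weight_p
  st <- es_stat(pos, w, n)
  steps <- rep(-1 / (n - length(pos)), n)
  tot <- sum(w); if (tot <= 0) { w <- rep(1, length(pos)); tot <- length(pos) }
  steps[pos] <- w / tot
  running <- cumsum(steps)
  extremum_pos <- if (st$positive) pos[st$i_star] else pos[st$i_star] - 1L
  structure(list(es = st$es, extremum_pos = extremum_pos,
                 i_star = st$i_star, positive = st$positive,
                 hit_positions = pos, running_sum = running, n_universe = n,
                 weight_p = weight_p),
            class = "enrichment_score")
}

#' Leading-edge membership and before/after contingency counts
#'
#' The leading edge is the stretch of the ranked list between its relevant
#' end and the enrichment-score extremum: for a positive ES, list positions
#' from the start to the extremum; for a negative ES, from the extremum to
#' the end. Counts partition both set members (hits) and non-members
#' (misses) into the leading-edge ("before") side and the remainder
#' ("after").
#'
#' @param es an [enrichment_score()] result.
#' @return List with `leading_edge` (member list positions), `hits_before`,
#'   `misses_before`, `hits_after`, `misses_after`.
#' @export
leading_edge <- function(es) {
  stopifnot(inherits(es, "enrichment_score"))
  if (es$es == 0) stop_param("leading edge is undefined for ES = 0")
  n <- es$n_universe; k <- length(es$hit_positions)
  if (es$positive) {
    boundary <- es$hit_positions[es$i_star]
    hb <- es$i_star
    mb <- boundary - hb
    le <- es$hit_positions[seq_len(hb)]
  } else {
    boundary <- es$hit_positions[es$i_star]  # first hit inside the leading edge
    hb <- k - es$i_star + 1L
    mb <- (n - boundary + 1L) - hb
    le <- es$hit_positions[seq(es$i_star, k)]
  }
  list(leading_edge = le, hits_before = hb, misses_before = mb,
       hits_after = k - hb, misses_after = (n - k) - mb)
}

#' Gene-permutation null distribution of the enrichment score
#'
#' Each permutation draws a uniform random gene set of the same size from the
#' ranked universe and records its enrichment score -- the "permute by gene"
#' null recommended for very small sample sizes, where phenotype permutation
#' is degenerate.
#'
#' @param scores named descending score vector.
#' @param set_size size of the random sets.
#' @param n_perm number of permutations (default 5000).
#' @param weight_p hit-weight exponent.
#' @param seed integer seed (optional; permutations continue the current RNG
#'   stream when NULL).
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(scores, set_size, n_perm = 5000L, weight_p = 1,
                             seed = NULL) {
  n <- length(scores)
  if (set_size < 1L || set_size >= n) stop_param("set_size must lie in [1, universe)")
  if (n_perm < 1L) stop_param("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  absw <- abs(scores)^weight_p
  vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(n, set_size))
    es_stat(pos, absw[pos], n)$es
  }, numeric(1L))
}

#' Normalize an enrichment score against its null and compute the nominal p
#'
#' NES divides the ES by the mean magnitude of same-sign null scores; the
#' nominal p-value is the fraction of same-sign null scores at least as
#' extreme. When no null score shares the sign of the ES the p-value falls
#' back to `1 / (n_perm + 1)` and the result is flagged.
#'
#' @param es observed enrichment score (scalar).
#' @param null_es numeric vector of null enrichment scores.
#' @return List with `nes`, `nominal_p` and logical `flagged`.
#' @export
normalize_and_test <- function(es, null_es) {
  if (length(null_es) == 0L) stop_param("empty null sample")
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0L) {
    return(list(nes = NA_real_, nominal_p = 1 / (length(null_es) + 1),
                flagged = TRUE))
  }
  list(nes = es / mean(abs(same)),
       nominal_p = mean(abs(same) >= abs(es)),
       flagged = FALSE)
}

# Normalize a null ES vector by its own signed means (for FDR/FWER).
normalize_null <- function(null_es) {
  pos_mean <- mean(null_es[null_es >= 0])
  neg_mean <- mean(abs(null_es[null_es < 0]))
  out <- null_es
  out[null_es >= 0] <- null_es[null_es >= 0] / pos_mean
  out[null_es < 0] <- null_es[null_es < 0] / neg_mean
  out
}

#' GSEA-style FDR q-values and FWER p-values from a null NES matrix
#'
#' The q-value of a set with normalized score NES* is the ratio of the null
#' tail fraction to the observed tail fraction at NES*, computed separately
#' for positive and negative scores over the pooled null, capped at 1 and
#' monotonized so that q never decreases as |NES| decreases. The
#' family-wise error p-value compares NES* with the per-permutation extreme
#' (maximum positive / minimum negative) NES across all sets.
#'
#' @param nes_obs numeric vector of observed NES (NA allowed for flagged
#'   sets).
#' @param nes_null matrix of null NES, permutations x sets.
#' @return Data frame with `FDR_q` and `FWER_p` per set.
#' @export
fdr_fwer <- function(nes_obs, nes_null) {
  stopifnot(is.matrix(nes_null), ncol(nes_null) == length(nes_obs))
  null_all <- as.vector(nes_null)
  null_pos <- null_all[null_all >= 0]
  null_neg <- null_all[null_all < 0]
  obs_pos <- nes_obs[!is.na(nes_obs) & nes_obs >= 0]
  obs_neg <- nes_obs[!is.na(nes_obs) & nes_obs < 0]
  row_max <- apply(nes_null, 1L, function(r) max(c(r[r >= 0], 0)))
  row_min <- apply(nes_null, 1L, function(r) min(c(r[r < 0], 0)))
  q <- fw <- rep(NA_real_, length(nes_obs))
  for (i in seq_along(nes_obs)) {
    s <- nes_obs[i]
    if (is.na(s)) next
    if (s >= 0) {
      num <- if (length(null_pos)) mean(null_pos >= s) else 0
      den <- mean(obs_pos >= s)
      fw[i] <- mean(row_max >= s)
    } else {
      num <- if (length(null_neg)) mean(null_neg <= s) else 0
      den <- mean(obs_neg <= s)
      fw[i] <- mean(row_min <= s)
    }
    q[i] <- min(1, num / den)
  }
  # monotonize within each sign: a more extreme |NES| never has a larger q
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(!is.na(nes_obs) & nes_obs >= 0) else which(!is.na(nes_obs) & nes_obs < 0)
    if (length(idx) < 2L) next
    ord <- idx[order(-abs(nes_obs[idx]))]          # most extreme first
    q[ord] <- rev(cummin(rev(q[ord])))             # step-up monotonization
  }
  data.frame(FDR_q = q, FWER_p = fw)
}

#' Leading-edge odds ratio
#'
#' `OR = (hits_before / misses_before) / (hits_after / misses_after)`. A zero
#' denominator in either odds yields an infinity (or zero) flag; a
#' Haldane-corrected companion (0.5 added to every cell) is always reported
#' alongside.
#'
#' @param hits_before,misses_before,hits_after,misses_after non-negative
#'   counts partitioning set members and non-members at the leading-edge
#'   boundary.
#' @return List with `odds_ratio`, logical `degenerate` (any zero cell made a
#'   ratio undefined or infinite) and `haldane` (corrected OR).
#' @examples
#' leading_edge_odds_ratio(10, 5, 2, 8)  # (10/5)/(2/8) = 8
#' @export
leading_edge_odds_ratio <- function(hits_before, misses_before,
                                    hits_after, misses_after) {
  cells <- c(hits_before, misses_before, hits_after, misses_after)
  if (any(cells < 0)) stop_param("counts must be non-negative")
  if (all(cells == 0)) stop_param("all four counts are zero")
  haldane <- ((hits_before + 0.5) / (misses_before + 0.5)) /
             ((hits_after + 0.5) / (misses_after + 0.5))
  or <- (hits_before / misses_before) / (hits_after / misses_after)
  degenerate <- !is.finite(or) || or == 0
  list(odds_ratio = or, degenerate = degenerate, haldane = haldane)
}

#' Run the full gene-set enrichment analysis
#'
#' Ranks genes, computes each set's enrichment score and leading-edge
#' contingency, builds a seeded gene-permutation null per set, and derives
#' NES, nominal p, FDR q, FWER p and the leading-edge odds ratio.
#'
#' @param exprs log-scale expression matrix, genes x samples.
#' @param classes per-sample class labels (two classes).
#' @param genesets named list of gene-identifier vectors.
#' @param metric ranking metric, see [rank_genes()].
#' @param n_perm gene permutations per set (default 5000).
#' @param weight_p hit-weight exponent (default 1).
#' @param seed integer seed for the permutation null.
#' @param min_size sets smaller than this within the universe are dropped.
#' @param positive_class forwarded to [rank_genes()].
#' @return Object of class `gsea_result`: a data frame with one row per set
#'   (`name`, `size`, `ES`, `NES`, `nominal_p`, `FDR_q`, `FWER_p`,
#'   `hits_before`, `misses_before`, `hits_after`, `misses_after`,
#'   `odds_ratio`, `odds_ratio_haldane`, `or_degenerate`, `flagged`), sorted
#'   by NES descending, with the per-set leading-edge gene lists in
#'   `attr(, "leading_edge")` and the ranked scores in `attr(, "ranking")`.
#' @export
run_gsea <- function(exprs, classes, genesets,
                     metric = "signal_to_noise", n_perm = 5000L, weight_p = 1,
                     seed = 1L, min_size = 2L, positive_class = NULL) {
  scores <- rank_genes(exprs, classes, metric, positive_class = positive_class)
  n <- length(scores)
  genesets <- lapply(genesets, function(g) intersect(unique(g), names(scores)))
  genesets <- genesets[lengths(genesets) >= min_size & lengths(genesets) < n]
  if (length(genesets) == 0L) stop_param("no gene set intersects the universe")
  set.seed(seed)
  absw <- abs(scores)^weight_p

  res <- vector("list", length(genesets))
  nes_null <- matrix(NA_real_, n_perm, length(genesets))
  for (s in seq_along(genesets)) {
    es <- enrichment_score(scores, genesets[[s]], weight_p)
    le <- leading_edge(es)
    or <- leading_edge_odds_ratio(le$hits_before, le$misses_before,
                                  le$hits_after, le$misses_after)
    k <- length(es$hit_positions)
    null_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(n, k))
      es_stat(pos, absw[pos], n)$es
    }, numeric(1L))
    nt <- normalize_and_test(es$es, null_es)
    nes_null[, s] <- normalize_null(null_es)
    res[[s]] <- list(
      row = data.frame(name = names(genesets)[s], size = k, ES = es$es,
                       NES = nt$nes, nominal_p = nt$nominal_p,
                       hits_before = le$hits_before, misses_before = le$misses_before,
                       hits_after = le$hits_after, misses_after = le$misses_after,
                       odds_ratio = or$odds_ratio, odds_ratio_haldane = or$haldane,
                       or_degenerate = or$degenerate, flagged = nt$flagged),
      le_genes = names(scores)[le$leading_edge])
  }
  tab <- do.call(rbind, lapply(res, `[[`, "row"))
  qf <- fdr_fwer(tab$NES, nes_null)
  tab$FDR_q <- qf$FDR_q
  tab$FWER_p <- qf$FWER_p
  le_list <- stats::setNames(lapply(res, `[[`, "le_genes"), tab$name)
  ord <- order(-tab$NES)
  tab <- tab[ord, c("name", "size", "ES", "NES", "nominal_p", "FDR_q", "FWER_p",
                    "hits_before", "misses_before", "hits_after", "misses_after",
                    "odds_ratio", "odds_ratio_haldane", "or_degenerate", "flagged")]
  rownames(tab) <- NULL
  structure(tab, leading_edge = le_list[tab$name], ranking = scores,
            n_perm = n_perm, metric = metric, weight_p = weight_p, seed = seed,
            class = c("gsea_result", "data.frame"))
}

#' Filter and order an enrichment table by the odds-ratio criterion
#'
#' Splits results by enrichment sign, sorts by NES, and flags the sets whose
#' leading-edge odds ratio exceeds the threshold -- the post-hoc filter
#' applied because the nominal p is uninformative under a gene-permutation
#' null and NES is biased toward larger sets.
#'
#' @param results a `gsea_result` (or compatible data frame with `NES` and
#'   `odds_ratio` columns).
#' @param or_threshold odds-ratio cutoff (default 2).
#' @return Data frame with a logical `or_pass` column, positive sets first
#'   (NES descending), then negative sets (NES ascending).
#' @export
filter_results <- function(results, or_threshold = 2.0) {
  df <- as.data.frame(results)
  df$or_pass <- df$odds_ratio > or_threshold
  pos <- df[df$NES >= 0 | is.na(df$NES), , drop = FALSE]
  neg <- df[!is.na(df$NES) & df$NES < 0, , drop = FALSE]
  out <- rbind(pos[order(-pos$NES), , drop = FALSE],
               neg[order(neg$NES), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write an enrichment report in the classic tab-separated layout
#'
#' Columns: NAME, SIZE, ES, NES, NOM p-val, FDR q-val, FWER p-val,
#' oddsRatios. A companion `<path>.leading_edge.tsv` lists each set's
#' leading-edge genes.
#'
#' @param results a `gsea_result`.
#' @param path output TSV path.
#' @param or_threshold odds-ratio filter threshold recorded in the report.
#' @return Invisibly, `path`.
#' @export
write_gsea_report <- function(results, path, or_threshold = 2.0) {
  df <- filter_results(results, or_threshold)
  out <- data.frame(NAME = df$name, SIZE = df$size,
                    ES = sprintf("%.4f", df$ES), NES = sprintf("%.4f", df$NES),
                    `NOM p-val` = sprintf("%.4f", df$nominal_p),
                    `FDR q-val` = sprintf("%.4f", df$FDR_q),
                    `FWER p-val` = sprintf("%.4f", df$FWER_p),
                    oddsRatios = ifelse(df$or_degenerate,
                                        sprintf("Inf (Haldane %.4f)", df$odds_ratio_haldane),
                                        sprintf("%.4f", df$odds_ratio)),
                    `OR>threshold` = df$or_pass, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  le <- attr(results, "leading_edge")
  if (!is.null(le)) {
    le_df <- data.frame(NAME = names(le),
                        LEADING_EDGE = vapply(le, paste, character(1L), collapse = ","))
    utils::write.table(le_df, paste0(path, ".leading_edge.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA result: %d gene sets, %d gene permutations, metric = %s\n",
              nrow(x), attr(x, "n_perm"), attr(x, "metric")))
  df <- as.data.frame(x)
  show <- df[, c("name", "size", "ES", "NES", "nominal_p", "FDR_q", "FWER_p",
                 "odds_ratio")]
  print(utils::head(show, 10L), digits = 4)
  if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more sets\n")
  invisible(x)
}
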