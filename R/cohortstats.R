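# Outcome statistics for the 4-arm xenograft cohort: exact tests on metastasis
# incidence, rank-based comparison of tumor weights, and the summary rule used
# for multiply-repeated assays.

#' Fisher's exact test for a 2x2 contingency table
#'
#' Computes the exact hypergeometric tail probability for a 2x2 table of
#' counts (rows = treatment arms, columns = outcome present/absent). The
#' one-sided alternatives are tail sums of the hypergeometric distribution of
#' the top-left cell given fixed margins; the two-sided p-value follows the
#' point-probability convention (sum of the probabilities of all tables, at
#' the observed margins, whose point probability does not exceed that of the
#' observed table).
#'
#' @param table 2x2 integer matrix of non-negative counts, or a length-4
#'   vector `(a, b, c, d)` filled row-wise.
#' @param alternative `"two.sided"`, `"greater"` (odds of outcome higher in
#'   row 1) or `"less"`.
#' @return An object of class `fisher2x2`: list with `p.value`, `alternative`
#'   and the observed `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(12, 1, 8, 9), 2, byrow = TRUE), "greater")
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, 2L, byrow = TRUE)
  if (any(dim(table) != 2L)) stop_param("need a 2x2 table")
  x <- as.vector(t(table))
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop_param("counts must be non-negative integers")
  }
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    stop_param("Fisher's exact test is undefined for a table with a zero margin")
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- switch(alternative,
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]),
    two.sided = {
      # guard against floating-point ties at the observed point probability
      rel_err <- 1 + 1e-7
      sum(dens[dens <= dens[support == a] * rel_err])
    })
  p <- min(p, 1)
  structure(list(p.value = p, alternative = alternative,
                 table = matrix(x, 2L, 2L, byrow = TRUE)),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat("Fisher's exact test (2x2), alternative =", x$alternative, "\n")
  print(x$table)
  cat(sprintf("p = %.4g\n", x$p.value))
  invisible(x)
}

#' Kruskal-Wallis rank test on per-arm tumor weights
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution on
#' k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors, one per arm; missing values dropped.
#' @return List with `H`, `df` and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop_param("every group must be nonempty")
  if (length(unique(unlist(groups))) == 1L) {
    # all observations tied: no rank variation, H defined as 0
    return(list(H = 0, df = length(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = unname(kt$p.value))
}

#' Per-arm metastasis incidence summary
#'
#' @param cohort data frame with columns `arm` and logical `metastasis`.
#' @param arm_order optional character vector fixing the arm order of the
#'   output (defaults to order of first appearance).
#' @return Data frame with per-arm `count_met`, `n` and integer `percent`
#'   (rounded half-up).
#' @examples
#' ch <- data.frame(arm = rep(c("ctrl", "combo"), c(13, 15)),
#'                  metastasis = rep(c(TRUE, FALSE, TRUE, FALSE), c(12, 1, 2, 13)))
#' incidence_summary(ch)
#' @export
incidence_summary <- function(cohort, arm_order = NULL) {
  stopifnot(all(c("arm", "metastasis") %in% names(cohort)))
  arm_order <- arm_order %||% unique(cohort$arm)
  if (!all(cohort$arm %in% arm_order)) stop_param("arm_order must cover all arms")
  n <- table(factor(cohort$arm, levels = arm_order))
  if (any(n == 0L)) stop_param("empty arm in cohort")
  met <- tapply(cohort$metastasis, factor(cohort$arm, levels = arm_order), sum)
  data.frame(arm = arm_order,
             count_met = as.integer(met),
             n = as.integer(n),
             percent = as.integer(round_half_up(100 * as.integer(met) / as.integer(n))),
             row.names = NULL)
}

#' Per-arm tumor-weight reduction relative to the control arm
#'
#' Reduction is `100 * (1 - mean(arm) / mean(control))`, the convention of
#' expressing treated tumor weights as a percentage of control tumors.
#'
#' @param weights_by_arm named list of numeric weight vectors.
#' @param control name of the control arm (default first element).
#' @return Data frame with per-arm `mean_weight`, `percent_of_control` and
#'   `percent_reduction`.
#' @export
percent_of_control <- function(weights_by_arm, control = names(weights_by_arm)[1L]) {
  stopifnot(is.list(weights_by_arm), control %in% names(weights_by_arm))
  means <- vapply(weights_by_arm, function(w) mean(w, na.rm = TRUE), numeric(1L))
  if (!is.finite(means[[control]]) || means[[control]] == 0) {
    stop_param("control arm mean weight is zero or undefined")
  }
  poc <- 100 * means / means[[control]]
  data.frame(arm = names(weights_by_arm), mean_weight = unname(means),
             percent_of_control = unname(poc),
             percent_reduction = unname(100 - poc), row.names = NULL)
}

#' Summary of multiply-repeated assays
#'
#' A repeated assay (e.g. an ELISA run several times) is summarized as the
#' mean of the per-assay means with a standard error equal to the square root
#' of the interassay variance (unbiased variance of the per-assay means).
#'
#' @param assay_means numeric vector of per-assay means, length >= 2.
#' @return List with `summary_mean`, `interassay_variance`, `standard_error`
#'   and `n_assays`.
#' @examples
#' repeated_assay_summary(c(1, 3))  # mean 2, SE sqrt(2)
#' @export
repeated_assay_summary <- function(assay_means) {
  assay_means <- assay_means[!is.na(assay_means)]
  if (length(assay_means) < 2L) stop_param("need at least two assay means")
  v <- stats::var(assay_means)
  list(summary_mean = mean(assay_means), interassay_variance = v,
       standard_error = sqrt(v), n_assays = length(assay_means))
}

#' Two-sided pooled-variance two-sample t-test
#'
#' Degenerate inputs are resolved deterministically: if the pooled variance is
#' zero and the sample means are equal the test is reported as t = 0, p = 1;
#' if the means differ with zero pooled variance the result carries a
#' `degenerate` flag and an infinite statistic.
#'
#' @param x,y numeric vectors, each with at least two values.
#' @return List with `t`, `df`, `p.value` and logical `degenerate`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop_param("each sample needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  pooled_var <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = df, p.value = 1, degenerate = FALSE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p.value = 0,
                degenerate = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(pooled_var * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p.value = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}
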