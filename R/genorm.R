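# Reference-gene stability ranking and normalization for qPCR panels, after
# the geNorm procedure: relative quantities from Cq, pairwise-log-ratio
# stability values M, iterative exclusion of the least stable reference,
# pairwise variation V(n, n+1), and geometric-mean normalization factors.

#' Relative quantities from quantification cycles
#'
#' Per gene, `RQ = E^(min(Cq) - Cq)`, so the best-expressed sample of each
#' gene has RQ = 1 and one Cq cycle corresponds to one factor of the
#' amplification efficiency E (2 for perfect doubling).
#'
#' @param cq numeric matrix of Cq values, genes x samples.
#' @param efficiency amplification efficiency per gene (scalar or per-gene
#'   vector), in (1, 2].
#' @return Matrix of relative quantities, same shape as `cq`.
#' @examples
#' relative_quantity(matrix(c(20, 21, 23), 1, dimnames = list("g", NULL)))
#' @export
relative_quantity <- function(cq, efficiency = 2) {
  stopifnot(is.matrix(cq))
  if (any(!is.finite(cq))) stop_param("Cq values must be finite")
  if (any(efficiency <= 1) || any(efficiency > 2)) stop_param("efficiency must lie in (1, 2]")
  e <- rep_len(efficiency, nrow(cq))
  rq <- e^(apply(cq, 1L, min) - cq)
  dimnames(rq) <- dimnames(cq)
  rq
}

#' geNorm stability value M for each candidate reference gene
#'
#' `M_j` is the mean, over all other candidates k, of the standard deviation
#' across samples of `log2(RQ_j / RQ_k)`. A perfectly stable pair has a
#' constant log-ratio and contributes 0; larger M means less stable.
#'
#' @param rq relative-quantity matrix restricted to candidate reference genes
#'   (genes x samples), all values positive.
#' @return Named numeric vector of M values.
#' @export
pairwise_stability <- function(rq) {
  stopifnot(is.matrix(rq), nrow(rq) >= 2L, ncol(rq) >= 2L)
  if (any(rq <= 0)) stop_param("relative quantities must be positive")
  lg <- log2(rq)
  n <- nrow(lg)
  m <- vapply(seq_len(n), function(j) {
    mean(vapply(setdiff(seq_len(n), j),
                function(k) stats::sd(lg[j, ] - lg[k, ]), numeric(1L)))
  }, numeric(1L))
  stats::setNames(m, rownames(rq))
}

#' Geometric-mean normalization factor per sample
#'
#' @param rq relative-quantity matrix (genes x samples).
#' @param references character vector (or indices) of reference genes to use;
#'   at least two.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factor <- function(rq, references = rownames(rq)) {
  sel <- rq[references, , drop = FALSE]
  if (nrow(sel) < 2L) stop_param("need at least two selected references")
  if (any(sel <= 0)) stop_param("relative quantities must be positive")
  apply(sel, 2L, geometric_mean)
}

#' Rank candidate reference genes by iterative exclusion
#'
#' Repeatedly removes the gene with the highest stability value M and
#' recomputes on the remainder until two genes are left. The pairwise
#' variation `V(n, n+1)` is the standard deviation across samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n` uses the n most stable genes; small
#' V(n, n+1) means the (n+1)-th gene adds little.
#'
#' Ties in the maximal M are broken by excluding the gene that appears later
#' in the input row order, so the ranking is deterministic.
#'
#' @param rq relative-quantity matrix restricted to candidate references
#'   (>= 3 genes).
#' @return List of class `genorm_ranking`: `exclusion_order` (least stable
#'   first, final stable pair last, in input order), `M_final` (M at each
#'   gene's exclusion step; the final pair shares its step's values),
#'   `stepwise_M` (list of M vectors per elimination round) and `V` (named
#'   vector, `V2_3`, `V3_4`, ...).
#' @export
rank_reference_genes <- function(rq) {
  stopifnot(is.matrix(rq), nrow(rq) >= 3L)
  remaining <- rownames(rq) %||% as.character(seq_len(nrow(rq)))
  rownames(rq) <- remaining
  exclusion <- character(0L)
  m_at_exclusion <- numeric(0L)
  stepwise <- list()
  while (length(remaining) > 2L) {
    m <- pairwise_stability(rq[remaining, , drop = FALSE])
    stepwise[[length(stepwise) + 1L]] <- m
    worst <- max(m)
    # tie-break: later input-order gene leaves first
    drop_gene <- remaining[max(which(m >= worst - 1e-12))]
    exclusion <- c(exclusion, drop_gene)
    m_at_exclusion <- c(m_at_exclusion, m[[drop_gene]])
    remaining <- setdiff(remaining, drop_gene)
  }
  m_last <- pairwise_stability(rq[remaining, , drop = FALSE])
  stepwise[[length(stepwise) + 1L]] <- m_last
  # stability ranking: most stable first
  ranking <- rev(c(exclusion, remaining))
  v <- numeric(0L)
  ngenes <- nrow(rq)
  for (n in 2L:(ngenes - 1L)) {
    nf_n <- normalization_factor(rq, ranking[seq_len(n)])
    nf_n1 <- normalization_factor(rq, ranking[seq_len(n + 1L)])
    v[sprintf("V%d_%d", n, n + 1L)] <- stats::sd(log2(nf_n / nf_n1))
  }
  structure(list(exclusion_order = c(exclusion, remaining),
                 ranking = ranking,
                 M_final = stats::setNames(c(m_at_exclusion, m_last[remaining]),
                                           c(exclusion, remaining)),
                 stepwise_M = stepwise, V = v),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm reference ranking (most stable first):\n ",
      paste(x$ranking, collapse = " > "), "\n")
  cat("M at exclusion / final step:\n")
  print(round(x$M_final, 4))
  cat("Pairwise variation V(n, n+1):\n")
  print(round(x$V, 4))
  invisible(x)
}

#' Normalize target-gene quantities by per-sample normalization factors
#'
#' @param rq_targets relative-quantity matrix of target genes (genes x
#'   samples).
#' @param nf per-sample normalization factor vector, same samples in the same
#'   order.
#' @return Normalized expression matrix (`rq / NF` per sample).
#' @export
normalize_targets <- function(rq_targets, nf) {
  stopifnot(is.matrix(rq_targets))
  if (ncol(rq_targets) != length(nf)) stop_param("sample sets of targets and NF differ")
  if (!is.null(colnames(rq_targets)) && !is.null(names(nf)) &&
      !identical(colnames(rq_targets), names(nf))) {
    stop_param("sample names of targets and NF differ")
  }
  sweep(rq_targets, 2L, nf, `/`)
}

#' Full geNorm analysis of a Cq plate
#'
#' Converts Cq to relative quantities, ranks the reference genes, computes the
#' normalization factor (all references by default, matching the six-gene
#' normalization of the emulated study; `n_select` restricts to the n most
#' stable) and normalizes the targets. When a two-group sample split is given,
#' each target is compared between groups with a pooled-variance t-test on
#' log2 normalized quantities.
#'
#' @param cq Cq matrix, genes x samples.
#' @param roles per-gene role, `"reference"` or `"target"`.
#' @param efficiency amplification efficiency (scalar or per gene).
#' @param n_select optional number of most stable references to use for the
#'   normalization factor (default: all references).
#' @param group optional per-sample two-level grouping for target t-tests.
#' @return List of class `genorm_result`: `ranking` (a `genorm_ranking`),
#'   `M`, `V`, `NF`, `normalized_targets`, and `target_tests` (data frame or
#'   NULL).
#' @export
genorm_analysis <- function(cq, roles, efficiency = 2, n_select = NULL,
                            group = NULL) {
  stopifnot(nrow(cq) == length(roles), all(roles %in% c("reference", "target")))
  rq <- relative_quantity(cq, efficiency)
  refs <- rownames(rq)[roles == "reference"]
  if (length(refs) < 3L) stop_param("need at least three reference genes")
  ranking <- rank_reference_genes(rq[refs, , drop = FALSE])
  use <- if (is.null(n_select)) refs else ranking$ranking[seq_len(n_select)]
  nf <- normalization_factor(rq, use)
  targets <- rq[roles == "target", , drop = FALSE]
  norm <- normalize_targets(targets, nf)
  tests <- NULL
  if (!is.null(group)) {
    lev <- unique(group)
    if (length(lev) != 2L) stop_param("group must have exactly two levels")
    tests <- do.call(rbind, lapply(rownames(norm), function(g) {
      tt <- two_sample_t(log2(norm[g, group == lev[1L]]),
                         log2(norm[g, group == lev[2L]]))
      data.frame(gene = g,
                 log2_fc = mean(log2(norm[g, group == lev[2L]])) -
                           mean(log2(norm[g, group == lev[1L]])),
                 t = tt$t, p.value = tt$p.value)
    }))
  }
  structure(list(ranking = ranking, M = ranking$M_final, V = ranking$V,
                 NF = nf, references_used = use, normalized_targets = norm,
                 target_tests = tests),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  print(x$ranking)
  cat("NF computed from:", paste(x$references_used, collapse = ", "), "\n")
  if (!is.null(x$target_tests)) {
    cat("Per-target group comparisons (log2 normalized quantities):\n")
    print(x$target_tests, digits = 3)
  }
  invisible(x)
}
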