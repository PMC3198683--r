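# Independent oracles used across the suite. Each recomputes a quantity by a
# route deliberately different from the package implementation: explicit
# log-factorial enumeration for the exact test, the textbook rank formula for
# Kruskal-Wallis, and a literal N-step running-sum walk for enrichment
# scores.

# Fisher 2x2 by direct enumeration of all tables with the observed margins,
# point probabilities from lchoose arithmetic.
oracle_fisher <- function(a, b, c_, d, alternative) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[support == a]
  switch(alternative,
         greater = sum(p[support >= a]),
         less = sum(p[support <= a]),
         two.sided = sum(p[p <= obs * (1 + 1e-7)]))
}

# Kruskal-Wallis H by the explicit rank formula with tie correction.
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Enrichment score by the literal N-step walk (signed extremum of the
# running sum), independent of the hits-only fast path.
oracle_es <- function(scores, set_genes, p = 1) {
  n <- length(scores)
  hit <- names(scores) %in% set_genes
  w <- abs(scores)^p * hit
  if (sum(w) == 0) w <- hit * 1
  steps <- ifelse(hit, w / sum(w), -1 / (n - sum(hit)))
  walk <- cumsum(steps)
  # signed extremum; an exact max/|min| tie resolves to the positive side
  if (max(walk) >= -min(walk) - 1e-12) max(walk) else min(walk)
}

# Exact null ES distribution of all same-size sets on a small universe.
oracle_es_null_exhaustive <- function(scores, set_size, p = 1) {
  sets <- utils::combn(names(scores), set_size, simplify = FALSE)
  vapply(sets, function(s) oracle_es(scores, s, p), numeric(1))
}

# Binary disk mask used by the morphometry tests.
disk_mask <- function(radius_px, pad = 4L, center_offset = c(0, 0)) {
  n <- 2L * (radius_px + pad) + 1L
  ctr <- (n + 1) / 2 + center_offset
  d <- sqrt(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`))
  d <= radius_px
}
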