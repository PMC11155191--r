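# Independent oracles, written before and kept independent of the
# implementation paths they check.

# Weir & Cockerham (1984) variance components for two populations,
# transcribed from the published formulas one locus at a time.
oracle_wc_theta <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  r <- 2
  n1 <- length(gA); n2 <- length(gB)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Mean pairwise allele difference over all C(2n, 2) sequence pairs.
oracle_pi <- function(g) {
  g <- g[!is.na(g)]
  alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(alleles)
  if (n < 4) return(NA_real_)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Quadratic scan for fractional-overlap interval matching.
oracle_overlap_pairs <- function(A, B, fa, fb, mode) {
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (A$chrom[i] != B$chrom[j]) next
    ov <- min(A$end[i], B$end[j]) - max(A$start[i], B$start[j])
    if (ov <= 0) next
    okA <- ov >= fa * (A$end[i] - A$start[i])
    okB <- ov >= fb * (B$end[j] - B$start[j])
    ok <- if (mode == "either") okA || okB else okA && okB
    if (ok) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# Per-breakpoint window scan.
oracle_window_counts <- function(bp_pos, chrlen, window = 1e6, step = 5e5) {
  starts <- seq(0, chrlen - 1, by = step)
  vapply(starts, function(s) sum(bp_pos >= s & bp_pos < s + window),
         numeric(1))
}

# Exhaustive permutation distribution of theta for a 4-vs-4 split.
oracle_exhaustive_perm_p <- function(g8, obs) {
  splits <- utils::combn(8, 4)
  thetas <- apply(splits, 2, function(a) oracle_wc_theta(g8[a], g8[-a]))
  mean(thetas > obs, na.rm = FALSE)
}

# Exact rank-sum P by enumeration of all group splits (no ties assumed).
oracle_wilcoxon_p <- function(x, y) {
  v <- c(x, y); n1 <- length(x)
  splits <- utils::combn(length(v), n1)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  nulls <- apply(splits, 2, function(ix) sum(r[ix]))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(nulls - mu) >= abs(obs - mu))
}
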