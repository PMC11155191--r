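#' Per-SV association of a phenotype with genotype dosage
#'
#' Simple per-locus ordinary least squares of the phenotype on the
#' alt-allele dosage: slope, its standard error and a two-sided t-test
#' P-value. This is a single-marker score for exercising summary-statistic
#' post-processing (kinship-corrected mixed models are out of scope;
#' [variance_explained()] accepts externally produced beta/se/MAF/N).
#'
#' @param svset an [sv_set()].
#' @param y named phenotype vector (names = sample ids) or a plain vector
#'   in `svset` sample order.
#' @return data.frame of class `assoc_table`: `id`, `beta`, `se`, `p`,
#'   `n`, `maf`; loci with zero dosage variance or fewer than 3 complete
#'   pairs get `NA` and are flagged in `skipped`.
#' @export
per_sv_association <- function(svset, y) {
  if (!is.null(names(y))) y <- y[svset$samples]
  if (length(y) != length(svset$samples))
    stop("phenotype length != sample count")
  g <- svset$genotypes
  L <- ncol(g)
  beta <- se <- p <- maf <- rep(NA_real_, L)
  n <- integer(L)
  for (j in seq_len(L)) {
    ok <- !is.na(g[, j]) & !is.na(y)
    x <- g[ok, j]; yy <- y[ok]
    n[j] <- sum(ok)
    if (n[j] < 3 || stats::var(x) == 0) next
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (yy - mean(yy))) / sxx
    res <- yy - mean(yy) - b * (x - mean(x))
    s2 <- sum(res^2) / (n[j] - 2)
    seb <- sqrt(s2 / sxx)
    tt <- b / seb
    beta[j] <- b; se[j] <- seb
    p[j] <- 2 * stats::pt(-abs(tt), df = n[j] - 2)
    pa <- mean(x) / 2
    maf[j] <- min(pa, 1 - pa)
  }
  out <- data.frame(id = svset$records$id, beta = beta, se = se, p = p,
                    n = n, maf = maf, stringsAsFactors = FALSE)
  attr(out, "skipped") <- out$id[is.na(out$beta)]
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Variance explained by a variant from GWAS summary statistics
#'
#' Computed exactly as the summary-statistic formula
#' `2 b^2 MAF (1-MAF) / (2 b^2 MAF (1-MAF) + 2 N se^2 MAF (1-MAF))`,
#' which simplifies algebraically to `b^2 / (b^2 + N se^2)` (the MAF
#' factor cancels); it is evaluated in the unsimplified form as printed
#' in GWAS practice. Undefined (NA) at `maf = 0`.
#'
#' @param beta effect size estimate(s).
#' @param se standard error(s) of `beta` (> 0).
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size (> 0).
#' @return variance-explained value(s) in \[0, 1\].
#' @export
variance_explained <- function(beta, se, maf, n) {
  stopifnot(all(n > 0), all(se > 0, na.rm = TRUE))
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  num <- 2 * beta^2 * maf * (1 - maf)
  den <- num + 2 * n * se^2 * maf * (1 - maf)
  v <- num / den
  v[!is.na(maf) & maf == 0] <- NA_real_
  v
}

#' Flag significantly associated SVs (top P-value fraction)
#'
#' Significance by ascending-P rank: threshold at rank `ceiling(q * m)` of
#' the ascending order among defined P-values, ties included. Purely
#' deterministic in the P vector.
#'
#' @param assoc an `assoc_table` (or any data.frame with `id` and `p`).
#' @param q flagged fraction (default 0.05).
#' @return list: `ids` (flagged), `threshold`, `q`.
#' @export
significant_svs <- function(assoc, q = 0.05) {
  p <- assoc$p
  def <- which(!is.na(p))
  if (!length(def)) stop("all P-values undefined")
  if (length(def) < 20)
    warning("top-fraction rule on < 20 defined P-values")
  srt <- sort(p[def])
  thr <- srt[ceiling(q * length(def))]
  list(ids = assoc$id[!is.na(p) & p <= thr], threshold = thr, q = q)
}

#' Copy-number call from a delta-delta-CT value
#'
#' qPCR validation rule: values between 1.414 and 2.449 (inclusive
#' bounds) indicate a normal copy number of two.
#'
#' @param ddct numeric vector of delta-delta-CT values (finite).
#' @return character vector, `"two"` or `"not_two"`.
#' @export
ddct_copy_number <- function(ddct) {
  if (any(!is.finite(ddct))) stop("non-finite ddct value")
  ifelse(ddct >= 1.414 & ddct <= 2.449, "two", "not_two")
}
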