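#' Per-site nucleotide diversity for an SV locus
#'
#' Expected pairwise allele difference per locus with the small-sample
#' correction: `pi = n/(n-1) * 2 p (1-p)` where `n = 2 * n_called` haploid
#' sequences. Equivalently, the mean number of allele differences over all
#' `choose(n, 2)` sequence pairs. Undefined (`NA`) when fewer than 2
#' diploid calls are available.
#'
#' @param p alt-allele frequency (vector ok).
#' @param n_called number of diploid samples with a non-missing call.
#' @return numeric vector of per-site pi values.
#' @export
site_pi <- function(p, n_called) {
  n <- 2 * n_called
  out <- ifelse(n >= 4, n / (n - 1) * 2 * p * (1 - p), NA_real_)
  out[is.na(p)] <- NA_real_
  out
}

#' Windowed nucleotide diversity
#'
#' Sums per-site pi over sliding windows. Two conventions are reported
#' side by side because field tools disagree on the denominator:
#' `pi_bp` divides the window's summed pi by the window length in bp,
#' `pi_site` averages over the SV sites in the window.
#'
#' @param svset an [sv_set()].
#' @param meta optional [sample_meta()]; when given with `stratum`, only
#'   that population's samples are used.
#' @param stratum optional population name.
#' @param genome named chromosome lengths (bp); defaults to the span of
#'   the observed loci.
#' @param window window size in bp (default 10 Mb, non-overlapping).
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `pi_sum`,
#'   `pi_bp`, `pi_site` (half-open windows).
#' @export
windowed_pi <- function(svset, meta = NULL, stratum = NULL, genome = NULL,
                        window = 10e6) {
  if (!is.null(stratum)) {
    idx <- meta_index(svset, meta, "population")[[stratum]]
    if (is.null(idx)) stop("unknown population: ", stratum)
    svset <- sv_subset(svset, samples = idx)
  }
  ls <- locus_summary(svset)
  pis <- site_pi(ls$p, ls$n_called)
  iv <- sv_intervals(svset)
  if (is.null(genome)) {
    genome <- tapply(iv$end, iv$chrom, max)
  }
  out <- list()
  for (ch in names(genome)) {
    starts <- seq(0, max(genome[[ch]] - 1, 0), by = window)
    on_ch <- iv$chrom == ch
    mid <- iv$start[on_ch]           # breakpoint-start position indexes a site
    w <- findInterval(mid, starts)
    pi_ch <- pis[on_ch]
    n_sites <- tabulate(w, nbins = length(starts))
    pi_sum <- vapply(seq_along(starts), function(k)
      sum(pi_ch[w == k], na.rm = TRUE), numeric(1))
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = pmin(starts + window, genome[[ch]]),
      n_sites = n_sites, pi_sum = pi_sum,
      pi_bp = pi_sum / pmin(window, genome[[ch]] - starts),
      pi_site = ifelse(n_sites > 0, pi_sum / n_sites, NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Heterozygosity rate
#'
#' Proportion of heterozygous calls among non-missing calls at segregating
#' SV sites within a stratum.
#'
#' @param svset an [sv_set()].
#' @param meta optional [sample_meta()].
#' @param stratum optional population/group/species name (with `grouping`);
#'   default uses all samples.
#' @param grouping metadata column used to resolve `stratum`.
#' @return list: `rate`, `n_het`, `n_called` (denominator), `n_sites`.
#' @export
heterozygosity_rate <- function(svset, meta = NULL, stratum = NULL,
                                grouping = c("population", "group", "species")) {
  if (!is.null(stratum)) {
    grouping <- match.arg(grouping)
    idx <- meta_index(svset, meta, grouping)[[stratum]]
    if (is.null(idx) || !length(idx)) stop("empty stratum: ", stratum)
    svset <- sv_subset(svset, samples = idx)
  }
  g <- svset$genotypes
  ac <- colSums(g, na.rm = TRUE)
  an <- 2 * colSums(!is.na(g))
  seg <- !is.na(ac) & ac > 0 & ac < an
  g <- g[, seg, drop = FALSE]
  n_called <- sum(!is.na(g))
  if (n_called == 0)
    return(list(rate = NA_real_, n_het = 0L, n_called = 0L, n_sites = sum(seg)))
  n_het <- sum(g == 1, na.rm = TRUE)
  list(rate = n_het / n_called, n_het = n_het, n_called = n_called,
       n_sites = sum(seg))
}

# Weir & Cockerham (1984) two-level variance components for r populations,
# computed per locus from dosage matrices. Returns a, b, c vectors.
wc_components <- function(glist) {
  r <- length(glist)
  n <- sapply(glist, function(g) colSums(!is.na(g)))
  p <- sapply(glist, function(g) {
    nn <- colSums(!is.na(g))
    ifelse(nn > 0, colSums(g, na.rm = TRUE) / (2 * nn), NA_real_)
  })
  h <- sapply(glist, function(g) {
    nn <- colSums(!is.na(g))
    ifelse(nn > 0, colSums(g == 1, na.rm = TRUE) / nn, NA_real_)
  })
  if (is.null(dim(n))) { n <- matrix(n, 1); p <- matrix(p, 1); h <- matrix(h, 1) }
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  undef <- apply(n, 1, function(x) any(x < 2)) | is.na(a) |
    (a + b + cc) == 0
  a[undef] <- NA_real_; b[undef] <- NA_real_; cc[undef] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Implements the 1984 diploid two-level estimator from genotype counts
#' (observed heterozygosity enters the within-individual component c).
#' Per-site theta-hat may be negative and is kept unclamped; loci where a
#' population has fewer than 2 called diploids, or where a+b+c = 0
#' (monomorphic across both populations), are undefined and excluded from
#' the genome-wide ratio-of-sums.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @param popA,popB population names.
#' @param grouping metadata column the names refer to.
#' @return list of class `fst_result`: `per_site` (data.frame `id`, `a`,
#'   `b`, `c`, `theta`), `weighted` (ratio of sums), `mean_of_ratios`,
#'   `n_defined`, `n_undefined`.
#' @export
wc_fst <- function(svset, meta, popA, popB,
                   grouping = c("population", "group", "species")) {
  grouping <- match.arg(grouping)
  idx <- meta_index(svset, meta, grouping)
  if (is.null(idx[[popA]])) stop("unknown stratum: ", popA)
  if (is.null(idx[[popB]])) stop("unknown stratum: ", popB)
  gA <- svset$genotypes[idx[[popA]], , drop = FALSE]
  gB <- svset$genotypes[idx[[popB]], , drop = FALSE]
  fst_from_matrices(list(gA, gB), svset$records$id)
}

fst_from_matrices <- function(glist, ids) {
  comp <- wc_components(glist)
  theta <- comp$a / (comp$a + comp$b + comp$c)
  ok <- !is.na(theta)
  weighted <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  structure(list(
    per_site = data.frame(id = ids, a = comp$a, b = comp$b, c = comp$c,
                          theta = theta, stringsAsFactors = FALSE),
    weighted = weighted,
    mean_of_ratios = mean(theta[ok]),
    n_defined = sum(ok), n_undefined = sum(!ok)),
    class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham F_ST: ", x$n_defined, " defined loci (",
      x$n_undefined, " undefined)\n", sep = "")
  cat("  genome-wide weighted (ratio of sums):",
      format(x$weighted, digits = 4), "\n")
  cat("  mean of per-site ratios:            ",
      format(x$mean_of_ratios, digits = 4), "\n")
  invisible(x)
}

#' Global F_ST: per-SV mean of breed-vs-rest theta-hat
#'
#' For each population, theta-hat is computed between that population and
#' all other samples pooled; the per-SV mean over populations is the
#' global F_ST. Populations with an undefined theta-hat at a locus are
#' omitted from that locus's mean.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @param populations which populations to cycle over (default all).
#' @return data.frame `id`, `global_fst`, `n_contrasts`.
#' @export
global_fst <- function(svset, meta, populations = NULL) {
  idx <- meta_index(svset, meta, "population")
  if (is.null(populations)) populations <- names(idx)
  if (length(populations) < 2) stop("need >= 2 populations")
  thetas <- sapply(populations, function(p) {
    rows <- idx[[p]]
    rest <- setdiff(unlist(idx[populations]), rows)
    comp <- wc_components(list(svset$genotypes[rows, , drop = FALSE],
                               svset$genotypes[rest, , drop = FALSE]))
    comp$a / (comp$a + comp$b + comp$c)
  })
  if (is.null(dim(thetas))) thetas <- matrix(thetas, nrow = 1)
  n_contrasts <- rowSums(!is.na(thetas))
  gf <- ifelse(n_contrasts >= 1, rowMeans(thetas, na.rm = TRUE), NA_real_)
  data.frame(id = svset$records$id, global_fst = gf,
             n_contrasts = n_contrasts, stringsAsFactors = FALSE)
}

#' Pairwise LD between two SV loci
#'
#' Squared Pearson correlation of genotype dosages over samples called at
#' both loci (a phase-free, genotype-based r-squared).
#'
#' @param svset an [sv_set()].
#' @param locusA,locusB locus ids or indices.
#' @return r-squared in \[0, 1\], or `NA` if either locus has zero dosage
#'   variance among the jointly called samples.
#' @export
ld_r2 <- function(svset, locusA, locusB) {
  if (is.character(locusA)) locusA <- match(locusA, svset$records$id)
  if (is.character(locusB)) locusB <- match(locusB, svset$records$id)
  gA <- svset$genotypes[, locusA]; gB <- svset$genotypes[, locusB]
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(gA[ok]) == 0 || stats::sd(gB[ok]) == 0) return(NA_real_)
  stats::cor(gA[ok], gB[ok])^2
}

#' LD decay profile within chromosomes
#'
#' Computes genotype-correlation r-squared for all same-chromosome locus
#' pairs up to `max_dist` apart and averages by distance bin.
#'
#' @param svset an [sv_set()].
#' @param max_dist maximum pair distance in bp (default 300 kb).
#' @param bins number of distance bins.
#' @return data.frame `bin_lo`, `bin_hi`, `mean_r2`, `n_pairs`; attribute
#'   `"pairs"` holds the per-pair table (idA, idB, dist, r2).
#' @export
ld_decay_profile <- function(svset, max_dist = 300e3, bins = 30) {
  r <- svset$records
  g <- svset$genotypes
  pair_rows <- list()
  for (ch in unique(r$chrom)) {
    loci <- which(r$chrom == ch)
    if (length(loci) < 2) next
    pos <- r$start[loci]
    cmb <- utils::combn(seq_along(loci), 2)
    d <- abs(pos[cmb[1, ]] - pos[cmb[2, ]])
    keep <- d <= max_dist
    if (!any(keep)) next
    cmb <- cmb[, keep, drop = FALSE]; d <- d[keep]
    r2 <- vapply(seq_len(ncol(cmb)), function(k)
      ld_r2(svset, loci[cmb[1, k]], loci[cmb[2, k]]), numeric(1))
    pair_rows[[ch]] <- data.frame(
      idA = r$id[loci[cmb[1, ]]], idB = r$id[loci[cmb[2, ]]],
      dist = d, r2 = r2, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(idA = character(0), idB = character(0),
               dist = numeric(0), r2 = numeric(0))
  brk <- seq(0, max_dist, length.out = bins + 1)
  bin <- cut(pairs$dist, brk, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin_lo = brk[-length(brk)], bin_hi = brk[-1],
    mean_r2 = vapply(seq_len(bins), function(k)
      mean(pairs$r2[bin == k], na.rm = TRUE), numeric(1)),
    n_pairs = vapply(seq_len(bins), function(k)
      sum(bin == k & !is.na(pairs$r2)), numeric(1)))
  attr(out, "pairs") <- pairs
  rownames(out) <- NULL
  out
}
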