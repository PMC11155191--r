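#' Per-stratum allele frequencies
#'
#' Computes the alt-allele frequency of every SV locus within each stratum
#' of the metadata (population, group or species):
#' `p = sum(alt dosages) / (2 * n_called)`, over non-missing calls only.
#' Strata with no called genotype at a locus get `NA` (undefined), never a
#' silent zero.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table covering every sample.
#' @param grouping `"population"`, `"group"` or `"species"`.
#' @return data.frame of class `freq_table` in long form with columns
#'   `id`, `stratum`, `p`, `n_called`, `maf`, `missing_rate`.
#' @export
allele_frequencies <- function(svset, meta,
                               grouping = c("population", "group", "species")) {
  grouping <- match.arg(grouping)
  idx <- meta_index(svset, meta, grouping)
  out <- lapply(names(idx), function(st) {
    g <- svset$genotypes[idx[[st]], , drop = FALSE]
    n_called <- colSums(!is.na(g))
    p <- ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), NA_real_)
    data.frame(id = svset$records$id, stratum = st, p = p,
               n_called = n_called, maf = pmin(p, 1 - p),
               missing_rate = 1 - n_called / nrow(g),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  class(res) <- c("freq_table", "data.frame")
  res
}

#' Allele frequencies as a loci x strata matrix
#' @inheritParams allele_frequencies
#' @return numeric matrix (rows = loci, columns = strata), `NA` where no
#'   genotype was called.
#' @export
freq_matrix <- function(svset, meta,
                        grouping = c("population", "group", "species")) {
  grouping <- match.arg(grouping)
  idx <- meta_index(svset, meta, grouping)
  L <- n_loci(svset)
  m <- vapply(idx, function(i) {
    g <- svset$genotypes[i, , drop = FALSE]
    n <- colSums(!is.na(g))
    ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  }, numeric(L))
  if (L == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(idx)))
  rownames(m) <- svset$records$id
  m
}

#' Cohort-wide per-locus summaries
#' @param svset an [sv_set()].
#' @return data.frame with `id`, `p`, `maf`, `n_called`, `missing_rate`
#'   over the whole cohort.
#' @export
locus_summary <- function(svset) {
  g <- svset$genotypes
  n_called <- colSums(!is.na(g))
  p <- ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), NA_real_)
  data.frame(id = svset$records$id, p = p, maf = pmin(p, 1 - p),
             n_called = n_called,
             missing_rate = 1 - n_called / nrow(g),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter SV loci on length, missingness and MAF
#'
#' Retains loci with `min_len <= length <= max_len` (both inclusive),
#' cohort missing rate `<= max_missing` and cohort MAF `>= min_maf`.
#' The removal tally (attribute `"removed"`) counts, per rule, loci removed
#' by that rule among those that passed the preceding rules
#' (length, then missingness, then MAF).
#'
#' @param svset an [sv_set()].
#' @param min_len,max_len inclusive length bounds in bp (defaults 50 and 1e6).
#' @param max_missing maximum missing-genotype rate (default 0.25).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return The filtered `svset`; attributes `"removed"` (named counts) and
#'   `"n_input"`.
#' @export
filter_svs <- function(svset, min_len = 50, max_len = 1e6,
                       max_missing = 0.25, min_maf = 0.01) {
  stopifnot(min_len > 0, max_len >= min_len, max_missing >= 0, min_maf >= 0)
  ls <- locus_summary(svset)
  len_ok <- svset$records$length >= min_len & svset$records$length <= max_len
  miss_ok <- ls$missing_rate <= max_missing
  maf_ok <- !is.na(ls$maf) & ls$maf >= min_maf
  removed <- c(length = sum(!len_ok),
               missing = sum(len_ok & !miss_ok),
               maf = sum(len_ok & miss_ok & !maf_ok))
  keep <- len_ok & miss_ok & maf_ok
  if (!any(keep)) warning("all loci removed by filters")
  out <- sv_subset(svset, loci = which(keep))
  attr(out, "removed") <- removed
  attr(out, "n_input") <- n_loci(svset)
  out
}

#' Group presence sharing summary (Venn cells)
#'
#' An SV is "present" in a group iff at least one non-missing genotype in
#' that group is a carrier (dosage > 0). Returns all seven Venn cells for
#' the wild/native/improved partition plus per-group totals; cells satisfy
#' inclusion-exclusion exactly.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @return list with `present` (loci x group logical matrix), `totals`,
#'   `cells` (named 7-vector: wild_only, native_only, improved_only,
#'   wild_native, wild_improved, native_improved, all_three) and
#'   `n_union`.
#' @export
sharing_summary <- function(svset, meta) {
  idx <- meta_index(svset, meta, "group")
  present <- sapply(GROUPS, function(g) {
    if (is.null(idx[[g]]) || !length(idx[[g]]))
      return(rep(FALSE, n_loci(svset)))
    colSums(svset$genotypes[idx[[g]], , drop = FALSE] > 0, na.rm = TRUE) > 0
  })
  present <- matrix(present, ncol = 3,
                    dimnames = list(svset$records$id, GROUPS))
  w <- present[, "wild"]; n <- present[, "native"]; i <- present[, "improved"]
  cells <- c(
    wild_only = sum(w & !n & !i),
    native_only = sum(!w & n & !i),
    improved_only = sum(!w & !n & i),
    wild_native = sum(w & n & !i),
    wild_improved = sum(w & !n & i),
    native_improved = sum(!w & n & i),
    all_three = sum(w & n & i))
  totals <- colSums(present)
  n_union <- sum(w | n | i)
  stopifnot(sum(cells) == n_union)  # inclusion-exclusion audit
  list(present = present, totals = totals, cells = cells, n_union = n_union)
}

#' SV accumulation (saturation) curve
#'
#' Mean number of distinct carried SVs over random sample subsets of
#' increasing size. A locus counts for a subset iff some subset member is a
#' carrier (dosage > 0, non-missing).
#'
#' @param svset an [sv_set()].
#' @param sizes subsample sizes (default an even grid up to the cohort size).
#' @param reps random subsets per size (default 10).
#' @param seed RNG seed.
#' @return data.frame `size`, `mean_svs`, `sd_svs`; attribute
#'   `"per_rep"` holds the size x rep count matrix.
#' @export
sv_accumulation_curve <- function(svset, sizes = NULL, reps = 10, seed = 1) {
  n <- length(svset$samples)
  if (is.null(sizes)) sizes <- unique(round(seq(1, n, length.out = min(n, 10))))
  stopifnot(reps >= 1, all(sizes >= 1), all(sizes <= n))
  sizes <- sort(sizes)
  carrier <- !is.na(svset$genotypes) & svset$genotypes > 0
  set.seed(seed)
  counts <- matrix(NA_real_, length(sizes), reps)
  for (r in seq_len(reps)) {
    perm <- sample.int(n)   # nested subsets => monotone within replicate
    for (k in seq_along(sizes)) {
      sub <- perm[seq_len(sizes[k])]
      counts[k, r] <- sum(colSums(carrier[sub, , drop = FALSE]) > 0)
    }
  }
  out <- data.frame(size = sizes, mean_svs = rowMeans(counts),
                    sd_svs = apply(counts, 1, stats::sd))
  attr(out, "per_rep") <- counts
  out
}
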