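#' Polarize alleles against a wild (ancestral-proxy) population
#'
#' The ancestral allele at each locus is the majority allele among the
#' non-missing allele copies of the wild population; ties are flagged
#' ambiguous and excluded from derived-frequency statistics; loci with no
#' wild call are unpolarizable. Derived-allele frequency in any stratum is
#' `1 - (ancestral-allele frequency)` in that stratum.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @param wild_population population name used as the ancestral proxy.
#' @return data.frame `id`, `ancestral` ("ref"/"alt"/NA), `status`
#'   ("ok", "ambiguous", "unpolarizable").
#' @export
polarize_ancestral <- function(svset, meta, wild_population) {
  idx <- meta_index(svset, meta, "population")[[wild_population]]
  if (is.null(idx)) stop("unknown population: ", wild_population)
  g <- svset$genotypes[idx, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  alt_copies <- colSums(g, na.rm = TRUE)
  ref_copies <- 2 * n_called - alt_copies
  ancestral <- ifelse(alt_copies > ref_copies, "alt", "ref")
  status <- rep("ok", length(ancestral))
  status[alt_copies == ref_copies] <- "ambiguous"
  status[n_called == 0] <- "unpolarizable"
  ancestral[status != "ok"] <- NA_character_
  data.frame(id = svset$records$id, ancestral = ancestral, status = status,
             stringsAsFactors = FALSE)
}

#' Derived-allele frequencies per population given a polarization
#' @param freqs alt-allele frequency matrix from [freq_matrix()].
#' @param polarization output of [polarize_ancestral()] (row order must
#'   match `freqs`).
#' @return matrix of derived-allele frequencies; `NA` rows where the locus
#'   is not polarizable.
#' @export
derived_frequencies <- function(freqs, polarization) {
  stopifnot(nrow(freqs) == nrow(polarization))
  out <- freqs
  ref_anc <- polarization$ancestral == "ref" & polarization$status == "ok"
  alt_anc <- polarization$ancestral == "alt" & polarization$status == "ok"
  out[which(alt_anc), ] <- 1 - freqs[which(alt_anc), , drop = FALSE]
  out[polarization$status != "ok", ] <- NA_real_
  out
}

#' Differentiation index DI_SV between a domestic and a wild population
#'
#' Signed difference in derived-allele frequency,
#' `DI_SV = f_derived(domestic) - f_derived(wild)`; positive values mean
#' the derived allele rose in the domestic population. Unpolarizable or
#' ambiguous loci are `NA`.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @param domestic_pop,wild_pop population names.
#' @param polarize_with population providing the ancestral polarization
#'   (default `wild_pop`); fixing it makes DI_SV antisymmetric in the two
#'   frequency arguments.
#' @return data.frame `id`, `f_dom`, `f_wild` (derived frequencies),
#'   `di_sv`.
#' @export
di_sv <- function(svset, meta, domestic_pop, wild_pop,
                  polarize_with = wild_pop) {
  fr <- freq_matrix(svset, meta, "population")
  pol <- polarize_ancestral(svset, meta, polarize_with)
  der <- derived_frequencies(fr, pol)
  data.frame(id = svset$records$id,
             f_dom = der[, domestic_pop], f_wild = der[, wild_pop],
             di_sv = der[, domestic_pop] - der[, wild_pop],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation P-values for per-locus F_ST
#'
#' For each of `B` replicates, sample labels of the two populations are
#' shuffled and per-locus Weir-Cockerham theta-hat recomputed;
#' `P = #(permuted theta > observed theta) / B` (strict "higher than", so
#' P = 0 is reportable). By default one label permutation per replicate is
#' shared across all loci, preserving inter-locus correlation; set
#' `per_locus = TRUE` for independent per-locus shuffles.
#'
#' With the default strict rule, permutation ties with the observed value
#' do not count, which is anti-conservative when the statistic is discrete
#' (small samples, low-frequency loci). `ties = "midp"` counts half of the
#' tied replicates (approximately uniform null P) and `ties = "geq"`
#' counts all of them (conservative, always valid); both are departures
#' from the strict rule and are opt-in.
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table.
#' @param popA,popB population names.
#' @param B number of permutations (default 200).
#' @param seed RNG seed.
#' @param per_locus logical; independent shuffles per locus.
#' @param smooth logical; report `(k + 1) / (B + 1)` instead of `k / B`.
#' @param ties tie handling: `"strict"` (default), `"midp"` or `"geq"`.
#' @return data.frame `id`, `theta_obs`, `p_perm` (`NA` where the observed
#'   theta is undefined); attribute `"B"`.
#' @export
fst_permutation_pvalue <- function(svset, meta, popA, popB, B = 200,
                                   seed = 1, per_locus = FALSE,
                                   smooth = FALSE,
                                   ties = c("strict", "midp", "geq")) {
  stopifnot(B >= 1)
  ties <- match.arg(ties)
  idx <- meta_index(svset, meta, "population")
  rows <- c(idx[[popA]], idx[[popB]])
  nA <- length(idx[[popA]])
  g <- svset$genotypes[rows, , drop = FALSE]
  obs <- wc_theta_split(g, seq_len(nA))
  set.seed(seed)
  L <- ncol(g)
  exceed <- numeric(L)
  tied <- numeric(L)
  for (b in seq_len(B)) {
    if (per_locus) {
      gp <- apply(g, 2, sample)
      th <- wc_theta_split(gp, seq_len(nA))
    } else {
      perm <- sample.int(nrow(g))
      th <- wc_theta_split(g[perm, , drop = FALSE], seq_len(nA))
    }
    ok <- !is.na(th) & !is.na(obs)
    exceed <- exceed + (ok & th > obs + 1e-12)
    tied <- tied + (ok & abs(th - obs) <= 1e-12)
  }
  k <- switch(ties, strict = exceed, midp = exceed + 0.5 * tied,
              geq = exceed + tied)
  p <- if (smooth) (k + 1) / (B + 1) else k / B
  p[is.na(obs)] <- NA_real_
  out <- data.frame(id = svset$records$id, theta_obs = obs, p_perm = p,
                    stringsAsFactors = FALSE)
  attr(out, "B") <- B
  out
}

wc_theta_split <- function(g, a_rows) {
  comp <- wc_components(list(g[a_rows, , drop = FALSE],
                             g[-a_rows, , drop = FALSE]))
  comp$a / (comp$a + comp$b + comp$c)
}

#' Population branch statistic
#'
#' `PBS = (T12 + T13 - T23) / 2` with the divergence transform
#' `T = -log(1 - theta)`; theta is clamped to at most `1 - 1e-9` so the
#' log stays finite, and negative per-site values pass through (T < 0 is
#' allowed). Population 1 is the focal branch.
#'
#' @param theta12,theta13,theta23 pairwise F_ST values (vectors ok);
#'   1 = focal, 2 = sister, 3 = outgroup.
#' @return numeric vector of PBS values.
#' @export
pbs <- function(theta12, theta13, theta23) {
  Tf <- function(x) -log(1 - pmin(x, 1 - 1e-9))
  (Tf(theta12) + Tf(theta13) - Tf(theta23)) / 2
}

#' Flag candidate loci by top-quantile / P-value rules
#'
#' The top-fraction threshold for a statistic over `m` defined loci is the
#' value at rank `ceiling(q * m)` of the descending order; ties at the
#' threshold are included. Rules are combined by set intersection.
#'
#' @param stats named list of numeric vectors (all same length), e.g.
#'   `list(di_sv = ..., p_perm = ...)`.
#' @param rules list of rules; each is `list(stat =, type = "top"|"lt",
#'   q =)` where `"top"` keeps the top fraction `q` (descending) and
#'   `"lt"` keeps values `< q`.
#' @param ids locus ids.
#' @return list of class `candidate_set`: `flags` (per-rule logical
#'   matrix), `candidate` (intersection), `thresholds` (per-rule record),
#'   `ids`.
#' @export
candidate_selection <- function(stats, rules, ids) {
  m <- length(ids)
  flags <- matrix(FALSE, m, length(rules),
                  dimnames = list(ids, vapply(rules, function(r) r$stat, "")))
  thresholds <- list()
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    x <- stats[[r$stat]]
    if (is.null(x)) stop("no such statistic: ", r$stat)
    if (all(is.na(x))) stop("statistic all-undefined: ", r$stat)
    if (r$type == "top") {
      def <- which(!is.na(x))
      if (length(def) < 20)
        warning("top-quantile rule on ", r$stat, " with < 20 defined loci")
      srt <- sort(x[def], decreasing = TRUE)
      thr <- srt[ceiling(r$q * length(def))]
      flags[, k] <- !is.na(x) & x >= thr
      thresholds[[k]] <- list(stat = r$stat, type = "top", q = r$q,
                              threshold = thr)
    } else if (r$type == "lt") {
      flags[, k] <- !is.na(x) & x < r$q
      thresholds[[k]] <- list(stat = r$stat, type = "lt", q = r$q,
                              threshold = r$q)
    } else stop("unknown rule type: ", r$type)
  }
  candidate <- rowSums(flags) == length(rules)
  if (!any(candidate)) warning("empty candidate set")
  structure(list(flags = flags, candidate = candidate,
                 thresholds = thresholds, ids = ids),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", sum(x$candidate), "of", length(x$ids),
      "loci flagged\n")
  for (t in x$thresholds)
    cat("  rule ", t$stat, " [", t$type, " ", t$q, "] threshold = ",
        format(t$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum test on population-level allele frequencies
#'
#' Compares per-population alt-allele frequencies between two groups of
#' populations for each SV (two-sided rank-sum test; exact when sample
#' sizes are small and ties are absent), with Benjamini-Hochberg
#' adjustment across the tested SV set.
#'
#' @param freqs loci x population frequency matrix ([freq_matrix()]).
#' @param group1,group2 character vectors of population names (each of
#'   length >= 2).
#' @return data.frame `id`, `w_stat`, `p`, `p_adj`.
#' @export
group_freq_wilcoxon <- function(freqs, group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs >= 2 populations")
  miss <- setdiff(c(group1, group2), colnames(freqs))
  if (length(miss)) stop("unknown population(s): ", paste(miss, collapse = ", "))
  res <- t(apply(freqs, 1, function(row) {
    x <- row[group1]; y <- row[group2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    # fully tied data has zero rank variance; the maximal attainable P is 1
    if (is.na(wt$p.value)) wt$p.value <- 1
    c(wt$statistic, wt$p.value)
  }))
  p_adj <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(id = rownames(freqs), w_stat = res[, 1], p = res[, 2],
             p_adj = p_adj, stringsAsFactors = FALSE, row.names = NULL)
}
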