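#' Breakpoints of each SV (0-based positions)
#'
#' DEL/DUP/INV contribute two breakpoints (span start and end), INS one
#' (insertion site) and TRA one per involved chromosome (the merged
#' call-set representation used here carries a single chromosome per TRA
#' record, hence one breakpoint at its start).
#'
#' @param svset an [sv_set()].
#' @return data.frame `id`, `chrom`, `pos` (one row per breakpoint).
#' @export
sv_breakpoints <- function(svset) {
  iv <- sv_intervals(svset)
  two <- iv$svtype %in% c("DEL", "DUP", "INV")
  out <- rbind(
    data.frame(id = iv$id, chrom = iv$chrom, pos = iv$start,
               stringsAsFactors = FALSE),
    data.frame(id = iv$id[two], chrom = iv$chrom[two],
               pos = iv$end[two] - 1L, stringsAsFactors = FALSE))
  out[order(out$chrom, out$pos, out$id), , drop = FALSE]
}

#' Sliding-window breakpoint density
#'
#' Counts SV breakpoints in 1-Mb windows advanced by a 500-kb step along
#' each chromosome; with window = 2 x step every interior position is
#' covered by exactly two windows, and a breakpoint counts in every window
#' containing it.
#'
#' @param svset an [sv_set()].
#' @param genome named chromosome lengths (bp).
#' @param window,step window size and step in bp.
#' @return [interval_set()] with a `count` column (class also
#'   `window_density`).
#' @export
breakpoint_density <- function(svset, genome, window = 1e6, step = 5e5) {
  bp <- sv_breakpoints(svset)
  unknown <- setdiff(unique(bp$chrom), names(genome))
  if (length(unknown))
    stop("SV on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  out <- list()
  for (ch in names(genome)) {
    starts <- seq(0, max(genome[[ch]] - 1, 0), by = step)
    ends <- pmin(starts + window, genome[[ch]])
    pos <- bp$pos[bp$chrom == ch]
    count <- vapply(seq_along(starts), function(k)
      sum(pos >= starts[k] & pos < starts[k] + window), numeric(1))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            count = count, stringsAsFactors = FALSE)
  }
  res <- interval_set(do.call(rbind, out))
  class(res) <- c("window_density", class(res))
  res
}

#' Detect SV hotspots from a window density
#'
#' Hotspot windows are those in the top `top_fraction` of breakpoint
#' counts (rank cutoff `ceiling(top_fraction * W)` over all windows, ties
#' at the threshold included, genome-wide by default); overlapping or
#' adjacent hotspot windows merge into hotspot regions.
#'
#' @param density a [breakpoint_density()] result.
#' @param top_fraction fraction of windows called hotspots (default 0.10).
#' @param per_chrom logical; rank within each chromosome instead of
#'   genome-wide.
#' @return list of class `hotspot_set`: `windows` (the hotspot windows),
#'   `regions` (merged), `threshold`, `summary` (n_regions, total_span).
#' @export
hotspot_detect <- function(density, top_fraction = 0.10, per_chrom = FALSE) {
  W <- nrow(density)
  if (W < 10) stop("need >= 10 windows")
  if (all(density$count == 0)) stop("all-zero breakpoint density")
  pick <- function(d) {
    srt <- sort(d$count, decreasing = TRUE)
    thr <- srt[ceiling(top_fraction * nrow(d))]
    d[d$count >= thr, , drop = FALSE]
  }
  if (per_chrom) {
    parts <- lapply(split(seq_len(W), density$chrom),
                    function(i) pick(density[i, , drop = FALSE]))
    windows <- do.call(rbind, parts)
    threshold <- NA_real_
  } else {
    srt <- sort(density$count, decreasing = TRUE)
    threshold <- srt[ceiling(top_fraction * W)]
    windows <- density[density$count >= threshold, , drop = FALSE]
  }
  windows <- interval_set(as.data.frame(windows))
  regions <- merge_intervals(windows)
  structure(list(windows = windows, regions = regions,
                 threshold = threshold,
                 summary = c(n_regions = nrow(regions),
                             total_span = total_span(regions))),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("hotspot_set: ", nrow(x$windows), " windows -> ",
      x$summary["n_regions"], " merged regions spanning ",
      format(x$summary["total_span"], big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Telomere enrichment of SV breakpoints
#'
#' Telomeric regions are the first and last `telomere_len` bp of each
#' chromosome; breakpoints are counted in non-overlapping `bin`-sized bins
#' and telomeric vs non-telomeric bin counts are compared with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param svset an [sv_set()].
#' @param genome named chromosome lengths (bp); chromosomes must exceed
#'   `2 * telomere_len`.
#' @param telomere_len telomeric span per chromosome end (default 5 Mb).
#' @param bin bin size (default 1 Mb).
#' @param exclude chromosomes to drop from the analysis.
#' @return list: `bins` (data.frame chrom, start, end, count, telomeric),
#'   `n_telomeric`, `n_nontelomeric` (breakpoint counts), `w_stat`, `p`.
#' @export
telomere_enrichment <- function(svset, genome, telomere_len = 5e6,
                                bin = 1e6, exclude = character(0)) {
  genome <- genome[setdiff(names(genome), exclude)]
  short <- names(genome)[genome <= 2 * telomere_len]
  if (length(short))
    stop("chromosome(s) too short for both telomeric ends: ",
         paste(short, collapse = ", "))
  bp <- sv_breakpoints(svset)
  bp <- bp[bp$chrom %in% names(genome), , drop = FALSE]
  out <- list()
  for (ch in names(genome)) {
    starts <- seq(0, genome[[ch]] - 1, by = bin)
    ends <- pmin(starts + bin, genome[[ch]])
    pos <- bp$pos[bp$chrom == ch]
    count <- vapply(seq_along(starts), function(k)
      sum(pos >= starts[k] & pos < ends[k]), numeric(1))
    telomeric <- ends <= telomere_len | starts >= genome[[ch]] - telomere_len
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            count = count, telomeric = telomeric,
                            stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  if (!any(!bins$telomeric)) stop("no non-telomeric bins")
  wt <- suppressWarnings(stats::wilcox.test(
    bins$count[bins$telomeric], bins$count[!bins$telomeric]))
  list(bins = bins,
       n_telomeric = sum(bins$count[bins$telomeric]),
       n_nontelomeric = sum(bins$count[!bins$telomeric]),
       w_stat = unname(wt$statistic), p = wt$p.value)
}

#' Fractional-overlap interval matching (reciprocal-overlap rules)
#'
#' Pair (a, b) matches iff the overlap length covers at least
#' `fraction_a` of a AND/OR at least `fraction_b` of b, per `mode`
#' (`"either"` reproduces BEDtools' `-f x -F y -e`; `"both"` requires
#' both). `invert` returns the records of `setA` with no match
#' (BEDtools' `-v`).
#'
#' @param setA,setB [interval_set()]s (same coordinate convention).
#' @param fraction_a,fraction_b required overlap fractions in (0, 1].
#' @param mode `"either"` or `"both"`.
#' @param invert logical; return unmatched-A instead of pairs.
#' @return If `invert`, the unmatched subset of `setA`; otherwise a
#'   data.frame of matched pairs (`idx_a`, `idx_b`, `overlap`,
#'   `frac_a`, `frac_b`) in (idx_a, idx_b) order.
#' @export
overlap_match <- function(setA, setB, fraction_a = 0.5, fraction_b = 0.5,
                          mode = c("either", "both"), invert = FALSE) {
  mode <- match.arg(mode)
  stopifnot(fraction_a > 0, fraction_a <= 1, fraction_b > 0, fraction_b <= 1)
  if (any(setA$end <= setA$start) || any(setB$end <= setB$start))
    stop("zero-length interval")
  pairs <- overlap_pairs(setA, setB)
  if (nrow(pairs)) {
    len_a <- setA$end[pairs$idx_a] - setA$start[pairs$idx_a]
    len_b <- setB$end[pairs$idx_b] - setB$start[pairs$idx_b]
    okA <- pairs$overlap >= fraction_a * len_a
    okB <- pairs$overlap >= fraction_b * len_b
    ok <- if (mode == "either") okA | okB else okA & okB
    frac_a <- pairs$overlap / len_a
    frac_b <- pairs$overlap / len_b
    pairs <- pairs[ok, , drop = FALSE]
    pairs$frac_a <- frac_a[ok]
    pairs$frac_b <- frac_b[ok]
  } else {
    pairs$frac_a <- pairs$frac_b <- numeric(0)
  }
  pairs <- pairs[order(pairs$idx_a, pairs$idx_b), , drop = FALSE]
  rownames(pairs) <- NULL
  if (invert) {
    un <- setdiff(seq_len(nrow(setA)), pairs$idx_a)
    return(setA[un, , drop = FALSE])
  }
  pairs
}

# All positively-overlapping index pairs between two interval sets.
overlap_pairs <- function(setA, setB) {
  res <- list()
  for (ch in intersect(unique(setA$chrom), unique(setB$chrom))) {
    ia <- which(setA$chrom == ch); ib <- which(setB$chrom == ch)
    ra <- IRanges::IRanges(start = setA$start[ia] + 1L, end = setA$end[ia])
    rb <- IRanges::IRanges(start = setB$start[ib] + 1L, end = setB$end[ib])
    hits <- IRanges::findOverlaps(ra, rb)
    if (!length(hits)) next
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(setA$end[qa], setB$end[qb]) - pmax(setA$start[qa], setB$start[qb])
    keep <- ov > 0
    res[[ch]] <- data.frame(idx_a = qa[keep], idx_b = qb[keep],
                            overlap = ov[keep])
  }
  if (!length(res))
    return(data.frame(idx_a = integer(0), idx_b = integer(0),
                      overlap = numeric(0)))
  do.call(rbind, res)
}

#' Identify novel SVs against a published catalog
#'
#' An SV is the "same variant" as a catalog entry when the two intervals
#' share a 30% reciprocal overlap in either direction; SVs with no such
#' match are novel.
#'
#' @param svset an [sv_set()].
#' @param catalog an [interval_set()] of published SV spans (same genome
#'   coordinates; no liftover is performed).
#' @return list: `novel_ids`, `per_type` (data.frame svtype, n, n_novel,
#'   pct_novel), `n_novel`, `n_total`.
#' @export
novel_svs <- function(svset, catalog) {
  iv <- interval_set(sv_intervals(svset))
  if (nrow(catalog) == 0) {
    warning("empty catalog: all SVs novel")
    novel <- iv
  } else {
    novel <- overlap_match(iv, catalog, 0.3, 0.3, mode = "either",
                           invert = TRUE)
  }
  per_type <- do.call(rbind, lapply(SV_TYPES, function(tp) {
    n <- sum(iv$svtype == tp)
    nn <- sum(novel$svtype == tp)
    data.frame(svtype = tp, n = n, n_novel = nn,
               pct_novel = ifelse(n > 0, 100 * nn / n, NA_real_))
  }))
  list(novel_ids = novel$id, per_type = per_type,
       n_novel = nrow(novel), n_total = nrow(iv))
}

#' Per-individual QTL fold enrichment of carried SVs
#'
#' For each individual and QTL trait: observed = number of the
#' individual's carried SVs (dosage > 0) matching the trait's QTL
#' intervals under the 50% either-side overlap rule; expected = carried
#' SVs x (merged QTL span / genome span); `log2_fe = log2(observed /
#' expected)` with a 0.5 pseudocount on observed when it is zero (such
#' cells are flagged).
#'
#' @param svset an [sv_set()].
#' @param qtls an [interval_set()] with a `trait` column (pre-filtered to
#'   spans <= 5 Mb by [read_interval_table()]).
#' @param genome named chromosome lengths (bp).
#' @return data.frame `sample`, `trait`, `observed`, `expected`,
#'   `log2_fe`, `pseudocount` (logical).
#' @export
qtl_enrichment <- function(svset, qtls, genome) {
  gsize <- sum(as.numeric(genome))
  if (gsize <= 0) stop("zero genome span")
  iv <- interval_set(sv_intervals(svset))
  traits <- unique(qtls$trait)
  # which SVs match each trait's QTLs (50% either-side rule)
  match_by_trait <- lapply(traits, function(tr) {
    q <- qtls[qtls$trait == tr, , drop = FALSE]
    m <- overlap_match(iv, q, 0.5, 0.5, mode = "either")
    unique(iv$id[m$idx_a])
  })
  names(match_by_trait) <- traits
  span_by_trait <- vapply(traits, function(tr)
    total_span(interval_set(as.data.frame(qtls[qtls$trait == tr, ]))),
    numeric(1))
  carrier <- !is.na(svset$genotypes) & svset$genotypes > 0
  rows <- list()
  for (s in seq_along(svset$samples)) {
    carried <- svset$records$id[carrier[s, ]]
    n_carried <- length(carried)
    for (tr in traits) {
      obs <- sum(carried %in% match_by_trait[[tr]])
      expd <- n_carried * span_by_trait[[tr]] / gsize
      pseudo <- obs == 0
      fe <- (obs + ifelse(pseudo, 0.5, 0)) / expd
      rows[[length(rows) + 1L]] <- data.frame(
        sample = svset$samples[s], trait = tr, observed = obs,
        expected = expd, log2_fe = log2(fe), pseudocount = pseudo,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify SVs as Peak-SVs vs nonPeak-SVs
#'
#' A Peak-SV has at least 50% of its length covered by the merged
#' open-chromatin peak set; because peaks are merged first, overlap may
#' accumulate across several peaks. The partition is exhaustive and
#' exclusive.
#'
#' @param svset an [sv_set()].
#' @param peaks an [interval_set()] of peaks (merged internally if not).
#' @param min_fraction required covered fraction (default 0.5, `>=`).
#' @return list: `peak_sv` (ids), `nonpeak_sv` (ids), `coverage`
#'   (per-SV covered fraction).
#' @export
peak_sv_classify <- function(svset, peaks, min_fraction = 0.5) {
  merged <- merge_intervals(peaks)
  if (nrow(merged) != nrow(peaks))
    message("peaks were not merged; merged internally")
  iv <- interval_set(sv_intervals(svset))
  pairs <- overlap_pairs(iv, merged)
  cov_by_sv <- rep(0, nrow(iv))
  if (nrow(pairs)) {
    agg <- tapply(pairs$overlap, pairs$idx_a, sum)
    cov_by_sv[as.integer(names(agg))] <- agg
  }
  frac <- cov_by_sv / (iv$end - iv$start)
  names(frac) <- iv$id
  is_peak <- frac >= min_fraction
  list(peak_sv = iv$id[is_peak], nonpeak_sv = iv$id[!is_peak],
       coverage = frac)
}

#' Candidate enhancer peaks (promoter exclusion)
#'
#' Promoter peaks intersect a strand-aware TSS window (TSS +/-
#' `promoter_window` bp); the remaining peaks are candidate enhancers.
#'
#' @param peaks an [interval_set()] of (merged) peaks.
#' @param genes list of [gene_model()]s (strand required).
#' @param promoter_window half-width of the promoter window (default 2 kb).
#' @return list: `candidates` (interval_set), `promoter_idx` (indices of
#'   excluded peaks), `n_promoter`.
#' @export
enhancer_candidates <- function(peaks, genes, promoter_window = 2000) {
  tss <- vapply(genes, gene_tss, numeric(1))
  chrom <- vapply(genes, function(g) g$chrom, "")
  prom <- interval_set(chrom = chrom,
                       start = pmax(tss - promoter_window, 0),
                       end = tss + promoter_window + 1)
  pairs <- overlap_pairs(peaks, prom)
  promoter_idx <- sort(unique(pairs$idx_a))
  keep <- setdiff(seq_len(nrow(peaks)), promoter_idx)
  list(candidates = peaks[keep, , drop = FALSE],
       promoter_idx = promoter_idx, n_promoter = length(promoter_idx))
}

#' Enhancer candidates supported by SVs
#'
#' A candidate enhancer peak is SV-supported when it contains at least
#' `min_fraction` of some SV's length.
#'
#' @param candidates candidate enhancer [interval_set()] (from
#'   [enhancer_candidates()]).
#' @param svset an [sv_set()].
#' @param min_fraction required fraction of the SV inside the peak.
#' @return The supported subset of `candidates`, with an attribute
#'   `"sv_ids"` listing the supporting SVs per peak row.
#' @export
sv_supported_enhancers <- function(candidates, svset, min_fraction = 0.5) {
  iv <- interval_set(sv_intervals(svset))
  pairs <- overlap_match(iv, candidates, fraction_a = min_fraction,
                         fraction_b = 1e-9, mode = "both")
  idx <- sort(unique(pairs$idx_b))
  out <- candidates[idx, , drop = FALSE]
  attr(out, "sv_ids") <- lapply(idx, function(i)
    iv$id[pairs$idx_a[pairs$idx_b == i]])
  out
}
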