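#' Allele-frequency scan for wild-to-domestic introgressed SVs
#'
#' For every domestic (non-wild) population, an SV is a candidate
#' introgression call iff, over non-missing calls:
#' (i) its alt-allele frequency is > 0 in the recipient population,
#' exactly 0 in every other domestic population, and exactly 1 (fixed) in
#' at least one wild species; (ii) exactly 0 in the designated outgroup
#' species; and (iii) after per-SV calling, only populations with more
#' than `min_svs` candidate SVs are reported. Domestic populations with
#' fewer than `min_samples` samples are excluded up front, and a
#' population with no called genotype at a locus fails any exactness
#' check there (absence cannot be certified from missing data).
#'
#' @param svset an [sv_set()].
#' @param meta a [sample_meta()] table; wild species are the `species` of
#'   samples with `group == "wild"`.
#' @param outgroup species name used to exclude shared ancestral alleles.
#' @param min_samples minimum samples per domestic population (default 2).
#' @param min_svs a population is reported only with more than this many
#'   candidate SVs (default 2, strict).
#' @param tol frequency tolerance for the "fixed"/"absent" checks
#'   (default 0, exact).
#' @return list of class `introgression_scan`: `calls` (data.frame `id`,
#'   `recipient`, `donor`, `f_recipient`, `f_donor`, `f_outgroup`,
#'   `f_other_dom_max`), `suppressed` (per-population candidate counts
#'   failing rule iii), `excluded_pops`.
#' @export
introgression_scan <- function(svset, meta, outgroup, min_samples = 2,
                               min_svs = 2, tol = 0) {
  meta <- sample_meta(meta, svset)
  if (!outgroup %in% meta$species) stop("outgroup species not in metadata: ", outgroup)
  pop_idx <- meta_index(svset, meta, "population")
  pop_info <- unique(as.data.frame(meta)[, c("population", "group", "species")])
  wild_species <- unique(pop_info$species[pop_info$group == "wild"])
  dom_pops <- pop_info$population[pop_info$group != "wild"]
  sizes <- vapply(pop_idx, length, integer(1))
  excluded <- dom_pops[sizes[dom_pops] < min_samples]
  dom_pops <- setdiff(dom_pops, excluded)
  if (!length(dom_pops)) stop("no domestic population passes min_samples")

  fr_pop <- freq_matrix(svset, meta, "population")     # loci x populations
  fr_sp <- freq_matrix(svset, meta, "species")         # loci x species
  wild_cols <- intersect(wild_species, colnames(fr_sp))
  fw <- fr_sp[, wild_cols, drop = FALSE]
  # donor: a wild species fixed (freq == 1) with a called genotype
  donor_fixed <- !is.na(fw) & fw >= 1 - tol
  has_donor <- rowSums(donor_fixed) > 0
  f_out <- fr_sp[, outgroup]
  out_zero <- !is.na(f_out) & f_out <= tol

  rows <- list()
  for (p in dom_pops) {
    others <- setdiff(dom_pops, p)
    fo <- fr_pop[, others, drop = FALSE]
    others_zero <- if (length(others))
      rowSums(is.na(fo) | fo > tol) == 0 else rep(TRUE, nrow(fr_pop))
    fp <- fr_pop[, p]
    call <- !is.na(fp) & fp > 0 & others_zero & has_donor & out_zero
    if (!any(call)) next
    donors <- apply(donor_fixed[call, , drop = FALSE], 1, function(z)
      paste(wild_cols[z], collapse = ","))
    rows[[p]] <- data.frame(
      id = svset$records$id[call], recipient = p, donor = donors,
      f_recipient = fp[call],
      f_donor = apply(fw[call, , drop = FALSE], 1, max, na.rm = TRUE),
      f_outgroup = f_out[call],
      f_other_dom_max = if (length(others))
        apply(fo[call, , drop = FALSE], 1, function(z)
          if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)) else 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), recipient = character(0),
               donor = character(0), f_recipient = numeric(0),
               f_donor = numeric(0), f_outgroup = numeric(0),
               f_other_dom_max = numeric(0))
  counts <- table(calls$recipient)
  keep_pops <- names(counts)[counts > min_svs]
  suppressed <- counts[!(names(counts) %in% keep_pops)]
  calls <- calls[calls$recipient %in% keep_pops, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, suppressed = suppressed,
                 excluded_pops = excluded),
            class = "introgression_scan")
}

#' @export
print.introgression_scan <- function(x, ...) {
  cat("introgression scan:", nrow(x$calls), "candidate SV call(s) in",
      length(unique(x$calls$recipient)), "population(s)\n")
  if (length(x$suppressed))
    cat("  suppressed (<=", 2, "candidates):",
        paste(names(x$suppressed), x$suppressed, sep = "=", collapse = " "), "\n")
  invisible(x)
}
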