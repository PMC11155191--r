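#' @keywords internal
"_PACKAGE"

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "TRA")
GROUPS <- c("wild", "native", "improved")

#' Construct an SV cohort object
#'
#' An `svset` bundles a table of structural-variant loci with a diploid
#' genotype matrix. Coordinates in `records` follow the VCF convention
#' (1-based, inclusive); interval operations convert to 0-based half-open
#' internally via [sv_intervals()]. Loci are stored sorted by
#' (chrom, start, end, id).
#'
#' @param records data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (one of DEL, DUP, INV, INS, TRA) and `length` (bp; for INS the
#'   inserted length, otherwise `end - start + 1`).
#' @param genotypes integer matrix, samples x loci, values 0/1/2 (alt-allele
#'   dosage) or `NA` for a missing call.
#' @param samples character vector of sample ids (rows of `genotypes`).
#' @return An object of class `svset`.
#' @export
sv_set <- function(records, genotypes, samples) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "svtype", "length")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks columns: ", paste(miss, collapse = ", "))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(samples))
    stop("genotype rows (", nrow(genotypes), ") != samples (", length(samples), ")")
  if (ncol(genotypes) != nrow(records))
    stop("genotype columns (", ncol(genotypes), ") != loci (", nrow(records), ")")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype values must be 0, 1, 2 or NA")
  if (any(records$start < 1)) stop("start must be >= 1")
  if (any(records$end < records$start)) stop("end must be >= start")
  if (any(records$length < 1)) stop("length must be >= 1")
  if (anyDuplicated(records$id)) stop("duplicate SV ids")
  unk <- setdiff(unique(records$svtype), SV_TYPES)
  if (length(unk)) stop("unknown svtype: ", paste(unk, collapse = ", "))
  ord <- order(records$chrom, records$start, records$end, records$id)
  records <- records[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  rownames(records) <- NULL
  dimnames(genotypes) <- list(samples, records$id)
  structure(list(records = records, genotypes = genotypes,
                 samples = as.character(samples)),
            class = "svset")
}

#' @export
print.svset <- function(x, ...) {
  cat("svset: ", nrow(x$records), " loci x ", length(x$samples), " samples\n", sep = "")
  tab <- table(factor(x$records$svtype, levels = SV_TYPES))
  cat("  types:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  missing genotype rate:",
      format(mean(is.na(x$genotypes)), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.svset <- function(x) c(length(x$samples), nrow(x$records))

n_loci <- function(svset) nrow(svset$records)

#' Subset an svset by locus and/or sample
#'
#' @param svset an [sv_set()] object.
#' @param loci logical/integer/character index into loci (ids allowed).
#' @param samples logical/integer/character index into samples.
#' @return A new `svset`.
#' @export
sv_subset <- function(svset, loci = NULL, samples = NULL) {
  rec <- svset$records; gt <- svset$genotypes; smp <- svset$samples
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, rec$id)
    rec <- rec[loci, , drop = FALSE]
    gt <- gt[, loci, drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, smp)
    smp <- smp[samples]
    gt <- gt[samples, , drop = FALSE]
  }
  sv_set(rec, gt, smp)
}

#' SV spans as 0-based half-open intervals
#'
#' Converts the 1-based inclusive record coordinates to the BED convention
#' used by all interval arithmetic in the package: `[start - 1, end)`.
#' Insertions are treated as 1-bp points at the insertion site.
#'
#' @param svset an [sv_set()] object.
#' @return data.frame with `id`, `chrom`, `start`, `end`, `svtype`, `length`
#'   (0-based half-open).
#' @export
sv_intervals <- function(svset) {
  r <- svset$records
  start0 <- r$start - 1L
  end0 <- r$end
  ins <- r$svtype == "INS"
  end0[ins] <- start0[ins] + 1L
  data.frame(id = r$id, chrom = r$chrom, start = start0, end = end0,
             svtype = r$svtype, length = r$length, stringsAsFactors = FALSE)
}

#' Construct or validate a sample metadata table
#'
#' @param x data.frame with columns `sample_id`, `population`, `group`
#'   (one of wild/native/improved) and `species`.
#' @param svset optional [sv_set()]; if given, every sample must have exactly
#'   one metadata row.
#' @return The validated data.frame (class `sample_meta`).
#' @export
sample_meta <- function(x, svset = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "group", "species")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$group), GROUPS)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "),
                        " (allowed: ", paste(GROUPS, collapse = ", "), ")")
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in metadata")
  if (!is.null(svset)) {
    missing_meta <- setdiff(svset$samples, x$sample_id)
    if (length(missing_meta))
      stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  }
  class(x) <- c("sample_meta", "data.frame")
  x
}

meta_index <- function(svset, meta, by = c("population", "group", "species")) {
  by <- match.arg(by)
  meta <- sample_meta(meta, svset)
  key <- meta[[by]][match(svset$samples, meta$sample_id)]
  split(seq_along(svset$samples), key)
}
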