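#' Read a structural-variant VCF into an svset
#'
#' Consumes the multi-sample merged SV-VCF dialect (VCF 4.2 with INFO keys
#' `SVTYPE`, `END` and, for insertions, `SVLEN`; one diploid `GT` per
#' sample). Genotypes are mapped 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2 and
#' ./. -> missing. VCF 1-based coordinates are preserved in the records;
#' loci come back sorted by (chrom, start, end, id).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return An [sv_set()].
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  if (any(no_id)) ids[no_id] <- paste0("sv_", which(no_id))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic SV records are not supported (split upstream): ",
         paste(ids[multi], collapse = ", "))
  svtype <- vcfR::extract.info(v, "SVTYPE")
  endv <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))

  bad_type <- is.na(svtype)
  if (any(bad_type))
    stop("records missing SVTYPE: ", paste(ids[bad_type], collapse = ", "))
  unk <- !(svtype %in% SV_TYPES)
  if (any(unk))
    stop("unknown SVTYPE (allowed ", paste(SV_TYPES, collapse = "/"), "): ",
         paste(unique(svtype[unk]), collapse = ", "))
  ins <- svtype == "INS"
  need_end <- !ins & is.na(endv)
  if (any(need_end))
    stop("records missing END: ", paste(ids[need_end], collapse = ", "))
  need_len <- ins & is.na(svlen) & is.na(endv)
  if (any(need_len))
    stop("INS records missing SVLEN (and END): ", paste(ids[need_len], collapse = ", "))

  len <- ifelse(ins, abs(svlen), endv - pos + 1L)
  len[ins & is.na(svlen)] <- 1L
  endv[ins] <- pos[ins]

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no genotype (GT) fields")
  samples <- colnames(gt)
  dose <- gt_to_dosage(gt)
  records <- data.frame(id = ids, chrom = chrom, start = pos, end = endv,
                        svtype = svtype, length = as.integer(len),
                        stringsAsFactors = FALSE)
  sv_set(records, t(dose), samples)
}

gt_to_dosage <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g %in% c("0/0")] <- 0L
  out[g %in% c("0/1", "1/0")] <- 1L
  out[g %in% c("1/1")] <- 2L
  known <- g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".") | is.na(g)
  if (!all(known)) {
    bad <- unique(g[!known])
    stop("non-diploid or unrecognized GT value(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Write an svset to a plain-text SV-VCF
#'
#' Emits a VCF 4.2 file with INFO keys `SVTYPE`, `END` and `SVLEN`, one
#' diploid GT column per sample. `read_sv_vcf(write_sv_vcf(x, f))`
#' reproduces the same records, genotypes and sorted order.
#'
#' @param svset an [sv_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svset, path) {
  r <- svset$records
  gt <- svset$genotypes
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svpopgen",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", svset$samples), collapse = "\t"))
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", r$svtype, r$end,
                  ifelse(r$svtype == "DEL", -r$length, r$length))
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  gt_chr[is.na(gt)] <- "./."
  body <- paste(r$chrom, r$start, r$id, "N", paste0("<", r$svtype, ">"),
                ".", "PASS", info, "GT",
                apply(gt_chr, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
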