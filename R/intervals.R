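#' Construct an interval set (BED convention)
#'
#' Intervals are 0-based half-open `[start, end)`, sorted by
#' (chrom, start, end). Extra columns (trait, peak id, ...) are carried
#' through as payload.
#'
#' @param chrom,start,end vectors, or a data.frame in `chrom` with those
#'   columns.
#' @param name optional labels.
#' @param ... further payload columns.
#' @return data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, name = NULL, ...) {
  if (is.data.frame(chrom)) {
    df <- as.data.frame(chrom, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     stringsAsFactors = FALSE)
    if (!is.null(name)) df$name <- name
    extra <- list(...)
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  }
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("interval set needs chrom, start, end")
  if (any(df$end <= df$start))
    stop("end <= start at row(s): ",
         paste(which(df$end <= df$start), collapse = ", "))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set: ", nrow(x), " intervals on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Merge overlapping or bookended intervals
#'
#' @param x an [interval_set()].
#' @return An `interval_set` whose intervals do not overlap; each merged
#'   interval is the union of a run of overlapping/adjacent inputs.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  parts <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    s <- x$start[idx]; e <- x$end[idx]
    o <- order(s, e); s <- s[o]; e <- e[o]
    cmax <- cummax(e)
    newrun <- c(TRUE, s[-1] > cmax[-length(cmax)])
    grp <- cumsum(newrun)
    data.frame(chrom = x$chrom[idx][1],
               start = tapply(s, grp, min),
               end = tapply(e, grp, max),
               stringsAsFactors = FALSE)
  })
  interval_set(do.call(rbind, parts))
}

total_span <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

#' Read an interval table (BED, gene, QTL or peak dialect)
#'
#' All dialects use 0-based half-open coordinates. The `gene` dialect is
#' BED12-like: chrom, start, end, name, score, strand, thickStart, thickEnd,
#' itemRgb, blockCount, blockSizes, blockStarts; blocks become exons and the
#' thick region is read as the CDS, so exon portions outside it become the
#' 5'/3' UTRs (strand-aware). The `qtl` dialect is a TSV with columns chrom,
#' start, end, trait and applies the <= 5 Mb span filter, reporting how many
#' records were removed in attribute `"removed"`.
#'
#' @param path file path.
#' @param dialect one of `"bed"`, `"gene"`, `"qtl"`, `"peak"`.
#' @param max_qtl_span maximum retained QTL span in bp (default 5e6).
#' @return An [interval_set()] (`bed`, `peak`, `qtl`) or a list of gene
#'   models (`gene`, see [gene_model()]).
#' @export
read_interval_table <- function(path, dialect = c("bed", "gene", "qtl", "peak"),
                                max_qtl_span = 5e6) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  has_header <- dialect == "qtl"
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (dialect %in% c("bed", "peak")) {
    names(df)[1:3] <- c("chrom", "start", "end")
    if (ncol(df) >= 4) names(df)[4] <- "name"
    check_starts(df, path)
    return(interval_set(df))
  }
  if (dialect == "qtl") {
    need <- c("chrom", "start", "end", "trait")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("QTL table lacks column(s): ",
                           paste(miss, collapse = ", "))
    check_starts(df, path)
    span <- df$end - df$start
    keep <- span <= max_qtl_span
    out <- interval_set(df[keep, , drop = FALSE])
    attr(out, "removed") <- sum(!keep)
    if (any(!keep))
      message(sum(!keep), " QTL record(s) removed (span > ",
              format(max_qtl_span, scientific = FALSE), " bp)")
    return(out)
  }
  # gene dialect (BED12-like)
  if (ncol(df) < 12) stop("gene dialect needs 12 BED12-like columns")
  names(df)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                       "thickStart", "thickEnd", "itemRgb", "blockCount",
                       "blockSizes", "blockStarts")
  check_starts(df, path)
  lapply(seq_len(nrow(df)), function(i) {
    sizes <- as.integer(strsplit(as.character(df$blockSizes[i]), ",")[[1]])
    offs <- as.integer(strsplit(as.character(df$blockStarts[i]), ",")[[1]])
    if (length(sizes) != df$blockCount[i] || length(offs) != df$blockCount[i])
      stop("block count mismatch at line ", i, " of ", path)
    ex_start <- df$start[i] + offs
    ex_end <- ex_start + sizes
    gene_model(gene_id = df$name[i], chrom = df$chrom[i],
               start = df$start[i], end = df$end[i], strand = df$strand[i],
               exon_start = ex_start, exon_end = ex_end,
               cds_start = df$thickStart[i], cds_end = df$thickEnd[i])
  })
}

check_starts <- function(df, path) {
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("end <= start at line(s) ", paste(bad, collapse = ", "), " of ", path)
}

#' Construct a gene model
#'
#' Half-open 0-based coordinates throughout. Exons must be sorted,
#' non-overlapping and contained in the gene span. When `cds_start` equals
#' `cds_end` the gene has no annotated CDS and no UTRs are derived.
#'
#' @param gene_id,chrom,start,end,strand scalar gene description; `strand`
#'   is `"+"` or `"-"`.
#' @param exon_start,exon_end exon coordinates.
#' @param cds_start,cds_end optional CDS (thick) region; exon portions
#'   outside it become UTRs, 5' vs 3' assigned by strand.
#' @return list of class `gene_model` with elements `utr5`/`utr3` as
#'   two-column matrices (possibly 0 rows).
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       exon_start = start, exon_end = end,
                       cds_start = start, cds_end = start) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-' for gene ", gene_id)
  o <- order(exon_start)
  exon_start <- exon_start[o]; exon_end <- exon_end[o]
  if (any(exon_end <= exon_start)) stop("empty exon in gene ", gene_id)
  if (length(exon_start) > 1 &&
      any(exon_start[-1] < exon_end[-length(exon_end)]))
    stop("overlapping exons in gene ", gene_id)
  if (exon_start[1] < start || exon_end[length(exon_end)] > end)
    stop("exons outside gene span in gene ", gene_id)
  utr_lo <- utr_hi <- cbind(start = integer(0), end = integer(0))
  if (cds_end > cds_start) {
    utr_lo <- clip_intervals(exon_start, exon_end, start, cds_start)
    utr_hi <- clip_intervals(exon_start, exon_end, cds_end, end)
  }
  if (strand == "+") { utr5 <- utr_lo; utr3 <- utr_hi } else { utr5 <- utr_hi; utr3 <- utr_lo }
  structure(list(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand,
                 exons = cbind(start = exon_start, end = exon_end),
                 cds = c(cds_start, cds_end), utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

clip_intervals <- function(s, e, lo, hi) {
  ns <- pmax(s, lo); ne <- pmin(e, hi)
  keep <- ne > ns
  cbind(start = ns[keep], end = ne[keep])
}

#' Transcription start site of a gene model (strand-aware)
#' @param gene a [gene_model()].
#' @return 0-based position of the TSS.
#' @export
gene_tss <- function(gene) if (gene$strand == "+") gene$start else gene$end - 1L

#' Write an interval set as BED
#' @param x an [interval_set()].
#' @param path output path.
#' @param extra character vector of payload columns to append after name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = character(0)) {
  cols <- c("chrom", "start", "end",
            if ("name" %in% names(x)) "name", extra)
  utils::write.table(as.data.frame(x)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
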