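#' Classify SVs into the seven genic categories
#'
#' Each SV is assigned every category whose feature span it overlaps by at
#' least 1 bp: exonic, intronic, upstream (2 kb 5' of the TSS,
#' strand-aware), downstream (2 kb 3' of the gene end), 5' UTR and 3' UTR
#' (when the gene model has a CDS); an SV overlapping no feature or flank
#' of any gene is intergenic. An SV may therefore carry several categories
#' simultaneously. SV spans use the BED conversion of [sv_intervals()]
#' (insertions are 1-bp points).
#'
#' @param svset an [sv_set()].
#' @param genes list of [gene_model()]s.
#' @param flank flank size in bp for upstream/downstream (default 2000).
#' @return list of class `genic_annotation`: `categories` (per-SV list of
#'   category names), `hits` (data.frame `id`, `gene_id`, `category`),
#'   `category_counts` (SV-category incidences), `distinct_counts`
#'   (distinct SVs per category).
#' @export
classify_genic_regions <- function(svset, genes, flank = 2000) {
  iv <- sv_intervals(svset)
  feat <- gene_features(genes, flank)
  hits_rows <- list()
  if (nrow(feat)) {
    pairs <- overlap_pairs(interval_set(iv), feat)
    if (nrow(pairs)) {
      # overlap_pairs sorts interval sets internally via interval_set();
      # map back through the sorted copies
      ivs <- interval_set(iv)
      hits_rows <- data.frame(id = ivs$id[pairs$idx_a],
                              gene_id = feat$gene_id[pairs$idx_b],
                              category = feat$category[pairs$idx_b],
                              stringsAsFactors = FALSE)
      hits_rows <- unique(hits_rows)
    }
  }
  hits <- if (length(hits_rows)) hits_rows else
    data.frame(id = character(0), gene_id = character(0),
               category = character(0), stringsAsFactors = FALSE)
  cats <- lapply(iv$id, function(i) {
    cc <- unique(hits$category[hits$id == i])
    if (!length(cc)) "intergenic" else cc
  })
  names(cats) <- iv$id
  all_cats <- c("intergenic", "intronic", "exonic", "upstream",
                "downstream", "utr3", "utr5")
  incidence <- table(factor(unlist(cats), levels = all_cats))
  distinct <- vapply(all_cats, function(cc)
    sum(vapply(cats, function(x) cc %in% x, logical(1))), numeric(1))
  structure(list(categories = cats, hits = hits,
                 category_counts = c(incidence),
                 distinct_counts = distinct),
            class = "genic_annotation")
}

# Feature table (interval_set + gene_id + category) induced by gene models.
gene_features <- function(genes, flank = 2000) {
  rows <- list()
  for (g in genes) {
    if (is.null(g$strand)) stop("gene without strand: ", g$gene_id)
    ex <- g$exons
    if (nrow(ex) == 0) {
      message("gene ", g$gene_id, " has no exons; treated as single-exon span")
      ex <- cbind(start = g$start, end = g$end)
    }
    add <- function(s, e, cat) {
      keep <- e > s
      if (!any(keep)) return(NULL)
      data.frame(chrom = g$chrom, start = s[keep], end = e[keep],
                 gene_id = g$gene_id, category = cat,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add(ex[, "start"], ex[, "end"], "exonic")
    if (nrow(ex) > 1)
      rows[[length(rows) + 1L]] <-
        add(ex[-nrow(ex), "end"], ex[-1, "start"], "intronic")
    if (g$strand == "+") {
      up <- c(max(g$start - flank, 0), g$start)
      dn <- c(g$end, g$end + flank)
    } else {
      up <- c(g$end, g$end + flank)
      dn <- c(max(g$start - flank, 0), g$start)
    }
    rows[[length(rows) + 1L]] <- add(up[1], up[2], "upstream")
    rows[[length(rows) + 1L]] <- add(dn[1], dn[2], "downstream")
    if (nrow(g$utr5))
      rows[[length(rows) + 1L]] <- add(g$utr5[, "start"], g$utr5[, "end"], "utr5")
    if (nrow(g$utr3))
      rows[[length(rows) + 1L]] <- add(g$utr3[, "start"], g$utr3[, "end"], "utr3")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0),
                      category = character(0)))
  interval_set(do.call(rbind, rows))
}

#' Summarize SV-gene annotation
#'
#' SV-genes are genes overlapped by at least one SV in any genic category
#' (flanks included); the remaining genes are nonSV-genes. Reports how
#' many genes carry exonic and intronic SVs, their percentages over the
#' SV-gene total, and the intron/exon gene-count ratio.
#'
#' @param annotation a [classify_genic_regions()] result.
#' @param all_genes character vector of all gene ids in the annotation
#'   universe.
#' @return list: `sv_genes`, `nonsv_genes`, `n_exonic_genes`,
#'   `n_intronic_genes`, `pct_exonic`, `pct_intronic`,
#'   `intron_exon_ratio` (NA when no exonic genes).
#' @export
sv_gene_summary <- function(annotation, all_genes) {
  h <- annotation$hits
  sv_genes <- sort(unique(h$gene_id))
  nonsv <- sort(setdiff(all_genes, sv_genes))
  ex_genes <- unique(h$gene_id[h$category == "exonic"])
  in_genes <- unique(h$gene_id[h$category == "intronic"])
  n_sv <- length(sv_genes)
  list(sv_genes = sv_genes, nonsv_genes = nonsv,
       n_exonic_genes = length(ex_genes),
       n_intronic_genes = length(in_genes),
       pct_exonic = if (n_sv) 100 * length(ex_genes) / n_sv else NA_real_,
       pct_intronic = if (n_sv) 100 * length(in_genes) / n_sv else NA_real_,
       intron_exon_ratio = if (length(ex_genes))
         round(length(in_genes) / length(ex_genes), 2) else NA_real_)
}
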