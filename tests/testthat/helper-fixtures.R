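# Small in-code fixtures shared across test files.

toy_records <- function(n, chrom = "chr1", svtype = "DEL", start = NULL,
                        len = 100L) {
  if (is.null(start)) start <- seq(1000L, by = 10000L, length.out = n)
  len <- rep_len(as.integer(len), n)
  svtype <- rep_len(svtype, n)
  end <- ifelse(svtype == "INS", start, start + len - 1L)
  data.frame(id = sprintf("T%03d", seq_len(n)), chrom = rep_len(chrom, n),
             start = start, end = end, svtype = svtype,
             length = len, stringsAsFactors = FALSE)
}

# svset from an explicit samples x loci dosage matrix
toy_svset <- function(gt, ...) {
  gt <- as.matrix(gt)
  rec <- toy_records(ncol(gt), ...)
  sv_set(rec, gt, sprintf("s%02d", seq_len(nrow(gt))))
}

toy_meta <- function(svset, population, group = NULL, species = NULL) {
  population <- rep_len(population, length(svset$samples))
  if (is.null(group))
    group <- ifelse(grepl("wild", population), "wild", "native")
  if (is.null(species)) species <- population
  sample_meta(data.frame(sample_id = svset$samples,
                         population = population,
                         group = rep_len(group, length(population)),
                         species = rep_len(species, length(population)),
                         stringsAsFactors = FALSE))
}

total_span_of <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Two-population cohort with Balding-Nichols drift, no planted signals.
two_pop_cohort <- function(n_loci = 500, n = 20, F = 0.05, seed = 1,
                           F2 = F) {
  sc <- sv_scenario(
    n_loci = n_loci, seed = seed,
    populations = data.frame(
      name = c("wildA", "domB"), group = c("wild", "native"),
      species = c("wild_sp", "dom_sp"), n = c(n, n), F = c(F, F2),
      stringsAsFactors = FALSE))
  simulate_cohort(sc)
}
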