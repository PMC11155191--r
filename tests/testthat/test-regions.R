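test_that("breakpoints land in both overlapping windows", {
  rec <- toy_records(1, start = 2300001L, len = 100000L)  # [2.3, 2.4] Mb
  sv <- sv_set(rec, matrix(1L, 1, 1), "s1")
  dens <- breakpoint_density(sv, c(chr1 = 10e6))
  d <- as.data.frame(dens)
  hit <- d[d$count > 0, ]
  # both breakpoints fall in [1.5,2.5) and [2.0,3.0); each counts twice
  expect_setequal(hit$start, c(1.5e6, 2e6))
  expect_equal(hit$count, c(2, 2))
  expect_error(breakpoint_density(sv, c(chrX = 1e6)), "unknown chromosome")
})

test_that("window counts equal a brute-force per-breakpoint scan", {
  set.seed(23)
  n <- 100
  start <- sort(sample.int(9e6, n))
  rec <- toy_records(n, start = as.integer(start),
                     len = sample(100:5000, n, replace = TRUE),
                     svtype = sample(c("DEL", "INS", "DUP"), n, TRUE))
  rec$end <- ifelse(rec$svtype == "INS", rec$start,
                    rec$start + rec$length - 1L)
  sv <- sv_set(rec, matrix(1L, 1, n), "s1")
  dens <- breakpoint_density(sv, c(chr1 = 10e6))
  bp <- sv_breakpoints(sv)
  expect_equal(as.data.frame(dens)$count,
               oracle_window_counts(bp$pos, 10e6))
  # two breakpoints for span types, one for INS
  expect_equal(nrow(bp), sum(rec$svtype != "INS") * 2 + sum(rec$svtype == "INS"))
})

test_that("every interior position is tiled by exactly two windows", {
  coh <- two_pop_cohort(n_loci = 50, n = 4, seed = 77)
  dens <- breakpoint_density(coh$svset, c(chr1 = 50e6, chr2 = 40e6))
  d <- as.data.frame(dens)
  for (pos in c(1.7e6, 25e6, 33.2e6)) {
    cover <- sum(d$chrom == "chr1" & d$start <= pos & pos < d$start + 1e6)
    expect_equal(cover, 2)
  }
})

test_that("hotspot ranking, tie handling and merging follow the decile rule", {
  d <- interval_set(chrom = "chr1", start = seq(0, 4.5e6, by = 5e5),
                    end = seq(0, 4.5e6, by = 5e5) + 1e6)
  d$count <- c(9, 8, 7, 6, 5, 4, 3, 2, 1, 0)
  class(d) <- c("window_density", class(d))
  hs <- hotspot_detect(d)
  expect_equal(nrow(hs$windows), 1)
  expect_equal(hs$windows$count, 9)
  # adjacent hotspot windows merge into one region
  d2 <- d; d2$count <- c(9, 9, 0, 0, 0, 0, 0, 0, 0, 1)
  hs2 <- hotspot_detect(d2)
  expect_equal(nrow(hs2$regions), 1)
  expect_equal(hs2$regions$end - hs2$regions$start, 1.5e6)
  expect_equal(unname(hs2$summary["total_span"]), 1.5e6)
  # merged span equals the union of member windows
  expect_equal(unname(hs2$summary["total_span"]),
               total_span_of(hs2$windows))
  d0 <- d; d0$count <- rep(0, 10)
  expect_error(hotspot_detect(d0), "all-zero")
})

test_that("telomere counts are exact and the test flags extreme enrichment", {
  # all breakpoints in the first 5 Mb of a 50-Mb chromosome
  n <- 40
  rec <- toy_records(n, start = as.integer(seq(1e5, 4.5e6, length.out = n)),
                     len = 1000L)
  sv <- sv_set(rec, matrix(1L, 1, n), "s1")
  te <- telomere_enrichment(sv, c(chr1 = 50e6))
  expect_equal(te$n_telomeric, 2 * n)
  expect_equal(te$n_nontelomeric, 0)
  expect_lt(te$p, 0.01)
  # per-bin counts equal a brute-force recount
  bp <- sv_breakpoints(sv)
  brute <- vapply(seq(0, 49e6, by = 1e6), function(s)
    sum(bp$pos >= s & bp$pos < s + 1e6), numeric(1))
  expect_equal(te$bins$count, brute)
  expect_error(telomere_enrichment(sv, c(chr1 = 9e6)), "too short")
})

test_that("overlap matching reproduces the fractional-overlap rules", {
  a <- interval_set(chrom = "chr1", start = 100, end = 200)
  b <- interval_set(chrom = "chr1", start = 150, end = 350)
  # overlap 50 = 0.5 of a, 0.25 of b
  m_either <- overlap_match(a, b, 0.3, 0.3, mode = "either")
  expect_equal(nrow(m_either), 1)
  expect_equal(m_either$overlap, 50)
  m_both <- overlap_match(a, b, 0.3, 0.3, mode = "both")
  expect_equal(nrow(m_both), 0)
  inv <- overlap_match(a, b, 0.3, 0.3, mode = "both", invert = TRUE)
  expect_equal(nrow(inv), 1)
})

test_that("overlap matching equals the quadratic brute-force scan", {
  set.seed(29)
  mk <- function(n) {
    s <- sample.int(1e6, n)
    interval_set(chrom = sample(c("c1", "c2"), n, TRUE), start = s,
                 end = s + sample.int(5e4, n))
  }
  A <- mk(200); B <- mk(200)
  for (mode in c("either", "both")) {
    got <- overlap_match(A, B, 0.3, 0.3, mode = mode)
    want <- oracle_overlap_pairs(A, B, 0.3, 0.3, mode)
    got_keys <- sort(paste(got$idx_a, got$idx_b))
    want_keys <- sort(paste(want[, 1], want[, 2]))
    expect_identical(got_keys, want_keys)
  }
  # either-mode match existence is symmetric under set swap (equal fractions)
  gAB <- overlap_match(A, B, 0.3, 0.3, mode = "either")
  gBA <- overlap_match(B, A, 0.3, 0.3, mode = "either")
  expect_identical(sort(paste(gAB$idx_a, gAB$idx_b)),
                   sort(paste(gBA$idx_b, gBA$idx_a)))
})

test_that("novelty calls are exact on constructed catalogs", {
  coh <- two_pop_cohort(n_loci = 100, n = 4, seed = 83)
  iv <- sv_intervals(coh$svset)
  catalog <- interval_set(chrom = iv$chrom, start = iv$start, end = iv$end)
  nv <- novel_svs(coh$svset, catalog)
  expect_equal(nv$n_novel, 0)
  far <- interval_set(chrom = "chrZ", start = 1, end = 100)
  expect_equal(novel_svs(coh$svset, far)$n_novel, 100)
  # half-planted overlap fixture: catalog covers the first 50 loci only
  cat50 <- interval_set(chrom = iv$chrom[1:50], start = iv$start[1:50],
                        end = iv$end[1:50])
  nv50 <- novel_svs(coh$svset, cat50)
  expect_setequal(nv50$novel_ids, iv$id[51:100])
  expect_warning(novel_svs(coh$svset, catalog[0, ]), "empty catalog")
})

test_that("QTL fold enrichment follows the observed/expected arithmetic", {
  # toy genome 10 Mb, QTL 1 Mb, 10 carried SVs of which 3 inside the QTL
  starts <- c(as.integer(seq(1e5, 9e5, length.out = 3)),       # in QTL
              as.integer(seq(2e6, 9.5e6, length.out = 7)))     # outside
  rec <- toy_records(10, start = starts, len = 1000L)
  sv <- sv_set(rec, matrix(1L, 1, 10), "s1")
  qtl <- interval_set(chrom = "chr1", start = 0, end = 1e6, trait = "milk")
  fe <- qtl_enrichment(sv, qtl, c(chr1 = 10e6))
  expect_equal(fe$observed, 3)
  expect_equal(fe$expected, 1)
  expect_equal(fe$log2_fe, log2(3), tolerance = 1e-12)
  expect_equal(round(fe$log2_fe, 3), 1.585)
  # no carried SVs in the QTL -> pseudocount flagged
  sv2 <- sv_subset(sv, loci = 4:10)
  fe2 <- qtl_enrichment(sv2, qtl, c(chr1 = 10e6))
  expect_true(fe2$pseudocount)
  expect_equal(fe2$log2_fe, log2(0.5 / 0.7))
})

test_that("Peak-SV classification enforces the strict 50% boundary", {
  rec <- toy_records(2, start = c(1L, 10001L), len = 1000L)
  sv <- sv_set(rec, matrix(1L, 1, 2), "s1")
  # SV1 [0,1000): peak overlap 499 bp -> nonPeak; SV2 fully inside a peak
  peaks <- interval_set(chrom = "chr1", start = c(0, 9000), end = c(499, 12000))
  pc <- peak_sv_classify(sv, peaks)
  expect_equal(pc$nonpeak_sv, "T001")
  expect_equal(pc$peak_sv, "T002")
  # exactly 500 of 1000 -> Peak-SV (>= rule)
  peaks2 <- interval_set(chrom = "chr1", start = 0, end = 500)
  expect_equal(peak_sv_classify(sv, peaks2)$peak_sv, "T001")
  # coverage accumulates across merged peaks
  peaks3 <- interval_set(chrom = "chr1", start = c(0, 300), end = c(250, 600))
  expect_equal(peak_sv_classify(sv, peaks3)$peak_sv, "T001")  # 250+300 >= 500
  expect_equal(length(pc$peak_sv) + length(pc$nonpeak_sv), 2)
})

test_that("promoter peaks are excluded from enhancer candidates", {
  genes <- list(
    gene_model("gplus", "chr1", 10000, 20000, "+"),
    gene_model("gminus", "chr1", 50000, 60000, "-"))
  peaks <- interval_set(chrom = "chr1",
                        start = c(9500, 30000, 59500, 80000),
                        end = c(10500, 30400, 60500, 80400))
  ec <- enhancer_candidates(peaks, genes)
  # peak on + TSS (10000) and peak on - TSS (59999) excluded
  expect_equal(ec$n_promoter, 2)
  expect_equal(ec$candidates$start, c(30000, 80000))
  # SV support: candidate containing >= 50% of an SV
  rec <- toy_records(1, start = 30001L, len = 300L)
  sv <- sv_set(rec, matrix(1L, 1, 1), "s1")
  supp <- sv_supported_enhancers(ec$candidates, sv)
  expect_equal(supp$start, 30000)
})
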