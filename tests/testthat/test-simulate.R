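test_that("identical seeds give identical cohorts and truth", {
  a <- two_pop_cohort(n_loci = 200, n = 8, seed = 13)
  b <- two_pop_cohort(n_loci = 200, n = 8, seed = 13)
  expect_identical(a$svset, b$svset)
  expect_identical(a$truth, b$truth)
  c2 <- two_pop_cohort(n_loci = 200, n = 8, seed = 14)
  expect_false(identical(a$svset$genotypes, c2$svset$genotypes))
})

test_that("the no-drift limit yields near-zero differentiation", {
  coh <- two_pop_cohort(n_loci = 2000, n = 30, F = 0.001, seed = 17)
  fst <- wc_fst(coh$svset, coh$meta, "wildA", "domB")
  expect_lt(abs(fst$weighted), 0.02)
})

test_that("simulated drift is recovered by genome-wide weighted theta", {
  coh <- two_pop_cohort(n_loci = 5000, n = 30, F = 0.15, seed = 19)
  fst <- wc_fst(coh$svset, coh$meta, "wildA", "domB")
  expect_equal(fst$weighted, 0.15, tolerance = 0.03 / 0.15)
})

test_that("the ancestral-frequency law is rare-skewed at cohort scale", {
  coh <- two_pop_cohort(n_loci = 3000, n = 30, F = 0.05, seed = 23)
  ls <- locus_summary(coh$svset)
  seg <- !is.na(ls$p) & ls$p > 0 & ls$p < 1
  maf <- ls$maf[seg]
  # strongly rare-skewed spectrum: the lowest MAF band dominates and the
  # spectrum decreases towards intermediate frequencies
  expect_gte(mean(maf < 0.05), 0.25)
  expect_gt(mean(maf < 0.05), 3 * mean(maf >= 0.45))
  expect_gt(mean(maf < 0.01), 0.05)
})

test_that("the default type mix is DEL-dominant with lengths in 50bp-1Mb", {
  coh <- two_pop_cohort(n_loci = 2000, n = 4, seed = 29)
  tab <- table(coh$svset$records$svtype) / 2000
  expect_gt(tab[["DEL"]], 0.7)
  expect_true(all(coh$svset$records$length >= 50))
  expect_true(all(coh$svset$records$length <= 1e6))
})

test_that("planted hotspot clusters dominate breakpoint density", {
  hits <- vapply(1:10, function(s) {
    sc <- sv_scenario(
      n_loci = 600, seed = 100 + s,
      genome = c(chr1 = 50e6, chr2 = 40e6),
      hotspots = data.frame(chrom = c("chr1", "chr2"),
                            center = c(10e6, 30e6), sd = c(2e5, 2e5),
                            weight = c(5, 5)),
      populations = data.frame(
        name = c("wildA", "domB"), group = c("wild", "native"),
        species = c("w", "d"), n = c(6, 6), F = c(0.05, 0.05),
        stringsAsFactors = FALSE))
    coh <- simulate_cohort(sc)
    hs <- hotspot_detect(breakpoint_density(coh$svset, sc$genome))
    rg <- hs$regions
    in1 <- any(rg$chrom == "chr1" & rg$start <= 10e6 & rg$end > 10e6)
    in2 <- any(rg$chrom == "chr2" & rg$start <= 30e6 & rg$end > 30e6)
    in1 && in2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("planted introgressed loci satisfy the filter criteria exactly", {
  sc <- sv_scenario(
    n_loci = 400, seed = 31,
    populations = data.frame(
      name = c("mouflon", "nat1", "nat2", "bighorn"),
      group = c("wild", "native", "native", "wild"),
      species = c("mouflon_sp", "dom", "dom", "bighorn_sp"),
      n = c(10, 10, 10, 6), F = c(0.05, 0.05, 0.05, 0.2),
      stringsAsFactors = FALSE),
    introgressed = data.frame(recipient = "nat1", donor = "mouflon_sp",
                              n = 4))
  coh <- simulate_cohort(sc)
  fm_pop <- freq_matrix(coh$svset, coh$meta, "population")
  fm_sp <- freq_matrix(coh$svset, coh$meta, "species")
  for (id in coh$truth$introgressed$id) {
    expect_gt(fm_pop[id, "nat1"], 0)
    expect_equal(unname(fm_pop[id, "nat2"]), 0)
    expect_equal(unname(fm_sp[id, "mouflon_sp"]), 1)
    expect_equal(unname(fm_sp[id, "bighorn_sp"]), 0)
  }
})

test_that("phenotype simulation matches its analytic variance structure", {
  coh <- two_pop_cohort(n_loci = 100, n = 250, F = 0.05, seed = 37)
  # beta = 0: Var(y) = sigma^2
  ph0 <- simulate_phenotypes(coh$svset, NULL,
                             list(n_causal = 2, beta = 0, sigma = 2),
                             seed = 5)
  expect_equal(stats::var(ph0$y), 4, tolerance = 0.15)
  expect_error(simulate_phenotypes(coh$svset, NULL,
                                   list(n_causal = 1, beta = 1, sigma = 0)),
               "sigma")
  # single causal locus with true share 0.2 (share = v/(v + sigma^2))
  ls <- locus_summary(coh$svset)
  target <- coh$svset$records$id[which.min(abs(ls$p - 0.5))]
  p <- ls$p[ls$id == target]
  vg <- 2 * p * (1 - p)
  sigma <- sqrt(vg * (1 - 0.2) / 0.2)
  ph <- simulate_phenotypes(coh$svset, NULL,
                            list(causal = target, beta = 1, sigma = sigma),
                            seed = 6)
  expect_equal(ph$causal$var_share, 0.2, tolerance = 0.05 / 0.2)
})

test_that("phenotypes track samples, not positions", {
  coh <- two_pop_cohort(n_loci = 50, n = 10, seed = 41)
  ph <- simulate_phenotypes(coh$svset, NULL,
                            list(n_causal = 3, beta = 1, sigma = 1),
                            seed = 7)
  perm <- sample(length(coh$svset$samples))
  sv_perm <- sv_subset(coh$svset, samples = perm)
  ph_perm <- simulate_phenotypes(sv_perm, NULL,
                                 list(causal = ph$causal$id, beta = 1,
                                      sigma = 1), seed = 7)
  # genetic values must permute with the samples (residuals are redrawn,
  # so compare the deterministic genetic component)
  gv <- function(sv, ids) {
    G <- sv$genotypes[, ids, drop = FALSE]; G[is.na(G)] <- 0L
    rowSums(G)
  }
  expect_equal(unname(gv(sv_perm, ph$causal$id)),
               unname(gv(coh$svset, ph$causal$id)[perm]))
})

test_that("fixture sets round-trip and reference only real loci", {
  coh <- two_pop_cohort(n_loci = 80, n = 5, seed = 43)
  d <- withr::local_tempdir()
  fx <- write_fixture_set(coh, d)
  back <- read_sv_vcf(fx[["vcf"]])
  expect_identical(back$genotypes, coh$svset$genotypes)
  truth <- jsonlite::read_json(fx[["truth"]], simplifyVector = TRUE)
  expect_true(all(rownames(coh$truth$pop_freq) %in% back$records$id))
  expect_equal(truth$scenario_seed, 43)
  # regenerating from the recorded seed is byte-identical
  coh2 <- two_pop_cohort(n_loci = 80, n = 5, seed = truth$scenario_seed)
  d2 <- withr::local_tempdir()
  fx2 <- write_fixture_set(coh2, d2)
  expect_identical(readLines(fx[["vcf"]]), readLines(fx2[["vcf"]]))
})
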