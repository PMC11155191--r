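test_that("ancestral polarization follows the wild majority with tie rule", {
  # wild genotypes [0,0,1]: 5 ref vs 1 alt copies -> ancestral ref
  sv <- toy_svset(cbind(c(0L, 0L, 1L, 2L, 2L)))
  meta <- toy_meta(sv, c(rep("wildA", 3), rep("domB", 2)))
  pol <- polarize_ancestral(sv, meta, "wildA")
  expect_equal(pol$ancestral, "ref")
  fr <- freq_matrix(sv, meta)
  der <- derived_frequencies(fr, pol)
  expect_equal(unname(der["T001", "wildA"]), 1 / 6)
  # tie: [1,1] -> 2 ref, 2 alt copies -> ambiguous
  sv2 <- toy_svset(cbind(c(1L, 1L, 0L)))
  meta2 <- toy_meta(sv2, c("wildA", "wildA", "domB"))
  pol2 <- polarize_ancestral(sv2, meta2, "wildA")
  expect_equal(pol2$status, "ambiguous")
  expect_true(is.na(di_sv(sv2, meta2, "domB", "wildA")$di_sv))
  # no wild calls -> unpolarizable
  sv3 <- toy_svset(cbind(c(NA, 1L)))
  meta3 <- toy_meta(sv3, c("wildA", "domB"))
  expect_equal(polarize_ancestral(sv3, meta3, "wildA")$status, "unpolarizable")
})

test_that("polarization recovers the simulator's ancestral allele", {
  coh <- two_pop_cohort(n_loci = 2000, n = 30, F = 0.05, seed = 61)
  pol <- polarize_ancestral(coh$svset, coh$meta, "wildA")
  ok <- pol$status == "ok"
  truth_anc <- ifelse(coh$truth$p0 > 0.5, "alt", "ref")
  # at loci where the ancestral frequency is decisive
  decisive <- ok & abs(coh$truth$p0 - 0.5) > 0.1
  expect_gt(mean(pol$ancestral[decisive] == truth_anc[decisive]), 0.95)
})

test_that("DI_SV is the signed derived-frequency difference", {
  # wild 1/10 alt (ancestral ref), domestic 9/10 alt
  sv <- toy_svset(cbind(c(0L, 0L, 0L, 0L, 1L, 2L, 2L, 2L, 2L, 1L)))
  meta <- toy_meta(sv, rep(c("wildA", "domB"), each = 5))
  d <- di_sv(sv, meta, "domB", "wildA")
  expect_equal(d$f_wild, 0.1)
  expect_equal(d$f_dom, 0.9)
  expect_equal(d$di_sv, 0.8)
  # swapping the frequency arguments under a fixed polarization flips the sign
  d_sw <- di_sv(sv, meta, "wildA", "domB", polarize_with = "wildA")
  expect_equal(d_sw$di_sv, -d$di_sv)
  # equal derived frequencies -> 0
  sv2 <- toy_svset(cbind(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L)))
  meta2 <- toy_meta(sv2, rep(c("wildA", "domB"), 4))
  expect_equal(di_sv(sv2, meta2, "domB", "wildA")$di_sv, 0)
})

test_that("permutation P is 0 at a fixed difference and matches enumeration", {
  sv <- toy_svset(cbind(c(rep(2L, 4), rep(0L, 4))))
  meta <- toy_meta(sv, rep(c("A", "B"), each = 4))
  pp <- fst_permutation_pvalue(sv, meta, "A", "B", B = 50, seed = 1)
  expect_equal(pp$p_perm, 0)
  # 4-vs-4: Monte Carlo vs exhaustive enumeration over C(8,4) = 70 splits
  g8 <- c(0L, 1L, 2L, 1L, 0L, 0L, 1L, 2L)
  sv2 <- toy_svset(cbind(g8))
  meta2 <- toy_meta(sv2, rep(c("A", "B"), each = 4))
  obs <- oracle_wc_theta(g8[1:4], g8[5:8])
  p_exact <- oracle_exhaustive_perm_p(g8, obs)
  p_mc <- fst_permutation_pvalue(sv2, meta2, "A", "B", B = 10000,
                                 seed = 2)$p_perm
  expect_equal(p_mc, p_exact, tolerance = 0.02 / max(p_exact, 0.01))
})

test_that("permutation P is calibrated under the null", {
  # both populations drawn from the same distribution; independent
  # per-locus shuffles so loci are exchangeable draws for the KS test.
  # theta-hat is discrete at this scale, so calibration is assessed on
  # the mid-P variant; the conservative >= variant must remain valid.
  set.seed(3)
  g <- matrix(rbinom(40 * 400, 2, 0.4), 40, 400)
  sv <- toy_svset(g, start = seq(1000L, by = 3000L, length.out = 400))
  meta <- toy_meta(sv, rep(c("A", "B"), each = 20))
  pp <- fst_permutation_pvalue(sv, meta, "A", "B", B = 200, seed = 5,
                               per_locus = TRUE, ties = "midp")
  p <- pp$p_perm[!is.na(pp$p_perm)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(p), 0.5, tolerance = 0.1)
  pg <- fst_permutation_pvalue(sv, meta, "A", "B", B = 200, seed = 5,
                               per_locus = TRUE, ties = "geq")$p_perm
  expect_lte(mean(pg <= 0.05, na.rm = TRUE), 0.07)  # valid at alpha = 0.05
})

test_that("PBS matches closed forms and branch-length properties", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.5, 0), -log(0.5), tolerance = 1e-6)
  expect_equal(pbs(0.5, 0.5, 0), 0.6931, tolerance = 1e-3)
  # theta = 1 stays finite via the clamp
  expect_true(is.finite(pbs(1, 0.5, 0.2)))
  set.seed(7)
  for (k in 1:20) {
    th <- runif(3, -0.1, 0.9)
    # symmetric in exchange of populations 2 and 3
    expect_equal(pbs(th[1], th[2], th[3]), pbs(th[2], th[1], th[3]))
    # strictly increasing in theta12
    expect_gt(pbs(th[1] + 0.05, th[2], th[3]), pbs(th[1], th[2], th[3]))
  }
  # equidistant outgroup: PBS = T12/2
  expect_equal(pbs(0.3, 0.2, 0.2), -log(1 - 0.3) / 2)
})

test_that("candidate thresholds use descending rank with ties included", {
  x <- c(100:1) / 100                     # 100 loci, values 1.00 ... 0.01
  cs <- candidate_selection(list(s = x),
                            list(list(stat = "s", type = "top", q = 0.05)),
                            ids = sprintf("L%03d", 1:100))
  expect_equal(sum(cs$candidate), 5)
  expect_equal(cs$thresholds[[1]]$threshold, 0.96)
  # ties at the threshold included
  x2 <- c(rep(1, 3), rep(0.96, 4), 93:1 / 100)
  cs2 <- candidate_selection(list(s = x2),
                             list(list(stat = "s", type = "top", q = 0.05)),
                             ids = sprintf("M%03d", 1:100))
  expect_equal(sum(cs2$candidate), 7)   # 3 + all four tied at 0.96
  # intersection of disjoint rules is empty with a warning
  expect_warning(
    cs3 <- candidate_selection(
      list(a = c(rep(1, 5), rep(0, 95)), b = c(rep(0, 95), rep(1, 5))),
      list(list(stat = "a", type = "top", q = 0.05),
           list(stat = "b", type = "top", q = 0.05)),
      ids = sprintf("N%03d", 1:100)),
    "empty")
  expect_equal(sum(cs3$candidate), 0)
})

test_that("candidate flagging is idempotent given the stored threshold", {
  set.seed(9)
  x <- runif(200)
  ids <- sprintf("L%03d", 1:200)
  cs <- candidate_selection(list(s = x),
                            list(list(stat = "s", type = "top", q = 0.05)),
                            ids = ids)
  thr <- cs$thresholds[[1]]$threshold
  expect_equal(as.integer(which(cs$candidate)), which(x >= thr))
  # re-applying the stored threshold reproduces the flag set exactly
  expect_equal(cs$ids[cs$candidate], ids[x >= thr])
})

test_that("planted selected loci are found by the intersection rule", {
  sc <- sv_scenario(
    n_loci = 2000, seed = 71,
    populations = data.frame(
      name = c("wildA", "domB"), group = c("wild", "native"),
      species = c("w", "d"), n = c(30, 30), F = c(0.05, 0.05),
      stringsAsFactors = FALSE),
    selected = data.frame(pop = "domB", delta = 0.6, n = 100))
  coh <- simulate_cohort(sc)
  pp <- fst_permutation_pvalue(coh$svset, coh$meta, "domB", "wildA",
                               B = 200, seed = 72)
  dv <- di_sv(coh$svset, coh$meta, "domB", "wildA")
  cs <- candidate_selection(
    list(p_perm = pp$p_perm, di_sv = dv$di_sv),
    list(list(stat = "p_perm", type = "lt", q = 0.05),
         list(stat = "di_sv", type = "top", q = 0.05)),
    ids = coh$svset$records$id)
  called <- cs$ids[cs$candidate]
  truth <- coh$truth$selected$id
  precision <- mean(called %in% truth)
  recall <- mean(truth %in% called)
  expect_gte(precision, 0.5)
  expect_gte(recall, 0.5)
  # planted loci rank in the top 5% of DI_SV
  top5 <- cs$ids[cs$flags[, "di_sv"]]
  expect_gte(mean(truth %in% top5), 0.5)
})

test_that("group-frequency Wilcoxon matches exhaustive rank enumeration", {
  freqs <- rbind(L1 = c(0.9, 0.8, 0.85, 0.1, 0.2),
                 L2 = c(0.5, 0.52, 0.48, 0.5, 0.51))
  colnames(freqs) <- c("p1", "p2", "p3", "q1", "q2")
  gw <- group_freq_wilcoxon(freqs, c("p1", "p2", "p3"), c("q1", "q2"))
  expect_equal(gw$p[1], oracle_wilcoxon_p(c(0.9, 0.8, 0.85), c(0.1, 0.2)))
  # BH: adjusted >= raw, monotone in rank order
  expect_true(all(gw$p_adj >= gw$p, na.rm = TRUE))
  ord <- order(gw$p)
  expect_true(all(diff(gw$p_adj[ord]) >= -1e-12))
  # identical groups -> maximal P
  freqs2 <- rbind(L1 = c(0.3, 0.3, 0.3, 0.3))
  colnames(freqs2) <- c("a1", "a2", "b1", "b2")
  gw2 <- group_freq_wilcoxon(freqs2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(gw2$p, 1)
  expect_error(group_freq_wilcoxon(freqs, "p1", c("q1", "q2")), ">= 2")
})
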