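#' Describe a synthetic SV cohort scenario
#'
#' The scenario fixes the statistical structure of a simulated
#' multi-population diploid SV cohort: a small genome, a DEL-dominant SV
#' type mix, log-uniform SV lengths in the 50 bp - 1 Mb calling window, a
#' rare-skewed ancestral allele-frequency law, Balding-Nichols drift per
#' population, optional Gaussian breakpoint hotspot clusters, planted
#' frequency-shifted (selected) loci, planted introgressed loci and an
#' additive SV-linked phenotype.
#'
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param n_loci number of SV loci.
#' @param type_mix probabilities over DEL/DUP/INV/INS/TRA (default
#'   approximates a domestic-sheep call set: DEL-dominant).
#' @param length_range log-uniform length bounds in bp.
#' @param maf_law `c(shape1, shape2)` of the Beta law for the ancestral
#'   alt-allele frequency (default `c(0.3, 2)`, rare-skewed).
#' @param populations data.frame with columns `name`, `group`
#'   (wild/native/improved), `species`, `n`, `F` (drift, in (0,1)).
#' @param hotspots optional data.frame `chrom`, `center`, `sd`, `weight`
#'   (weight = expected breakpoint mass relative to one uniform-background
#'   unit; loci are assigned to clusters with probability proportional to
#'   weight).
#' @param selected optional data.frame `pop` (target population name,
#'   may repeat), `delta` (derived-frequency shift, clipped to \[0,1\]),
#'   `n` (number of planted loci per row).
#' @param introgressed optional data.frame `recipient` (domestic
#'   population), `donor` (wild species name), `n` (loci); planted loci
#'   satisfy the three allele-frequency introgression criteria exactly on
#'   the realized genotypes (bounded resampling).
#' @param pheno optional list `n_causal`, `beta` (effect size per causal
#'   locus, recycled), `sigma` (residual sd).
#' @param seed RNG seed.
#' @return list of class `sv_scenario`.
#' @export
sv_scenario <- function(genome = c(chr1 = 50e6, chr2 = 40e6),
                        n_loci = 1000,
                        type_mix = c(DEL = 0.77, DUP = 0.05, INV = 0.02,
                                     INS = 0.10, TRA = 0.06),
                        length_range = c(50, 1e6),
                        maf_law = c(0.3, 2),
                        populations = data.frame(
                          name = c("wildA", "domB"),
                          group = c("wild", "native"),
                          species = c("wild_sp", "domestic_sp"),
                          n = c(20, 20), F = c(0.05, 0.05),
                          stringsAsFactors = FALSE),
                        hotspots = NULL, selected = NULL,
                        introgressed = NULL, pheno = NULL, seed = 1) {
  stopifnot(abs(sum(type_mix) - 1) < 1e-8,
            all(populations$F > 0), all(populations$F < 1),
            length_range[1] >= 50, length_range[2] <= 1e6)
  if (!all(populations$group %in% GROUPS))
    stop("population group must be one of ", paste(GROUPS, collapse = "/"))
  structure(list(genome = genome, n_loci = n_loci, type_mix = type_mix,
                 length_range = length_range, maf_law = maf_law,
                 populations = populations, hotspots = hotspots,
                 selected = selected, introgressed = introgressed,
                 pheno = pheno, seed = seed),
            class = "sv_scenario")
}

#' Simulate a multi-population diploid SV cohort
#'
#' Ancestral frequencies are drawn from the scenario's Beta law; each
#' population's frequency comes from the Balding-Nichols construction
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` so that the expected Weir-Cockerham
#' F_ST between two populations with drift `F` is approximately `F`.
#' Genotypes are binomial(2, p_pop) per sample. Breakpoint positions mix a
#' uniform background with the scenario's Gaussian hotspot clusters,
#' truncated to chromosome bounds. Selected loci get their target
#' populations' frequency shifted by `delta` (clipped to \[0,1\]);
#' introgressed loci are constructed to satisfy the introgression filter
#' criteria exactly on realized genotypes. Deterministic given the seed.
#'
#' @param scenario an [sv_scenario()].
#' @return list with `svset`, `meta` ([sample_meta()]) and `truth` (list:
#'   per-locus `p0`, population frequency matrix `pop_freq`, `selected`,
#'   `introgressed`, `hotspot_cluster`, `pheno`).
#' @export
simulate_cohort <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  pops <- sc$populations
  L <- sc$n_loci

  # --- loci ---------------------------------------------------------------
  svtype <- sample(names(sc$type_mix), L, replace = TRUE, prob = sc$type_mix)
  len <- as.integer(round(exp(stats::runif(
    L, log(sc$length_range[1]), log(sc$length_range[2])))))
  len <- pmin(pmax(len, 50L), 1000000L)
  chrom_names <- names(sc$genome)
  hot <- sc$hotspots
  n_clusters <- if (is.null(hot)) 0L else nrow(hot)
  cluster_of <- integer(L)   # 0 = background
  if (n_clusters > 0) {
    wts <- c(1, hot$weight)   # one unit of uniform background
    cluster_of <- sample.int(n_clusters + 1L, L, replace = TRUE,
                             prob = wts / sum(wts)) - 1L
  }
  chrom <- character(L); pos <- numeric(L)
  bg <- cluster_of == 0L
  chrom[bg] <- sample(chrom_names, sum(bg), replace = TRUE,
                      prob = sc$genome / sum(sc$genome))
  pos[bg] <- floor(stats::runif(sum(bg)) * sc$genome[chrom[bg]]) + 1
  for (k in seq_len(n_clusters)) {
    in_k <- cluster_of == k
    if (!any(in_k)) next
    chrom[in_k] <- hot$chrom[k]
    p <- round(stats::rnorm(sum(in_k), hot$center[k], hot$sd[k]))
    p <- pmin(pmax(p, 1), sc$genome[[hot$chrom[k]]] - 1)
    pos[in_k] <- p
  }
  chrlen <- sc$genome[chrom]
  # keep the whole span on-chromosome without shortening below 50 bp
  pos <- pmin(pos, pmax(chrlen - len, 1))
  start <- as.integer(pos)
  end <- as.integer(ifelse(svtype == "INS", start, start + len - 1L))
  len[svtype != "INS"] <- (end - start + 1L)[svtype != "INS"]
  ids <- sprintf("SV%05d", seq_len(L))
  records <- data.frame(id = ids, chrom = chrom, start = start, end = end,
                        svtype = svtype, length = len,
                        stringsAsFactors = FALSE)

  # --- frequencies --------------------------------------------------------
  p0 <- stats::rbeta(L, sc$maf_law[1], sc$maf_law[2])
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
  P <- matrix(NA_real_, L, nrow(pops), dimnames = list(ids, pops$name))
  for (j in seq_len(nrow(pops))) {
    F <- pops$F[j]
    P[, j] <- stats::rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  }

  selected_truth <- NULL
  locus_pool <- seq_len(L)
  if (!is.null(sc$selected)) {
    rows <- list()
    for (i in seq_len(nrow(sc$selected))) {
      tgt <- sc$selected$pop[i]
      if (!tgt %in% pops$name) stop("unknown selected target population: ", tgt)
      n_sel <- sc$selected$n[i]
      loci <- sample(locus_pool, n_sel)
      locus_pool <- setdiff(locus_pool, loci)
      P[loci, tgt] <- pmin(pmax(P[loci, tgt] + sc$selected$delta[i], 0), 1)
      rows[[i]] <- data.frame(id = ids[loci], pop = tgt,
                              delta = sc$selected$delta[i],
                              stringsAsFactors = FALSE)
    }
    selected_truth <- do.call(rbind, rows)
  }

  # --- genotypes ----------------------------------------------------------
  samples <- unlist(lapply(seq_len(nrow(pops)), function(j)
    sprintf("%s_%02d", pops$name[j], seq_len(pops$n[j]))))
  pop_of <- rep(pops$name, pops$n)
  G <- matrix(NA_integer_, length(samples), L,
              dimnames = list(samples, ids))
  for (j in seq_len(nrow(pops))) {
    rows <- which(pop_of == pops$name[j])
    G[rows, ] <- stats::rbinom(length(rows) * L, 2,
                               rep(P[, j], each = length(rows)))
  }

  # --- introgressed loci --------------------------------------------------
  introgressed_truth <- NULL
  if (!is.null(sc$introgressed)) {
    rows <- list()
    dom_pops <- pops$name[pops$group != "wild"]
    for (i in seq_len(nrow(sc$introgressed))) {
      rec_pop <- sc$introgressed$recipient[i]
      donor <- sc$introgressed$donor[i]
      donor_pops <- pops$name[pops$species == donor]
      if (!rec_pop %in% dom_pops) stop("recipient must be a domestic population")
      if (!length(donor_pops)) stop("unknown donor species: ", donor)
      n_int <- sc$introgressed$n[i]
      loci <- sample(locus_pool, n_int)
      locus_pool <- setdiff(locus_pool, loci)
      rec_rows <- which(pop_of == rec_pop)
      for (l in loci) {
        # donor wild species fixed; recipient segregating; everyone else 0
        G[, l] <- 0L
        G[pop_of %in% donor_pops, l] <- 2L
        for (try in 1:50) {
          g <- stats::rbinom(length(rec_rows), 2, 0.4)
          if (any(g > 0)) break
        }
        if (all(g == 0)) g[1] <- 1L
        G[rec_rows, l] <- g
        P[l, ] <- 0
        P[l, pops$name %in% donor_pops] <- 1
        P[l, rec_pop] <- sum(g) / (2 * length(g))
      }
      rows[[i]] <- data.frame(id = ids[loci], recipient = rec_pop,
                              donor = donor, stringsAsFactors = FALSE)
    }
    introgressed_truth <- do.call(rbind, rows)
  }

  meta <- sample_meta(data.frame(
    sample_id = samples, population = pop_of,
    group = pops$group[match(pop_of, pops$name)],
    species = pops$species[match(pop_of, pops$name)],
    stringsAsFactors = FALSE))
  svset <- sv_set(records, G, samples)

  # sv_set sorts loci; reorder truth to the sorted locus order
  ord <- match(svset$records$id, ids)
  truth <- list(
    p0 = p0[ord], pop_freq = P[ord, , drop = FALSE],
    selected = selected_truth, introgressed = introgressed_truth,
    hotspot_cluster = cluster_of[ord],
    scenario_seed = sc$seed, pheno = NULL)

  if (!is.null(sc$pheno)) {
    ph <- simulate_phenotypes(svset, truth, sc$pheno,
                              seed = sc$seed + 1L)
    truth$pheno <- ph
  }
  list(svset = svset, meta = meta, truth = truth)
}

#' Simulate an additive SV-linked phenotype
#'
#' `y_i = sum_k beta_k g_ik + e_i`, `e ~ N(0, sigma^2)`. The realized
#' variance share of causal locus k is `Var(beta_k g_k) / Var(y)`.
#'
#' @param svset an [sv_set()].
#' @param truth truth list from [simulate_cohort()] (used only to avoid
#'   picking planted selected/introgressed loci as causal; may be `NULL`).
#' @param pheno list with `n_causal` (or `causal`, explicit locus ids),
#'   `beta` (recycled over causal loci) and `sigma` (> 0).
#' @param seed RNG seed.
#' @return list: `y` (named by sample), `causal` (data.frame `id`, `beta`,
#'   `var_share`), `sigma`.
#' @export
simulate_phenotypes <- function(svset, truth = NULL, pheno, seed = 1) {
  if (pheno$sigma <= 0) stop("sigma must be > 0")
  set.seed(seed)
  ids <- svset$records$id
  if (!is.null(pheno$causal)) {
    causal <- match(pheno$causal, ids)
    if (anyNA(causal)) stop("causal loci not in svset")
  } else {
    avoid <- c(if (!is.null(truth$selected)) truth$selected$id,
               if (!is.null(truth$introgressed)) truth$introgressed$id)
    pool <- which(!(ids %in% avoid))
    causal <- sample(pool, pheno$n_causal)
  }
  beta <- rep_len(pheno$beta, length(causal))
  Gc <- svset$genotypes[, causal, drop = FALSE]
  Gc[is.na(Gc)] <- 0L
  gen <- as.vector(Gc %*% beta)
  y <- gen + stats::rnorm(length(gen), 0, pheno$sigma)
  names(y) <- svset$samples
  var_share <- vapply(seq_along(causal), function(k)
    stats::var(Gc[, k] * beta[k]) / stats::var(y), numeric(1))
  list(y = y,
       causal = data.frame(id = ids[causal], beta = beta,
                           var_share = var_share, stringsAsFactors = FALSE),
       sigma = pheno$sigma)
}

#' Write a simulated cohort as a plain-text fixture set
#'
#' Emits the SV-VCF, a metadata TSV and a ground-truth JSON (and nothing
#' binary), such that [read_sv_vcf()] on the output reproduces the cohort.
#'
#' @param cohort list from [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_set <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(outdir, "cohort.vcf")
  meta <- file.path(outdir, "meta.tsv")
  truth <- file.path(outdir, "truth.json")
  write_sv_vcf(cohort$svset, vcf)
  utils::write.table(as.data.frame(cohort$meta), meta, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  tr$pop_freq <- as.data.frame(tr$pop_freq)
  if (!is.null(tr$pheno)) tr$pheno$y <- unname(tr$pheno$y)
  jsonlite::write_json(tr, truth, digits = NA, auto_unbox = TRUE,
                       null = "null", dataframe = "columns")
  invisible(c(vcf = vcf, meta = meta, truth = truth))
}
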