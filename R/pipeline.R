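#' Pipeline configuration
#'
#' Collects input paths, filter thresholds, scan parameters and the RNG
#' seed of a full cohort analysis. The seed is recorded in the run
#' manifest of every [run_pipeline()] output.
#'
#' @param vcf path to the SV-VCF.
#' @param meta path to the sample metadata TSV
#'   (sample_id, population, group, species).
#' @param outdir output directory.
#' @param genome named chromosome lengths in bp; default derives them
#'   from the observed loci.
#' @param min_len,max_len,max_missing,min_maf cohort filter thresholds
#'   (see [filter_svs()]).
#' @param wild_pop,domestic_pop populations for the domestication scan
#'   (defaults: first wild and first non-wild population in the metadata).
#' @param outgroup species for the introgression scan (default: last wild
#'   species); set `stages` to skip stages.
#' @param permutations permutation count for F_ST P-values.
#' @param stages character vector of stages to run, a subset of
#'   `c("filter", "diversity", "selection", "regions", "introgression")`.
#' @param seed RNG seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, meta, outdir, genome = NULL,
                            min_len = 50, max_len = 1e6,
                            max_missing = 0.25, min_maf = 0.01,
                            wild_pop = NULL, domestic_pop = NULL,
                            outgroup = NULL, permutations = 200,
                            stages = c("filter", "diversity", "selection",
                                       "regions", "introgression"),
                            seed = 1) {
  stopifnot(min_len > 0, max_len >= min_len, permutations >= 1)
  structure(list(vcf = vcf, meta = meta, outdir = outdir, genome = genome,
                 min_len = min_len, max_len = max_len,
                 max_missing = max_missing, min_maf = min_maf,
                 wild_pop = wild_pop, domestic_pop = domestic_pop,
                 outgroup = outgroup, permutations = permutations,
                 stages = stages, seed = seed),
            class = "pipeline_config")
}

#' Run the SV population-genomics pipeline
#'
#' Executes the enabled stages (filter, diversity, selection scan,
#' regional genomics, introgression) on a VCF + metadata pair, writing
#' one TSV per stage plus a machine-readable JSON run manifest recording
#' inputs, thresholds and the seed. Two runs with the same config produce
#' byte-identical tables. A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return named character vector of written files, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  svset <- stage("read", read_sv_vcf(cfg$vcf))
  meta <- stage("read", sample_meta(
    utils::read.table(cfg$meta, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE), svset))
  genome <- cfg$genome
  if (is.null(genome)) {
    iv <- sv_intervals(svset)
    genome <- tapply(iv$end, iv$chrom, max) + 1
  }
  pops <- unique(as.data.frame(meta)[, c("population", "group", "species")])
  wild_pop <- cfg$wild_pop %||% pops$population[pops$group == "wild"][1]
  dom_pop <- cfg$domestic_pop %||% pops$population[pops$group != "wild"][1]

  if ("filter" %in% cfg$stages) {
    svset <- stage("filter", filter_svs(svset, cfg$min_len, cfg$max_len,
                                        cfg$max_missing, cfg$min_maf))
    rem <- attr(svset, "removed")
    emit(data.frame(rule = names(rem), removed = as.integer(rem)),
         "filter_tally.tsv")
  }
  if ("diversity" %in% cfg$stages) {
    stage("diversity", {
      emit(windowed_pi(svset, genome = genome), "windowed_pi.tsv")
      het <- heterozygosity_rate(svset)
      emit(data.frame(stat = c("het_rate", "n_het", "n_called", "n_sites"),
                      value = unlist(het)), "heterozygosity.tsv")
      emit(ld_decay_profile(svset), "ld_decay.tsv")
    })
  }
  if ("selection" %in% cfg$stages && !is.na(wild_pop) && !is.na(dom_pop)) {
    stage("selection", {
      fst <- wc_fst(svset, meta, dom_pop, wild_pop)
      perm <- fst_permutation_pvalue(svset, meta, dom_pop, wild_pop,
                                     B = cfg$permutations, seed = cfg$seed)
      div <- di_sv(svset, meta, dom_pop, wild_pop)
      tab <- data.frame(id = fst$per_site$id, theta = fst$per_site$theta,
                        p_perm = perm$p_perm, di_sv = div$di_sv)
      cand <- candidate_selection(
        list(p_perm = tab$p_perm, di_sv = tab$di_sv),
        list(list(stat = "p_perm", type = "lt", q = 0.05),
             list(stat = "di_sv", type = "top", q = 0.05)),
        ids = tab$id)
      tab$candidate <- cand$candidate
      emit(tab, "selection_scan.tsv")
    })
  }
  if ("regions" %in% cfg$stages) {
    stage("regions", {
      dens <- breakpoint_density(svset, genome)
      emit(as.data.frame(dens), "breakpoint_density.tsv")
      hs <- hotspot_detect(dens)
      emit(as.data.frame(hs$regions), "hotspot_regions.tsv")
    })
  }
  if ("introgression" %in% cfg$stages) {
    outg <- cfg$outgroup %||% rev(pops$species[pops$group == "wild"])[1]
    if (!is.null(outg) && !is.na(outg)) {
      stage("introgression", {
        sc <- introgression_scan(svset, meta, outgroup = outg)
        emit(sc$calls, "introgression_calls.tsv")
      })
    }
  }
  manifest <- list(inputs = list(vcf = cfg$vcf, meta = cfg$meta),
                   thresholds = cfg[c("min_len", "max_len", "max_missing",
                                      "min_maf")],
                   permutations = cfg$permutations,
                   stages = cfg$stages, seed = cfg$seed,
                   n_loci = n_loci(svset), n_samples = length(svset$samples),
                   package_version = as.character(
                     utils::packageVersion("svpopgen")))
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  written[["manifest.json"]] <- manifest_path
  invisible(unlist(written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
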