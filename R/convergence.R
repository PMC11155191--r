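#' Shared orthologous genes between two candidate sets
#'
#' `shared = {a in A : ortholog(a) in B}` under a one-to-one ortholog map.
#' Ids absent from the map are counted and reported, not errors.
#'
#' @param genesA,genesB character vectors of candidate gene ids in species
#'   A and B.
#' @param ortholog_map data.frame with columns `gene_a`, `gene_b`
#'   (one-to-one after filtering; duplicated ids are rejected).
#' @return list: `shared` (data.frame gene_a, gene_b), `n_shared`,
#'   `unmapped_a`, `unmapped_b`.
#' @export
shared_orthologs <- function(genesA, genesB, ortholog_map) {
  if (!nrow(ortholog_map)) stop("empty ortholog map")
  if (anyDuplicated(ortholog_map$gene_a) || anyDuplicated(ortholog_map$gene_b))
    stop("ortholog map is not one-to-one")
  a_in <- genesA[genesA %in% ortholog_map$gene_a]
  partner <- ortholog_map$gene_b[match(a_in, ortholog_map$gene_a)]
  hit <- partner %in% genesB
  shared <- data.frame(gene_a = a_in[hit], gene_b = partner[hit],
                       stringsAsFactors = FALSE)
  list(shared = shared, n_shared = nrow(shared),
       unmapped_a = sum(!genesA %in% ortholog_map$gene_a),
       unmapped_b = sum(!genesB %in% ortholog_map$gene_b))
}

#' Permutation test for excess convergent gene-use
#'
#' Each replicate draws uniform random candidate sets of sizes `nA` and
#' `nB` from a universe of `U` one-to-one ortholog pairs and counts the
#' shared pairs; `P = #(k_perm >= k_obs) / B` (upper tail). The
#' hypergeometric expectation `nA * nB / U` is reported alongside so the
#' dependence on the chosen universe is visible.
#'
#' @param nA,nB candidate-set sizes.
#' @param U universe size (number of ortholog pairs eligible for both
#'   scans); a required explicit argument.
#' @param k_obs observed shared count.
#' @param B number of permutation replicates (>= 100).
#' @param seed RNG seed.
#' @param smooth logical; report `(k + 1) / (B + 1)`.
#' @return list of class `convergence_result`: `k_obs`, `p`, `B`,
#'   `null_counts`, `expected` (hypergeometric mean), `seed`.
#' @export
convergence_permutation_test <- function(nA, nB, U, k_obs, B = 1000,
                                         seed = 1, smooth = FALSE) {
  stopifnot(nA <= U, nB <= U, B >= 100)
  if (k_obs > min(nA, nB)) stop("k_obs exceeds min(nA, nB)")
  set.seed(seed)
  null_counts <- vapply(seq_len(B), function(b) {
    a <- sample.int(U, nA)
    bb <- sample.int(U, nB)
    sum(a %in% bb)
  }, numeric(1))
  k_exceed <- sum(null_counts >= k_obs)
  p <- if (smooth) (k_exceed + 1) / (B + 1) else k_exceed / B
  structure(list(k_obs = k_obs, p = p, B = B, null_counts = null_counts,
                 expected = nA * nB / U, seed = seed),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("convergence permutation test: k_obs =", x$k_obs,
      "vs null mean", format(mean(x$null_counts), digits = 4),
      "(hypergeometric expectation", format(x$expected, digits = 4), ")\n")
  cat("  P =", format(x$p, digits = 4), "over", x$B, "replicates\n")
  invisible(x)
}
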