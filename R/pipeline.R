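#' Run the full similarity pipeline on a dataset
#'
#' Chains the stages: assign every probe set to a gene, enumerate
#' alternative pairs, build one significance-filtered covariation network
#' per call matrix (each with its own random-pair null), select the
#' calibration pairs (alternative pairs of single-gene probe sets that are
#' positively correlated in every network), calibrate the similarity-test
#' limits, and classify all alternative pairs.
#'
#' @param dataset list with `call_matrices` and `targets` (as produced by
#'   [generate_dataset()], or assembled from [read_call_matrix()] /
#'   [read_target_table()])
#' @param alpha significance level for network edges
#' @param null_samples random pairs per network null
#' @param probe_limit probe-number limit for gene assignment
#' @param seed seed for the per-network nulls
#' @param calibration_single_gene restrict calibration pairs to pairs whose
#'   members each target exactly one gene (default TRUE)
#' @return list with `networks`, `null`s, `assignments`, `pairs`
#'   (a `pair_similarity` data frame), `limits`, `calibration_pairs`
#' @export
run_similarity_pipeline <- function(dataset, alpha = 0.05,
                                    null_samples = 1000L, probe_limit = 7L,
                                    seed = 1L,
                                    calibration_single_gene = TRUE) {
  targets <- dataset$targets
  assignments <- assign_all_genes(targets, min_probes = probe_limit)
  pairs <- alternative_pairs(assignments)
  if (!nrow(pairs)) stop("no alternative probe-set pairs at this probe limit")

  nulls <- networks <- vector("list", length(dataset$call_matrices))
  for (w in seq_along(dataset$call_matrices)) {
    calls <- dataset$call_matrices[[w]]
    nulls[[w]] <- build_null(calls, null_samples, seed = seed + w)
    networks[[w]] <- build_network(calls, nulls[[w]], alpha = alpha)
  }

  vals <- pair_network_values(networks, pairs)
  pos_all <- Reduce(`&`, lapply(vals, function(v) v$corr > 0))
  calib <- pairs[pos_all, , drop = FALSE]
  if (calibration_single_gene) {
    n_genes_of <- table(targets$probe_set[targets$probes_total >= probe_limit])
    single <- names(n_genes_of)[n_genes_of == 1]
    calib <- calib[calib$probe_set_1 %in% single &
                   calib$probe_set_2 %in% single, , drop = FALSE]
  }
  limits <- calibrate_limits(networks, calib)
  classified <- classify_pairs(networks, pairs, limits)
  list(networks = networks, nulls = nulls, assignments = assignments,
       pairs = classified, limits = limits, calibration_pairs = calib)
}

#' Split classified pairs by similarity class
#'
#' @param pairs a `pair_similarity` data frame
#' @return named list: class ("0","1","25","50","75","100") -> 2-column
#'   matrix of pairs (classes with no pair omitted)
#' @export
pairs_by_class <- function(pairs) {
  out <- list()
  for (cls in c(0, 1, 25, 50, 75, 100)) {
    sel <- pairs$similarity_class == cls
    if (!any(sel)) next
    out[[as.character(cls)]] <- cbind(pairs$probe_set_1[sel],
                                      pairs$probe_set_2[sel])
  }
  out
}
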