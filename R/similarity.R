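## Multi-network similarity of alternative probe-set pairs.
##
## A pair is "similar in network i" when its positive correlation is at
## least the calibrated 5th-percentile limit, its negative correlation at
## most the 95th-percentile limit, and its neighbourhood-overlap log10
## p-value at most the 95th-percentile limit.  Limits are calibrated on the
## pairs that are positively correlated in every network — the
## best-behaved distribution, clearly separated from pairs correlated in
## only some networks.

# per-network corr/anti/overlap values for a set of pairs
pair_network_values <- function(networks, pairs) {
  pairs <- as.matrix(pairs[, 1:2])
  lapply(networks, function(net) {
    i1 <- match(pairs[, 1], net$probe_set_ids)
    i2 <- match(pairs[, 2], net$probe_set_ids)
    if (anyNA(i1) || anyNA(i2)) stop("pair member missing from a network")
    ov <- pair_overlap_scores(net, pairs)
    data.frame(corr = net$corr[cbind(i1, i2)],
               anti = net$anti[cbind(i1, i2)],
               log10_p = ov$log10_p)
  })
}

#' Number of networks in which a pair is positively correlated
#'
#' A pair counts as positively correlated in a network when it has a stored
#' (significance-filtered) positive correlation greater than zero.
#'
#' @param pair character vector of two probe-set identifiers
#' @param networks list of `covariation_network`
#' @return integer count in 0..length(networks)
#' @export
count_positive_networks <- function(pair, networks) {
  sum(vapply(networks, function(net) {
    i <- match(pair, net$probe_set_ids)
    if (anyNA(i)) stop("unknown probe set: ", pair[is.na(i)][1])
    net$corr[i[1], i[2]] > 0
  }, NA))
}

#' Calibrate similarity-test limits
#'
#' Pools the per-network positive correlations, negative correlations and
#' neighbourhood-overlap log10 p-values of the calibration pairs (pairs
#' positively correlated in all networks), and takes the nearest-rank 5th
#' percentile of the positive correlations (`corr_5th`) and 95th
#' percentiles of the negative correlations (`anti_95th`) and of the log10
#' p-values (`overlap_95th`).
#'
#' @param networks list of `covariation_network`
#' @param calibration_pairs data frame / matrix of probe-set pairs (first
#'   two columns), each positively correlated in all networks
#' @return a `similarity_limits`: list with `corr_5th`, `anti_95th`,
#'   `overlap_95th`, `n_networks`, `n_calibration_pairs`
#' @export
calibrate_limits <- function(networks, calibration_pairs) {
  if (is.null(calibration_pairs) || nrow(calibration_pairs) == 0) {
    stop("no calibration pairs: need alternative pairs positively correlated ",
         "in all networks; consider more networks or more comparisons")
  }
  vals <- pair_network_values(networks, calibration_pairs)
  pooled <- do.call(rbind, vals)
  structure(list(corr_5th = nearest_rank_percentile(pooled$corr, 5),
                 anti_95th = nearest_rank_percentile(pooled$anti, 95),
                 overlap_95th = nearest_rank_percentile(pooled$log10_p, 95),
                 n_networks = length(networks),
                 n_calibration_pairs = nrow(calibration_pairs)),
            class = "similarity_limits")
}

#' Three-condition similarity test for one pair in one network
#'
#' Similar iff `corr >= corr_5th` and `anti <= anti_95th` and
#' `overlap <= overlap_95th`.  A correlation filtered out by the
#' significance test enters as 0, and an absent overlap as log10(1) = 0, so
#' non-significance never helps a pair pass.
#'
#' @param corr,anti percentages (0 if absent)
#' @param overlap log10 overlap p-value (0 if absent)
#' @param limits a `similarity_limits`
#' @return logical
#' @export
test_pair_in_network <- function(corr, anti, overlap, limits) {
  corr >= limits$corr_5th & anti <= limits$anti_95th &
    overlap <= limits$overlap_95th
}

#' Similarity class from network counts
#'
#' 0 when the pair is similar in no network; 100 when similar in all; else
#' the largest threshold t in \{1, 25, 50, 75\} such that the pair is
#' similar in at least t% of networks (t = 1 meaning at least one network).
#'
#' @param n_similar number of networks in which the pair passes the test
#' @param n_networks total number of networks (>= 1)
#' @return one of 0, 1, 25, 50, 75, 100
#' @export
similarity_class <- function(n_similar, n_networks) {
  stopifnot(n_networks >= 1, n_similar >= 0, n_similar <= n_networks)
  if (n_similar == 0) return(0)
  if (n_similar == n_networks) return(100)
  pct <- 100 * n_similar / n_networks
  ths <- c(1, 25, 50, 75)
  max(ths[pct >= ths])
}

#' Classify alternative pairs across networks
#'
#' Runs the similarity test for every pair in every network and maps the
#' count of passing networks to a similarity class.
#'
#' @param networks list of `covariation_network`
#' @param pairs data frame with `probe_set_1`, `probe_set_2` and optional
#'   `gene` (from [alternative_pairs()])
#' @param limits a `similarity_limits` from [calibrate_limits()]
#' @return a `pair_similarity` data frame: the pair columns plus
#'   `n_networks_similar`, `n_networks`, `similarity_class`, `mean_corr`,
#'   `mean_anti`, and matrix attribute `per_network` (logical,
#'   pairs x networks)
#' @export
classify_pairs <- function(networks, pairs, limits) {
  vals <- pair_network_values(networks, pairs)
  pass <- vapply(vals, function(v)
    test_pair_in_network(v$corr, v$anti, v$log10_p, limits),
    logical(nrow(pairs)))
  pass <- matrix(pass, nrow = nrow(pairs))
  n_sim <- rowSums(pass)
  out <- data.frame(probe_set_1 = pairs$probe_set_1,
                    probe_set_2 = pairs$probe_set_2,
                    gene = if ("gene" %in% names(pairs)) pairs$gene else NA_character_,
                    n_networks_similar = as.integer(n_sim),
                    n_networks = length(networks),
                    similarity_class = vapply(n_sim, similarity_class, 0,
                                              n_networks = length(networks)),
                    mean_corr = rowMeans(vapply(vals, `[[`, numeric(nrow(pairs)), "corr")),
                    mean_anti = rowMeans(vapply(vals, `[[`, numeric(nrow(pairs)), "anti")),
                    stringsAsFactors = FALSE)
  attr(out, "per_network") <- pass
  class(out) <- c("pair_similarity", "data.frame")
  out
}

# class -> the equivalent-class set used by reproducibility counts
equivalent_classes <- function(cls) {
  if (cls == 0) c(0, 1) else if (cls == 100) c(75, 100) else cls
}

#' Pair-level similarity reproducibility between two conditions
#'
#' For the pairs classified 0% (resp. 100%) in condition a and also present
#' in condition b, the percentage whose condition-b class is equivalent:
#' 0%-1% for the 0% class, 75%-100% for the 100% class (a single positive
#' network is enough to shift a pair between the members of each
#' equivalence set).
#'
#' @param classes_a,classes_b named numeric vectors: pair key -> class
#' @return list with `rep0` and `rep100` (percent; NA when no shared pair
#'   is in the tested class)
#' @export
pair_reproducibility <- function(classes_a, classes_b) {
  shared <- intersect(names(classes_a), names(classes_b))
  one <- function(cls) {
    sel <- shared[classes_a[shared] == cls]
    if (!length(sel)) return(NA_real_)
    100 * sum(classes_b[sel] %in% equivalent_classes(cls)) / length(sel)
  }
  list(rep0 = one(0), rep100 = one(100))
}

#' Gene-level similarity reproducibility between two chips
#'
#' For class c in \{0, 100\}: candidate genes have all their alternative
#' pairs in class c on chip a and at least one alternative pair on chip b;
#' the score is the percentage of candidates whose chip-b pairs are all in
#' the equivalent class set (\{0, 1\} or \{75, 100\}).
#'
#' @param classes_a,classes_b `pair_similarity` data frames with a `gene`
#'   column
#' @return list with `rep0` and `rep100` (percent; NA when no candidate)
#' @export
gene_reproducibility <- function(classes_a, classes_b) {
  by_gene_a <- split(classes_a$similarity_class, classes_a$gene)
  by_gene_b <- split(classes_b$similarity_class, classes_b$gene)
  one <- function(cls) {
    cand <- names(by_gene_a)[vapply(by_gene_a, function(v) all(v == cls), NA)]
    cand <- intersect(cand, names(by_gene_b))
    if (!length(cand)) return(NA_real_)
    ok <- vapply(by_gene_b[cand],
                 function(v) all(v %in% equivalent_classes(cls)), NA)
    100 * sum(ok) / length(cand)
  }
  list(rep0 = one(0), rep100 = one(100))
}

#' @exportS3Method base::print
print.similarity_limits <- function(x, ...) {
  cat(sprintf(paste0("similarity limits (%d networks, %d calibration pairs):\n",
                     "  corr >= %.1f, anti <= %.1f, overlap log10 p <= %.1f\n"),
              x$n_networks, x$n_calibration_pairs,
              x$corr_5th, x$anti_95th, x$overlap_95th))
  invisible(x)
}
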