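#' Merge grouped probe sets inside a covariation network
#'
#' Each group collapses to a single node whose positive and negative
#' correlations with any outside node are the arithmetic means of its
#' members' values (absent, i.e. non-significant, values counted as 0).
#' Edges internal to a group disappear with the merge.
#'
#' @param network a `covariation_network`
#' @param groups list of character vectors of probe-set identifiers; must be
#'   disjoint (resolve pivots to a single group beforehand)
#' @return a `merged_network`: list with `network` (a
#'   `covariation_network` over merged node ids), `merge_map` (named
#'   vector original id -> merged id), `size_reduction` (percent)
#' @export
merge_probe_sets <- function(network, groups) {
  ids <- network$probe_set_ids
  flat <- unlist(groups)
  if (anyDuplicated(flat)) stop("groups overlap on probe set ",
                                flat[duplicated(flat)][1])
  if (!all(flat %in% ids)) stop("group member absent from network")
  merge_map <- setNames(ids, ids)
  for (k in seq_along(groups)) {
    merged_id <- paste0("merged_", k)
    merge_map[groups[[k]]] <- merged_id
  }
  new_ids <- unique(unname(merge_map))
  # membership matrix B (new x old); averaging rows/cols of the old matrices
  B <- Matrix::sparseMatrix(i = match(merge_map, new_ids), j = seq_along(ids),
                            x = 1, dims = c(length(new_ids), length(ids)))
  sz <- Matrix::rowSums(B)
  Bavg <- B / sz
  mix <- function(M) {
    out <- Bavg %*% M %*% Matrix::t(Bavg)
    out <- methods::as(out, "CsparseMatrix")
    Matrix::diag(out) <- 0       # intra-group edges dropped
    out
  }
  net <- structure(list(probe_set_ids = new_ids,
                        corr = mix(network$corr), anti = mix(network$anti),
                        alpha = network$alpha,
                        n_comparisons = network$n_comparisons),
                   class = "covariation_network")
  structure(list(network = net, merge_map = merge_map,
                 size_reduction = 100 * (1 - length(new_ids) / length(ids))),
            class = "merged_network")
}

#' Markov clustering of a covariation network
#'
#' Random-walk clustering on the positive-correlation matrix (negative
#' correlations are not valid walk weights).  A self-loop equal to the
#' node's maximum incident weight is added, columns are normalised to
#' probabilities, and the process iterates expansion (matrix square),
#' inflation (elementwise power, renormalise) and pruning (zero entries
#' below `prune_threshold`, renormalise) until the matrix changes by less
#' than 1e-8 elementwise or `max_iter` is reached.  Attractors are rows
#' with positive diagonal; every node joins the attractor with the largest
#' incoming value (ties to the lexicographically smallest attractor).
#'
#' The pruning score is `floor(100 * mean retained column mass)` over all
#' pruning steps: 100 means pruning discarded nothing.
#'
#' @param network a `covariation_network` (or a `merged_network`)
#' @param inflation inflation exponent (> 1); default 2
#' @param prune_threshold entries below this are zeroed each iteration
#' @param max_iter iteration cap
#' @return an `mcl_result`: list with `clusters` (list of id vectors,
#'   size-descending), `pruning_score`, `inflation`, `n_iterations`
#' @export
mcl_cluster <- function(network, inflation = 2, prune_threshold = 1e-4,
                        max_iter = 100L) {
  if (inherits(network, "merged_network")) network <- network$network
  ids <- network$probe_set_ids
  if (!length(ids)) stop("empty network")
  M <- as.matrix(network$corr)
  if (any(M < 0)) stop("negative edge weight")
  dimnames(M) <- list(ids, ids)
  self <- apply(M, 2, max)
  self[self == 0] <- 1           # isolated nodes keep a unit self-loop
  diag(M) <- self
  norm_cols <- function(X) sweep(X, 2, colSums(X), "/")
  M <- norm_cols(M)
  retained <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    E <- M %*% M                       # expansion
    E <- norm_cols(E^inflation)        # inflation
    pre <- colSums(E)                  # = 1 by construction
    E[E < prune_threshold] <- 0        # pruning
    retained <- c(retained, colSums(E) / pre)
    E <- norm_cols(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < 1e-8 || iter >= max_iter) break
  }
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_along(ids)  # degenerate guard
  # assign each node to the attractor with the largest incoming value
  W <- M[attractors, , drop = FALSE]
  assign_to <- apply(W, 2, function(col) {
    best <- which(col == max(col))
    attractors[best[order(ids[attractors[best]])[1]]]
  })
  clusters <- split(ids, ids[assign_to])
  clusters <- unname(clusters[order(-vapply(clusters, length, 0L),
                                    vapply(clusters, min, ""))])
  structure(list(clusters = clusters,
                 pruning_score = as.integer(floor(100 * mean(retained))),
                 inflation = inflation, n_iterations = iter),
            class = "mcl_result")
}

#' Reproducibility of two clusterings
#'
#' Both clusterings are restricted to their shared universe.  For each of
#' the `k` largest clusters of `result_a`, the best-overlapping cluster of
#' `result_b` is found; that cluster's reproducibility is
#' `100 |common| / sqrt(|c_a| |c_b|)` (common members over the geometric
#' mean of the sizes).  The clustering reproducibility is the weighted mean
#' over the k clusters, with weights the inverse geometric means, so small
#' clusters are not swamped by big ones.
#'
#' @param result_a,result_b `mcl_result` objects (or plain lists of id
#'   vectors)
#' @param k number of largest `result_a` clusters considered (capped at the
#'   available number with a warning)
#' @return percent in \[0, 100\]
#' @export
cluster_reproducibility <- function(result_a, result_b, k = 10L) {
  ca <- if (inherits(result_a, "mcl_result")) result_a$clusters else result_a
  cb <- if (inherits(result_b, "mcl_result")) result_b$clusters else result_b
  if (!length(ca) || !length(cb)) stop("need at least one cluster on each side")
  shared <- intersect(unlist(ca), unlist(cb))
  ca <- Filter(length, lapply(ca, intersect, shared))
  cb <- Filter(length, lapply(cb, intersect, shared))
  if (!length(ca) || !length(cb)) stop("clusterings share no probe set")
  ca <- ca[order(-vapply(ca, length, 0L))]
  if (k > length(ca)) {
    warning("k reduced to the available ", length(ca), " clusters")
    k <- length(ca)
  }
  reps <- wts <- numeric(k)
  for (i in seq_len(k)) {
    ov <- vapply(cb, function(x) length(intersect(ca[[i]], x)), 0L)
    sizes <- vapply(cb, length, 0L)
    best <- which(ov == max(ov))
    # ties to the larger partner cluster, then lexicographic smallest member
    best <- best[order(-sizes[best],
                       vapply(cb[best], function(x) sort(x)[1], ""))][1]
    gm <- sqrt(length(ca[[i]]) * sizes[best])
    reps[i] <- 100 * ov[best] / gm
    wts[i] <- 1 / gm
  }
  sum(wts * reps) / sum(wts)
}

#' Rank-normalise a signal matrix
#'
#' Within each biological condition (row), raw signals are replaced by
#' their average-tie ranks mapped linearly to a 0-100 scale: the smallest
#' signal of a condition becomes 0 and the largest 100.
#'
#' @param signals numeric matrix, conditions x probe sets (dimnames kept)
#' @return matrix of the same shape with values in \[0, 100\]
#' @export
rank_normalize <- function(signals) {
  if (ncol(signals) < 2) stop("need at least 2 probe sets per condition")
  t(apply(signals, 1, function(v) {
    r <- rank(v, ties.method = "average")
    100 * (r - 1) / (length(v) - 1)
  }))
}

#' Mean cumulative distributions of rank differences by similarity class
#'
#' For each pair, the empirical CDF of the absolute rank difference across
#' conditions is evaluated on the integer grid 0..100; per class the CDFs
#' are averaged pointwise.  A seeded `random` class of uniformly drawn
#' probe-set pairs is appended as a baseline.
#'
#' @param ranks matrix from [rank_normalize()] (conditions x probe sets)
#' @param pairs_by_class named list: class -> 2-column matrix of pairs
#' @param n_random size of the random baseline class (0 disables)
#' @param seed seed for the random pairs
#' @return list: class -> numeric vector of length 101 (mean CDF on 0..100)
#' @export
rank_diff_cdfs <- function(ranks, pairs_by_class, n_random = 100L, seed = 1L) {
  grid <- 0:100
  one_class <- function(pr) {
    pr <- as.matrix(pr)
    cdfs <- vapply(seq_len(nrow(pr)), function(r) {
      d <- abs(ranks[, pr[r, 1]] - ranks[, pr[r, 2]])
      vapply(grid, function(g) mean(d <= g), 0)
    }, numeric(101))
    rowMeans(cdfs)
  }
  out <- list()
  for (cls in names(pairs_by_class)) {
    pr <- pairs_by_class[[cls]]
    if (is.null(pr) || nrow(as.matrix(pr)) == 0) next
    out[[cls]] <- one_class(pr)
  }
  if (n_random > 0) {
    ps <- colnames(ranks)
    rp <- withr_seed(seed, t(replicate(n_random, sample(ps, 2))))
    out[["random"]] <- one_class(rp)
  }
  out
}
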