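#' Probe-set neighbourhood in a covariation network
#'
#' The neighbourhood of a probe set is the set of probe sets connected to it
#' by a stored (significant) positive-correlation edge; the centre is never
#' a member.  Negative edges can be included with `include_anti = TRUE`,
#' but positive-only is the default: the overlap is used alongside positive
#' correlation as evidence that two probe sets report the same signal.
#'
#' @param network a `covariation_network`
#' @param ps probe-set identifier
#' @param include_anti also count negative-correlation partners
#' @return character vector of probe-set identifiers
#' @export
neighbourhood <- function(network, ps, include_anti = FALSE) {
  i <- match(ps, network$probe_set_ids)
  if (is.na(i)) stop("unknown probe set: ", ps)
  v <- network$corr[i, ] != 0
  if (include_anti) v <- v | (network$anti[i, ] != 0)
  v[i] <- FALSE
  network$probe_set_ids[which(v)]
}

#' Hypergeometric tail probability of a neighbourhood overlap
#'
#' Probability of drawing an overlap of size `n_overlap` or larger between
#' two neighbourhoods of sizes `n1` and `n2` sampled from a population of
#' `population` probe sets:
#' `p = sum_{k >= N} C(N1,k) C(M-N1, N2-k) / C(M, N2)`.
#' Returned on the log10 scale, computed in log space so it is safe for
#' populations up to ~1e5 and beyond.
#'
#' @param n_overlap observed overlap N (0 <= N <= min(n1, n2))
#' @param n1,n2 neighbourhood sizes
#' @param population network size M (n1, n2 <= M)
#' @return log10 of the upper-tail p-value (<= 0; 0 when `n_overlap` = 0)
#' @examples
#' overlap_log_pvalue(5, 5, 5, 10)  # log10(1/252) ~ -2.4014
#' @export
overlap_log_pvalue <- function(n_overlap, n1, n2, population) {
  if (n1 > population || n2 > population) stop("neighbourhood larger than population")
  if (n_overlap > min(n1, n2)) stop("overlap exceeds the smaller neighbourhood")
  if (n_overlap < 0 || n1 < 0 || n2 < 0 || population < 0) stop("counts must be >= 0")
  if (n_overlap == 0) return(0)
  lp <- phyper(n_overlap - 1, m = n1, n = population - n1, k = n2,
               lower.tail = FALSE, log.p = TRUE)
  lp / log(10)
}

# overlap scores for a set of pairs in one network: N, N1, N2, log10 p.
# Neighbour sets come from the significant positive edges; M = network size.
pair_overlap_scores <- function(network, pairs) {
  ids <- network$probe_set_ids
  Adj <- network$corr != 0
  Matrix::diag(Adj) <- FALSE
  deg <- Matrix::rowSums(Adj)
  i1 <- match(pairs[, 1], ids); i2 <- match(pairs[, 2], ids)
  if (anyNA(i1) || anyNA(i2)) stop("pair member not in network")
  M <- length(ids)
  out <- data.frame(n_overlap = integer(nrow(pairs)),
                    n1 = as.integer(deg[i1]), n2 = as.integer(deg[i2]),
                    log10_p = numeric(nrow(pairs)))
  for (k in seq_len(nrow(pairs))) {
    # a is never in its own neighbourhood, so the intersection is free of
    # both pair members by construction
    ov <- as.integer(sum(Adj[i1[k], ] & Adj[i2[k], ]))
    out$n_overlap[k] <- ov
    out$log10_p[k] <- overlap_log_pvalue(ov, out$n1[k], out$n2[k], M)
  }
  out
}
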