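## Covariation between ternary call strings and significance-filtered networks.
##
## Calls are coded internally as integers: I = +1, D = -1, N = 0.  For two
## coded vectors x, y the cross-products give all pair counts at once:
##   sum(|x||y|)  = concordant + discordant positions
##   sum(x y)     = concordant - discordant positions
##   informative  = positions where at least one symbol is non-N
## which is what makes the all-pairs computation a pair of matrix products.

code_calls <- function(s) {
  v <- c(I = 1L, D = -1L, N = 0L)[s]
  if (anyNA(v)) stop("illegal call symbol (allowed: I, D, N)")
  unname(v)
}

#' Positive and negative correlation between two call strings
#'
#' Positions where both strings read `N` are non-informative and removed.
#' Over the remaining informative positions, the positive correlation `corr`
#' is the percentage of concordant positions (`II` or `DD`) and the negative
#' correlation `anti` the percentage of discordant positions (`ID` or `DI`).
#' A position where exactly one string reads `N` is informative but neither
#' concordant nor discordant, so it dilutes both percentages.
#'
#' @param s1,s2 call strings: character vectors over \{I, D, N\} of equal
#'   length, or single strings (split into characters)
#' @return list with `corr`, `anti` (percent), `n_informative`, and
#'   `degenerate` (TRUE when no position is informative; then
#'   `corr = anti = 0`)
#' @examples
#' corr_anti("IDNNI", "IDNDN")  # corr 50, anti 0, 4 informative positions
#' @export
corr_anti <- function(s1, s2) {
  if (length(s1) == 1 && nchar(s1) > 1) s1 <- strsplit(s1, "")[[1]]
  if (length(s2) == 1 && nchar(s2) > 1) s2 <- strsplit(s2, "")[[1]]
  if (length(s1) != length(s2)) stop("call strings have unequal lengths")
  if (length(s1) < 1) stop("call strings must have length >= 1")
  x <- code_calls(s1)
  y <- code_calls(s2)
  informative <- sum(x != 0L | y != 0L)
  if (informative == 0) {
    return(list(corr = 0, anti = 0, n_informative = 0L, degenerate = TRUE))
  }
  p <- x * y
  list(corr = 100 * sum(p == 1L) / informative,
       anti = 100 * sum(p == -1L) / informative,
       n_informative = as.integer(informative),
       degenerate = FALSE)
}

# All-pairs corr/anti/informative for a coded matrix Z (probe sets x
# comparisons); returns dense matrices (n x n).  n is expected to be at most
# a few thousand here.
all_pairs_corr_anti <- function(Z) {
  A <- abs(Z)
  P <- tcrossprod(Z)            # concordant - discordant
  S <- tcrossprod(A)            # concordant + discordant
  m <- ncol(Z)
  bothN <- tcrossprod(1 - A)    # positions where both are N
  info <- m - bothN
  conc <- (S + P) / 2
  disc <- (S - P) / 2
  corr <- ifelse(info > 0, 100 * conc / info, 0)
  anti <- ifelse(info > 0, 100 * disc / info, 0)
  list(corr = corr, anti = anti, info = info)
}

#' Empirical null distribution of random-pair correlations
#'
#' Samples `n_samples` distinct unordered probe-set pairs (self-pairs
#' excluded) uniformly without replacement, computes their positive and
#' negative correlations, and records the sorted values.  When `n_samples`
#' meets or exceeds the number of distinct pairs, all pairs are used
#' exhaustively (with a message).  Degenerate pairs (no informative
#' position) contribute 0 to both nulls: a random pair with no signal is
#' evidence of nothing.
#'
#' @param calls a `call_matrix`
#' @param n_samples number of random pairs (>= 100)
#' @param seed integer seed; the null is reproducible given the seed
#' @return a `null_distribution`: list with sorted `corr_null`, `anti_null`,
#'   `n_samples` (pairs actually used), `seed`
#' @export
build_null <- function(calls, n_samples, seed) {
  n <- nrow(calls)
  if (n < 2) stop("need at least 2 probe sets to build a null")
  if (n_samples < 100) stop("n_samples must be >= 100")
  n_pairs <- n * (n - 1) / 2
  if (n_samples >= n_pairs) {
    message("n_samples >= number of distinct pairs (", n_pairs,
            "); using all pairs exhaustively")
    idx <- seq_len(n_pairs)
    n_samples <- n_pairs
  } else {
    idx <- withr_seed(seed, sample.int(n_pairs, n_samples))
  }
  # map linear index k in 1..C(n,2) to pair (i, j), i < j, column-block order
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  Z <- code_matrix(calls)
  co <- numeric(n_samples); an <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    x <- Z[i[k], ]; y <- Z[j[k], ]
    informative <- sum(x != 0L | y != 0L)
    if (informative == 0) next
    p <- x * y
    co[k] <- 100 * sum(p == 1L) / informative
    an[k] <- 100 * sum(p == -1L) / informative
  }
  structure(list(corr_null = sort(co), anti_null = sort(an),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "null_distribution")
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

code_matrix <- function(calls) {
  Z <- matrix(c(I = 1L, D = -1L, N = 0L)[calls], nrow = nrow(calls),
              dimnames = dimnames(calls))
  Z
}

#' Upper-tail empirical p-value with add-one correction
#'
#' `p = (#\{null >= value\} + 1) / (n + 1)`: the probability that a random
#' pair reaches a correlation at least as large as `value`, never returning
#' an exact zero.
#'
#' @param value observed percentage in \[0, 100\]
#' @param null sorted (or unsorted) numeric vector of null values
#' @return p-value in (0, 1\]
#' @export
empirical_pvalue <- function(value, null) {
  if (length(null) == 0) stop("empty null distribution")
  if (value < 0 || value > 100) stop("value must be in [0, 100]")
  (sum(null >= value) + 1) / (length(null) + 1)
}

#' Build a significance-filtered covariation network
#'
#' Computes corr/anti for every unordered probe-set pair and stores a value
#' only when its upper-tail empirical p-value against the matching null is
#' at most `alpha`; filtered and degenerate values are absent (0 in the
#' sparse matrices).  Raising `alpha` can only add edges.
#'
#' @param calls a `call_matrix`
#' @param null a `null_distribution` from [build_null()]
#' @param alpha significance level in (0, 1\]
#' @return a `covariation_network`: list with `probe_set_ids`, sparse
#'   symmetric percent matrices `corr` and `anti`, `alpha`, `n_comparisons`
#' @export
build_network <- function(calls, null, alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  Z <- code_matrix(calls)
  ap <- all_pairs_corr_anti(Z)
  keep_cut <- function(sorted_null) {
    # value passes iff (#null >= value) + 1 <= alpha * (n + 1); by sortedness
    # this is value > s[n - K] with K = floor(alpha*(n+1)) - 1 (K >= n: all pass)
    n <- length(sorted_null)
    K <- floor(alpha * (n + 1)) - 1
    if (K < 0) return(Inf)
    if (K >= n) return(-Inf)
    sorted_null[n - K]
  }
  cut_c <- keep_cut(null$corr_null)
  cut_a <- keep_cut(null$anti_null)
  n <- nrow(Z)
  ut <- upper.tri(ap$corr)
  nondeg <- ap$info > 0
  sel_c <- ut & nondeg & (ap$corr > cut_c)
  sel_a <- ut & nondeg & (ap$anti > cut_a)
  mk <- function(sel, vals) {
    w <- which(sel, arr.ind = TRUE)
    Matrix::sparseMatrix(i = w[, 1], j = w[, 2], x = vals[sel],
                         dims = c(n, n), symmetric = TRUE)
  }
  structure(list(probe_set_ids = rownames(calls),
                 corr = mk(sel_c, ap$corr), anti = mk(sel_a, ap$anti),
                 alpha = alpha, n_comparisons = ncol(calls)),
            class = "covariation_network")
}

#' Extract the stored edges of a network
#'
#' @param network a `covariation_network`
#' @return data frame `ps_a`, `ps_b`, `corr`, `anti` (absent values 0),
#'   one row per unordered pair with at least one stored value,
#'   lexicographic order
#' @export
network_edges <- function(network) {
  tr <- function(M) {
    T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    k <- T@i < T@j & T@x != 0   # explicit zeros are "stored but absent"
    data.frame(i = T@i[k] + 1L, j = T@j[k] + 1L, x = T@x[k])
  }
  ec <- tr(network$corr); ea <- tr(network$anti)
  key <- union(paste(ec$i, ec$j), paste(ea$i, ea$j))
  if (!length(key)) {
    return(data.frame(ps_a = character(0), ps_b = character(0),
                      corr = numeric(0), anti = numeric(0)))
  }
  ij <- do.call(rbind, lapply(strsplit(key, " "), as.integer))
  co <- setNames(ec$x, paste(ec$i, ec$j))
  an <- setNames(ea$x, paste(ea$i, ea$j))
  ids <- network$probe_set_ids
  df <- data.frame(ps_a = ids[ij[, 1]], ps_b = ids[ij[, 2]],
                   corr = unname(ifelse(is.na(co[key]), 0, co[key])),
                   anti = unname(ifelse(is.na(an[key]), 0, an[key])),
                   stringsAsFactors = FALSE)
  df[order(df$ps_a, df$ps_b), , drop = FALSE]
}

#' @exportS3Method base::print
print.covariation_network <- function(x, ...) {
  ne <- Matrix::nnzero(x$corr) / 2
  na <- Matrix::nnzero(x$anti) / 2
  cat(sprintf(paste0("covariation network: %d probe sets, %d comparisons,\n",
                     "  %d positive and %d negative significant edges (alpha = %g)\n"),
              length(x$probe_set_ids), x$n_comparisons, ne, na, x$alpha))
  invisible(x)
}
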