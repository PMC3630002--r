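#' Cross-group comparison design
#'
#' Every condition of `group_a` is compared with every condition of
#' `group_b`, in row-major order (all of `group_b` for the first `group_a`
#' condition, then the second, ...).  Two groups of 30 conditions thus give
#' the canonical 30 x 30 = 900 comparisons from which one covariation
#' network is built.
#'
#' @param group_a,group_b non-empty, disjoint character vectors of condition
#'   identifiers
#' @return a `comparison_design`: list with `groups`, `comparisons`
#'   (data frame `condition_a`, `condition_b`), `mode = "cross_group"`
#' @export
build_cross_design <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("comparison groups must be non-empty")
  if (anyDuplicated(group_a) || anyDuplicated(group_b))
    stop("duplicate condition identifiers within a group")
  if (length(intersect(group_a, group_b)))
    stop("comparison groups overlap: ", intersect(group_a, group_b)[1])
  comparisons <- data.frame(
    condition_a = rep(group_a, each = length(group_b)),
    condition_b = rep(group_b, times = length(group_a)),
    stringsAsFactors = FALSE)
  structure(list(groups = list(group_a = group_a, group_b = group_b),
                 comparisons = comparisons, mode = "cross_group"),
            class = "comparison_design")
}

#' All-pairs comparison design
#'
#' All n(n-1)/2 unordered pairs of distinct conditions, each once, in
#' lexicographic order.
#'
#' @param conditions character vector of >= 2 distinct condition identifiers
#' @return a `comparison_design` with `mode = "all_pairs"`
#' @export
build_all_pairs_design <- function(conditions) {
  if (anyDuplicated(conditions)) stop("duplicate condition identifiers")
  if (length(conditions) < 2) stop("need at least 2 conditions")
  s <- sort(conditions)
  n <- length(s)
  a <- rep(s[-n], times = (n - 1):1)
  b <- s[unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))]
  comparisons <- data.frame(condition_a = a, condition_b = b,
                            stringsAsFactors = FALSE)
  structure(list(groups = list(conditions = s), comparisons = comparisons,
                 mode = "all_pairs"),
            class = "comparison_design")
}

#' Number of comparisons in a design
#' @param design a `comparison_design`
#' @return integer count
#' @export
n_comparisons <- function(design) nrow(design$comparisons)

#' Read a comparison design group file
#'
#' TSV with columns `group_name`, `condition_id`.
#'
#' @param path TSV path
#' @return named list of condition-identifier vectors, one per group
#' @export
read_design_groups <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("group_name", "condition_id") %in% names(df)))
    stop("design file needs columns group_name, condition_id")
  split(df$condition_id, df$group_name)
}

#' Per-comparison correlation percentages by similarity class
#'
#' For each comparison (column of the call matrix) and each similarity
#' class, the percentage of the class's pairs that are concordant (`II` or
#' `DD`; `pcorr`) or discordant (`ID` or `DI`; `panti`) in that comparison,
#' over the fixed class membership.  `rel = 100 * panti / (pcorr + panti)`
#' characterises the balance of negative correlation, defined only where
#' the denominator is positive.  The summary gives, per class, the mean and
#' the nearest-rank 95th percentile of each statistic over comparisons
#' (`rel` averaged over the comparisons where it is defined).
#'
#' @param calls a `call_matrix`
#' @param pairs_by_class named list: similarity class -> 2-column character
#'   matrix (or data frame) of probe-set pairs
#' @return list with `per_comparison` (data frame `comparison_id`, `class`,
#'   `pcorr`, `panti`, `rel`) and `summary` (data frame `class`,
#'   `mean_pcorr`, `p95_pcorr`, `mean_panti`, `p95_panti`, `mean_rel`)
#' @export
comparison_pair_stats <- function(calls, pairs_by_class) {
  Z <- code_matrix(calls)
  per <- list(); summ <- list()
  for (cls in names(pairs_by_class)) {
    pr <- pairs_by_class[[cls]]
    pr <- as.matrix(pr)
    if (nrow(pr) == 0) {
      warning("similarity class ", cls, " has no pairs; omitted")
      next
    }
    if (!all(pr %in% rownames(Z))) stop("pair member not present in call matrix")
    P <- Z[pr[, 1], , drop = FALSE] * Z[pr[, 2], , drop = FALSE]
    np <- nrow(pr)
    pcorr <- 100 * colSums(P == 1L) / np
    panti <- 100 * colSums(P == -1L) / np
    rel <- ifelse(pcorr + panti > 0, 100 * panti / (pcorr + panti), NA_real_)
    per[[cls]] <- data.frame(comparison_id = colnames(Z), class = cls,
                             pcorr = pcorr, panti = panti, rel = rel,
                             row.names = NULL, stringsAsFactors = FALSE)
    summ[[cls]] <- data.frame(class = cls,
                              mean_pcorr = mean(pcorr),
                              p95_pcorr = nearest_rank_percentile(pcorr, 95),
                              mean_panti = mean(panti),
                              p95_panti = nearest_rank_percentile(panti, 95),
                              mean_rel = if (all(is.na(rel))) NA_real_
                                         else mean(rel, na.rm = TRUE),
                              stringsAsFactors = FALSE)
  }
  list(per_comparison = do.call(rbind, per) %||% NULL,
       summary = do.call(rbind, summ) %||% NULL)
}
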