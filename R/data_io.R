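#' Read a variation-call matrix
#'
#' A variation-call matrix records, for each probe set, one ternary call per
#' biological comparison: `I` (increased), `D` (decreased) or `N` (not
#' changed).  The file is tab-separated UTF-8 with a header row of comparison
#' identifiers; the first column holds probe-set identifiers.
#'
#' @param path path to a TSV file
#' @return a `call_matrix`: character matrix over \{I, D, N\} with probe sets
#'   as rows (rownames) and comparisons as columns (colnames), rows in file
#'   order
#' @seealso [write_call_matrix()], [corr_anti()]
#' @export
read_call_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("call matrix needs a probe_set column plus >=1 comparison column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate probe-set identifier: ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  bad <- which(!(m %in% c("I", "D", "N")))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("invalid call '%s' at row %d, column %d (allowed: I, D, N)",
                 m[i, j], i, j))
  }
  as_call_matrix(m)
}

#' Construct a call matrix from a character matrix
#'
#' @param m character matrix over \{I, D, N\} with rownames (probe sets) and
#'   colnames (comparison identifiers)
#' @return a validated `call_matrix`
#' @export
as_call_matrix <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  if (is.null(rownames(m))) stop("call matrix needs probe-set rownames")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  if (!all(m %in% c("I", "D", "N"))) stop("calls must be in {I, D, N}")
  if (anyDuplicated(rownames(m))) stop("duplicate probe-set identifiers")
  structure(m, class = c("call_matrix", "matrix", "array"))
}

#' Write a variation-call matrix
#'
#' @param calls a `call_matrix`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_call_matrix <- function(calls, path) {
  df <- data.frame(probe_set = rownames(calls), unclass(calls),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

target_sources <- c("Ensembl", "AceView", "GOP")

#' Read a probe-target annotation table
#'
#' One record per (probe set, gene) pair, describing how the probe set's
#' probes fall on the gene: counts of probes in exons, introns, upstream and
#' downstream regions, the transcripts targeted and not targeted,
#' the indices of targeted exons, and the number of probes in the last exon.
#' `source` records where the gene model comes from: `Ensembl`, `AceView`, or
#' `GOP` (a group of probes clustered outside known genes, see
#' [cluster_gops()]).  Semicolon-separated lists; empty string = empty list.
#'
#' @param path path to a TSV file with columns `probe_set`, `gene`, `source`,
#'   `probes_exon`, `probes_intron`, `probes_up`, `probes_down`,
#'   `transcripts_targeted`, `transcripts_untargeted`, `exons_targeted`,
#'   `probes_last_exon`
#' @return a `target_table` data frame; list columns `transcripts_targeted`,
#'   `transcripts_untargeted` (character) and `exons_targeted` (integer)
#' @export
read_target_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = list(probe_set = "character", gene = "character",
                                     source = "character",
                                     transcripts_targeted = "character",
                                     transcripts_untargeted = "character",
                                     exons_targeted = "character"))
  as_target_table(df)
}

#' Validate and normalise a target table
#'
#' @param df data frame with the columns of [read_target_table()]; the three
#'   list columns may be given as `;`-separated strings or as list columns
#' @return a `target_table`
#' @export
as_target_table <- function(df) {
  need <- c("probe_set", "gene", "source", "probes_exon", "probes_intron",
            "probes_up", "probes_down", "transcripts_targeted",
            "transcripts_untargeted", "exons_targeted", "probes_last_exon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("target table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("probe_set", "gene")])) {
    stop("duplicate (probe_set, gene) record in target table")
  }
  bad_src <- setdiff(unique(df$source), target_sources)
  if (length(bad_src)) {
    stop("unknown source '", bad_src[1], "' (allowed: ",
         paste(target_sources, collapse = ", "), ")")
  }
  cnt <- c("probes_exon", "probes_intron", "probes_up", "probes_down",
           "probes_last_exon")
  for (col in cnt) {
    v <- as.integer(df[[col]])
    if (anyNA(v) || any(v < 0)) stop("column ", col, " must hold non-negative integers")
    df[[col]] <- v
  }
  split_list <- function(x, conv = identity) {
    if (is.list(x)) return(lapply(x, conv))
    lapply(strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";", fixed = TRUE),
           function(v) if (length(v) == 1 && is.na(v)) conv(character(0)) else conv(v))
  }
  df$transcripts_targeted <- split_list(df$transcripts_targeted)
  df$transcripts_untargeted <- split_list(df$transcripts_untargeted)
  df$exons_targeted <- split_list(df$exons_targeted, as.integer)
  df$probes_total <- df$probes_exon + df$probes_intron + df$probes_up + df$probes_down
  class(df) <- c("target_table", "data.frame")
  df
}

#' Write a target table
#'
#' @param targets a `target_table`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_target_table <- function(targets, path) {
  df <- as.data.frame(targets)
  glue <- function(x) vapply(x, paste, "", collapse = ";")
  df$transcripts_targeted <- glue(df$transcripts_targeted)
  df$transcripts_untargeted <- glue(df$transcripts_untargeted)
  df$exons_targeted <- glue(df$exons_targeted)
  df$probes_total <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pair-similarity table
#'
#' One row per alternative probe-set pair with its similarity class, the
#' number of networks in which the pair passed the similarity test, and its
#' mean positive/negative correlation across networks.  Rows are ordered
#' lexicographically by (probe_set_1, probe_set_2) so output is
#' deterministic.
#'
#' @param pairs a `pair_similarity` data frame from [classify_pairs()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_similarity_table <- function(pairs, path) {
  cols <- c("probe_set_1", "probe_set_2", "gene", "similarity_class",
            "n_networks_similar", "n_networks", "mean_corr", "mean_anti")
  df <- as.data.frame(pairs)[, cols, drop = FALSE]
  df <- df[order(df$probe_set_1, df$probe_set_2), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair-similarity table written by [write_similarity_table()]
#'
#' @param path TSV path
#' @return data frame with one row per pair
#' @export
read_similarity_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = list(probe_set_1 = "character",
                               probe_set_2 = "character",
                               gene = "character"))
}

#' Read probe genomic positions from a BED file
#'
#' Standard 0-based half-open BED: `chrom start end name score strand`.
#' Only the chromosome, start and strand are used for probe clustering
#' ([cluster_gops()]); the probe position is the interval start.
#'
#' @param path BED path (no header)
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `strand`
#' @export
read_probe_bed <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("probe BED needs 6 columns (chrom start end name score strand)")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df[, c("chrom", "start", "end", "name", "strand")]
}

#' Read a covariation network from an edge list
#'
#' Inverse of [write_network()].  The probe-set universe defaults to the
#' identifiers seen in the file; pass `probe_set_ids` to embed the edges in
#' a larger universe (isolated probe sets are legitimate network members).
#'
#' @param path TSV edge list `ps_a ps_b corr anti`
#' @param probe_set_ids optional character vector of the full universe
#' @param alpha,n_comparisons metadata to attach (not recoverable from the
#'   edge list itself)
#' @return a `covariation_network`
#' @export
read_network <- function(path, probe_set_ids = NULL, alpha = NA_real_,
                         n_comparisons = NA_integer_) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = list(ps_a = "character", ps_b = "character"))
  ids <- probe_set_ids %||% sort(unique(c(df$ps_a, df$ps_b)))
  i <- match(df$ps_a, ids); j <- match(df$ps_b, ids)
  if (anyNA(i) || anyNA(j)) stop("edge references a probe set outside the universe")
  n <- length(ids)
  mk <- function(x) {
    keep <- x != 0
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                         dims = c(n, n), symmetric = TRUE)
  }
  structure(list(probe_set_ids = ids, corr = mk(df$corr), anti = mk(df$anti),
                 alpha = alpha, n_comparisons = n_comparisons),
            class = "covariation_network")
}

#' Read/write a signal matrix
#'
#' Conditions x probe sets, TSV with a `condition` first column.
#'
#' @param path TSV path
#' @return numeric matrix with condition rownames and probe-set colnames
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = list(condition = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$condition
  storage.mode(m) <- "double"
  m
}

#' @rdname read_signal_matrix
#' @param signals numeric matrix (conditions x probe sets)
#' @export
write_signal_matrix <- function(signals, path) {
  df <- data.frame(condition = rownames(signals), signals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a covariation network as an edge list
#'
#' TSV columns `ps_a ps_b corr anti`; a value filtered out by the
#' significance test is written as 0.  Only pairs with at least one stored
#' value appear.
#'
#' @param network a `covariation_network`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_network <- function(network, path) {
  df <- network_edges(network)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
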