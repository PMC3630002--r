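#' Bipartite probe-set x gene adjacency at a probe-number limit
#'
#' Cell (i, j) is set when probe set i places at least `limit` probes on
#' gene j (total over exon, intron, upstream and downstream categories).
#' Probe sets and genes left without any cell are dropped from the bipartite
#' universe.  The default limit of 7 balances specificity (not calling a
#' gene a target on a couple of stray probes) against sensitivity.
#'
#' @param targets a `target_table`
#' @param limit probe-number limit (>= 1)
#' @return a `ps_gene_adjacency`: list with `probe_sets`, `genes`, and
#'   logical sparse matrix `adj` (probe sets x genes)
#' @export
build_adjacency <- function(targets, limit = 7L) {
  if (limit < 1) stop("probe-number limit must be >= 1")
  keep <- targets$probes_total >= limit
  df <- as.data.frame(targets)[keep, c("probe_set", "gene")]
  ps <- sort(unique(df$probe_set)); gn <- sort(unique(df$gene))
  adj <- Matrix::sparseMatrix(i = match(df$probe_set, ps),
                              j = match(df$gene, gn),
                              x = TRUE, dims = c(length(ps), length(gn)),
                              dimnames = list(ps, gn))
  structure(list(probe_sets = ps, genes = gn, adj = adj, limit = limit),
            class = "ps_gene_adjacency")
}

#' Extract the bicluster reachable from a seed probe set
#'
#' Alternating closure on the bipartite graph: depth 1 takes the seed's
#' genes and every probe set targeting them; each further depth adds genes
#' newly targeted by the previous depth's probe sets, and the probe sets
#' targeting those new genes; it stops when nothing new appears.  The
#' recorded depth is the last depth at which any element was added, so it
#' depends on the seed; membership does not (it is the connected component).
#'
#' @param seed probe-set identifier present in the adjacency
#' @param adjacency a `ps_gene_adjacency`
#' @return a `bicluster`: list with `probe_sets`, `genes`, `depth`,
#'   `density` (percent of filled cells), `seed`
#' @export
extract_bicluster <- function(seed, adjacency) {
  A <- adjacency$adj
  i0 <- match(seed, adjacency$probe_sets)
  if (is.na(i0)) stop("unknown seed probe set: ", seed)
  ps_in <- logical(nrow(A)); gn_in <- logical(ncol(A))
  ps_in[i0] <- TRUE
  depth <- 0L
  frontier_ps <- i0
  repeat {
    new_gn <- which(Matrix::colSums(A[frontier_ps, , drop = FALSE]) > 0 & !gn_in)
    if (!length(new_gn)) break
    gn_in[new_gn] <- TRUE
    new_ps <- which(Matrix::rowSums(A[, new_gn, drop = FALSE]) > 0 & !ps_in)
    ps_in[new_ps] <- TRUE
    depth <- depth + 1L
    if (!length(new_ps)) break
    frontier_ps <- new_ps
  }
  ps <- adjacency$probe_sets[ps_in]
  gn <- adjacency$genes[gn_in]
  filled <- sum(A[ps_in, gn_in, drop = FALSE])
  structure(list(probe_sets = ps, genes = gn, depth = max(depth, 1L),
                 density = 100 * filled / (length(ps) * length(gn)),
                 seed = seed),
            class = "bicluster")
}

#' Classify a bicluster
#'
#' Single/multiple probe sets x single/multiple genes, with the
#' multiple-multiple case split by the recursion depth needed to assemble
#' it: `SS` (1 probe set, 1 gene), `SM` (1, >1), `MS` (>1, 1), and for
#' multiple x multiple `MM` (depth 1), `CX` (depth 2), `HX` (depth >= 3).
#'
#' @param b a `bicluster` (or any list with `probe_sets`, `genes`, `depth`)
#' @return class label, one of "SS","SM","MS","MM","CX","HX"
#' @export
classify_bicluster <- function(b) {
  np <- length(b$probe_sets); ng <- length(b$genes)
  if (np == 1 && ng == 1) return("SS")
  if (np == 1) return("SM")
  if (ng == 1) return("MS")
  if (b$depth == 1) return("MM")
  if (b$depth == 2) return("CX")
  "HX"
}

#' Partition a chip's adjacency into biclusters
#'
#' Biclusters are the connected components of the bipartite probe-set/gene
#' graph; every probe set belongs to exactly one.  A component's depth is
#' the minimum recursion depth over all its probe-set seeds, making the
#' class label independent of seed order.
#'
#' @param adjacency a `ps_gene_adjacency`
#' @return list with `biclusters` (list of `bicluster`, each with
#'   `class_label`) and `summary`: data frame of per-class counts of
#'   biclusters, probe sets and genes, plus `pct_alternative`, the
#'   percentage of probe sets sharing their assigned gene with another
#'   probe set
#' @export
partition_chip <- function(adjacency) {
  A <- adjacency$adj
  np <- nrow(A)
  g <- igraph::graph_from_biadjacency_matrix(A)
  comp <- igraph::components(g)$membership
  ps_comp <- comp[seq_len(np)]
  gn_comp <- comp[np + seq_len(ncol(A))]
  bics <- lapply(sort(unique(ps_comp)), function(cid) {
    ps <- adjacency$probe_sets[ps_comp == cid]
    gn <- adjacency$genes[gn_comp == cid]
    depths <- vapply(ps, function(s) extract_bicluster(s, adjacency)$depth, 0L)
    filled <- sum(A[ps_comp == cid, gn_comp == cid, drop = FALSE])
    b <- structure(list(probe_sets = ps, genes = gn, depth = min(depths),
                        density = 100 * filled / (length(ps) * length(gn)),
                        seed = ps[which.min(depths)]),
                   class = "bicluster")
    b$class_label <- classify_bicluster(b)
    b
  })
  cls <- vapply(bics, function(b) b$class_label, "")
  summary <- do.call(rbind, lapply(c("SS", "SM", "MS", "MM", "CX", "HX"), function(k) {
    sel <- cls == k
    data.frame(class = k, n_biclusters = sum(sel),
               n_probe_sets = sum(vapply(bics[sel], function(b) length(b$probe_sets), 0L)),
               n_genes = sum(vapply(bics[sel], function(b) length(b$genes), 0L)),
               stringsAsFactors = FALSE)
  }))
  # alternative probe sets: share an assigned gene with another probe set;
  # within the adjacency, a probe set is alternative when some gene it is
  # assigned to is also assigned to another probe set
  list(biclusters = bics, summary = summary)
}

#' Fraction of alternative probe sets under a gene assignment
#'
#' @param assignments named character vector: probe set -> assigned gene
#' @return percentage of probe sets whose assigned gene is shared
#' @export
pct_alternative <- function(assignments) {
  tab <- table(assignments)
  100 * sum(tab[assignments] > 1) / length(assignments)
}

#' Assign a probe set to a single gene
#'
#' When a probe set targets several genes, candidates are filtered through
#' six criteria in order, stopping as soon as one gene is left:
#' \enumerate{
#'   \item highest number of targeting probes (all categories);
#'   \item best target type, exon > intron > upstream > downstream, compared
#'     by the probe count in the best populated category;
#'   \item maximal ratio between the number of probe sets targeting the gene
#'     and the number of groups of probe sets targeting the same
#'     transcript(s) (probe sets grouped by identical targeted-transcript
#'     sets);
#'   \item minimal number of targeting probe sets;
#'   \item gene source, Ensembl > AceView > GOP;
#'   \item first gene in alphabetic order.
#' }
#'
#' @param ps probe-set identifier
#' @param targets a `target_table`
#' @param min_probes only genes targeted with at least this many probes are
#'   candidates (the probe-number limit; default 1 considers every record)
#' @return the assigned gene identifier
#' @export
assign_gene <- function(ps, targets, min_probes = 1L) {
  df <- as.data.frame(targets)
  rec <- df[df$probe_set == ps & df$probes_total >= min_probes, , drop = FALSE]
  if (!nrow(rec)) stop("probe set ", ps, " targets no gene at this limit")
  if (nrow(rec) == 1) return(rec$gene)
  # 1: most targeting probes
  rec <- rec[rec$probes_total == max(rec$probes_total), , drop = FALSE]
  if (nrow(rec) == 1) return(rec$gene)
  # 2: best target type; rank categories, keep genes whose best populated
  #    category ranks highest, then the largest count in that category
  cats <- c("probes_exon", "probes_intron", "probes_up", "probes_down")
  cnts <- as.matrix(rec[, cats])
  best_rank <- apply(cnts, 1, function(v) {
    w <- which(v > 0)
    if (length(w)) min(w) else length(cats) + 1L
  })
  rec <- rec[best_rank == min(best_rank), , drop = FALSE]
  cnts <- cnts[best_rank == min(best_rank), , drop = FALSE]
  if (nrow(rec) == 1) return(rec$gene)
  br <- min(best_rank)
  if (br <= length(cats)) {
    bc <- cnts[, br]
    rec <- rec[bc == max(bc), , drop = FALSE]
    if (nrow(rec) == 1) return(rec$gene)
  }
  # 3: max ratio (#probe sets targeting gene) / (#transcript-set groups)
  ratio <- vapply(rec$gene, function(g) {
    sub <- df[df$gene == g & df$probes_total >= min_probes, , drop = FALSE]
    keys <- vapply(sub$transcripts_targeted,
                   function(tt) paste(sort(tt), collapse = ";"), "")
    nrow(sub) / max(1L, length(unique(keys)))
  }, 0)
  rec <- rec[ratio == max(ratio), , drop = FALSE]
  if (nrow(rec) == 1) return(rec$gene)
  # 4: min number of targeting probe sets
  nps <- vapply(rec$gene, function(g)
    sum(df$gene == g & df$probes_total >= min_probes), 0L)
  rec <- rec[nps == min(nps), , drop = FALSE]
  if (nrow(rec) == 1) return(rec$gene)
  # 5: source Ensembl > AceView > GOP
  src_rank <- match(rec$source, target_sources)
  rec <- rec[src_rank == min(src_rank), , drop = FALSE]
  if (nrow(rec) == 1) return(rec$gene)
  # 6: alphabetic
  sort(rec$gene)[1]
}

#' Assign every probe set of a target table to a gene
#'
#' @param targets a `target_table`
#' @param min_probes probe-number limit passed to [assign_gene()]
#' @return named character vector: probe set -> gene (probe sets with no
#'   gene at the limit are dropped)
#' @export
assign_all_genes <- function(targets, min_probes = 1L) {
  ps <- unique(targets$probe_set[targets$probes_total >= min_probes])
  setNames(vapply(ps, assign_gene, "", targets = targets,
                  min_probes = min_probes), ps)
}

#' Alternative probe-set pairs under a gene assignment
#'
#' All unordered pairs of distinct probe sets assigned to the same gene.
#'
#' @param assignments named vector from [assign_all_genes()]
#' @return data frame `probe_set_1`, `probe_set_2` (lexicographic within and
#'   across pairs), `gene`
#' @export
alternative_pairs <- function(assignments) {
  by_gene <- split(names(assignments), assignments)
  out <- lapply(names(by_gene), function(g) {
    m <- sort(by_gene[[g]])
    if (length(m) < 2) return(NULL)
    cmb <- t(combn(m, 2))
    data.frame(probe_set_1 = cmb[, 1], probe_set_2 = cmb[, 2], gene = g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(probe_set_1 = character(0), probe_set_2 = character(0),
                      gene = character(0)))
  }
  out[order(out$probe_set_1, out$probe_set_2), , drop = FALSE]
}
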