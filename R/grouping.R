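#' Triangles of similar probe-set pairs
#'
#' All unordered triples \{A, B, C\} whose three pairs are all similar.
#'
#' @param similar_pairs 2-column character matrix / data frame of unordered
#'   pairs
#' @return character matrix with 3 columns, one sorted triple per row
#'   (zero rows when there is no triangle), rows in lexicographic order
#' @export
find_triangles <- function(similar_pairs) {
  pr <- unique_pairs(similar_pairs)
  if (nrow(pr) == 0) return(matrix(character(0), ncol = 3))
  g <- igraph::graph_from_edgelist(as.matrix(pr), directed = FALSE)
  tri <- igraph::triangles(g)
  if (!length(tri)) return(matrix(character(0), ncol = 3))
  m <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

unique_pairs <- function(pairs) {
  pr <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (nrow(pr) == 0) return(pr)
  swap <- pr[, 1] > pr[, 2]
  pr[swap, ] <- pr[swap, 2:1]
  unique(pr)
}

#' Aggregate triangles of similar pairs into probe-set groups
#'
#' Two triangles belong to the same group when they share an edge (two
#' probe sets); a group's members are the union of its triangles' vertices.
#' Aggregation can pull in member pairs that are not themselves similar —
#' for instance triangles (ABC) and (ABD) share edge AB and form the group
#' (ABCD), introducing the pair (CD) even when it is not similar; such
#' pairs are recorded as the group's bad links.  A similar pair contained
#' in no group becomes a 2-member group of its own.  A probe set belonging
#' to several groups (e.g. two triangles sharing only that probe set) is a
#' pivot, reported apart with all its groups.
#'
#' @param similar_pairs 2-column matrix / data frame of similar pairs
#' @param triangles optional precomputed [find_triangles()] output
#' @return list with `groups` (list of `probe_set_group`: `members`,
#'   `bad_links` 2-column matrix, `source_triangles`) and `pivots`
#'   (data frame `probe_set`, `group_ids` ;-list)
#' @export
aggregate_groups <- function(similar_pairs, triangles = NULL) {
  pr <- unique_pairs(similar_pairs)
  if (is.null(triangles)) triangles <- find_triangles(pr)
  sim_keys <- if (nrow(pr)) pair_key(pr[, 1], pr[, 2]) else character(0)
  groups <- list()
  if (nrow(triangles)) {
    # triangle graph: triangles adjacent iff they share an edge
    tkeys <- lapply(seq_len(nrow(triangles)), function(r) {
      v <- triangles[r, ]
      c(pair_key(v[1], v[2]), pair_key(v[1], v[3]), pair_key(v[2], v[3]))
    })
    edge_to_tri <- split(rep(seq_along(tkeys), each = 3), unlist(tkeys))
    nt <- nrow(triangles)
    adj_pairs <- do.call(rbind, lapply(edge_to_tri, function(ts) {
      if (length(ts) < 2) return(NULL)
      t(combn(ts, 2))
    }))
    g <- igraph::make_empty_graph(n = nt, directed = FALSE)
    if (!is.null(adj_pairs)) g <- igraph::add_edges(g, t(adj_pairs))
    comp <- igraph::components(g)$membership
    groups <- lapply(sort(unique(comp)), function(cid) {
      tr <- triangles[comp == cid, , drop = FALSE]
      members <- sort(unique(as.vector(tr)))
      allp <- t(combn(members, 2))
      bad <- allp[!(pair_key(allp[, 1], allp[, 2]) %in% sim_keys), , drop = FALSE]
      structure(list(members = members, bad_links = bad,
                     source_triangles = tr),
                class = "probe_set_group")
    })
  }
  # similar pairs not contained in any group become 2-member groups
  in_group <- rep(FALSE, nrow(pr))
  for (grp in groups) {
    in_group <- in_group | (pr[, 1] %in% grp$members & pr[, 2] %in% grp$members)
  }
  lone <- pr[!in_group, , drop = FALSE]
  groups <- c(groups, lapply(seq_len(nrow(lone)), function(r) {
    structure(list(members = sort(lone[r, ]),
                   bad_links = matrix(character(0), ncol = 2),
                   source_triangles = matrix(character(0), ncol = 3)),
              class = "probe_set_group")
  }))
  membership <- data.frame(
    probe_set = unlist(lapply(groups, `[[`, "members")),
    group = rep(seq_along(groups),
                vapply(groups, function(g) length(g$members), 0L)),
    stringsAsFactors = FALSE)
  per_ps <- split(membership$group, membership$probe_set)
  piv <- per_ps[vapply(per_ps, length, 0L) >= 2]
  pivots <- data.frame(probe_set = names(piv),
                       group_ids = vapply(piv, paste, "", collapse = ";"),
                       stringsAsFactors = FALSE, row.names = NULL)
  pivots <- pivots[order(pivots$probe_set), , drop = FALSE]
  list(groups = groups, pivots = pivots)
}

#' Write groups and pivots to TSV
#'
#' @param grouping result of [aggregate_groups()]
#' @param class_label similarity class the grouping was computed in
#' @param groups_path,pivots_path output TSV paths
#' @return invisibly, the two paths
#' @export
write_groups <- function(grouping, class_label, groups_path, pivots_path) {
  gl <- grouping$groups
  df <- data.frame(
    group_id = seq_along(gl), class = class_label,
    members = vapply(gl, function(g) paste(g$members, collapse = ";"), ""),
    bad_links = vapply(gl, function(g) {
      if (!nrow(g$bad_links)) return("")
      paste(paste(g$bad_links[, 1], g$bad_links[, 2], sep = "|"), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  write.table(df, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(grouping$pivots, pivots_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(groups_path, pivots_path))
}
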