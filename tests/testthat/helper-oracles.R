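# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (position loops, subset enumeration, BFS) so they check
# the vectorised implementations from the outside.

# build a call_matrix from a character vector of strings like "IDN..."
calls_from_strings <- function(strings, ids = NULL) {
  ids <- ids %||% sprintf("ps%02d", seq_along(strings))
  m <- do.call(rbind, strsplit(strings, ""))
  rownames(m) <- ids
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  as_call_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# position-by-position triple counter for two call strings
bf_corr_anti <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  conc <- disc <- info <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "N" && b[k] == "N") next
    info <- info + 1L
    if (a[k] != "N" && a[k] == b[k]) conc <- conc + 1L
    if ((a[k] == "I" && b[k] == "D") || (a[k] == "D" && b[k] == "I"))
      disc <- disc + 1L
  }
  if (info == 0) list(corr = 0, anti = 0, n_informative = 0L)
  else list(corr = 100 * conc / info, anti = 100 * disc / info,
            n_informative = info)
}

random_call_string <- function(len) {
  paste(sample(c("I", "D", "N"), len, replace = TRUE), collapse = "")
}

# exhaustive hypergeometric tail via choose(); independent of phyper
bf_overlap_p <- function(N, N1, N2, M) {
  ks <- N:min(N1, N2)
  sum(choose(N1, ks) * choose(M - N1, N2 - ks)) / choose(M, N2)
}

# BFS over the bipartite graph; returns the component of a seed probe set
bf_component <- function(seed, edges) {
  # edges: data.frame(probe_set, gene)
  ps <- seed; gn <- character(0)
  repeat {
    gn2 <- unique(edges$gene[edges$probe_set %in% ps])
    ps2 <- unique(edges$probe_set[edges$gene %in% gn2])
    if (setequal(ps2, ps) && setequal(gn2, gn)) break
    ps <- union(ps, ps2); gn <- union(gn, gn2)
  }
  list(probe_sets = sort(ps), genes = sort(gn))
}

# random bipartite target table: n_ps probe sets, n_gn genes, edge prob p
random_target_table <- function(n_ps, n_gn, p) {
  ps <- sprintf("p%02d", seq_len(n_ps)); gn <- sprintf("g%02d", seq_len(n_gn))
  sel <- which(matrix(runif(n_ps * n_gn) < p, n_ps, n_gn), arr.ind = TRUE)
  # each probe set needs >= 1 gene to live in the adjacency universe
  if (nrow(sel) == 0) sel <- cbind(1L, 1L)
  df <- data.frame(probe_set = ps[sel[, 1]], gene = gn[sel[, 2]],
                   source = "Ensembl",
                   probes_exon = sample(1:11, nrow(sel), replace = TRUE),
                   probes_intron = 0L, probes_up = 0L, probes_down = 0L,
                   transcripts_targeted = "", transcripts_untargeted = "",
                   exons_targeted = "", probes_last_exon = 0L,
                   stringsAsFactors = FALSE)
  as_target_table(df)
}

# brute-force triangle listing: every triple checked against the pair set
bf_triangles <- function(pairs) {
  verts <- sort(unique(as.vector(as.matrix(pairs))))
  keys <- pair_key_t(pairs)
  if (length(verts) < 3) return(matrix(character(0), ncol = 3))
  tri <- t(combn(verts, 3))
  ok <- apply(tri, 1, function(v)
    all(c(pk(v[1], v[2]), pk(v[1], v[3]), pk(v[2], v[3])) %in% keys))
  tri[ok, , drop = FALSE]
}
pk <- function(a, b) if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
pair_key_t <- function(pairs) {
  m <- as.matrix(pairs)
  mapply(pk, m[, 1], m[, 2], USE.NAMES = FALSE)
}

# brute-force grouping oracle: explicit triangle graph + BFS components,
# lone-pair groups, bad links, pivots as multi-group members
bf_aggregate <- function(pairs) {
  pairs <- as.matrix(pairs)
  tri <- bf_triangles(pairs)
  keys <- pair_key_t(pairs)
  groups <- list()
  nt <- nrow(tri)
  if (nt) {
    share_edge <- function(u, v) {
      shared <- intersect(u, v)
      length(shared) >= 2
    }
    adj <- matrix(FALSE, nt, nt)
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      if (i != j) adj[i, j] <- share_edge(tri[i, ], tri[j, ])
    }
    seen <- rep(FALSE, nt)
    for (s in seq_len(nt)) {
      if (seen[s]) next
      comp <- s
      repeat {
        nb <- which(apply(adj[comp, , drop = FALSE], 2, any) & !seq_len(nt) %in% comp)
        if (!length(nb)) break
        comp <- c(comp, nb)
      }
      seen[comp] <- TRUE
      members <- sort(unique(as.vector(tri[comp, , drop = FALSE])))
      allp <- t(combn(members, 2))
      bad <- allp[!(mapply(pk, allp[, 1], allp[, 2]) %in% keys), , drop = FALSE]
      groups[[length(groups) + 1]] <- list(members = members, bad = bad)
    }
  }
  for (r in seq_len(nrow(pairs))) {
    covered <- any(vapply(groups, function(g)
      all(pairs[r, ] %in% g$members), NA))
    if (!covered) {
      groups[[length(groups) + 1]] <-
        list(members = sort(pairs[r, ]), bad = matrix(character(0), ncol = 2))
    }
  }
  memb <- table(unlist(lapply(groups, `[[`, "members")))
  list(groups = groups, pivots = sort(names(memb)[memb >= 2]))
}

# canonical form of a grouping result for comparison
canon_groups <- function(groups) {
  sigs <- vapply(groups, function(g) {
    members <- if (is.list(g)) g$members else g
    bad <- if (is.list(g)) (g$bad_links %||% g$bad) else NULL
    bl <- if (!is.null(bad) && nrow(bad)) {
      sort(mapply(pk, bad[, 1], bad[, 2]))
    } else character(0)
    paste(paste(sort(members), collapse = ","), paste(bl, collapse = ","),
          sep = " / ")
  }, "")
  unname(sort(sigs))
}

# tiny deterministic target-table row
tt_row <- function(ps, gene, source = "Ensembl", exon = 11L, intron = 0L,
                   up = 0L, down = 0L, tt = "", tu = "", ex = "", last = 0L) {
  data.frame(probe_set = ps, gene = gene, source = source,
             probes_exon = exon, probes_intron = intron, probes_up = up,
             probes_down = down, transcripts_targeted = tt,
             transcripts_untargeted = tu, exons_targeted = ex,
             probes_last_exon = last, stringsAsFactors = FALSE)
}
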