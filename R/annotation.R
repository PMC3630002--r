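#' Cluster probes outside known genes into GOPs
#'
#' A GOP (group of probes) is a maximal run of probes on the same chromosome
#' and strand in which each probe is at most `gap` bases (default 2 kb) from
#' its direct neighbour.  Input order is irrelevant: positions are sorted
#' internally, and identifiers are deterministic
#' (`GOP_<chrom><strand>_<k>` in coordinate order).
#'
#' @param probes data frame with columns `chrom`, `strand`, `position`
#'   (0-based; use interval starts from [read_probe_bed()])
#' @param gap maximum neighbour distance in bases (> 0)
#' @return list of `gop`: `id`, `chrom`, `strand`, sorted `positions`
#' @export
cluster_gops <- function(probes, gap = 2000L) {
  stopifnot(gap > 0)
  if (!all(c("chrom", "strand", "position") %in% names(probes))) {
    if (all(c("chrom", "strand", "start") %in% names(probes))) {
      probes$position <- probes$start
    } else stop("probes need columns chrom, strand, position")
  }
  out <- list()
  for (key in sort(unique(paste(probes$chrom, probes$strand)))) {
    sel <- paste(probes$chrom, probes$strand) == key
    pos <- sort(probes$position[sel])
    brk <- c(0L, which(diff(pos) > gap), length(pos))
    chrom <- probes$chrom[sel][1]; strand <- probes$strand[sel][1]
    for (k in seq_len(length(brk) - 1)) {
      run <- pos[(brk[k] + 1):brk[k + 1]]
      out[[length(out) + 1]] <- structure(
        list(id = sprintf("GOP_%s%s_%d", chrom, strand, k),
             chrom = chrom, strand = strand, positions = run),
        class = "gop")
    }
  }
  out
}

#' Localisation scores of an alternative probe-set pair on its gene
#'
#' Compares where the two probe sets sit on the shared gene.  With T1, T2
#' the targeted-transcript sets and E1, E2 the targeted-exon index sets:
#' \itemize{
#'   \item `pct_transcripts_both = 100 |T1 n T2| / |T1 u T2|`
#'   \item `pct_transcripts_one  = 100 |T1 xor T2| / |T1 u T2|`
#'   \item `n_exons_both = |E1 n E2|`
#'   \item `pct_exon_probes_both`: of the pair's exon-located probes, the
#'     percentage attributed to exons targeted by both probe sets (each
#'     probe set's exon probes split evenly over its targeted exons)
#'   \item `pct_exon_probes_one`: likewise for exons targeted by only one
#'   \item `pct_probes_last_exon`: the larger of the two probe sets'
#'     fractions of probes in the last exon
#' }
#'
#' @param ps1,ps2 probe-set identifiers
#' @param gene shared gene identifier
#' @param targets a `target_table`
#' @return list of the six scores (transcript percents NA when neither
#'   probe set targets a known transcript)
#' @export
pair_localisation_scores <- function(ps1, ps2, gene, targets) {
  df <- as.data.frame(targets)
  r1 <- df[df$probe_set == ps1 & df$gene == gene, , drop = FALSE]
  r2 <- df[df$probe_set == ps2 & df$gene == gene, , drop = FALSE]
  if (nrow(r1) != 1 || nrow(r2) != 1) stop("both probe sets must target the gene")
  T1 <- r1$transcripts_targeted[[1]]; T2 <- r2$transcripts_targeted[[1]]
  E1 <- r1$exons_targeted[[1]]; E2 <- r2$exons_targeted[[1]]
  tu <- union(T1, T2)
  if (length(tu)) {
    both_t <- 100 * length(intersect(T1, T2)) / length(tu)
    one_t <- 100 - both_t
  } else both_t <- one_t <- NA_real_
  # split each probe set's exon probes evenly over its targeted exons, then
  # attribute to shared / exclusive exons
  shared_e <- intersect(E1, E2)
  exon_mass <- function(rec, E) {
    if (!length(E)) return(c(both = 0, one = 0))
    per <- rec$probes_exon / length(E)
    c(both = per * sum(E %in% shared_e), one = per * sum(!(E %in% shared_e)))
  }
  m <- exon_mass(r1, E1) + exon_mass(r2, E2)
  tot <- r1$probes_exon + r2$probes_exon
  pct_both_e <- if (tot > 0) 100 * m[["both"]] / tot else NA_real_
  pct_one_e <- if (tot > 0) 100 * m[["one"]] / tot else NA_real_
  frac_last <- function(rec) {
    if (rec$probes_total == 0) return(0)
    rec$probes_last_exon / rec$probes_total
  }
  list(pct_transcripts_both = both_t,
       pct_transcripts_one = one_t,
       pct_exon_probes_both = pct_both_e,
       pct_exon_probes_one = pct_one_e,
       pct_probes_last_exon = 100 * max(frac_last(r1), frac_last(r2)),
       n_exons_both = length(shared_e))
}

#' Localisation-score distributions by similarity class
#'
#' Restricts to pairs in which both probe sets target the shared gene with
#' at least `min_probes` probes (default 11, a full probe set), computes
#' [pair_localisation_scores()] for each, and summarises every score per
#' similarity class by its mean and deciles.
#'
#' @param pairs a `pair_similarity` data frame (with `gene`)
#' @param targets a `target_table`
#' @param min_probes per-probe-set probe-count filter
#' @return list per class: list with `n_pairs`, and per score `mean` and
#'   `deciles` (0%..100% nearest-rank); empty classes are omitted with a
#'   warning
#' @export
scores_by_similarity <- function(pairs, targets, min_probes = 11L) {
  df <- as.data.frame(targets)
  cnt <- setNames(df$probes_total, paste(df$probe_set, df$gene, sep = "|"))
  keep <- cnt[paste(pairs$probe_set_1, pairs$gene, sep = "|")] >= min_probes &
    cnt[paste(pairs$probe_set_2, pairs$gene, sep = "|")] >= min_probes
  keep[is.na(keep)] <- FALSE
  pr <- pairs[keep, , drop = FALSE]
  fields <- c("pct_transcripts_both", "pct_transcripts_one",
              "pct_exon_probes_both", "pct_exon_probes_one",
              "pct_probes_last_exon", "n_exons_both")
  out <- list()
  for (cls in sort(unique(pairs$similarity_class))) {
    sub <- pr[pr$similarity_class == cls, , drop = FALSE]
    if (!nrow(sub)) {
      warning("similarity class ", cls, " has no pair passing the probe filter")
      next
    }
    sc <- lapply(seq_len(nrow(sub)), function(r)
      pair_localisation_scores(sub$probe_set_1[r], sub$probe_set_2[r],
                               sub$gene[r], targets))
    summ <- lapply(fields, function(f) {
      v <- vapply(sc, function(s) as.numeric(s[[f]]), 0)
      v <- v[!is.na(v)]
      if (!length(v)) return(list(mean = NA_real_, deciles = rep(NA_real_, 11)))
      list(mean = mean(v),
           deciles = vapply(seq(0, 100, 10), nearest_rank_percentile, 0, x = v))
    })
    names(summ) <- fields
    out[[as.character(cls)]] <- c(list(n_pairs = nrow(sub)), summ)
  }
  out
}
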