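#' Specification of a synthetic benchmark dataset
#'
#' Emulates the inputs of the real pipeline at desk scale: latent
#' transcript modules emit correlated ternary call strings over
#' group-vs-group comparison designs; probe sets copy their module's latent
#' string with noise; matched raw signals and a probe-target annotation
#' table carry planted shared-transcript/exon structure.
#'
#' Alternative probe sets on one gene are planted as `same` (copies of one
#' module: truly similar), `anti` (sign-flipped module: mutually exclusive
#' isoform behaviour) or `independent` (separate modules), with
#' probabilities `frac_same_module`, `frac_anti` and the remainder.
#'
#' @param n_genes number of genes
#' @param probe_sets_per_gene integer vector sampled uniformly per gene
#' @param n_networks number of covariation networks
#' @param group_size conditions per comparison group (a network compares
#'   two disjoint groups: `group_size^2` comparisons)
#' @param n_conditions size of the condition pool; default
#'   `n_networks * 2 * group_size` (every network draws fresh groups)
#' @param p_change probability that a module is Increased (equally,
#'   Decreased) in a comparison; must be <= 0.5
#' @param epsilon per-position probability that a probe set reports N
#'   instead of its module's symbol
#' @param delta per-position probability of an I/D flip
#' @param frac_same_module,frac_anti planting probabilities for multi-probe-set
#'   genes
#' @param seed master seed; per-network sub-seeds are derived from it
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_genes = 200L, probe_sets_per_gene = 1:3,
                           n_networks = 5L, group_size = 10L,
                           n_conditions = NULL,
                           p_change = 0.25, epsilon = 0.2, delta = 0.02,
                           frac_same_module = 0.5, frac_anti = 0.1,
                           seed = 1L) {
  if (is.null(n_conditions)) n_conditions <- n_networks * 2L * group_size
  stopifnot(p_change >= 0, p_change <= 0.5, epsilon >= 0, epsilon <= 1,
            delta >= 0, delta <= 1, frac_same_module + frac_anti <= 1,
            2L * group_size <= n_conditions)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Fully reproducible from `spec$seed`.  Per network, two disjoint
#' condition groups are drawn from the pool and crossed into a comparison
#' design; per comparison, every module draws a latent symbol (I with
#' probability `p_change`, D with `p_change`, else N); every probe set
#' copies its module's latent string (sign-flipped for `anti` members),
#' substitutes N at rate `epsilon` and flips I/D at rate `delta`,
#' independently per position.  Signals give each module a level per
#' condition (normal around 10), inherited by its probe sets with a scale
#' factor and unit noise; `anti` members move opposite to their module.
#' The annotation table places 11 probes per probe set on its gene:
#' `same` pairs share transcripts and exons (including the last exon),
#' `anti` and `independent` pairs target disjoint transcripts and exons.
#'
#' @param spec a `synthetic_spec`
#' @return list with `dataset` (fields `call_matrices`, `signals`,
#'   `targets`, `designs`, `conditions`) and `truth` (fields `modules`:
#'   probe set -> module, `pairs`: data frame with planted `label`)
#' @export
generate_dataset <- function(spec) {
  withr_seed(spec$seed, {
    conditions <- sprintf("cond_%03d", seq_len(spec$n_conditions))
    sub_seeds <- sample.int(2^31 - 1, spec$n_networks + 1L)

    ## genes, probe sets, modules ------------------------------------------
    genes <- sprintf("gene_%04d", seq_len(spec$n_genes))
    n_ps_per_gene <- sample(spec$probe_sets_per_gene, spec$n_genes,
                            replace = TRUE)
    ps_gene <- rep(genes, n_ps_per_gene)
    ps_ids <- sprintf("ps_%05d", seq_along(ps_gene))
    module <- character(length(ps_ids))
    sign <- rep(1L, length(ps_ids))
    plant <- character(spec$n_genes)   # per-gene planting label
    idx_by_gene <- split(seq_along(ps_ids), ps_gene)[genes]
    for (g in seq_len(spec$n_genes)) {
      idx <- idx_by_gene[[g]]
      if (length(idx) == 1) {
        plant[g] <- "single"
        module[idx] <- paste0("M_", genes[g])
        next
      }
      u <- runif(1)
      if (u < spec$frac_same_module) {
        plant[g] <- "same"
        module[idx] <- paste0("M_", genes[g])
      } else if (u < spec$frac_same_module + spec$frac_anti) {
        plant[g] <- "anti"
        module[idx] <- paste0("M_", genes[g])
        sign[idx[-1]] <- -1L
      } else {
        plant[g] <- "independent"
        module[idx] <- paste0("M_", genes[g], "_", seq_along(idx))
      }
    }
    modules <- unique(module)

    ## call matrices, one per network --------------------------------------
    designs <- vector("list", spec$n_networks)
    call_matrices <- vector("list", spec$n_networks)
    for (w in seq_len(spec$n_networks)) {
      withr_seed(sub_seeds[w], {
        picked <- sample(conditions, 2L * spec$group_size)
        ga <- picked[seq_len(spec$group_size)]
        gb <- picked[spec$group_size + seq_len(spec$group_size)]
        designs[[w]] <- build_cross_design(ga, gb)
        n_comp <- n_comparisons(designs[[w]])
        latent <- matrix(sample(c(1L, -1L, 0L), length(modules) * n_comp,
                                replace = TRUE,
                                prob = c(spec$p_change, spec$p_change,
                                         1 - 2 * spec$p_change)),
                         nrow = length(modules),
                         dimnames = list(modules, NULL))
        Z <- latent[module, , drop = FALSE] * sign
        flip <- matrix(runif(length(Z)) < spec$delta, nrow = nrow(Z))
        Z[flip] <- -Z[flip]
        drop_n <- matrix(runif(length(Z)) < spec$epsilon, nrow = nrow(Z))
        Z[drop_n] <- 0L
        calls <- matrix(c("N", "I", "D")[match(Z, c(0L, 1L, -1L))],
                        nrow = nrow(Z))
        rownames(calls) <- ps_ids
        colnames(calls) <- paste(designs[[w]]$comparisons$condition_a,
                                 designs[[w]]$comparisons$condition_b,
                                 sep = "~")
        call_matrices[[w]] <- as_call_matrix(calls)
      })
    }

    ## signals ---------------------------------------------------------------
    withr_seed(sub_seeds[spec$n_networks + 1L], {
      level <- matrix(rnorm(length(modules) * spec$n_conditions, 10, 2),
                      nrow = spec$n_conditions,
                      dimnames = list(conditions, modules))
      scale <- runif(length(ps_ids), 0.8, 1.25)
      signals <- sapply(seq_along(ps_ids), function(i) {
        base <- level[, module[i]]
        if (sign[i] < 0) base <- 20 - base
        pmax(scale[i] * base + rnorm(spec$n_conditions), 0.01)
      })
      colnames(signals) <- ps_ids
      rownames(signals) <- conditions
    })

    ## annotation table -------------------------------------------------------
    rows <- lapply(seq_len(spec$n_genes), function(g) {
      idx <- idx_by_gene[[g]]
      tA <- paste0("t_", genes[g], "_A"); tB <- paste0("t_", genes[g], "_B")
      shared <- plant[g] %in% c("single", "same")
      do.call(rbind, lapply(seq_along(idx), function(k) {
        if (shared) {
          tt <- c(tA, tB); tu <- character(0); ex <- c(8L, 9L, 10L); last <- 4L
        } else if (k == 1) {
          tt <- tA; tu <- tB; ex <- c(1L, 2L, 3L); last <- 0L
        } else {
          tt <- tB; tu <- tA; ex <- c(8L, 9L, 10L); last <- 4L
        }
        data.frame(probe_set = ps_ids[idx[k]], gene = genes[g],
                   source = "Ensembl", probes_exon = 11L, probes_intron = 0L,
                   probes_up = 0L, probes_down = 0L,
                   transcripts_targeted = paste(tt, collapse = ";"),
                   transcripts_untargeted = paste(tu, collapse = ";"),
                   exons_targeted = paste(ex, collapse = ";"),
                   probes_last_exon = last, stringsAsFactors = FALSE)
      }))
    })
    targets <- as_target_table(do.call(rbind, rows))

    ## ground truth -----------------------------------------------------------
    pair_rows <- lapply(which(n_ps_per_gene >= 2), function(g) {
      idx <- idx_by_gene[[g]]
      cmb <- t(combn(sort(ps_ids[idx]), 2))
      i1 <- match(cmb[, 1], ps_ids); i2 <- match(cmb[, 2], ps_ids)
      label <- ifelse(module[i1] != module[i2], "independent",
                      ifelse(sign[i1] == sign[i2], "same", "anti"))
      data.frame(probe_set_1 = cmb[, 1], probe_set_2 = cmb[, 2],
                 gene = genes[g], label = label,
                 module_a = module[i1], module_b = module[i2],
                 stringsAsFactors = FALSE)
    })
    truth_pairs <- do.call(rbind, pair_rows)

    list(dataset = list(call_matrices = call_matrices, signals = signals,
                        targets = targets, designs = designs,
                        conditions = conditions),
         truth = list(modules = setNames(module, ps_ids),
                      signs = setNames(sign, ps_ids),
                      pairs = truth_pairs, spec = spec,
                      sub_seeds = sub_seeds))
  })
}

#' Cross-tabulate planted pair labels against recovered similarity classes
#'
#' @param truth the `truth` element of [generate_dataset()]
#' @param classes a `pair_similarity` data frame over the same pairs
#' @return list with `table` (label x class contingency table),
#'   `recovery_same` (percent of planted `same` pairs in class >= 75) and
#'   `recovery_independent` (percent of planted `independent` pairs in
#'   class <= 1)
#' @export
truth_recovery_report <- function(truth, classes) {
  key_t <- pair_key(truth$pairs$probe_set_1, truth$pairs$probe_set_2)
  key_c <- pair_key(classes$probe_set_1, classes$probe_set_2)
  m <- match(key_t, key_c)
  if (anyNA(m)) stop("classified pairs do not cover the planted pairs")
  lab <- truth$pairs$label
  cls <- classes$similarity_class[m]
  rate <- function(sel, good) if (!sum(sel)) NA_real_ else
    100 * sum(cls[sel] %in% good) / sum(sel)
  list(table = table(planted = lab, class = cls),
       recovery_same = rate(lab == "same", c(75, 100)),
       recovery_independent = rate(lab == "independent", c(0, 1)))
}
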