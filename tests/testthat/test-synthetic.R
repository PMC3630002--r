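test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(n_genes = 20, n_networks = 2, seed = 33)
  g1 <- generate_dataset(spec)
  g2 <- generate_dataset(spec)
  expect_identical(g1, g2)
  g3 <- generate_dataset(synthetic_spec(n_genes = 20, n_networks = 2, seed = 34))
  expect_false(identical(g1$dataset$call_matrices[[1]],
                         g3$dataset$call_matrices[[1]]))
})

test_that("noise-free same-module pairs have identical call strings", {
  spec <- synthetic_spec(n_genes = 30, probe_sets_per_gene = 2,
                         n_networks = 1, epsilon = 0, delta = 0,
                         frac_same_module = 1, frac_anti = 0, seed = 2)
  gen <- generate_dataset(spec)
  calls <- gen$dataset$call_matrices[[1]]
  pr <- gen$truth$pairs
  expect_true(all(pr$label == "same"))
  for (r in seq_len(nrow(pr))) {
    ca <- corr_anti(paste(calls[pr$probe_set_1[r], ], collapse = ""),
                    paste(calls[pr$probe_set_2[r], ], collapse = ""))
    if (!ca$degenerate) {
      expect_equal(ca$corr, 100)
      expect_equal(ca$anti, 0)
    }
  }
})

test_that("anti pairs are exact sign mirrors in the noise-free setting", {
  spec <- synthetic_spec(n_genes = 30, probe_sets_per_gene = 2,
                         n_networks = 1, epsilon = 0, delta = 0,
                         frac_same_module = 0, frac_anti = 1, seed = 6)
  gen <- generate_dataset(spec)
  calls <- gen$dataset$call_matrices[[1]]
  pr <- gen$truth$pairs
  expect_true(all(pr$label == "anti"))
  for (r in seq_len(nrow(pr))) {
    ca <- corr_anti(paste(calls[pr$probe_set_1[r], ], collapse = ""),
                    paste(calls[pr$probe_set_2[r], ], collapse = ""))
    if (!ca$degenerate) {
      expect_equal(ca$anti, 100)
      expect_equal(ca$corr, 0)
    }
  }
})

test_that("independent pairs concord at the closed-form background rate", {
  # conditional concordance among informative positions:
  # 100 * 2 p^2 / (1 - (1 - 2p)^2) with p = 0.25 -> 16.67%
  spec <- synthetic_spec(n_genes = 200, probe_sets_per_gene = 2,
                         n_networks = 1, group_size = 20,  # 400 comparisons
                         epsilon = 0, delta = 0,
                         frac_same_module = 0, frac_anti = 0, seed = 11)
  gen <- generate_dataset(spec)
  calls <- gen$dataset$call_matrices[[1]]
  pr <- gen$truth$pairs
  expect_true(all(pr$label == "independent"))
  corr <- vapply(seq_len(nrow(pr)), function(r)
    corr_anti(paste(calls[pr$probe_set_1[r], ], collapse = ""),
              paste(calls[pr$probe_set_2[r], ], collapse = ""))$corr, 0)
  p <- spec$p_change
  expected <- 100 * 2 * p^2 / (1 - (1 - 2 * p)^2)
  expect_lt(abs(mean(corr) - expected), 3)  # within 3 percentage points
})

test_that("latent symbol frequencies track p_change within binomial bounds", {
  spec <- synthetic_spec(n_genes = 100, probe_sets_per_gene = 1,
                         n_networks = 1, epsilon = 0, delta = 0, seed = 12)
  gen <- generate_dataset(spec)
  calls <- unclass(gen$dataset$call_matrices[[1]])
  n <- length(calls)
  for (sym in c("I", "D")) {
    phat <- mean(calls == sym)
    se <- sqrt(0.25 * 0.75 / n)
    expect_lt(abs(phat - 0.25), 2 * se + 1e-12)
  }
})

test_that("the annotation plants shared structure for same-module pairs only", {
  spec <- synthetic_spec(n_genes = 60, probe_sets_per_gene = 2,
                         n_networks = 1, seed = 13)
  gen <- generate_dataset(spec)
  tt <- gen$dataset$targets
  pr <- gen$truth$pairs
  for (r in seq_len(nrow(pr))) {
    sc <- pair_localisation_scores(pr$probe_set_1[r], pr$probe_set_2[r],
                                   pr$gene[r], tt)
    if (pr$label[r] == "same") {
      expect_equal(sc$pct_transcripts_both, 100)
      expect_gt(sc$n_exons_both, 0)
    } else {
      expect_equal(sc$pct_transcripts_both, 0)
      expect_equal(sc$n_exons_both, 0)
    }
  }
})

test_that("truth recovery cross-tabulates planted labels against classes", {
  truth <- list(pairs = data.frame(probe_set_1 = c("a", "c", "e"),
                                   probe_set_2 = c("b", "d", "f"),
                                   label = c("same", "independent", "anti"),
                                   stringsAsFactors = FALSE))
  classes <- data.frame(probe_set_1 = c("a", "c", "e"),
                        probe_set_2 = c("b", "d", "f"),
                        similarity_class = c(100, 0, 0),
                        stringsAsFactors = FALSE)
  rep <- truth_recovery_report(truth, classes)
  expect_equal(rep$recovery_same, 100)
  expect_equal(rep$recovery_independent, 100)
  expect_equal(sum(rep$table), 3)
})
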