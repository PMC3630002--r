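# small deterministic network builder from an edge list
net_from_edges <- function(ids, edges) {
  n <- length(ids)
  corr <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[[1]][r], ids); j <- match(edges[[2]][r], ids)
    corr[i, j] <- corr[j, i] <- as.numeric(edges[[3]][r])
  }
  structure(list(probe_set_ids = ids,
                 corr = methods::as(corr, "CsparseMatrix"),
                 anti = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(n, n),
                                             symmetric = TRUE),
                 alpha = 0.05, n_comparisons = NA_integer_),
            class = "covariation_network")
}

test_that("merging replaces groups by mean-correlation nodes", {
  net <- net_from_edges(c("A", "B", "X", "Y"),
                        data.frame(a = c("A", "B", "A"), b = c("X", "X", "B"),
                                   w = c(40, 60, 80)))
  merged <- merge_probe_sets(net, list(c("A", "B")))
  m <- merged$network
  i <- match("merged_1", m$probe_set_ids); x <- match("X", m$probe_set_ids)
  expect_equal(m$corr[i, x], 50)            # mean of 40 and 60
  y <- match("Y", m$probe_set_ids)
  expect_equal(m$corr[i, y], 0)             # absent values count as 0 -> mean 0
  expect_equal(length(m$probe_set_ids), 3)  # g members collapse to one node
  expect_equal(m$corr[i, i], 0)             # intra-group edge dropped
  expect_equal(merged$size_reduction, 25)

  big <- net_from_edges(sprintf("n%03d", 1:100),
                        data.frame(a = "n001", b = "n002", w = 10))
  groups <- lapply(0:9, function(k) sprintf("n%03d", 2 * k + 1:2))
  expect_equal(merge_probe_sets(big, groups)$size_reduction, 10)
  expect_error(merge_probe_sets(net, list(c("A", "B"), c("B", "X"))), "overlap")
})

test_that("MCL separates disconnected cliques and scores pruning honestly", {
  ids <- c(paste0("a", 1:3), paste0("b", 1:3))
  cl <- t(combn(1:3, 2))
  edges <- data.frame(a = c(ids[cl[, 1]], ids[3 + cl[, 1]]),
                      b = c(ids[cl[, 2]], ids[3 + cl[, 2]]), w = 1)
  net <- net_from_edges(ids, edges)
  res <- mcl_cluster(net)
  expect_length(res$clusters, 2)
  expect_equal(canon_groups(res$clusters),
               canon_groups(list(paste0("a", 1:3), paste0("b", 1:3))))

  single <- net_from_edges("solo", data.frame(a = character(0),
                                              b = character(0), w = numeric(0)))
  res1 <- mcl_cluster(single)
  expect_equal(res1$clusters, list("solo"))

  expect_equal(mcl_cluster(net, prune_threshold = 0)$pruning_score, 100)
})

test_that("cluster reproducibility is the weighted geometric-mean overlap", {
  a <- list(letters[1:4], letters[5:7])
  expect_equal(cluster_reproducibility(a, a, k = 2), 100)

  # 9- and 16-member clusters sharing 6 members: 6 / sqrt(144) = 50%;
  # both clusterings cover the same 19 probe sets
  ca <- c(list(sprintf("s%02d", 1:9)), as.list(sprintf("t%02d", 1:10)))
  cb <- list(c(sprintf("s%02d", 1:6), sprintf("t%02d", 1:10)),
             "s07", "s08", "s09")
  expect_equal(cluster_reproducibility(ca, cb, k = 1), 50)

  # disjoint clusterings: restrict to the shared universe first
  d1 <- list(c("u1", "u2"), c("u3", "u4"))
  d2 <- list(c("u1", "u3"), c("u2", "u4"))
  r <- cluster_reproducibility(d1, d2, k = 2)
  expect_equal(r, 100 * 1 / sqrt(4))  # best overlap is always 1 of 2x2

  expect_warning(cluster_reproducibility(a, a, k = 10), "reduced")
  expect_error(cluster_reproducibility(list(), a), "at least one")
})

test_that("rank normalisation maps average-tie ranks onto 0-100", {
  sig <- rbind(cond1 = c(5, 1, 9, 3, 7), cond2 = c(1, 1, 2, 0, 3))
  colnames(sig) <- paste0("p", 1:5)
  r <- rank_normalize(sig)
  expect_equal(unname(r["cond1", ]), c(50, 0, 100, 25, 75))
  expect_equal(min(r["cond2", ]), 0)
  expect_equal(max(r["cond2", ]), 100)

  tied <- rbind(c1 = c(1, 1, 2))
  colnames(tied) <- paste0("p", 1:3)
  expect_equal(unname(rank_normalize(tied)[1, ]), c(25, 25, 100))
  expect_error(rank_normalize(matrix(1, 2, 1)), "at least 2")
})

test_that("rank-difference CDFs average pointwise within classes", {
  sig <- cbind(p1 = c(1, 2, 3, 4), p2 = c(1, 2, 3, 4), p3 = c(4, 3, 2, 1),
               p4 = c(2, 1, 4, 3))
  rownames(sig) <- paste0("cond", 1:4)
  ranks <- rank_normalize(sig)
  cdfs <- rank_diff_cdfs(ranks, list("100" = cbind("p1", "p2"),
                                     "0" = cbind("p1", "p3")),
                         n_random = 0)
  expect_equal(cdfs[["100"]], rep(1, 101))  # identical signals: all diffs 0
  expect_true(all(diff(cdfs[["0"]]) >= 0))
  expect_equal(cdfs[["0"]][101], 1)

  two <- rank_diff_cdfs(ranks, list(k = rbind(c("p1", "p2"), c("p1", "p3"))),
                        n_random = 0)
  expect_equal(two$k, (cdfs[["100"]] + cdfs[["0"]]) / 2)

  # the seeded random baseline is reproducible
  r1 <- rank_diff_cdfs(ranks, list(), n_random = 10, seed = 3)
  r2 <- rank_diff_cdfs(ranks, list(), n_random = 10, seed = 3)
  expect_identical(r1, r2)
})
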