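# tiny multi-network fixture: pair (a,b) strongly positive everywhere,
# (a,c) positive in some networks only, d anti-correlated with a
make_networks <- function(strings_per_net, ids) {
  lapply(strings_per_net, function(strings) {
    calls <- calls_from_strings(strings, ids = ids)
    null <- suppressMessages(build_null(calls, 100, seed = 4))
    build_network(calls, null, alpha = 1)
  })
}

test_that("counting positive networks uses stored positive edges only", {
  ids <- c("a", "b", "c")
  nets <- make_networks(list(
    c("IDIDID", "IDIDID", "IDIDID"),   # a~c positive
    c("IDIDID", "IDIDID", "DIDIDI"),   # a~c anti
    c("IDIDID", "IDIDID", "IDIDII"),
    c("IDIDID", "IDIDID", "DIDIDI"),
    c("IDIDID", "IDIDID", "IDIDDD")), ids)
  expect_equal(count_positive_networks(c("a", "b"), nets), 5)
  expect_equal(count_positive_networks(c("a", "c"), nets), 3)
  expect_error(count_positive_networks(c("a", "zz"), nets), "unknown")
})

test_that("limits are pooled nearest-rank percentiles of calibration values", {
  expect_equal(nearest_rank_percentile(1:100, 5), 5)
  expect_equal(nearest_rank_percentile(1:100, 95), 95)
  expect_equal(nearest_rank_percentile(rep(62, 9), 5), 62)

  ids <- c("a", "b", "c", "d")
  nets <- make_networks(list(
    c("IDIDIDID", "IDIDIDID", "IDIDIDIN", "NDIDIDID"),
    c("IDIDIDID", "IDIDIDIN", "IDIDIDID", "IDIDIDID")), ids)
  calib <- data.frame(probe_set_1 = c("a", "c"), probe_set_2 = c("b", "d"))
  lim <- calibrate_limits(nets, calib)
  expect_equal(lim$n_networks, 2)
  expect_equal(lim$n_calibration_pairs, 2)
  # pooled corr values: a-b = {100, 87.5}, c-d = {75, 100}
  pooled <- c(100, 75, 100 * 7 / 8, 100)
  expect_equal(lim$corr_5th, nearest_rank_percentile(pooled, 5))
  expect_equal(lim$anti_95th, 0)
  expect_error(calibrate_limits(nets, calib[0, ]), "calibration")

  # limits are invariant under permutation of network order
  expect_equal(calibrate_limits(rev(nets), calib)[1:3], lim[1:3])
})

test_that("the three-condition test enforces all limits at their boundaries", {
  lim <- structure(list(corr_5th = 60, anti_95th = 10, overlap_95th = -10),
                   class = "similarity_limits")
  expect_true(test_pair_in_network(70, 5, -12, lim))
  expect_false(test_pair_in_network(59, 5, -12, lim))   # corr boundary
  expect_false(test_pair_in_network(70, 11, -12, lim))  # anti boundary
  expect_false(test_pair_in_network(70, 5, -9, lim))    # overlap boundary
  expect_true(test_pair_in_network(60, 10, -10, lim))   # equality passes all
  # absent values (0, 0, 0) can never pass a corr limit above 0
  expect_false(test_pair_in_network(0, 0, 0, lim))
})

test_that("similarity classes follow the largest-threshold rule", {
  expect_equal(similarity_class(21, 21), 100)
  expect_equal(similarity_class(0, 21), 0)
  expect_equal(similarity_class(6, 21), 25)    # 28.6%
  expect_equal(similarity_class(16, 21), 75)   # 76.2%
  expect_equal(similarity_class(1, 21), 1)
  expect_equal(similarity_class(1, 1), 100)
  # monotone non-decreasing in n_similar
  for (n in c(1, 4, 5, 21)) {
    cls <- vapply(0:n, similarity_class, 0, n_networks = n)
    expect_true(all(diff(cls) >= 0))
  }
})

test_that("pair reproducibility uses the 0-1 and 75-100 equivalence sets", {
  a <- c(p1 = 0, p2 = 0, q = 100)
  expect_equal(pair_reproducibility(a, a), list(rep0 = 100, rep100 = 100))
  b <- c(p1 = 0, p2 = 25, q = 75)
  r <- pair_reproducibility(a, b)
  expect_equal(r$rep0, 50)
  expect_equal(r$rep100, 100)      # 100 -> 75 counts as equivalent
  expect_true(is.na(pair_reproducibility(c(x = 50), c(x = 50))$rep0))
})

test_that("gene reproducibility requires all pairs equivalent in the test chip", {
  mk <- function(genes, cls) data.frame(
    probe_set_1 = sprintf("a%d", seq_along(genes)),
    probe_set_2 = sprintf("b%d", seq_along(genes)),
    gene = genes, similarity_class = cls, stringsAsFactors = FALSE)
  a <- mk(c("g1", "g2", "g3"), c(0, 0, 100))
  b_ok <- mk(c("g1", "g2", "g3"), c(1, 0, 75))
  expect_equal(gene_reproducibility(a, b_ok), list(rep0 = 100, rep100 = 100))
  b_half <- mk(c("g1", "g2", "g3"), c(25, 0, 50))
  r <- gene_reproducibility(a, b_half)
  expect_equal(r$rep0, 50)    # g1 fails (25 not in {0,1}), g2 passes
  expect_equal(r$rep100, 0)   # g3's pair fell to 50
  # a gene with mixed classes in chip a is no candidate
  a_mixed <- rbind(a, mk("g1", 100)[1, ])
  expect_equal(gene_reproducibility(a_mixed, b_ok)$rep0, 100)  # only g2 left
})
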