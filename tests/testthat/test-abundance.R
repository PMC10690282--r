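test_that("abundance score is a pixel-weighted grand mean over frames", {
  expect_equal(abundance_score(matrix(4.2, 64, 64)), 4.2)
  f2 <- list(matrix(2, 8, 8), matrix(4, 8, 8))
  expect_equal(abundance_score(f2), 3)
  # unequal frame sizes: grand mean, not mean of frame means
  f3 <- list(matrix(2, 2, 2), matrix(8, 2, 4))
  expect_equal(abundance_score(f3), (2 * 4 + 8 * 8) / 12)
  expect_error(abundance_score(list()), "at least one")
})

test_that("log2 fold change uses a pseudocount and is antisymmetric", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(3, 7), 1)
  expect_equal(log2_fold_change(7, 3), -1)
  expect_equal(log2_fold_change(2, 9), -log2_fold_change(9, 2))
  expect_error(log2_fold_change(-1, 2), "nonnegative")
})

test_that("rank-sum test matches closed forms and behaves at scale", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p, 1 / 3)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(8)
  big <- rank_sum_test(rnorm(200), rnorm(200, 5))
  expect_lt(big$p, 1e-6)
  expect_false(big$exact)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("rank-sum p equals exhaustive enumeration for small tie-free samples", {
  set.seed(21)
  for (m in 1:4) for (n in m:4) {
    if (m + n > 8) next
    for (rep in 1:3) {
      x <- sample(seq_len(50), m)
      y <- sample(setdiff(seq_len(50), x), n)
      expect_equal(rank_sum_test(x, y)$p, enum_rank_sum_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("m=%d n=%d rep=%d", m, n, rep))
    }
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stepup_bh(p), tolerance = 1e-12)
  }
  # monotone in the order statistics: ordering of q respects ordering of p
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("abundance classification applies the effect and significance gates", {
  expect_equal(classify_abundance(0.25, 0.01), "increased")
  expect_equal(classify_abundance(0.25, 0.10), "none")
  expect_equal(classify_abundance(-0.30, 0.001), "decreased")
  expect_equal(classify_abundance(0.2, 0.049), "increased")   # inclusive lfc
  expect_equal(classify_abundance(0.2, 0.05), "none")         # strict q
  expect_equal(classify_abundance(c(0.3, -0.3, 0), c(0.01, 0.01, 0.01)),
               c("increased", "decreased", "none"))
})

test_that("compensation and dependency calls follow the response logic", {
  expect_equal(call_comp_dep("increased")$call, "compensation")
  expect_equal(call_comp_dep("none", relocalized_to = "vacuole",
                             own_wt_compartment = "Golgi",
                             paralog_wt_compartment = "vacuole")$call,
               "compensation")
  expect_equal(call_comp_dep("none", relocalized_to = "mitochondria",
                             own_wt_compartment = "Golgi",
                             paralog_wt_compartment = "vacuole")$call,
               "dependency")
  expect_equal(call_comp_dep("decreased")$call, "dependency")
  expect_equal(call_comp_dep("none")$call, "none")
  expect_warning(
    out <- call_comp_dep("decreased", relocalized_to = "vacuole",
                         own_wt_compartment = "Golgi",
                         paralog_wt_compartment = "vacuole"),
    "conflict")
  expect_true(out$compensation && out$dependency)
})

test_that("swapping condition labels negates lfc and preserves p", {
  set.seed(4)
  x <- rlnorm(80, 3); y <- rlnorm(80, 3.4)
  a <- abundance_compare(x, y)
  b <- abundance_compare(y, x)
  expect_equal(a$lfc, -b$lfc)
  expect_equal(a$p, b$p)
})
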