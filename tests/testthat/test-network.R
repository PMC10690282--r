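gi_edges <- function(...) {
  e <- data.frame(...)
  e$type <- "gi"
  e
}

test_that("genetic-interaction stringency classes apply the published thresholds", {
  e <- gi_edges(geneA = c("a", "b", "c"), geneB = c("x", "y", "z"),
                epsilon = c(-0.20, -0.40, -0.20), p = c(0.01, 0.01, 0.20))
  nw <- interaction_network(e)
  pass <- function(class) filter_gi(nw, class)$geneA
  expect_equal(pass("lenient"), c("a", "b"))
  expect_equal(pass("intermediate"), c("a", "b"))
  expect_equal(pass("stringent"), c("a", "b"))
  expect_equal(pass("stringent_neg"), c("a", "b"))
  expect_equal(pass("synthetic_lethal"), "b")
  # positive strong interaction passes stringent but not the negative classes
  e2 <- gi_edges(geneA = "d", geneB = "w", epsilon = 0.20, p = 0.01)
  expect_equal(nrow(filter_gi(interaction_network(e2), "stringent")), 1L)
  expect_equal(nrow(filter_gi(interaction_network(e2), "stringent_neg")), 0L)
  # missing scores are skipped with a warning
  e3 <- gi_edges(geneA = c("a", "b"), geneB = c("x", "y"),
                 epsilon = c(NA, -0.5), p = c(0.01, 0.01))
  expect_warning(out <- filter_gi(interaction_network(e3), "lenient"),
                 "skipped")
  expect_equal(out$geneA, "b")
})

test_that("network cleaning drops self-loops and collapses duplicates", {
  e <- data.frame(geneA = c("a", "b", "a", "c"),
                  geneB = c("b", "a", "a", "d"),
                  type = "gi", epsilon = c(-0.1, -0.3, -0.2, -0.1),
                  p = c(0.04, 0.01, 0.01, 0.2))
  nw <- interaction_network(e)
  expect_equal(nrow(nw$edges), 2L)  # a-b collapsed, a-a removed
  ab <- nw$edges[nw$edges$geneA == "a" & nw$edges$geneB == "b", ]
  expect_equal(ab$epsilon, -0.3)    # strongest evidence kept
})

test_that("shared-interactor counts bin against the cohort median", {
  # neighborhoods: pair (A,B) shares {y, z}; cohort engineered to give
  # shared counts 0, 1, 2, 3 -> median 1.5, so count 2 is "high"
  mk <- function(g, nb) data.frame(geneA = g, geneB = nb, type = "ppi")
  e <- rbind(mk("A", c("x", "y", "z")), mk("B", c("y", "z", "w")),
             mk("C", "u1"), mk("D", "u2"),                 # share 0
             mk("E", c("s1", "e1")), mk("F", c("s1", "f1")),  # share 1
             mk("G", paste0("t", 1:3)), mk("H", paste0("t", 1:3)))  # 3
  nw <- interaction_network(e, ppi_experiment_type = NULL,
                            ppi_throughput = NULL)
  cohort <- data.frame(gene = c("A", "C", "E", "G"),
                       paralog = c("B", "D", "F", "H"))
  res <- shared_interactor_bin(nw, "A", "B", cohort)
  expect_equal(res$count, 2L)
  expect_equal(sort(res$counts), c(0, 1, 2, 3))
  expect_equal(res$bin, "high")
  res0 <- shared_interactor_bin(nw, "C", "D", cohort)
  expect_equal(res0$count, 0L)
  expect_equal(res0$bin, "low")
  # ties at the median go to "low"
  res1 <- shared_interactor_bin(nw, "E", "F",
                                data.frame(gene = c("A", "E"),
                                           paralog = c("B", "F")))
  expect_equal(res1$median, 1.5)
  res2 <- shared_interactor_bin(nw, "E", "F",
                                data.frame(gene = "E", paralog = "F"))
  expect_equal(res2$bin, "low")  # count 1 equals cohort median 1
  # absent gene is flagged
  resx <- shared_interactor_bin(nw, "Q", "B", cohort)
  expect_true(is.na(resx$bin))
})

test_that("path-length bins distinguish direct edges from everything else", {
  e <- data.frame(geneA = c("a", "x", "p"), geneB = c("x", "b", "q"),
                  type = "ppi")
  nw <- interaction_network(e, ppi_experiment_type = NULL,
                            ppi_throughput = NULL)
  direct <- path_length_bin(nw, "a", "x")
  expect_equal(direct$length, 1)
  expect_equal(direct$bin, "1")
  two <- path_length_bin(nw, "a", "b")
  expect_equal(two$length, 2)
  expect_equal(two$bin, "1+")
  disc <- path_length_bin(nw, "a", "p")
  expect_equal(disc$bin, "1+")
  expect_true(is.infinite(disc$length))
})

test_that("shortest paths obey the triangle inequality on sampled triples", {
  set.seed(14)
  genes <- paste0("g", 1:15)
  e <- data.frame(geneA = sample(genes, 40, replace = TRUE),
                  geneB = sample(genes, 40, replace = TRUE), type = "ppi")
  e <- e[e$geneA != e$geneB, ]
  nw <- interaction_network(e, ppi_experiment_type = NULL,
                            ppi_throughput = NULL)
  g <- nw$graphs$ppi
  vs <- igraph::V(g)$name
  for (i in 1:30) {
    t3 <- sample(vs, 3)
    d <- igraph::distances(g, v = t3, to = t3)
    expect_lte(d[1, 2], d[1, 3] + d[3, 2])
  }
})

test_that("colocalization Jaccard uses the inclusive 50 percent rule", {
  expect_equal(coloc_jaccard(c("ER", "cyto"), c("ER", "cyto")),
               list(jaccard = 100, colocalized = TRUE))
  res <- coloc_jaccard(c("ER", "cytoplasm"), "ER")
  expect_equal(res$jaccard, 50)
  expect_true(res$colocalized)
  res2 <- coloc_jaccard("nucleus", "vacuole")
  expect_equal(res2$jaccard, 0)
  expect_false(res2$colocalized)
  # symmetry, range, and 100 iff equal sets
  a <- c("ER", "Golgi", "vacuole"); b <- c("Golgi", "nucleus")
  expect_equal(coloc_jaccard(a, b)$jaccard, coloc_jaccard(b, a)$jaccard)
  expect_lt(coloc_jaccard(a, b)$jaccard, 100)
  expect_error(coloc_jaccard(character(), "ER"), "non-empty")
})

test_that("private-interactor enrichment reports cross-product OR and exact p", {
  flags <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 3), rep(FALSE, 9))
  redis <- rep(c(TRUE, FALSE), c(12, 12))
  res <- private_interactor_enrichment(redis, flags)
  expect_equal(unname(res$odds_ratio), 15)
  expect_false(res$haldane)
  expect_equal(res$p, enum_fisher_p(res$table), tolerance = 1e-9)

  bal <- private_interactor_enrichment(rep(c(TRUE, FALSE), each = 10),
                                       rep(c(TRUE, FALSE), 10))
  expect_equal(unname(bal$odds_ratio), 1)
  expect_equal(bal$p, 1)

  zero <- private_interactor_enrichment(rep(c(TRUE, FALSE), c(4, 4)),
                                        c(TRUE, TRUE, TRUE, TRUE,
                                          FALSE, FALSE, FALSE, TRUE))
  expect_true(zero$haldane)
  expect_true(is.finite(zero$odds_ratio))

  degen <- private_interactor_enrichment(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(is.na(degen$odds_ratio))
  expect_equal(degen$p, 1)
})

test_that("Fisher p is invariant to simultaneous row and column swaps", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(8:24, 1)
    redis <- sample(c(TRUE, FALSE), n, replace = TRUE)
    flags <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(redis)) < 2 || length(unique(flags)) < 2) next
    p1 <- private_interactor_enrichment(redis, flags)$p
    p2 <- private_interactor_enrichment(!redis, !flags)$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("score-bin comparison reports rank-sum p and boxplot statistics", {
  idn <- compare_score_bins(c(1:5, 1:5), rep(c("lo", "hi"), each = 5))
  expect_equal(idn$p, 1)
  sh <- compare_score_bins(c(rnorm(30), rnorm(30, 10)),
                           rep(c("lo", "hi"), each = 30))
  expect_lt(sh$p, 1e-6)
  bp <- compare_score_bins(c(1:9, 1:9), rep(c("a", "b"), each = 9))
  expect_equal(bp$summary$median, c(5, 5))
  expect_equal(bp$summary$q1, c(3, 3))
  expect_equal(bp$summary$q3, c(7, 7))
  expect_equal(bp$summary$whisker_low, c(-3, -3))
  expect_equal(bp$summary$whisker_high, c(13, 13))
  expect_error(compare_score_bins(1:4, rep("a", 4)), "two")
})

test_that("ppi cleaning keeps physical high-throughput evidence", {
  e <- data.frame(geneA = c("a", "a", "a"), geneB = c("b", "c", "d"),
                  type = "ppi",
                  experiment_type = c("physical", "genetic", "physical"),
                  throughput = c("high", "high", "low"))
  nw <- interaction_network(e)
  expect_equal(nw$edges$geneB, "b")
})
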