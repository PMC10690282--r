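test_that("per-stencil cross erosion separates labels and respects borders", {
  lab <- matrix(0L, 5, 5); lab[2:4, 2:4] <- 1L
  er <- erode_stencils(lab)
  expect_equal(which(er), 13L)  # only the 3x3 center survives

  lab1 <- matrix(0L, 3, 3); lab1[2, 2] <- 1L
  expect_false(any(erode_stencils(lab1)))

  # two 2-px-wide stencils touching along a 6x4 grid: every pixel of each
  # stencil has a neighbor outside its own label, so both erode away,
  # leaving a background gap between the (empty) remnants
  lab2 <- matrix(0L, 6, 4)
  lab2[, 1:2] <- 1L; lab2[, 3:4] <- 2L
  expect_false(any(erode_stencils(lab2)))

  # 3-px-wide touching stencils keep disjoint 1-px-wide cores
  lab3 <- matrix(0L, 6, 6)
  lab3[, 1:3] <- 1L; lab3[, 4:6] <- 2L
  er3 <- erode_stencils(lab3)
  expect_identical(which(er3, arr.ind = TRUE)[, "col"],
                   rep(c(2L, 5L), each = 4L), ignore_attr = TRUE)
})

test_that("target transform combines eroded binary and clipped distance", {
  expect_equal(make_target_map(matrix(0L, 32, 32))$values,
               matrix(0, 32, 32))

  lab <- matrix(0L, 100, 100); lab[31:74, 31:74] <- 1L  # 44x44 stencil
  tm <- make_target_map(lab)
  er <- erode_stencils(lab)  # 42x42
  border <- er & !erode_stencils(matrix(as.integer(er), 100, 100))
  expect_equal(unique(round(tm$values[border], 10)), 0.81)
  # interior pixel at Euclidean distance 10 from background: center column,
  # 10 rows inside the eroded stencil
  expect_equal(tm$values[32 + 9, 52], 0.9)
  # deepest interior reaches the clip distance, so the maximum is exactly 1
  expect_equal(max(tm$values), 1)
  # background exactly 0; eroded foreground within [0.81, 1]
  expect_true(all(tm$values[!er] >= 0 & tm$values[!er] < 0.81))
  expect_true(all(tm$values[lab == 0L] == 0))
  expect_true(all(tm$values[er] >= 0.81 & tm$values[er] <= 1))
})

test_that("watershed splits seed-separated bumps and obeys its invariants", {
  expect_length(watershed_postprocess(matrix(0, 50, 50))$areas, 0L)

  # two Gaussian bumps, peaks 1.0, 40 px apart, sigma 20: the 0.5 supports
  # merge into one blob while the 0.8 supports stay disjoint
  r <- matrix(rep(1:60, 100), 60, 100)
  c <- matrix(rep(1:100, each = 60), 60, 100)
  bump <- function(cy, cx) exp(-((r - cy)^2 + (c - cx)^2) / (2 * 20^2))
  prob <- pmax(bump(30, 30), bump(30, 70))
  merged <- sum(tabulate(paraloc:::.cc_label4(prob >= 0.5)) > 0)
  expect_equal(merged, 1L)
  seg <- watershed_postprocess(prob, min_area = 50, max_area = 8192)
  expect_length(seg$areas, 2L)

  # invariants on irregular maps
  set.seed(42)
  for (trial in 1:5) {
    k <- sample(2:6, 1)
    p <- matrix(0, 80, 80)
    rr <- matrix(rep(1:80, 80), 80, 80)
    cc <- matrix(rep(1:80, each = 80), 80, 80)
    for (i in seq_len(k)) {
      cy <- runif(1, 10, 70); cx <- runif(1, 10, 70)
      s <- runif(1, 4, 12)
      p <- pmax(p, runif(1, 0.6, 1) *
                  exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2)))
    }
    seeds <- paraloc:::.cc_label4(p >= 0.8)
    seg <- watershed_postprocess(p, min_area = 1, max_area = 1e5)
    n_obj <- length(seg$areas)
    expect_lte(n_obj, max(seeds))
    if (n_obj > 0) {
      for (o in seq_len(n_obj)) {
        px <- seg$labels == o
        expect_true(any(seeds[px] > 0))       # contains a seed pixel
        expect_true(all(p[px] >= 0.5))        # within boundary support
      }
    }
  }
})

test_that("area filter keeps exactly the bounds-inclusive objects", {
  lab <- matrix(0L, 200, 3000)
  lab[1:15, 1:17] <- 1L                    # 255 px: removed
  lab[30:45, 30:45] <- 2L                  # 256 px: kept
  lab[60:123, 100:227] <- 3L               # 8192 px: kept
  lab[130:132, 250:2980] <- 4L             # 8193 px: removed
  flt <- filter_labels_by_area(lab, min_area = 256, max_area = 8192)
  expect_equal(unname(flt$areas), c(256, 8192))
  expect_identical(sort(unique(as.integer(flt$labels))), 0:2)
})

test_that("oracle probability maps reproduce the target transform", {
  s <- generate_scene(5, "nucleus", seed = 2, shape = c(200, 200),
                      cell_area = c(400, 900))
  pm <- reference_probability_map(s, "oracle")
  expect_equal(pm$values, make_target_map(s$labels)$values)

  # intensity mode on a noise-free two-cell scene finds both objects
  s2 <- generate_scene(2, "cytoplasm", seed = 4, shape = c(160, 160),
                       cell_area = c(500, 900), intensity_cv = 0,
                       noise = list(bg_mean = 0, bg_sd = 0, shot = 0))
  pm2 <- reference_probability_map(s2$image, "intensity")
  expect_length(watershed_postprocess(pm2)$areas, 2L)

  pm3 <- reference_probability_map(matrix(0, 80, 80), "intensity")
  expect_equal(max(pm3$values), 0)
  expect_length(watershed_postprocess(pm3)$areas, 0L)
})
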