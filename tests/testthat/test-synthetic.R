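noise_off <- list(bg_mean = 0, bg_sd = 0, shot = 0)

test_that("empty and deterministic scenes honor the generation contract", {
  s0 <- generate_scene(0, seed = 1, shape = c(64, 64), noise = noise_off)
  expect_equal(s0$image, matrix(0, 64, 64))
  expect_equal(max(s0$labels), 0L)
  expect_equal(nrow(s0$cells), 0L)

  s1 <- generate_scene(8, "nucleus", seed = 7, shape = c(200, 200))
  s2 <- generate_scene(8, "nucleus", seed = 7, shape = c(200, 200))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$cells, s2$cells)
})

test_that("programmed abundance doubles foreground intensity exactly", {
  wt <- generate_scene(6, "cytoplasm", effect = effect_spec("G", "wild-type"),
                       seed = 3, shape = c(200, 200), noise = noise_off)
  del <- generate_scene(6, "cytoplasm",
                        effect = effect_spec("G", "deletion",
                                             abundance_lfc = 1),
                        seed = 3, shape = c(200, 200), noise = noise_off)
  expect_identical(wt$labels, del$labels)
  for (k in seq_len(6)) {
    mwt <- mean(wt$image[wt$labels == k])
    mdel <- mean(del$image[del$labels == k])
    expect_equal(mdel / mwt, 2, tolerance = 1e-9)
  }
})

test_that("noise-free intensity is conserved per cell and centroids fall inside", {
  s <- generate_scene(10, "ER", seed = 11, shape = c(256, 256),
                      noise = noise_off)
  for (k in seq_len(10)) {
    tot <- sum(s$image[s$labels == k])
    expect_equal(tot, s$cells$intensity[k] * s$cells$area[k],
                 tolerance = 1e-6)
    r <- as.integer(round(s$cells$row[k]))
    c <- as.integer(round(s$cells$col[k]))
    expect_equal(s$labels[r, c], k)
  }
  expect_identical(sort(unique(as.integer(s$labels))), 0:10)
})

test_that("programmed relocalized fraction lands in the target render region", {
  f <- 0.6
  mixed <- generate_scene(8, "cytoplasm",
                          effect = effect_spec("G", "deletion",
                                               reloc_fraction = f,
                                               reloc_target = "ER"),
                          seed = 5, shape = c(256, 256), noise = noise_off,
                          intensity_cv = 0)
  full <- generate_scene(8, "cytoplasm",
                         effect = effect_spec("G", "deletion",
                                              reloc_fraction = 1,
                                              reloc_target = "ER"),
                         seed = 5, shape = c(256, 256), noise = noise_off,
                         intensity_cv = 0)
  expect_identical(mixed$labels, full$labels)
  for (k in seq_len(8)) {
    in_cell <- mixed$labels == k
    er_region <- in_cell & full$image > 0
    frac <- sum(mixed$image[er_region]) / sum(mixed$image[in_cell])
    expect_equal(frac, f, tolerance = 0.02)
  }
})

test_that("impossible packings raise an explicit error", {
  expect_error(
    generate_scene(60, seed = 1, shape = c(64, 64),
                   cell_area = c(400, 600), max_tries = 20L),
    "impossible packing")
})

test_that("panels enumerate strains x replicates x fields with reproducible metadata", {
  p <- paralog_pair("G1", "G2", lfc1 = 0.5)
  panel <- generate_strain_panel(list(p), replicates = 3,
                                 fields_per_replicate = 4,
                                 n_cells = c(5L, 8L), seed = 9,
                                 shape = c(128L, 128L),
                                 cell_area = c(400, 700))
  expect_length(panel$scenes, 48L)
  expect_equal(nrow(panel$metadata), 48L)
  expect_equal(length(unique(panel$metadata$strain)), 4L)
  expect_equal(unname(table(panel$metadata$strain)), rep(12L, 4L),
               ignore_attr = TRUE)
  panel2 <- generate_strain_panel(list(p), replicates = 3,
                                  fields_per_replicate = 4,
                                  n_cells = c(5L, 8L), seed = 9,
                                  shape = c(128L, 128L),
                                  cell_area = c(400, 700))
  expect_identical(panel$metadata, panel2$metadata)

  bad <- list(paralog_pair("A", "B"), paralog_pair("A", "B"))
  expect_error(generate_strain_panel(bad, seed = 1), "duplicate strain")
})

test_that("wild-type effects must be null", {
  expect_error(effect_spec("G", "wild-type", abundance_lfc = 1),
               "wild-type")
  expect_error(effect_spec("G", "deletion", reloc_fraction = 0.5),
               "reloc_target")
  expect_error(effect_spec("G", "deletion", reloc_fraction = 1.2,
                           reloc_target = "ER"), "0, 1")
})
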