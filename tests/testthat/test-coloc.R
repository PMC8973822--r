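make_roi <- function(n = 9) {
  mask <- matrix(0L, n, n)
  mask[2:(n - 1), 2:(n - 1)] <- 1L
  mask
}

test_that("per-ROI Pearson hits the algebraic limits", {
  mask <- make_roi()
  set.seed(1)
  a <- matrix(runif(81, 0, 100), 9, 9)
  expect_equal(pearson_roi(a, a, mask, 1), 1)
  expect_equal(pearson_roi(a, -a + 300, mask, 1), -1)
})

test_that("per-ROI Pearson matches the definitional two-pass oracle", {
  mask <- matrix(0L, 5, 5); mask[2:4, 2:4] <- 3L
  a <- matrix(c(12, 5, 8, 1, 7,
                3, 40, 22, 15, 2,
                9, 31, 27, 18, 4,
                6, 25, 20, 11, 8,
                2, 7, 5, 3, 1), 5, 5, byrow = TRUE)
  b <- matrix(c(1, 2, 3, 4, 5,
                8, 35, 19, 12, 6,
                7, 28, 30, 17, 3,
                5, 22, 24, 14, 9,
                4, 6, 2, 8, 7), 5, 5, byrow = TRUE)
  r_pkg <- pearson_roi(a, b, mask, 3)
  r_orc <- pearson_oracle(a[mask == 3], b[mask == 3])
  expect_equal(r_pkg, r_orc, tolerance = 1e-12)
})

test_that("r is invariant under positive affine rescaling of either channel", {
  mask <- make_roi()
  set.seed(2)
  a <- matrix(rnorm(81, 50, 10), 9, 9)
  b <- matrix(rnorm(81, 50, 10), 9, 9)
  r0 <- pearson_roi(a, b, mask, 1)
  expect_equal(pearson_roi(3.7 * a + 12, b, mask, 1), r0, tolerance = 1e-11)
  expect_equal(pearson_roi(a, 0.01 * b + 999, mask, 1), r0, tolerance = 1e-11)
})

test_that("r depends only on pixels inside the labelled region", {
  mask <- make_roi()
  set.seed(3)
  a <- matrix(rnorm(81), 9, 9); b <- matrix(rnorm(81), 9, 9)
  r0 <- pearson_roi(a, b, mask, 1)
  a2 <- a; a2[mask == 0] <- 1e6
  b2 <- b; b2[mask == 0] <- -1e6
  expect_identical(pearson_roi(a2, b2, mask, 1), r0)
})

test_that("constant channels inside the ROI raise a typed error", {
  mask <- make_roi()
  a <- matrix(5, 9, 9); b <- matrix(rnorm(81), 9, 9)
  expect_error(pearson_roi(a, b, mask, 1), class = "cellcoloc_constant_roi")
  expect_error(pearson_roi(b, a, mask, 1), class = "cellcoloc_constant_roi")
  expect_error(pearson_roi(b, b, mask, 99), "not present")
})

test_that("batch measurement agrees with the single-ROI path and sorts records", {
  specs <- list(scene_spec(genotype_label = "WT", alpha = 0.8, n_cells = 1,
                           image_height = 160, image_width = 160,
                           cell_radius_range = c(34, 42)),
                scene_spec(genotype_label = "mutA", alpha = 0.1, n_cells = 1,
                           image_height = 160, image_width = 160,
                           cell_radius_range = c(34, 42)))
  ds <- generate_dataset(specs, images_per_genotype = 2, base_seed = 11)
  recs <- measure_dataset(ds)
  expect_s3_class(recs, "coloc_records")
  expect_true(all(recs$pearson_r >= -1 & recs$pearson_r <= 1))
  expect_true(all(recs$n_pixels >= 800))
  expect_false(is.unsorted(order(recs$genotype_label, recs$image_id, recs$cell_label)))
  # batch values equal recomputing each ROI directly
  for (i in seq_len(nrow(recs))) {
    sc <- ds$scenes[[recs$image_id[i]]]
    mk <- extract_rois(sc$channels$protein)
    expect_equal(recs$pearson_r[i],
                 pearson_roi(sc$channels$protein, sc$channels$comarker,
                             mk, recs$cell_label[i]), tolerance = 1e-12)
  }
})

test_that("empty masks give zero records with a warning", {
  sc <- generate_scene(test_spec(seed = 2))
  empty <- extract_rois(sc$channels$protein,
                        segmentation_params(min_area = 1e5, max_area = 2e5))
  expect_warning(recs <- measure_dataset(list(img = sc), list(img = empty)),
                 "no cells")
  expect_equal(nrow(recs), 0)
})

test_that("cells with a constant channel are dropped and logged", {
  mask_mat <- matrix(0L, 30, 30)
  mask_mat[5:14, 5:14] <- 1L
  mask_mat[18:27, 18:27] <- 2L
  params <- segmentation_params(min_area = 50)
  mk <- cellcoloc:::build_label_mask(mask_mat, params, provenance = "auto")
  set.seed(4)
  protein <- matrix(rnorm(900, 50, 5), 30, 30)
  marker <- matrix(rnorm(900, 50, 5), 30, 30)
  marker[mask_mat == 2L] <- 7  # constant inside cell 2
  sc <- list(channels = list(protein = protein, comarker = marker),
             genotype_label = "g", comarker = "PM")
  expect_message(recs <- measure_dataset(list(im = sc), list(im = mk)),
                 "dropped 1")
  expect_equal(nrow(recs), 1)
  expect_equal(nrow(attr(recs, "dropped")), 1)
})

test_that("a stack without the co-marker channel errors", {
  sc <- generate_scene(test_spec(seed = 2))
  sc$channels$comarker <- NULL
  mk <- extract_rois(sc$channels$protein)
  expect_error(measure_dataset(list(a = sc), list(a = mk)), "comarker")
})

test_that("randomization p-value is bounded by add-one smoothing", {
  sc <- generate_scene(test_spec(seed = 6, noise = noise_off))
  mk <- sc$truth$mask
  res <- randomization_pvalue(sc$channels$protein, sc$channels$comarker,
                              mk, 1, n_shuffles = 99, block = 8, seed = 2)
  expect_equal(res$observed_r, pearson_roi(sc$channels$protein,
                                           sc$channels$comarker, mk, 1))
  expect_gte(res$p_value, 1 / 100)
  expect_lt(res$p_value, 0.05)  # structured signal: shuffles cannot reach r
  expect_error(randomization_pvalue(sc$channels$protein, sc$channels$comarker,
                                    mk, 1, n_shuffles = 0), "n_shuffles")
  expect_error(randomization_pvalue(sc$channels$protein, sc$channels$comarker,
                                    mk, 1, n_shuffles = 9, block = 500),
               "bounding box")
})

test_that("randomization p-values are calibrated under independent noise", {
  mask <- matrix(0L, 32, 32); mask[1:32, 1:32] <- 1L
  set.seed(8)
  hits <- 0L; n_null <- 150L
  for (i in seq_len(n_null)) {
    a <- matrix(rnorm(1024), 32, 32)
    b <- matrix(rnorm(1024), 32, 32)
    p <- randomization_pvalue(a, b, mask, 1, n_shuffles = 99, block = 8,
                              seed = 1000 + i)$p_value
    if (p <= 0.05) hits <- hits + 1L
  }
  ci <- qbinom(c(0.025, 0.975), n_null, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
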