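test_that("shade correction: identity on flat fields, idempotent, removes vignetting", {
  flat <- fluor_image(matrix(500, 64, 64) + matrix(rnorm(64 * 64, 0, 2), 64, 64))
  out <- shade_correct(flat)
  expect_equal(out$pixels, flat$pixels, tolerance = 0.02)
  expect_equal(mean(out$pixels), mean(flat$pixels), tolerance = 0.01 * mean(flat$pixels))

  # constant image returns unchanged (degenerate fit)
  const <- fluor_image(matrix(300, 32, 32))
  expect_message(out_const <- shade_correct(const), "constant")
  expect_identical(out_const$pixels, const$pixels)

  # vignetted generator image: residual radial trend < 0.1 * amplitude
  v <- 80
  strains <- strain_spec("m", "G", true_inclusion_prob = 0.3)
  cfg <- imaging_config(image_shape = c(128L, 128L), vignette_amplitude = v,
                        noise_sd = 0, cells_per_image = c(20L, 30L))
  plate <- generate_plate_images(strains, cfg, replicates = 1, seed = 6)
  img <- plate$images[[1]]
  corr <- shade_correct(img)
  bg_mask <- img$pixels < 200 + v + 100  # background-only pixels
  d2 <- outer((seq_len(128) - 64.5)^2, (seq_len(128) - 64.5)^2, "+")
  ring <- cut(sqrt(d2[bg_mask]), 8)
  trend <- tapply(corr$pixels[bg_mask], ring, mean)
  expect_lt(max(trend) - min(trend), 0.1 * v)
  expect_equal(mean(corr$pixels), mean(img$pixels),
               tolerance = 0.01 * mean(img$pixels))

  # idempotence within tolerance
  twice <- shade_correct(corr)
  expect_equal(twice$pixels, corr$pixels, tolerance = 1)
})

test_that("background estimation matches ground truth and is translation-equivariant", {
  params <- segmentation_params()
  const <- fluor_image(matrix(200, 96, 96))
  expect_identical(estimate_background(const, params)$level, 200)

  strains <- strain_spec("m", "G", true_inclusion_prob = 0)
  cfg <- imaging_config(image_shape = c(128L, 128L), background_level = 200,
                        vignette_amplitude = 0, noise_sd = 0,
                        diffuse_signal_delta = 600,
                        cells_per_image = c(20L, 30L))
  plate <- generate_plate_images(strains, cfg, replicates = 1, seed = 8)
  img <- plate$images[[1]]
  expect_lt(mean(img$pixels > 200 + 300), 0.3)  # cells cover < 30%
  for (method in c("median", "rolling_ball")) {
    p <- segmentation_params(background_method = method)
    est <- estimate_background(img, p)
    expect_lt(abs(est$level - 200), 5)
    shifted <- img; shifted$pixels <- img$pixels + 37
    est2 <- estimate_background(shifted, p)
    expect_equal(est2$level, est$level + 37, tolerance = 1e-9)
    expect_equal(est2$map, est$map + 37, tolerance = 1e-9)
  }
  sat <- fluor_image(matrix(65535, 32, 32))
  expect_error(estimate_background(sat, params), "saturated")
})

test_that("cell threshold semantics: >=300 above background is a cell, below is not", {
  img <- disc_image(centers = rbind(c(30, 30), c(30, 70), c(70, 30), c(70, 70)),
                    radii = 6, deltas = c(400, 250, 300, 299))
  params <- segmentation_params()
  bg <- estimate_background(img, params)
  lab <- segment_cells(img, bg, params)
  expect_identical(max(lab), 2L)               # 400 and exactly 300 pass
  expect_gt(lab[30, 30], 0)
  expect_identical(lab[30, 70], 0L)            # 250 < 300
  expect_gt(lab[70, 30], 0)                    # boundary: >= is inclusive
  expect_identical(lab[70, 70], 0L)            # 299 < 300
  # uniform image -> empty mask
  flat <- fluor_image(matrix(200, 96, 96))
  expect_identical(max(segment_cells(flat, estimate_background(flat, params),
                                     params)), 0L)
})

test_that("segment_cells respects area gates and border policy", {
  img <- disc_image(centers = rbind(c(20, 20), c(50, 50), c(2, 80)),
                    radii = c(2, 6, 6), deltas = 400)
  params <- segmentation_params(min_cell_area_px = 20)
  lab <- segment_cells(img, estimate_background(img, params), params)
  expect_identical(lab[20, 20], 0L)            # radius-2 disc below area gate
  expect_gt(lab[50, 50], 0)
  expect_identical(lab[2, 80], 0L)             # touches border -> excluded
  inc <- segmentation_params(min_cell_area_px = 20, border_policy = "include")
  lab2 <- segment_cells(img, estimate_background(img, inc), inc)
  expect_gt(lab2[2, 80], 0)
})

test_that("inclusion threshold semantics: >=400 above the diffuse level, not below", {
  img <- disc_image(centers = rbind(c(30, 30), c(30, 70), c(70, 30)),
                    radii = 7, deltas = 500,
                    punctum_delta = c(450, 350, 400))
  params <- segmentation_params()
  cm <- segment_cells(img, estimate_background(img, params), params)
  expect_identical(max(cm), 3L)
  incl <- segment_inclusions(img, cm, params)
  expect_true(incl[30, 30])                    # +450 detected
  expect_false(any(incl[cm == cm[30, 70]]))    # +350 rejected
  expect_true(incl[70, 30])                    # boundary +400 is inclusive
  # inclusion mask is nested in the cell mask
  expect_true(all(cm[incl] > 0))
  # empty cell mask -> empty inclusion mask
  empty <- matrix(0L, 96, 96)
  expect_false(any(segment_inclusions(img, empty, params)))
})

test_that("threshold monotonicity and intensity-shift invariance", {
  strains <- strain_spec("m", "G", true_inclusion_prob = 0.5)
  cfg <- imaging_config(image_shape = c(128L, 128L), noise_sd = 10,
                        cells_per_image = c(20L, 30L))
  plate <- generate_plate_images(strains, cfg, replicates = 1, seed = 13)
  img <- plate$images[[1]]
  params <- segmentation_params()
  bg <- estimate_background(img, params)
  fg_count <- function(delta) {
    p <- segmentation_params(cell_delta = delta)
    sum(segment_cells(img, bg, p) > 0)
  }
  counts <- vapply(c(100, 300, 500, 700), fg_count, 0)
  expect_true(all(diff(counts) <= 0))

  incl_count <- function(delta) {
    p <- segmentation_params(inclusion_delta = delta)
    cm <- segment_cells(img, bg, p)
    sum(segment_inclusions(img, cm, p))
  }
  icounts <- vapply(c(200, 400, 600, 900), incl_count, 0)
  expect_true(all(diff(icounts) <= 0))

  # shifting all intensities leaves both masks unchanged
  shifted <- img; shifted$pixels <- img$pixels + 123
  bg2 <- estimate_background(shifted, params)
  expect_identical(segment_cells(img, bg, params),
                   segment_cells(shifted, bg2, params))
  cm <- segment_cells(img, bg, params)
  expect_identical(segment_inclusions(img, cm, params),
                   segment_inclusions(shifted, cm, params))
})

test_that("scoring: per-cell records combine the masks correctly", {
  img <- disc_image(centers = rbind(c(25, 25), c(25, 70), c(70, 25), c(70, 70)),
                    radii = 6, deltas = 500,
                    punctum_delta = c(500, 0, 500, 0))
  params <- segmentation_params()
  cm <- segment_cells(img, estimate_background(img, params), params)
  incl <- segment_inclusions(img, cm, params)
  recs <- score_cells(img, cm, incl)
  expect_identical(nrow(recs), 4L)
  expect_identical(sum(recs$has_inclusion), 2L)
  expect_true(all(recs$has_inclusion == (recs$inclusion_count >= 1)))
  expect_true(all(recs$inclusion_area_px <= recs$area_px))
  # mean intensity of a flat (punctum-free) cell equals its plateau exactly
  flat_cells <- recs[!recs$has_inclusion, ]
  expect_true(all(flat_cells$mean_intensity == 700))
  # empty inclusion mask -> all has_inclusion FALSE
  recs0 <- score_cells(img, cm, matrix(FALSE, 96, 96))
  expect_identical(sum(recs0$has_inclusion), 0L)
  # every cell contains an inclusion pixel -> all TRUE
  recs1 <- score_cells(img, cm, cm > 0)
  expect_true(all(recs1$has_inclusion))
})

test_that("score_well computes the phenotype and applies the QC floor", {
  recs <- data.frame(image = "i", label = 1:10, area_px = 50,
                     mean_intensity = c(rep(700, 5), rep(900, 5)),
                     inclusion_count = c(rep(1L, 3), rep(0L, 7)),
                     inclusion_area_px = 0, has_inclusion = rep(c(TRUE, FALSE), c(3, 7)))
  w <- score_well(recs, min_cells_for_scoring = 5)
  expect_equal(w$pct_inclusion, 30)
  expect_equal(w$mean_cell_intensity, 800)
  expect_true(w$qc_pass)
  expect_false(score_well(recs, min_cells_for_scoring = 300)$qc_pass)
  w0 <- score_well(recs[0, ], min_cells_for_scoring = 5)
  expect_identical(w0$n_cells, 0L)
  expect_true(is.na(w0$pct_inclusion))
  expect_false(w0$qc_pass)
  # extremes
  recs$has_inclusion <- TRUE
  expect_equal(score_well(recs, 5)$pct_inclusion, 100)
  recs$has_inclusion <- FALSE
  expect_equal(score_well(recs, 5)$pct_inclusion, 0)
  # pooled intensity mode is area-weighted
  recs2 <- recs
  recs2$area_px <- c(100, rep(50, 9))
  pooled <- score_well(recs2, 5, intensity_mode = "pooled")
  expect_equal(pooled$mean_cell_intensity,
               sum(recs2$mean_intensity * recs2$area_px) / sum(recs2$area_px))
})

test_that("full chain reproduces ground-truth flags exactly on noiseless plates", {
  strains <- rbind(strain_spec("WT", "HIS3", true_inclusion_prob = 0.4),
                   strain_spec("m1", "G1", true_inclusion_prob = 0.1))
  plate <- generate_plate_images(strains, imaging_config(noise_sd = 0),
                                 replicates = 2, seed = 31)
  conf <- truth_confusion(plate)
  expect_identical(conf$unmatched, 0L)
  expect_identical(conf$agree, conf$matched)
  # exactly one label per truth disc on a sparse field
  cfg <- imaging_config(image_shape = c(192L, 192L), noise_sd = 0,
                        cells_per_image = c(50L, 50L))
  p50 <- generate_plate_images(strains[1, ], cfg, replicates = 1, seed = 17)
  img <- p50$images[[1]]
  params <- segmentation_params(border_policy = "include")
  cm <- segment_cells(img, estimate_background(img, params), params)
  tc <- p50$truth_cells
  expect_identical(max(cm), nrow(tc))
  labs <- cm[cbind(round(tc$center_row), round(tc$center_col))]
  expect_identical(sort(unique(labs)), 1:nrow(tc))
})

test_that("quantify_plate pools fields into wells with replicate bookkeeping", {
  strains <- strain_spec("m", "G", true_inclusion_prob = 0.5)
  cfg <- imaging_config(image_shape = c(96L, 96L), cells_per_image = c(8L, 12L),
                        fields_per_well = 2L, noise_sd = 5)
  plate <- generate_plate_images(strains, cfg, replicates = 2, seed = 19)
  res <- quantify_plate(plate$images, plate$platemap,
                        segmentation_params(min_cells_for_scoring = 5))
  expect_identical(nrow(res$wells), 2L)
  expect_identical(sort(res$wells$replicate), c(1L, 2L))
  expect_true(all(res$wells$pct_inclusion >= 0 & res$wells$pct_inclusion <= 100))
  # conservation: per-well flagged count matches pct within rounding
  for (i in 1:2) {
    wl <- res$wells[i, ]
    ids <- sprintf("%s_s%d", wl$well, 1:2)
    n_flag <- sum(res$cells$has_inclusion[res$cells$image %in% ids])
    expect_equal(wl$n_cells * wl$pct_inclusion / 100, n_flag)
  }
})
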