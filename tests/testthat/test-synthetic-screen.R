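test_that("strain_spec enforces its invariants", {
  expect_error(strain_spec("s", "g", construct = "dsRed_only",
                           true_inclusion_prob = 0.2), "dsRed_only")
  expect_error(strain_spec("s", "g", true_inclusion_prob = 1.2), "0, 1")
  expect_error(strain_spec("s", "g", true_expression_scale = 0), "> 0")
  expect_error(strain_spec("s", "g", true_generation_time_h = -1), "> 0")
  ok <- strain_spec("s", "g", construct = "dsRed_only", true_inclusion_prob = 0)
  expect_identical(ok$true_inclusion_prob, 0)
})

test_that("plate generation is a pure function of its arguments (seeded determinism)", {
  strains <- rbind(strain_spec("WT", "HIS3", true_inclusion_prob = 0.4),
                   strain_spec("m1", "G1", true_inclusion_prob = 0.1))
  cfg <- imaging_config(image_shape = c(96L, 96L), cells_per_image = c(10L, 20L))
  a <- generate_plate_images(strains, cfg, replicates = 2, seed = 42)
  b <- generate_plate_images(strains, cfg, replicates = 2, seed = 42)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
  expect_identical(a$truth_cells, b$truth_cells)
  c <- generate_plate_images(strains, cfg, replicates = 2, seed = 43)
  expect_false(identical(a$images[[1]]$pixels, c$images[[1]]$pixels))
})

test_that("zero inclusion probability yields zero aggregated cells", {
  strains <- rbind(
    strain_spec("c1", "G1", construct = "dsRed_only", true_inclusion_prob = 0),
    strain_spec("c2", "G2", true_inclusion_prob = 0))
  plate <- generate_plate_images(strains,
                                 imaging_config(image_shape = c(96L, 96L),
                                                cells_per_image = c(10L, 20L)),
                                 replicates = 2, seed = 5)
  expect_identical(sum(plate$truth_cells$has_inclusion), 0L)
  expect_true(all(plate$truth_wells$true_fraction == 0))
})

test_that("per-well truth fraction equals the flagged/total ratio exactly", {
  strains <- strain_spec("m", "G", true_inclusion_prob = 0.5)
  plate <- generate_plate_images(strains,
                                 imaging_config(image_shape = c(96L, 96L),
                                                cells_per_image = c(10L, 20L),
                                                fields_per_well = 2L),
                                 replicates = 3, seed = 9)
  for (i in seq_len(nrow(plate$truth_wells))) {
    w <- plate$truth_wells[i, ]
    expect_identical(w$true_fraction, w$n_inclusion / w$n_cells)
  }
})

test_that("pooled truth fraction is within 3 binomial SE of the planted probability", {
  strains <- strain_spec("m", "G", true_inclusion_prob = 0.4)
  plate <- generate_plate_images(strains,
                                 imaging_config(image_shape = c(160L, 160L),
                                                cells_per_image = c(50L, 60L)),
                                 replicates = 10, seed = 21)
  n <- nrow(plate$truth_cells)
  expect_gte(n, 500)
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(mean(plate$truth_cells$has_inclusion) - 0.4), 3 * se)
})

test_that("noiseless rendering is analytically honest (background + vignette + delta)", {
  strains <- strain_spec("m", "G", true_inclusion_prob = 1)
  cfg <- imaging_config(image_shape = c(96L, 96L), cells_per_image = c(5L, 8L),
                        noise_sd = 0, vignette_amplitude = 0)
  plate <- generate_plate_images(strains, cfg, replicates = 1, seed = 3)
  px <- plate$images[[1]]$pixels
  expect_setequal(unique(as.vector(px)),
                  c(200, 200 + 800, 200 + 800 + 800))
})

test_that("growth curves have 145 points at 0.5 h / 72 h and reject bad inputs", {
  st <- strain_spec("m", "G", true_generation_time_h = 2)
  g <- generate_growth_curves(st, seed = 1)
  expect_identical(nrow(g$od), 145L)
  st_bad <- st; st_bad$true_generation_time_h <- -1
  expect_error(generate_growth_curves(st_bad, seed = 1), "non-positive")
  expect_error(generate_growth_curves(st, duration_h = 71.8, seed = 1),
               "multiple")
})

test_that("noiseless growth curves are exactly log2-linear in the exponential phase", {
  st <- strain_spec("m", "G", true_generation_time_h = 2.5)
  g <- generate_growth_curves(st, noise_sd = 0, lag_h = 2, od0 = 0.005,
                              replicates = 1, seed = 1)
  od <- g$od[[2]]; t <- g$od$time_h
  exp_phase <- which(t > 2 & od < 0.7)  # inside (lag, K/2)
  slopes <- diff(log2(od[exp_phase])) / diff(t[exp_phase])
  expect_equal(slopes, rep(1 / 2.5, length(slopes)), tolerance = 1e-10)
})

test_that("annotation generator plants the requested overlap and validates inputs", {
  uni <- sprintf("g%03d", 1:200)
  hits <- uni[1:40]
  ann <- generate_annotation(uni, c(t1 = 20, t2 = 200),
                             planted = list(term = "t1", hits = hits,
                                            overlap = 10), seed = 4)
  t1 <- ann$mapping$gene[ann$mapping$term == "t1"]
  expect_length(t1, 20)
  expect_identical(length(intersect(t1, hits)), 10L)
  expect_length(ann$mapping$gene[ann$mapping$term == "t2"], 200)
  expect_error(generate_annotation(uni, c(t1 = 5),
                                   planted = list(term = "t1", hits = hits,
                                                  overlap = 6)),
               "overlap")
})

test_that("interaction generator emits connected physical modules plus genetic decoys", {
  hits <- sprintf("h%02d", 1:12)
  expect_identical(nrow(generate_interactions(hits)), 0L)
  edges <- generate_interactions(hits, modules = list(hits[1:3]), seed = 2)
  expect_true(all(edges$kind == "physical"))
  expect_gte(nrow(edges), 2)
  mixed <- generate_interactions(hits, modules = list(hits[1:4], hits[5:7]),
                                 extra_genetic_edges = 4, seed = 2)
  expect_identical(sum(mixed$kind == "genetic"), 4L)
  expect_error(generate_interactions(hits, modules = list(c("zz", hits[1]))),
               "subset")
})
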