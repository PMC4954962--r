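test_that("students_t matches the classical pooled t and its contracts", {
  res <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_identical(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  # oracle: stats::t.test with var.equal = TRUE on random samples
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1), sample(-2:2, 1)); b <- rnorm(sample(2:8, 1))
    mine <- students_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # symmetry and positive-scale invariance
    swap <- students_t(b, a)
    expect_equal(swap$t, -mine$t)
    expect_equal(swap$p, mine$p)
    sc <- students_t(3.7 * a, 3.7 * b)
    expect_equal(sc$t, mine$t, tolerance = 1e-12)
  }

  # degenerate contracts
  same <- students_t(c(2, 2), c(2, 2))
  expect_identical(c(same$t, same$p), c(0, 1))
  ident <- students_t(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  deg <- students_t(c(2, 2), c(3, 3))
  expect_identical(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("call_hits applies the three criteria and routes confounded strains", {
  wt <- data.frame(strain_id = "WT", replicate = 1:3,
                   pct_inclusion = c(39, 40, 41),
                   mean_cell_intensity = c(990, 1000, 1010))
  mk <- function(id, pct, intens)
    data.frame(strain_id = id, replicate = 1:3, pct_inclusion = pct,
               mean_cell_intensity = intens)
  ph <- rbind(wt,
    mk("dec",  c(23, 24, 25), c(980, 1005, 1015)),  # 40% drop, intensity flat
    mk("inc",  c(59, 60, 61), c(995, 1000, 1005)),  # 50% rise
    mk("conf", c(23, 24, 25), c(490, 500, 510)),    # drop + halved intensity
    mk("same", c(39, 40, 41), c(990, 1000, 1010)),  # identical to WT
    mk("small", c(35, 36, 37), c(990, 1000, 1010))) # significant but ~10% only
  hits <- call_hits(ph, "WT")
  expect_setequal(hits$strain_id, c("dec", "inc", "conf", "same", "small"))
  get <- function(id) hits[hits$strain_id == id, ]
  expect_identical(get("dec")$category, "decreased")
  expect_lt(get("dec")$effect, 0)
  expect_lte(get("dec")$p_inclusion, 0.05)
  expect_gt(get("dec")$p_intensity, 0.05)
  expect_identical(get("inc")$category, "increased")
  expect_identical(get("conf")$category, "expression_confounded")
  expect_lte(get("conf")$p_intensity, 0.05)
  expect_identical(get("same")$category, "not_hit")
  expect_identical(get("small")$category, "not_hit")  # fails the 25% cutoff
  # partition: every strain gets exactly one category
  expect_identical(nrow(hits), 5L)
  expect_true(all(hits$category %in%
    c("decreased", "increased", "expression_confounded", "not_hit")))
  # absolute-points mode: a 16-point drop passes min_effect = 15 points
  abs_hits <- call_hits(ph, "WT",
                        hit_criteria(min_effect = 15,
                                     effect_mode = "absolute_points"))
  expect_identical(abs_hits[abs_hits$strain_id == "dec", "category"],
                   "decreased")
  expect_equal(abs_hits[abs_hits$strain_id == "dec", "effect"], -16)
  # missing WT errors; < 2 replicates skipped with message
  expect_error(call_hits(ph, "nope"), "missing")
  ph1 <- rbind(ph, mk("solo", 10, 1000)[1, ])
  expect_message(h1 <- call_hits(ph1, "WT"), "skipped")
  expect_false("solo" %in% h1$strain_id)
})

test_that("planted-hit recovery under realistic intensity noise", {
  # With i.i.d. replicate noise on the intensity control, 5% of true hits are
  # expected to route to the confounded bin (the control's exact type-I
  # rate), so pure-decreased sensitivity is capped at 0.95 x inclusion power;
  # detection of the significant decrease itself (decreased or confounded)
  # is what stays near-complete.
  dec <- 0L; det <- 0L; fp <- 0L; conf <- 0L; nrun <- 200L
  for (s in seq_len(nrun)) {
    strains <- rbind(
      strain_spec("WT", "HIS3", true_inclusion_prob = 0.30),
      strain_spec("dec", "G1", true_inclusion_prob = 0.15),
      strain_spec("nul", "G2", true_inclusion_prob = 0.30),
      strain_spec("cnf", "G3", true_inclusion_prob = 0.30,
                  true_expression_scale = 0.5))
    ph <- generate_phenotypes(strains, replicates = 3, pct_noise_sd = 3,
                              intensity_sd = 50, seed = s)
    hits <- call_hits(ph, "WT")
    cat_of <- function(id) hits$category[hits$strain_id == id]
    dec <- dec + (cat_of("dec") == "decreased")
    det <- det + (cat_of("dec") %in% c("decreased", "expression_confounded"))
    fp <- fp + (cat_of("nul") != "not_hit")
    conf <- conf + (cat_of("cnf") == "expression_confounded")
  }
  expect_gte(dec / nrun, 0.90)
  expect_gte(det / nrun, 0.95)
  expect_lte(fp / nrun, 0.05)
  expect_gte(conf / nrun, 0.90)
})

test_that("normalize_to_wt anchors the wild type at 50%", {
  expect_identical(normalize_to_wt(40, 40), 50)
  expect_identical(normalize_to_wt(0, 40), 0)
  expect_identical(normalize_to_wt(20, 40), 25)
  expect_identical(normalize_to_wt(80, 40), 100)  # increased hits exceed 50
  expect_error(normalize_to_wt(10, 0), "> 0")
})

test_that("confirmation_rate reproduces the published 92.9% / 7.1% split", {
  auto <- sprintf("h%02d", 1:14)
  res <- confirmation_rate(auto, auto[1:13])
  expect_equal(round(res$confirmation_pct, 1), 92.9)
  expect_equal(round(res$false_positive_pct, 1), 7.1)
  expect_equal(res$confirmation_pct + res$false_positive_pct, 100)
  all_conf <- confirmation_rate(auto, auto)
  expect_identical(c(all_conf$confirmation_pct, all_conf$false_positive_pct),
                   c(100, 0))
  expect_error(confirmation_rate(character(0), character(0)), "empty")
  expect_error(confirmation_rate(auto[1:3], c("zz")), "subset")
})

test_that("background registry reproduces the published collection arithmetic", {
  del <- data.frame(strain_id = sprintf("d%04d", 1:4368),
                    gene_id = sprintf("gene%04d", 1:4368))
  # 787 ts alleles covering 497 essential genes (disjoint from deletions)
  ts_genes <- sprintf("ess%03d", 1:497)
  ts <- data.frame(strain_id = sprintf("t%03d", 1:787),
                   gene_id = c(ts_genes, sample(ts_genes, 290, replace = TRUE)))
  reg <- build_background_registry(del, ts)
  expect_identical(reg$strain_count, 5155L)
  expect_identical(length(reg$essential_genes), 497L)
  expect_identical(length(reg$gene_universe), 4368L + 497L)
  # empty ts arm
  reg0 <- build_background_registry(del, ts[0, ])
  expect_identical(reg0$strain_count, 4368L)
  # duplicate strain ids across manifests are rejected
  expect_error(build_background_registry(del, data.frame(strain_id = "d0001",
                                                         gene_id = "x")),
               "duplicate")
})
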