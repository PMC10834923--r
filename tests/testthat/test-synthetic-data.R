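test_that("annotation catalog follows priors, vocabulary and seed", {
  # degenerate prior: every protein gets the single label
  cat1 <- generate_annotation_catalog(10, c(ER = 1.0), seed = 1)
  expect_true(all(vapply(cat1$labels, identical, TRUE, "ER")))

  # determinism
  a <- generate_annotation_catalog(1000, c(ER = 0.5, Golgi = 0.5), seed = 3)
  b <- generate_annotation_catalog(1000, c(ER = 0.5, Golgi = 0.5), seed = 3)
  expect_identical(a, b)

  # label frequencies converge to priors: with n = 10000 draws of a fair
  # binary prior the primary-label ER fraction is within 0.02 of 0.5
  # (4 binomial SDs = 0.02)
  big <- generate_annotation_catalog(10000, c(ER = 0.5, Golgi = 0.5),
                                     seed = 5, multi_label_prob = 0)
  er_frac <- mean(vapply(big$labels, identical, TRUE, "ER"))
  expect_lt(abs(er_frac - 0.5), 0.02)

  expect_error(generate_annotation_catalog(10, c(ER = 0.7)), "sum to 1")
})

test_that("planted truth respects fraction, archetype map and active times", {
  cfg <- sim_config(n_proteins = 5000, planted_fraction = 0.1, seed = 11)
  catalog <- generate_annotation_catalog(5000, cfg$organelle_priors, seed = 11)
  truth <- generate_truth(catalog, cfg)

  # binomial tolerance: 500 +- 4*sqrt(5000*0.1*0.9) ~ 500 +- 85
  expect_lt(abs(sum(truth$is_interactor) - 500), 85)
  expect_true(all(lengths(truth$active_times[!truth$is_interactor]) == 0))
  expect_true(all(!is.na(truth$archetype_id[truth$is_interactor])))
  expect_true(all(is.na(truth$archetype_id[!truth$is_interactor])))

  # active times follow the archetype mapped from the primary organelle
  ints <- which(truth$is_interactor)
  for (i in ints[seq_len(min(50, length(ints)))]) {
    expected <- archetype_active_times(cfg$archetype_map[[truth$organelle[i]]])
    expect_identical(truth$active_times[[i]], expected)
  }

  # no interactors when the fraction is 0
  cfg0 <- sim_config(n_proteins = 100, planted_fraction = 0, seed = 2)
  truth0 <- generate_truth(generate_annotation_catalog(100,
                           cfg0$organelle_priors, seed = 2), cfg0)
  expect_false(any(truth0$is_interactor))

  # archetype map must cover every organelle in the catalog
  cfg_bad <- sim_config(n_proteins = 50, seed = 1,
                        archetype_map = c(ER = 1L))
  expect_error(generate_truth(generate_annotation_catalog(50,
               cfg_bad$organelle_priors, seed = 1), cfg_bad),
               "archetype_map missing")
})

test_that("noiseless dropout-free data realize the planted design exactly", {
  cfg <- sim_config(n_proteins = 60, noise_sd = 0, dropout_rate = 0,
                    planted_fraction = 0.5, planted_log2fc = 1, seed = 4)
  catalog <- generate_annotation_catalog(60, cfg$organelle_priors, seed = 4)
  truth <- generate_truth(catalog, cfg)
  mat <- generate_lfq_dataset(truth, cfg)

  expect_identical(mat$scale, "LOG2")
  expect_false(anyNA(mat$values))
  for (tt in cfg$time_points_min) {
    pos <- rowMeans(mat$values[, mat$samples$condition == "POS" &
                                  mat$samples$time_min == tt])
    neg <- rowMeans(mat$values[, mat$samples$condition == "NEG" &
                                  mat$samples$time_min == tt])
    active <- vapply(truth$active_times, function(a) tt %in% a, TRUE)
    expect_equal(unname(pos - neg), ifelse(active, 1, 0))
  }

  # with no planted effect all log-ratios are exactly 0
  cfg0 <- sim_config(n_proteins = 30, noise_sd = 0, dropout_rate = 0,
                     planted_fraction = 0, seed = 5)
  truth0 <- generate_truth(generate_annotation_catalog(30,
                           cfg0$organelle_priors, seed = 5), cfg0)
  mat0 <- generate_lfq_dataset(truth0, cfg0)
  pos <- mat0$values[, mat0$samples$condition == "POS"]
  neg <- mat0$values[, mat0$samples$condition == "NEG"]
  expect_equal(pos, neg, ignore_attr = TRUE)
})

test_that("MNAR dropout calibration hits the requested overall rate", {
  cfg <- sim_config(n_proteins = 5000, dropout_rate = 0.2, seed = 9)
  truth <- generate_truth(generate_annotation_catalog(5000,
                          cfg$organelle_priors, seed = 9), cfg)
  mat <- generate_lfq_dataset(truth, cfg)
  expect_lt(abs(missing_fraction(mat) - 0.2), 0.02)

  # dropout is intensity-dependent: missing cells sit at lower true
  # intensity, so observed column means exceed the overall mean
  expect_gt(mean(mat$values, na.rm = TRUE), cfg$baseline_log2_mean)
})

test_that("generator is deterministic and realizes the planted effect", {
  cfg <- sim_config(n_proteins = 400, seed = 21)
  catalog <- generate_annotation_catalog(400, cfg$organelle_priors, seed = 21)
  truth <- generate_truth(catalog, cfg)
  m1 <- generate_lfq_dataset(truth, cfg)
  m2 <- generate_lfq_dataset(truth, cfg)
  expect_identical(m1, m2)

  # mean realized (+)-(-) difference at active times converges to the
  # planted log2 fold change (dropout off so no imputation is involved)
  cfgb <- sim_config(n_proteins = 2000, noise_sd = 0.25, dropout_rate = 0,
                     planted_fraction = 0.2, planted_log2fc = 1, seed = 22)
  truthb <- generate_truth(generate_annotation_catalog(2000,
                           cfgb$organelle_priors, seed = 22), cfgb)
  matb <- generate_lfq_dataset(truthb, cfgb)
  diffs <- c()
  for (tt in cfgb$time_points_min) {
    pos <- rowMeans(matb$values[, matb$samples$condition == "POS" &
                                   matb$samples$time_min == tt])
    neg <- rowMeans(matb$values[, matb$samples$condition == "NEG" &
                                   matb$samples$time_min == tt])
    active <- vapply(truthb$active_times, function(a) tt %in% a, TRUE)
    diffs <- c(diffs, (pos - neg)[active])
  }
  tol <- 3 * 0.25 / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1), tol)
})

test_that("replicate QC mirrors real-data behavior at moderate noise", {
  for (noise in c(0.25, 0.5)) {
    cfg <- sim_config(n_proteins = 800, noise_sd = noise, dropout_rate = 0.3,
                      seed = 31)
    truth <- generate_truth(generate_annotation_catalog(800,
                            cfg$organelle_priors, seed = 31), cfg)
    mat <- generate_lfq_dataset(truth, cfg)
    rc <- replicate_correlation(mat)
    expect_true(all(rc$pearson > 0.8))
  }
})

test_that("coloc image generator hits correlation targets and is deterministic", {
  # exact affine dependence at |target| = 1
  p1 <- generate_coloc_images(1, c(32, 32), seed = 1)
  expect_equal(pearson_coloc(p1), 1)
  pm1 <- generate_coloc_images(-1, c(32, 32), seed = 1)
  expect_equal(pearson_coloc(pm1), -1)

  # null target: |r| bounded by the Fisher-z 4-sigma radius for n = 10^4,
  # tanh(4/sqrt(n-3)) ~ 0.04 < 0.05
  p0 <- generate_coloc_images(0, c(100, 100), seed = 2)
  expect_lt(abs(pearson_coloc(p0)), 0.05)

  # intermediate target within sampling error
  p5 <- generate_coloc_images(0.5, c(100, 100), seed = 3)
  expect_lt(abs(pearson_coloc(p5) - 0.5), 0.05)

  expect_identical(generate_coloc_images(0.3, c(16, 16), seed = 9),
                   generate_coloc_images(0.3, c(16, 16), seed = 9))
  expect_error(generate_coloc_images(1.2, c(4, 4), seed = 1), "\\[-1, 1\\]")
  expect_true(all(p5$channel_a >= 0) && all(p5$channel_b >= 0))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(organelle_priors = c(ER = 0.6, Golgi = 0.3)),
               "sum to 1")
  expect_error(sim_config(time_points_min = c(0, 5, 5)), "increasing")
  expect_error(sim_config(planted_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_replicates = 0), ">= 1")
})
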