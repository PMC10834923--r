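test_that("log ratios are POS-mean minus NEG-mean per time point", {
  # hand arithmetic: POS {10,12}, NEG {9,9} -> 11 - 9 = 2
  mat <- make_lfq_1t(pos = matrix(c(10, 12), 1), neg = matrix(c(9, 9), 1))
  r <- compute_log_ratios(mat, 0)
  expect_equal(r$log2fc, 2)

  # identical conditions give all-zero ratios
  v <- matrix(rnorm(40, 25), 10, 4)
  same <- make_lfq(cbind(v[, 1:2], v[, 1:2]), time_points = 0, n_rep = 2)
  expect_equal(compute_log_ratios(same, 0)$log2fc, rep(0, 10))

  # 20-protein fixture vs cell-by-cell re-computation
  set.seed(8)
  vals <- matrix(rnorm(20 * 8, 25, 2), 20, 8)
  mat2 <- make_lfq(vals, time_points = c(0, 5), n_rep = 2)
  for (tt in c(0, 5)) {
    r2 <- compute_log_ratios(mat2, tt)
    manual <- vapply(seq_len(20), function(i) {
      pos <- mat2$values[i, mat2$samples$condition == "POS" &
                            mat2$samples$time_min == tt]
      neg <- mat2$values[i, mat2$samples$condition == "NEG" &
                            mat2$samples$time_min == tt]
      sum(pos) / length(pos) - sum(neg) / length(neg)
    }, numeric(1))
    expect_equal(r2$log2fc, manual)
  }

  miss <- mat2; miss$values[1, 1] <- NA
  expect_error(compute_log_ratios(miss, 0), "imputed")
  expect_error(compute_log_ratios(mat2, 99), "lacks POS or NEG")
})

test_that("mirror FDR matches the brute-force oracle on frozen cases", {
  # centered ratios {-1, +1}: the +1 protein sees one mirror count below -1
  # (pseudocount 0) -> raw 1/1 = 1 -> q = 1; with the default pseudocount the
  # numerator is 2 but clipping keeps q = 1
  for (pc in c(0, 1)) {
    r <- make_ratios(c(-1, 1, rep(0, 10)))
    q <- estimate_empirical_fdr(r, center = "none", pseudocount = pc)$qvalue
    expect_equal(q, mirror_fdr_oracle(r$log2fc, 0, pc))
    expect_equal(q[2], 1)
  }

  # centered {+3, +0.1, -0.1} plus nulls: with pseudocount 0 the +3 protein
  # has no mirror counterpart -> q = 0 (oracle-frozen); the default
  # pseudocount yields 1/1 -> q = 1
  r2 <- make_ratios(c(3, 0.1, -0.1, rep(0, 9)))
  q0 <- estimate_empirical_fdr(r2, center = "none", pseudocount = 0)$qvalue
  expect_equal(q0, mirror_fdr_oracle(r2$log2fc, 0, 0))
  expect_equal(q0[1], 0)
  q1 <- estimate_empirical_fdr(r2, center = "none", pseudocount = 1)$qvalue
  expect_equal(q1, mirror_fdr_oracle(r2$log2fc, 0, 1))
  expect_equal(q1[1], 1)

  # all centered ratios strictly positive: pseudocount-0 raw FDRs are all 0
  r3 <- make_ratios(seq(0.1, 1.2, length.out = 12))
  q3 <- estimate_empirical_fdr(r3, center = "none", pseudocount = 0)$qvalue
  expect_equal(q3, rep(0, 12))

  expect_error(estimate_empirical_fdr(make_ratios(1:5)), ">= 10")
})

test_that("mirror FDR equals the O(n^2) oracle on random ratio lists", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(10:100, 1)
    r <- round(rnorm(n, sd = sample(c(0.25, 1), 1)),
               digits = sample(c(1, 6), 1))  # coarse rounding forces ties
    rt <- make_ratios(r)
    pc <- sample(c(0, 1), 1)
    got <- estimate_empirical_fdr(rt, center = "median",
                                  pseudocount = pc)$qvalue
    expect_equal(got, mirror_fdr_oracle(r, median(r), pc))
  }
})

test_that("q-values are monotone and centering behaves as documented", {
  set.seed(3)
  r <- rnorm(200, sd = 0.5); r[1:10] <- r[1:10] + 2
  q <- estimate_empirical_fdr(make_ratios(r))$qvalue
  ord <- order(r)
  expect_true(all(diff(q[ord]) <= 1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # proteins at or below the center get q = 1
  expect_true(all(q[r <= median(r)] == 1))

  # mode centering and the gaussian-null variant produce valid q-values
  qm <- estimate_empirical_fdr(make_ratios(r), center = "mode")$qvalue
  qg <- estimate_empirical_fdr(make_ratios(r), null = "gaussian")$qvalue
  expect_true(all(qm >= 0 & qm <= 1) && all(qg >= 0 & qg <= 1))
  # the bulk of the strong planted tail is detected by the gaussian null
  # (the weakest planted draws can legitimately stay above the cut)
  expect_gte(mean(qg[1:10] <= 0.05), 0.7)
})

test_that("screening applies both gates and records thresholds", {
  r <- make_ratios(c(0.30, 0.20, 1.0, rep(-0.1, 9)))
  r$qvalue <- c(0.01, 0.001, 0.06, rep(1, 9))
  s <- screen_interactors(r, fc_threshold = 1.2, fdr_threshold = 0.05)
  # FC ~1.23 + q 0.01 passes; FC gate fails at 1.15; FDR gate fails at 0.06
  expect_identical(s$table$pass[1:3], c(TRUE, FALSE, FALSE))
  expect_identical(s$pass_set, "P001")
  expect_identical(s$fc_threshold, 1.2)
  expect_error(screen_interactors(r, fc_threshold = -1), "> 0")
  expect_error(screen_interactors(make_ratios(rnorm(12))), "unset")
})

test_that("raising a protein's POS intensities never hurts its call", {
  set.seed(14)
  vals <- matrix(rnorm(50 * 4, 25, 2), 50, 4)
  mat <- make_lfq(vals, time_points = 0, n_rep = 2)
  r0 <- estimate_empirical_fdr(compute_log_ratios(mat, 0))
  for (bump in c(0.5, 1, 2)) {
    mat2 <- mat
    mat2$values[7, mat$samples$condition == "POS"] <-
      mat$values[7, mat$samples$condition == "POS"] + bump
    r1 <- estimate_empirical_fdr(compute_log_ratios(mat2, 0))
    expect_gte(r1$log2fc[7], r0$log2fc[7])
    expect_lte(r1$qvalue[7], r0$qvalue[7])
  }
})

test_that("screening is one-sided: negating centered ratios empties the pass set", {
  set.seed(15)
  r <- rnorm(300, sd = 0.3); r[1:30] <- r[1:30] + 1.5
  x <- r - median(r)
  s_neg <- screen_interactors(estimate_empirical_fdr(make_ratios(-x),
                                                     center = "none"))
  expect_length(s_neg$pass_set, 0)
})

test_that("dynamics summary counts and sums the passing proteins", {
  set.seed(16)
  vals <- matrix(rnorm(10 * 8, 20, 1), 10, 8)
  mat <- make_lfq(vals, time_points = c(0, 5), n_rep = 2)
  screens <- list(make_screen(0, c("P001", "P002")), make_screen(5, "P003"))
  dyn <- summarize_dynamics(screens, mat)
  expect_equal(dyn$n_pass, c(2, 1))
  # hand-computed raw-scale sum over POS columns
  pos0 <- mat$samples$condition == "POS" & mat$samples$time_min == 0
  expect_equal(dyn$sum_lfq_pos[1], sum(2^mat$values[c("P001", "P002"), pos0]))
  pos5 <- mat$samples$condition == "POS" & mat$samples$time_min == 5
  expect_equal(dyn$sum_lfq_pos[2], sum(2^mat$values["P003", pos5]))

  empty <- list(make_screen(0, character(0)), make_screen(5, character(0)))
  dyn0 <- summarize_dynamics(empty, mat)
  expect_equal(dyn0$n_pass, c(0, 0))
  expect_equal(dyn0$sum_lfq_pos, c(0, 0))
  expect_error(summarize_dynamics(list(make_screen(0, "P001"),
                                       make_screen(0, "P002")), mat),
               "duplicated")
})
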