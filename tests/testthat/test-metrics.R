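# Illness metric arithmetic, validity gating, top-fraction extraction.

ctrl <- ctrl_from(p40 = c(100, 100, 100, 100), p20 = c(10, 10, 10, 10),
                  p30 = c(95, 105, 100, 100))

test_that("control statistics are means and n-1 standard deviations", {
  cs <- ctrl_from(p40 = c(1, 3), p20 = c(2, 2), p30 = c(1, 3))
  expect_equal(cs$mean_p30, 2)
  expect_equal(cs$sd_p30, sqrt(2))
  expect_equal(cs$n_subjects, 2)
  same <- ctrl_from(rep(5, 20), rep(1, 20), rep(7, 20))
  expect_equal(same$sd_p30, 0)
  expect_equal(same$mean_p40, 5)
  # permuting subject order changes nothing
  p40 <- c(3, 1, 4, 1, 5); p20 <- c(9, 2, 6, 5, 3); p30 <- c(5, 8, 9, 7, 9)
  i <- c(4, 2, 5, 1, 3)
  expect_equal(unclass(ctrl_from(p40, p20, p30)),
               unclass(ctrl_from(p40[i], p20[i], p30[i])))
  expect_error(control_stats(list(band_powers(1, 1, 1))), "single subject")
})

test_that("M1 is the relative 40 Hz reduction", {
  expect_equal(compute_M1(bp_const(100, 10, 100), ctrl), 0)
  expect_equal(compute_M1(bp_const(0, 10, 100), ctrl), 1)
  # the strongest overall reduction reported as 48.29% corresponds to
  # P40 = 0.5171 of the control mean
  expect_equal(compute_M1(bp_const(51.71, 10, 100), ctrl), 0.4829)
  expect_equal(compute_M1(bp_const(150, 10, 100), ctrl), -0.5)
  expect_error(compute_M1(bp_const(1, 1, 1), ctrl_from(c(0, 0), c(1, 1), c(1, 1))),
               "undefined")
})

test_that("the 30 Hz validity gate is within 3 sd, boundary inclusive", {
  sd30 <- ctrl$sd_p30
  expect_true(is_valid(bp_const(0, 0, ctrl$mean_p30), ctrl))
  expect_false(is_valid(bp_const(0, 0, ctrl$mean_p30 + 4 * sd30), ctrl))
  expect_true(is_valid(bp_const(0, 0, ctrl$mean_p30 + 3 * sd30), ctrl))
})

test_that("M2 equals M1 for valid vectors and 0 for invalid ones", {
  expect_equal(compute_M2(bp_const(65.51, 10, 100), ctrl), 0.3449)
  far <- ctrl$mean_p30 + 10 * ctrl$sd_p30
  expect_equal(compute_M2(bp_const(10, 10, far), ctrl), 0)
  expect_equal(compute_M2(bp_const(100, 10, 100), ctrl), 0)
  # M2 is always either 0 or M1
  set.seed(3)
  for (i in 1:50) {
    bp <- bp_const(runif(1, 0, 200), runif(1, 0, 50), runif(1, 50, 150))
    m2 <- compute_M2(bp, ctrl)
    expect_true(m2 == 0 || m2 == compute_M1(bp, ctrl))
  }
})

test_that("M3 rewards 40 Hz loss with 20 Hz gain, gated by validity", {
  expect_equal(compute_M3(bp_const(100, 10, 100), ctrl), 0)
  expect_equal(compute_M3(bp_const(0, 20, 100), ctrl), 1)
  far <- ctrl$mean_p30 + 10 * ctrl$sd_p30
  expect_equal(compute_M3(bp_const(0, 20, far), ctrl), 0)
  # monotonicity: M1 strictly decreasing in P40; M3 increasing in P20
  m1a <- compute_M1(bp_const(40, 10, 100), ctrl)
  m1b <- compute_M1(bp_const(60, 10, 100), ctrl)
  expect_gt(m1a, m1b)
  m3a <- compute_M3(bp_const(50, 30, 100), ctrl)
  m3b <- compute_M3(bp_const(50, 10, 100), ctrl)
  expect_gt(m3a, m3b)
})

test_that("metrics are invariant to a global power rescaling", {
  bp <- bp_const(70, 25, 101)
  for (s in c(0.01, 3, 1000)) {
    ctrl_s <- ctrl_from(c(100, 100, 100, 100) * s, rep(10, 4) * s,
                        c(95, 105, 100, 100) * s)
    bp_s <- bp_const(70 * s, 25 * s, 101 * s)
    expect_equal(compute_M1(bp_s, ctrl_s), compute_M1(bp, ctrl))
    expect_equal(compute_M2(bp_s, ctrl_s), compute_M2(bp, ctrl))
    expect_equal(compute_M3(bp_s, ctrl_s), compute_M3(bp, ctrl))
  }
})

test_that("top_fraction picks ceiling(qN) with deterministic tie-breaks", {
  scores <- runif(2025)
  expect_length(top_fraction(scores, 0.05), 102)
  ties <- rep(1, 10)
  expect_equal(top_fraction(ties, 0.3), 1:3)
  expect_equal(sort(top_fraction(seq_len(9) / 10, 0.999)), 1:9)
  expect_error(top_fraction(numeric(0), 0.05), "empty")
})

test_that("instance distributions sum to 100 and match direct counts", {
  pvs <- enumerate_grid(sweep_grid())
  sub <- pvs[pvs$tau_ie == 6, ]
  d <- instance_distribution(sub, "tau_ie")
  expect_equal(unname(d), c(100, 0, 0))
  d2 <- instance_distribution(pvs, "w_ie")
  expect_equal(unname(d2), rep(20, 5))
  set.seed(9)
  for (i in 1:10) {
    s <- pvs[sample(nrow(pvs), 37), ]
    expect_equal(sum(instance_distribution(s, "n_ii")), 100, tolerance = 1e-2)
  }
  expect_error(instance_distribution(pvs, "bogus"), "unknown parameter")
})
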