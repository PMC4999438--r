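# Grid enumeration, named parameter vectors, the validity-fraction
# arithmetic and the sweep runner on a toy grid.

test_that("the default grid enumerates 2025 unique vectors, baseline once", {
  pvs <- enumerate_grid(sweep_grid())
  expect_equal(nrow(pvs), 2025)
  expect_equal(nrow(unique(pvs)), 2025)
  base <- pvs$tau_ie == 6 & pvs$tau_ii == 6 & pvs$n_ie == 1 & pvs$n_ii == 1 &
    pvs$w_ie == 1 & pvs$w_ii == 1
  expect_equal(sum(base), 1)
  # lexicographic order: n_ie varies slowest, tau_ii fastest
  expect_equal(pvs$n_ie[1:675], rep(1, 675))
  expect_equal(pvs$tau_ii[1:3], c(6, 15, 25))
  one <- enumerate_grid(sweep_grid(n_ie = 1, n_ii = 1, w_ie = 1, w_ii = 1,
                                   tau_ie = 6, tau_ii = 6))
  expect_equal(nrow(one), 1)
})

test_that("named parameter vectors carry the selected field values", {
  pv1 <- named_pv("PV_M1")
  expect_equal(pv1$tau_ie, 25)
  expect_equal(pv1$tau_ii, 15)
  expect_equal(pv1$n_ie, 1.00)
  expect_equal(pv1$n_ii, 0.50)
  expect_equal(pv1$w_ie, 1.50)
  expect_equal(pv1$w_ii, 0.75)
  pv2 <- named_pv("PV_M2")
  expect_equal(pv2$tau_ie, 6)
  expect_equal(pv2$tau_ii, 25)
  expect_equal(pv2$n_ii, 1.00)
  expect_equal(pv2$w_ie, 0.75)
  expect_equal(pv2$w_ii, 1.25)
  pv3 <- named_pv("PV_M3")
  expect_equal(pv3$tau_ii, 6)
  expect_equal(pv3$n_ii, 0.50)
  expect_equal(pv3$w_ie, 1.50)
  expect_equal(pv3$w_ii, 0.50)
  expect_error(named_pv("PV_M4"))
})

test_that("a constructed table with 629 of 2025 valid rows gives 0.3106", {
  ctrl <- ctrl_from(rep(100, 20), rep(10, 20), c(rep(99, 10), rep(101, 10)))
  tab <- data.frame(p40_40 = rep(80, 2025), p20_40 = rep(10, 2025),
                    p30_30 = c(rep(100, 629), rep(500, 2025 - 629)))
  vf <- valid_fraction(tab, ctrl)
  expect_equal(vf$n_valid, 629)
  expect_equal(vf$n_total, 2025)
  expect_equal(round(vf$fraction, 4), 0.3106)
  all_valid <- valid_fraction(tab[1:629, ], ctrl)
  expect_equal(all_valid$fraction, 1)
  none <- valid_fraction(tab[630:700, ], ctrl)
  expect_equal(none$fraction, 0)
})

test_that("the sweep runner produces paired records and resumes checkpoints", {
  grid <- sweep_grid(n_ie = 1, n_ii = 1, w_ie = 1, w_ii = c(1, 0.5),
                     tau_ie = 6, tau_ii = 6)
  sim <- micro_sim_config(duration_ms = 1200,
                          transient_ms = 100)
  ck <- tempfile("sweep_ck_")
  t1 <- system.time(
    tab <- run_sweep(grid, micro_network_config(), sim,
                     stimulus_spec("periodic", 40, 1200),
                     stimulus_spec("periodic", 30, 1200), out_dir = ck))[3]
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$status == "ok"))
  expect_true(all(is.finite(tab$p40_40)) && all(is.finite(tab$p30_30)))
  # rerun over the completed directory: checkpoint hit, no recomputation
  t2 <- system.time(
    tab2 <- run_sweep(grid, micro_network_config(), sim,
                      stimulus_spec("periodic", 40, 1200),
                      stimulus_spec("periodic", 30, 1200), out_dir = ck))[3]
  expect_equal(tab2$p40_40, tab$p40_40, tolerance = 1e-12)
  expect_lt(t2, t1 / 2)
  # the baseline record equals a control subject run with the same seed
  net <- build_network(micro_network_config())
  r40 <- run_simulation(net, stimulus_spec("periodic", 40, 1200), sim)
  r30 <- run_simulation(net, stimulus_spec("periodic", 30, 1200), sim)
  bp <- extract_band_powers(r40, r30, transient_ms = 100)
  expect_equal(tab$p40_40[tab$w_ii == 1], bp$p40_40, tolerance = 1e-9)
  expect_equal(tab$p30_30[tab$w_ii == 1], bp$p30_30, tolerance = 1e-9)
  unlink(ck, recursive = TRUE)
})

test_that("metric and MI results do not depend on record order", {
  set.seed(31)
  pvs <- enumerate_grid(sweep_grid())
  tab <- cbind(pvs, data.frame(
    p40_40 = 100 * runif(2025), p20_40 = 10 * runif(2025),
    p30_30 = 100 + rnorm(2025, 0, 5)))
  ctrl <- ctrl_from(rep(100, 20), rep(10, 20), 100 + c(-2, 2, rep(0, 18)))
  sc1 <- compute_metrics(tab, ctrl)
  perm <- sample(2025)
  sc2 <- compute_metrics(tab[perm, ], ctrl)
  expect_equal(sc2$M2[order(perm)], sc1$M2)
  sc1$label <- discretize_phenotype(sc1$M1, "threshold", t = 0.5)
  sc2$label <- discretize_phenotype(sc2$M1, "threshold", t = 0.5)
  expect_equal(normalized_mi(sc1, c("tau_ie", "w_ie")),
               normalized_mi(sc2, c("tau_ie", "w_ie")))
})
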