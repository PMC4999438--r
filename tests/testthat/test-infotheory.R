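# Entropy, mutual information and normalized MI against brute-force oracles.

test_that("entropy matches closed forms and the brute-force oracle", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  joint <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  expect_equal(shannon_entropy(joint), oracle_entropy(joint), tolerance = 1e-12)
  expect_equal(shannon_entropy(joint), 1.7219, tolerance = 1e-4)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("entropy and MI match brute force on random joints (<= 4 vars)", {
  set.seed(42)
  for (rep in 1:20) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    joint <- matrix(rexp(nx * ny), nx, ny)
    joint <- joint / sum(joint)
    expect_equal(shannon_entropy(joint), oracle_entropy(joint),
                 tolerance = 1e-10)
    # build an empirical dataset realizing this joint exactly (counts)
    counts <- round(joint * 2000)
    dat <- joint_to_data(counts)
    emp <- counts / sum(counts)
    expect_equal(mutual_information(dat, "x", "label"), oracle_mi(emp),
                 tolerance = 1e-10)
  }
  # multi-variable compound subsets: 3 params + label, vs flattened oracle
  for (rep in 1:10) {
    dat <- data.frame(a = sample(1:3, 500, TRUE), b = sample(1:2, 500, TRUE),
                      c = sample(1:4, 500, TRUE))
    dat$label <- as.integer((dat$a + dat$b + dat$c) %% 2)
    key <- interaction(dat$a, dat$b, dat$c, drop = TRUE)
    joint <- table(key, dat$label) / nrow(dat)
    expect_equal(mutual_information(dat, c("a", "b", "c"), "label"),
                 oracle_mi(unclass(joint)), tolerance = 1e-10)
  }
})

test_that("MI chain consistency: H(Y) - H(Y|X) equals the three-entropy form", {
  set.seed(7)
  for (rep in 1:10) {
    dat <- data.frame(x = sample(1:4, 300, TRUE))
    dat$label <- as.integer(dat$x %in% c(1, 3)) + sample(0:1, 300, TRUE)
    mi <- mutual_information(dat, "x", "label")
    # conditional entropy computed independently
    hy_given_x <- 0
    for (v in unique(dat$x)) {
      sub <- dat$label[dat$x == v]
      p <- table(sub) / length(sub)
      hy_given_x <- hy_given_x + (length(sub) / nrow(dat)) * oracle_entropy(p)
    }
    hy <- oracle_entropy(table(dat$label) / nrow(dat))
    expect_equal(mi, hy - hy_given_x, tolerance = 1e-10)
  }
})

test_that("normalized MI has the right endpoints and the worked value", {
  dat <- data.frame(x = rep(1:2, each = 50))
  dat$label <- dat$x
  expect_equal(normalized_mi(dat, "x"), 100)
  dat$label <- rep(1:2, 50)  # independent of x
  expect_equal(normalized_mi(dat, "x"), 0, tolerance = 1e-9)
  dat2 <- joint_to_data(matrix(c(4, 1, 1, 4) * 10, 2, 2))
  expect_equal(mutual_information(dat2, "x"), 0.2781, tolerance = 1e-3)
  expect_equal(normalized_mi(dat2, "x"), 27.81, tolerance = 1e-2)
  dat$label <- 1
  expect_error(normalized_mi(dat, "x"), "degenerate")
})

test_that("phenotype discretization rules behave as documented", {
  scores <- seq(0, 1, length.out = 2025)
  lab <- discretize_phenotype(scores, "top_quantile", q = 0.05)
  expect_equal(sum(lab), 102)   # ceiling(0.05 * 2025)
  expect_true(all(lab[order(-scores)[1:102]] == 1))
  expect_equal(discretize_phenotype(scores, "threshold", t = -1),
               rep(1L, 2025))
  kb <- discretize_phenotype(scores, "k_bins", k = 4)
  expect_equal(as.numeric(table(kb)) / 2025, rep(0.25, 4), tolerance = 0.01)
  expect_error(discretize_phenotype(rep(1, 10), "top_quantile"), "degenerate")
})

test_that("subset enumeration counts and MI monotonicity under refinement", {
  set.seed(11)
  tab <- enumerate_grid(sweep_grid())
  tab$label <- as.integer(tab$tau_ie == 25 & tab$w_ie >= 1.25)
  r1 <- nmi_all_subsets(tab, "label", max_order = 1)
  expect_equal(nrow(r1), 6)
  r2 <- nmi_all_subsets(tab, "label", max_order = 2)
  expect_equal(nrow(r2), 21)
  expect_true(!is.null(attr(r2, "order_summary")))
  r6 <- nmi_all_subsets(tab, "label", max_order = 6)
  expect_equal(nrow(r6), 63)
  full <- r6$nmi_percent[r6$order == 6]
  expect_true(all(full >= r6$nmi_percent - 1e-9))
  # the full subset determines this deterministic label completely
  expect_equal(full, 100)
})

test_that("XOR code is invisible to single parameters but exact for the pair", {
  grid <- sweep_grid(tau_ii = c(6, 25), n_ii = c(1, 0.5))
  tab <- enumerate_grid(grid)
  b1 <- tab$tau_ii != 6
  b2 <- tab$n_ii != 1
  tab$label <- as.integer(xor(b1, b2))
  for (p in c("tau_ie", "tau_ii", "n_ie", "n_ii", "w_ie", "w_ii"))
    expect_lt(normalized_mi(tab, p), 1e-9)
  expect_equal(normalized_mi(tab, c("tau_ii", "n_ii")), 100)
})
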