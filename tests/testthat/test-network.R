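# Network assembly: synaptic defaults, distance-dependent connectivity,
# parameter-vector application, dual-exponential conductances.

test_that("the default synapse table carries the published values", {
  st <- default_synapse_table()
  row <- function(p) st[st$pathway == p, ]
  expect_equal(unlist(row("EE")[, 2:5], use.names = FALSE), c(0.15, 30, 1, 3))
  expect_equal(unlist(row("EI")[, 2:5], use.names = FALSE), c(0.45, 0.1, 3, 3))
  expect_equal(unlist(row("IE")[, 2:5], use.names = FALSE), c(0.60, 0.6, 1, 6))
  expect_equal(unlist(row("II")[, 2:5], use.names = FALSE), c(0.60, 0.15, 1, 6))
  expect_equal(unlist(row("ThE")[, 2:5], use.names = FALSE), c(1.0, 50, 1, 3))
  expect_equal(unlist(row("ThI")[, 2:5], use.names = FALSE), c(0.65, 1.5, 3, 3))
  expect_equal(unlist(row("BgE")[, 2:5], use.names = FALSE), c(1.0, 90, 1, 3))
  # no background drive onto inhibitory cells
  expect_false("BgI" %in% st$pathway)
})

test_that("connection probability decays with distance and preserves the mean", {
  co <- expand.grid(x = 0:23, y = 0:23)
  d <- sqrt(outer(co$x, co$x, "-")^2 + outer(co$y, co$y, "-")^2)
  dv <- d[row(d) != col(d)]
  p1 <- connection_probability(2, 0.15, 4, dv)
  p2 <- connection_probability(8, 0.15, 4, dv)
  expect_gte(p1, p2)
  # lambda -> infinity: uniform at base_p
  expect_equal(connection_probability(c(0, 5, 30), 0.15, 1e9, dv),
               rep(0.15, 3), tolerance = 1e-6)
  # brute-force average over all ordered E->E pairs on the default grid
  pall <- connection_probability(dv, 0.15, 4, dv)
  expect_equal(mean(pall), 0.15, tolerance = 0.001)
  # same holds for the dense I->E probability
  expect_equal(mean(connection_probability(dv, 0.6, 4, dv)), 0.6,
               tolerance = 0.001)
})

test_that("built networks have the right populations and edge statistics", {
  net <- build_network(network_config(seed = 3))
  expect_equal(sum(net$cells$class == "E"), 576)
  expect_equal(sum(net$cells$class == "I"), 144)
  expect_false(any(net$edges$pre == net$edges$post &
                     net$edges$pathway %in% c("EE", "II")))
  # realized I->E count within 5 sigma of Binomial(144*576, 0.6)
  n_ie <- sum(net$edges$pathway == "IE")
  n_pairs <- 144 * 576
  expect_lt(abs(n_ie - n_pairs * 0.6), 5 * sqrt(n_pairs * 0.6 * 0.4))
  # reproducibility
  net2 <- build_network(network_config(seed = 3))
  expect_identical(net$edges, net2$edges)
  net3 <- build_network(network_config(seed = 4))
  expect_false(identical(net$edges, net3$edges))
})

test_that("per-distance connection frequency matches the probability law", {
  # 200 seeds on the 6x6 / 3x3 mini-grid, E->E pathway, 99% binomial bands
  cfg <- micro_network_config()
  co <- expand.grid(x = 0:5, y = 0:5)
  d <- sqrt(outer(co$x, co$x, "-")^2 + outer(co$y, co$y, "-")^2)
  dv <- d[row(d) != col(d)]
  p_theory <- connection_probability(dv, 0.15, 4, dv)
  hits <- numeric(length(dv))
  for (s in 1:200) {
    net <- build_network(micro_network_config(seed = s))
    ee <- net$edges[net$edges$pathway == "EE", ]
    m <- matrix(FALSE, 36, 36)
    m[cbind(ee$pre, ee$post)] <- TRUE
    hits <- hits + as.numeric(m[row(m) != col(m)])
  }
  # pool by unique distance
  for (du in unique(round(dv, 6))) {
    i <- abs(dv - du) < 1e-6
    n <- 200 * sum(i)
    k <- sum(hits[i])
    p <- mean(p_theory[i])
    expect_lt(abs(k - n * p), 2.58 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("parameter vectors validate and apply per pathway", {
  expect_error(parameter_vector(n_ie = 1.2), "removes connections")
  expect_error(parameter_vector(tau_ie = 0), "positive")
  net <- build_network(micro_network_config(seed = 9))
  base_ie <- sum(net$edges$pathway == "IE")
  base_ii <- sum(net$edges$pathway == "II")

  # baseline pv is the identity
  same <- apply_parameter_vector(net, parameter_vector())
  expect_identical(same$edges, net$edges)
  expect_identical(same$synapse_table, net$synapse_table)

  pv <- parameter_vector(tau_ie = 15, tau_ii = 25, n_ie = 0.75, n_ii = 0.5,
                         w_ie = 1.5, w_ii = 0.75)
  mod <- apply_parameter_vector(net, pv, seed = 5)
  expect_equal(sum(mod$edges$pathway == "IE"), round(0.75 * base_ie))
  expect_equal(sum(mod$edges$pathway == "II"), round(0.5 * base_ii))
  expect_equal(unique(mod$edges$weight_ns[mod$edges$pathway == "IE"]),
               0.6 * 1.5)
  expect_equal(unique(mod$edges$weight_ns[mod$edges$pathway == "II"]),
               0.15 * 0.75)
  st <- mod$synapse_table
  expect_equal(st$tau2_ms[st$pathway == "IE"], 15)
  expect_equal(st$tau2_ms[st$pathway == "II"], 25)
  expect_equal(st$tau1_ms[st$pathway == "IE"], 1)   # rise times unchanged
  # pathway independence: tau_ii change leaves I->E records untouched
  only_ii <- apply_parameter_vector(net, parameter_vector(tau_ii = 25))
  expect_identical(only_ii$edges[only_ii$edges$pathway == "IE", ],
                   net$edges[net$edges$pathway == "IE", ])
  # original untouched
  expect_equal(sum(net$edges$pathway == "IE"), base_ie)
})

test_that("pruned connection sets are nested across fraction levels", {
  net <- build_network(micro_network_config(seed = 2))
  key <- function(n, pw) {
    e <- n$edges[n$edges$pathway == pw, ]
    paste(e$pre, e$post)
  }
  k75 <- key(apply_parameter_vector(net, parameter_vector(n_ie = 0.75),
                                    seed = 7), "IE")
  k50 <- key(apply_parameter_vector(net, parameter_vector(n_ie = 0.5),
                                    seed = 7), "IE")
  expect_true(all(k50 %in% k75))
})

test_that("weight multipliers invert exactly", {
  net <- build_network(micro_network_config(seed = 2))
  up <- apply_parameter_vector(net, parameter_vector(w_ie = 1.25))
  down <- up
  down$edges$weight_ns[down$edges$pathway == "IE"] <-
    down$edges$weight_ns[down$edges$pathway == "IE"] / 1.25
  expect_equal(down$edges$weight_ns, net$edges$weight_ns)
})

test_that("dual-exponential conductance has the documented shape", {
  expect_equal(dual_exp_conductance(0, 1, 6), 0)
  tp <- (1 * 6 / (6 - 1)) * log(6 / 1)
  expect_equal(dual_exp_conductance(tp, 1, 6, g_peak = 0.6), 0.6)
  # brute-force maximum over a dense grid equals g_peak
  tt <- seq(0, 60, by = 0.001)
  g <- dual_exp_conductance(tt, 1, 6, g_peak = 0.6)
  expect_equal(max(g), 0.6, tolerance = 1e-6)
  expect_equal(tt[which.max(g)], tp, tolerance = 1e-2)
  # the late tail is NOT below 1% of peak at 25 ms for tau2 = 6
  expect_gt(dual_exp_conductance(25, 1, 6, 0.6), 0.01 * 0.6)
  # alpha-function limit
  expect_equal(dual_exp_conductance(3, 3, 3, 2), 2)
  a <- dual_exp_conductance(seq(0, 30, 0.01), 3, 3, 2)
  expect_equal(max(a), 2, tolerance = 1e-9)
  expect_error(dual_exp_conductance(1, 6, 3), "tau1")
})

test_that("networks serialize to a JSON header plus CSV edge list", {
  net <- build_network(micro_network_config(seed = 11))
  d <- tempfile("net_")
  write_network(net, d)
  hdr <- jsonlite::read_json(file.path(d, "network.json"),
                             simplifyVector = TRUE)
  expect_equal(hdr$seed, 11)
  edges <- read.csv(file.path(d, "edges.csv"))
  expect_equal(nrow(edges), nrow(net$edges))
  expect_true(all(c("pre", "post", "pathway", "weight_ns", "tau2_ms") %in%
                    names(edges)))
  unlink(d, recursive = TRUE)
})
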