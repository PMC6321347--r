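test_that("two-channel branching matches the analytic ratio", {
  net <- make_toy_network("two_channel", k1 = 2, k2 = 1)
  rates <- network_rates(net, T = 300)
  res <- run_kmc(net, rates, kmc_config(replicas = 2000, t_max = 50,
                                        seed = 101))
  p <- 2 / 3
  tol3 <- 3 * sqrt(p * (1 - p) / 2000)
  expect_equal(dplyr::filter(res$branching, .data$species == "B")$fraction,
               p, tolerance = tol3 / p)
  expect_equal(sum(res$branching$fraction), 1)
})

test_that("single-channel decay reproduces the exponential law", {
  net <- make_toy_network("two_channel", k1 = 1, k2 = 0)
  rates <- network_rates(net, T = 300)
  res <- run_kmc(net, rates,
                 kmc_config(replicas = 4000, t_max = 5, seed = 102,
                            t_grid_n = 51))
  # survival at t = 1 is e^-1; binomial 3-sigma band
  pA <- dplyr::filter(tidy(res), .data$species == "A",
                      abs(.data$time - 1) < 1e-9)$population
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 4000)
  expect_lt(abs(pA - exp(-1)), 3 * se)
})

test_that("KMC means track the ODE master-equation oracle", {
  net <- make_toy_network("sequential", k1 = 1, k2 = 1)
  rates <- network_rates(net, T = 300)
  cfg <- kmc_config(replicas = 4000, t_max = 6, seed = 103,
                    initial = c(A = 1), t_grid_n = 25)
  res <- run_kmc(net, rates, cfg)
  ode <- ode_reference(net, rates, c(A = 1), res$times)
  # p_B(t) = t e^-t for equal rates
  expect_equal(ode$B, res$times * exp(-res$times), tolerance = 1e-5)
  for (sp in c("A", "B", "C")) {
    p <- ode[[sp]]
    se <- sqrt(pmax(p * (1 - p), 1e-12) / cfg$replicas)
    expect_true(all(abs(res$populations[[sp]] - p) <= 3 * se + 1e-9),
                info = sp)
  }
})

test_that("symmetric isomerization equilibrates to one half", {
  net <- reaction_network(
    wells = list(well("A", 0, 1000), well("B", 0, 1000)),
    transition_states = list(
      ts_record("TS", 10, 900, c("A", "B"), rate_fwd = 3, rate_rev = 3)))
  rates <- network_rates(net, T = 300)
  res <- run_kmc(net, rates,
                 kmc_config(replicas = 3000, t_max = 5, seed = 104))
  tail_A <- utils::tail(res$populations$A, 1)
  expect_lt(abs(tail_A - 0.5), 3 * sqrt(0.25 / 3000))
  ode <- ode_reference(net, rates, c(A = 1), c(0, 50))
  expect_equal(ode$A[2], 0.5, tolerance = 1e-6)
})

test_that("a dead network leaves populations untouched", {
  net <- make_toy_network("two_channel", k1 = 0, k2 = 0)
  rates <- network_rates(net, T = 300)
  res <- run_kmc(net, rates, kmc_config(replicas = 50, t_max = 1, seed = 105))
  expect_true(all(res$populations$A == 1))
  expect_equal(res$n_events, 0L)
  expect_true(all(is.na(res$branching$fraction)))
})

test_that("molecule count is conserved in unimolecular networks", {
  net <- make_toy_network("sequential")
  rates <- network_rates(net, T = 300)
  res <- run_kmc(net, rates, kmc_config(replicas = 500, t_max = 3,
                                        seed = 106, initial = c(A = 7)))
  totals <- rowSums(res$populations[, -1])
  expect_equal(totals, rep(7, length(totals)))
})

test_that("a fixed master seed reproduces the run bit-exactly", {
  net <- make_toy_network("two_channel")
  rates <- network_rates(net, T = 300)
  cfg <- kmc_config(replicas = 400, t_max = 20, seed = 999)
  r1 <- run_kmc(net, rates, cfg)
  r2 <- run_kmc(net, rates, cfg)
  expect_identical(r1$n_events, r2$n_events)
  expect_identical(r1$branching, r2$branching)
  expect_identical(r1$populations, r2$populations)
  r3 <- run_kmc(net, rates, kmc_config(replicas = 400, t_max = 20,
                                       seed = 1000))
  expect_false(identical(r1$branching$count, r3$branching$count))
})

test_that("species without outgoing channels are warned about and absorbed", {
  net <- reaction_network(
    wells = list(well("A", 0, 1000), well("B", -5, 1000)),  # B not a sink
    transition_states = list(
      ts_record("TS", 10, 900, c("A", "B"), rate_fwd = 2)))
  rates <- network_rates(net, T = 300)
  expect_warning(
    res <- run_kmc(net, rates, kmc_config(replicas = 100, t_max = 10,
                                          seed = 107)),
    "treated as sink")
  expect_equal(res$branching$species, "B")
  expect_equal(res$branching$fraction, 1)
})

test_that("doubling replicas roughly halves the branching variance", {
  net <- make_toy_network("two_channel")
  rates <- network_rates(net, T = 300)
  est <- function(reps, seed) {
    res <- run_kmc(net, rates, kmc_config(replicas = reps, t_max = 50,
                                          seed = seed))
    dplyr::filter(res$branching, .data$species == "B")$fraction
  }
  f1 <- vapply(1:40, function(s) est(250, 2000 + s), numeric(1))
  f2 <- vapply(1:40, function(s) est(500, 4000 + s), numeric(1))
  ratio <- stats::var(f1) / stats::var(f2)
  # F-distributed around 2; generous band
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.4)
})

test_that("branching scans sweep the energy grid deterministically", {
  net <- make_toy_network("vcn_like", barriers = c(60, 65, 70))
  cfg <- kmc_config(replicas = 200, t_max = 1e-3, seed = 7,
                    initial = c(R = 1))
  grid <- c(75, 100, 148)
  s1 <- branching_scan(net, cfg, grid, mode = "E")
  s2 <- branching_scan(net, cfg, grid, mode = "E")
  expect_identical(s1$fraction, s2$fraction)
  sums <- dplyr::summarise(dplyr::group_by(s1, .data$grid),
                           total = sum(.data$fraction))
  expect_equal(sums$total, rep(1, length(grid)), tolerance = 1e-9)
})

test_that("the lower barrier dominates near its threshold in RRKM branching", {
  # two competing unimolecular channels, barriers 60 and 65 kcal/mol
  net <- reaction_network(
    wells = list(well("A", 0, c(317, 523, 749, 1102, 1367, 2843)),
                 well("P1", -20, c(300, 800, 1500), sink = TRUE),
                 well("P2", -25, c(350, 900, 1600), sink = TRUE)),
    transition_states = list(
      ts_record("TSa", 60, c(600, 902, 1136, 1800, 2511), c("A", "P1")),
      ts_record("TSb", 65, c(580, 930, 1100, 1750, 2490), c("A", "P2"))))
  cfg <- kmc_config(replicas = 400, t_max = 1, seed = 8, initial = c(A = 1))
  near <- branching_scan(net, cfg, c(62), mode = "E")
  expect_equal(dplyr::filter(near, .data$species == "P1")$fraction, 1)
  high <- branching_scan(net, cfg, c(110), mode = "E")
  expect_lt(dplyr::filter(high, .data$species == "P1")$fraction, 1)
})
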