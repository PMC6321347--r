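test_that("path degeneracy is the optical-isomer ratio", {
  expect_equal(path_degeneracy(1, 2), 2)
  expect_equal(path_degeneracy(1, 1), 1)
  expect_equal(path_degeneracy(2, 1), 0.5)
  expect_equal(path_degeneracy(1, 2, symm_reactant = 3, symm_ts = 1), 6)
  expect_error(path_degeneracy(0, 1), ">= 1")
  expect_error(path_degeneracy(1, -2), ">= 1")
})

test_that("Eyring rate reproduces the universal frequency factor", {
  # kB * 298.15 / h, evaluated independently from CODATA values
  expect_equal(tst_rate(0, 298.15), 6.2124380e12, tolerance = 1e-6)
  # linearity in the path degeneracy
  expect_equal(tst_rate(12, 423, sigma = 2), 2 * tst_rate(12, 423))
  # a barrier of RT ln(10) costs exactly one decade
  T <- 298.15
  dG <- mech_constants$R_kcal * T * log(10)
  expect_equal(tst_rate(dG, T), tst_rate(0, T) / 10, tolerance = 1e-12)
  # monotone increasing in T at fixed non-negative barrier
  ks <- vapply(seq(200, 2000, by = 200), tst_rate, numeric(1),
               dG_ddag = 5, sigma = 1, delta_n = 0)
  expect_true(all(diff(ks) > 0))
  # bimolecular rates carry the standard-state volume factor
  expect_equal(tst_rate(0, 300, delta_n = 1) / tst_rate(0, 300),
               mech_constants$R_J * 300 / 1e5 * 1e6 / mech_constants$NA_mol)
  expect_error(tst_rate(5, -10), "positive")
})

test_that("Beyer-Swinehart reproduces worked direct counts", {
  sc <- beyer_swinehart(100, E_max = 400, grain = 10)
  expect_equal(state_count_W(sc, 350), 4)  # levels 0, 100, 200, 300
  expect_equal(state_count_W(sc, 0), 1)
  sc2 <- beyer_swinehart(c(100, 100), E_max = 300, grain = 10)
  expect_equal(state_count_W(sc2, 250), 6)
  expect_error(beyer_swinehart(numeric(), 100, 10), "non-empty")
  expect_error(beyer_swinehart(100, -5, 10), "non-negative")
})

test_that("Beyer-Swinehart equals brute-force enumeration", {
  set.seed(51)
  for (grain in c(1, 10)) {
    for (k in 1:12) {
      n_modes <- sample(1:4, 1)
      freqs <- sample(seq(200, 2000, by = 10), n_modes, replace = TRUE)
      sc <- beyer_swinehart(freqs, E_max = 5000, grain = grain)
      for (E in c(0, sort(sample(100:5000, 4)))) {
        expect_equal(state_count_W(sc, E), enumerate_states(freqs, E),
                     info = paste("freqs", paste(freqs, collapse = ","),
                                  "E", E, "grain", grain))
      }
    }
  }
})

test_that("sums of states are non-decreasing and stable under grain refinement", {
  freqs <- c(310, 420, 870, 1200, 1520, 2930, 3100)
  sc <- beyer_swinehart(freqs, E_max = 12000, grain = 10)
  expect_true(all(diff(sc$W) >= 0))
  sc5 <- beyer_swinehart(freqs, E_max = 12000, grain = 5)
  E_chk <- seq(2000, 12000, by = 500)
  rel <- abs(state_count_W(sc5, E_chk) - state_count_W(sc, E_chk)) /
    state_count_W(sc, E_chk)
  expect_true(all(rel < 0.01))
})

test_that("RRKM rates respect thresholds, degeneracy and the state-count oracle", {
  w <- well("A", 0, freqs = c(317, 523, 749, 1102, 1367, 2843))
  ts <- ts_record("TS", 20, freqs = c(600, 902, 1136, 1800, 2511), c("A", "B"))
  expect_equal(rrkm_rate(w, ts, E_total = 15), 0)    # below the barrier
  k1 <- rrkm_rate(w, ts, E_total = 40)
  expect_gt(k1, 0)
  expect_equal(rrkm_rate(w, ts, E_total = 40, sigma = 2), 2 * k1)
  expect_error(rrkm_rate(well("A", 50, 1000), ts, E_total = 40),
               "inaccessible")

  # zero-barrier, equal-frequency toy against brute-force enumeration:
  # with grain = level spacing, rho = 1/spacing and W/(h rho) is exact
  nu <- 100
  w0 <- well("A", 0, nu)
  ts0 <- ts_record("TS0", 0, nu, c("A", "B"))
  E <- 3  # kcal/mol
  E_cm <- E * mech_constants$kcal_to_cm
  k <- rrkm_rate(w0, ts0, E, grain = nu)
  W_oracle <- enumerate_states(nu, nu * floor(E_cm / nu))
  rho_oracle <- 1 / nu  # one state per level spacing
  expect_equal(k, mech_constants$c_cm * W_oracle / rho_oracle,
               tolerance = 1e-12)
})

test_that("Eckart correction has the classical and Wigner limits", {
  expect_equal(eckart_correction(10, 10, 0, 300), 1)
  expect_lt(abs(eckart_correction(10, 10, 1e-6, 300) - 1), 1e-6)
  # less tunneling when hot
  Ts <- c(250, 300, 400, 600, 1000)
  kappas <- vapply(Ts, eckart_correction, numeric(1),
                   dE_forward = 10, dE_reverse = 10, imag_freq = 1000)
  expect_true(all(diff(kappas) < 0))
  expect_true(all(kappas > 1))
  # symmetric barrier, small hc*nu/kB*T: kappa - 1 -> (hc nu / kB T)^2 / 24
  u <- mech_constants$c2_cmK * 20 / 300
  kappa <- eckart_correction(80, 80, 20, 300)
  expect_equal(kappa - 1, u^2 / 24, tolerance = 0.01)
  # asymmetric barriers are accepted, non-positive ones are not
  expect_gt(eckart_correction(12, 4, 900, 300), 1)
  expect_error(eckart_correction(-1, 5, 900, 300), "positive")
})
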