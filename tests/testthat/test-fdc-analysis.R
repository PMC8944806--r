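test_that("cycle averaging: identity, cancellation, 1/sqrt(n) shrinkage", {
  m <- toy_rv5_model()
  base <- equilibrium_fdc(m, default_separations(m, step = 1))
  avg1 <- average_cycles(base)
  expect_equal(avg1$separation_nm, base$separation_nm)
  expect_equal(avg1$force_pN, base$force_pN)
  # equal and opposite noise cancels exactly
  up <- base; up$force_pN <- up$force_pN + 0.4; up$cycle <- 1L
  dn <- base; dn$force_pN <- dn$force_pN - 0.4; dn$cycle <- 2L
  both <- average_cycles(dplyr::bind_rows(up, dn))
  expect_equal(both$force_pN, base$force_pN, tolerance = 1e-12)
  expect_error(average_cycles(base[0, ]), "empty")
  # Monte-Carlo: averaging error shrinks like 1/sqrt(cycles)
  rms_for <- function(n_cyc, seed) {
    nm <- noise_model(instrument_sigma = 0.5, thermal_from_stiffness = FALSE,
                      seed = seed, offset_sigma_force = 0,
                      offset_sigma_distance = 0)
    avg <- average_cycles(generate_fdc_cycles(m, nm, n_cycles = n_cyc))
    truth <- equilibrium_fdc(m, avg$separation_nm)$force_pN
    sqrt(mean((avg$force_pN - truth)^2))
  }
  r4 <- mean(vapply(1:4, function(s) rms_for(4L, s), numeric(1)))
  r36 <- mean(vapply(1:4, function(s) rms_for(36L, s), numeric(1)))
  expect_gt(r4 / r36, 3 * 0.6)
  expect_lt(r4 / r36, 3 / 0.6)
})

test_that("alignment recovers constructed offsets and is idempotent", {
  m <- toy_rv5_model()
  base <- equilibrium_fdc(m, default_separations(m, step = 1))
  a <- base; a$cycle <- 1L
  b <- base; b$cycle <- 2L
  same <- align_fdcs(dplyr::bind_rows(a, b))
  expect_equal(same$force_offset, c(0, 0), tolerance = 1e-6)
  expect_equal(same$distance_offset, c(0, 0), tolerance = 1e-4)
  shifted <- b
  shifted$force_pN <- shifted$force_pN + 0.5
  shifted$separation_nm <- shifted$separation_nm + 3
  off <- align_fdcs(dplyr::bind_rows(a, shifted))
  expect_equal(off$force_offset[2], -0.5, tolerance = 0.05)
  expect_equal(off$distance_offset[2], -3, tolerance = 0.25)
  aligned <- apply_alignment(dplyr::bind_rows(a, shifted), off)
  again <- align_fdcs(aligned)
  expect_equal(again$force_offset[2], 0, tolerance = 0.05)
  expect_equal(again$distance_offset[2], 0, tolerance = 0.25)
})

test_that("plateau force estimation: generator truth and noiseless constant", {
  set.seed(21)
  d <- seq(100, 220, by = 0.5)
  flat <- as_fdc(tibble::tibble(separation_nm = d,
                                force_pN = 9.5 + rnorm(length(d), 0, 0.5)))
  est <- plateau_force(flat, window = c(100, 220))
  expect_equal(est$plateau_force_pN, 9.5, tolerance = 0.05)
  expect_equal(est$plateau_sigma_pN, 0.5, tolerance = 0.15)
  const <- as_fdc(tibble::tibble(separation_nm = d, force_pN = 7.25))
  est2 <- plateau_force(const, window = c(100, 220))
  expect_equal(est2$plateau_force_pN, 7.25, tolerance = 0.05)
  expect_lt(est2$plateau_sigma_pN, 0.2)
})

test_that("unfolding work: zero protein, partition-function oracle, N-scaling", {
  m <- toy_rv5_model()
  d <- default_separations(m, step = 0.5)
  ref <- unfolded_reference_fdc(m, d)
  expect_equal(unfolding_work(ref, m), 0, tolerance = 1e-9)
  fdc <- equilibrium_fdc(m, d)
  wf <- unfolding_work(fdc, m)
  expect_lt(wf, 0)
  # oracle: difference of log partition-function ratios at the endpoints
  a <- fdc_free_energy(m, range(d))$free_energy_kT
  a_unf <- vapply(range(d), function(x) {
    configuration_total_energy(m, rep(0, m$n_units), x)
  }, numeric(1))
  oracle <- (a[1] - a_unf[1]) - (a[2] - a_unf[2])
  expect_equal(wf, oracle, tolerance = 0.05 * abs(oracle))
  # folding work magnitude grows with repeat number (Table parameter sets)
  m10 <- ctpr_model_preset("ctprrv10", approximation = "zipper")
  w10 <- unfolding_work(equilibrium_fdc(m10), m10)
  expect_gt(abs(w10), abs(wf))
})

test_that("contour-length gain: generator truth and linear N-scaling", {
  gains <- vapply(c(5L, 10L, 20L), function(n) {
    m <- ctpr_model_preset("ctprrv", n_repeats = n, approximation = "zipper")
    fdc <- equilibrium_fdc(m, default_separations(m, step = 0.5))
    contour_length_gain(fdc, m$network)$contour_gain_nm
  }, numeric(1))
  expect_equal(gains[1], 5 * 34 * 0.365, tolerance = 0.03)
  fitN <- stats::lm(gains ~ c(5, 10, 20))
  expect_equal(unname(stats::coef(fitN)[2]), 34 * 0.365, tolerance = 0.05)
})
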