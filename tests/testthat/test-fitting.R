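test_that("noiseless self-consistency: exact parameter recovery", {
  m <- toy_rv5_model()
  nm0 <- noise_model(instrument_sigma = 0, thermal_from_stiffness = FALSE,
                     seed = 3, offset_sigma_force = 0,
                     offset_sigma_distance = 0)
  # bin width equal to the generation grid: averaging is the identity
  avg <- average_cycles(generate_fdc_cycles(m, nm0, n_cycles = 1),
                        bin_width = 0.25)
  fit <- fit_fdc(avg, 5, geometry = m$geometry)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est["dG_unit"]), 1.5, tolerance = 1e-3)
  expect_equal(unname(est["dG_nn"]), -11.8, tolerance = 1e-3)
  expect_equal(unname(est["d_offset"]), 0, tolerance = 1e-2)
  en <- fit_repeat_energies(fit)
  expect_equal(en$dG_tot, total_free_energy(repeat_params(1.5, -11.8),
                                            n_repeats = 5), tolerance = 1e-2)
})

test_that("AIC table: formula, ranking and the useless-parameter penalty", {
  fake <- function(k, rss) {
    structure(list(variant = paste0("k", k), approximation = "zipper",
                   n = 100L, k = k, rss = rss, sigma = sqrt(rss / (100 - k)),
                   data = tibble::tibble(separation_nm = 1:3,
                                         force_pN = 1:3)),
              class = "ctpr_fit")
  }
  cmp <- compare_models(fake(4, 2), fake(6, 2))
  expect_identical(cmp$variant[1], "k4")
  expect_equal(cmp$delta_aic[2], 4)
  mismatched <- fake(4, 2)
  mismatched$data$force_pN <- c(9, 9, 9)
  expect_error(compare_models(fake(4, 2), mismatched), "identical data")
})

test_that("disabling the superhelix geometry worsens the fit of oscillating data", {
  m <- ctpr_model_preset("ctprrv10", approximation = "zipper")
  nm0 <- noise_model(0, FALSE, seed = 1, offset_sigma_force = 0,
                     offset_sigma_distance = 0)
  avg <- average_cycles(generate_fdc_cycles(m, nm0, n_cycles = 1))
  f_geom <- fit_fdc(avg, 10, geometry = m$geometry)
  f_beads <- fit_fdc(avg, 10, geometry = m$geometry,
                     extension_model = "beads")
  expect_gt(f_beads$rss, 10 * f_geom$rss)
})

test_that("parameter recovery across the energy grid at default noise", {
  grid <- expand.grid(dG_unit = c(-3, -0.5, 2), dG_nn = c(-14, -11.5, -9))
  errs <- purrr::map(seq_len(nrow(grid)), function(i) {
    hp <- helix_params_from_repeat(
      repeat_params(grid$dG_unit[i], grid$dG_nn[i]), split = "asymmetric")
    m <- ctpr_model(5, hp, approximation = "zipper")
    cyc <- generate_fdc_cycles(m, noise_model(seed = 40 + i), n_cycles = 30)
    avg <- average_cycles(apply_alignment(cyc, align_fdcs(cyc)))
    fit <- fit_fdc(avg, 5)
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    c(abs(est[["dG_unit"]] - grid$dG_unit[i]),
      abs(est[["dG_nn"]] - grid$dG_nn[i]))
  })
  expect_lt(median(unlist(errs)), 0.3)
})

test_that("variant ordering survives the fit: CTPRa sums below CTPRrv", {
  fitted_sum <- function(preset, n) {
    m <- ctpr_model_preset(preset, n_repeats = n, approximation = "zipper")
    cyc <- generate_fdc_cycles(m, noise_model(seed = 9), n_cycles = 20)
    avg <- average_cycles(apply_alignment(cyc, align_fdcs(cyc)))
    en <- fit_repeat_energies(fit_fdc(avg, n, geometry = m$geometry))
    en$dG_unit + en$dG_nn
  }
  expect_lt(fitted_sum("ctpra", 5), fitted_sum("ctprrv", 5))
})

test_that("global denaturation fit: exact recovery and midpoint ordering", {
  rp <- repeat_params(0.20, -6.8)
  dn <- generate_denaturation(rp, m_unit = 2.2, lengths = c(2L, 5L, 10L),
                              sigma = 0, seed = 1)
  fit <- fit_denaturation(dn, start = c(dG_unit = 0, m_unit = 2, dG_nn = -5))
  g <- glance(fit)
  expect_equal(g$dG_unit, 0.20, tolerance = 1e-3)
  expect_equal(g$dG_nn, -6.8, tolerance = 1e-3)
  expect_equal(g$m_unit, 2.2, tolerance = 1e-3)
  expect_equal(fit$totals$dG_tot[fit$totals$n_repeats == 5],
               total_free_energy(repeat_params(g$dG_unit, g$dG_nn),
                                 n_repeats = 5), tolerance = 1e-6)
  mids <- vapply(c(2, 5, 10), function(n) {
    denaturation_midpoint(rp, 2.2, n)
  }, numeric(1))
  expect_true(all(diff(mids) > 0))
  expect_warning(fit_denaturation(dn[dn$n_repeats == 5, ]), "lengths")
})
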