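test_that("synthetic cycles: determinism, noiseless exactness, offsets", {
  m <- toy_rv5_model()
  c1 <- generate_fdc_cycles(m, noise_model(seed = 5), n_cycles = 4)
  c2 <- generate_fdc_cycles(m, noise_model(seed = 5), n_cycles = 4)
  expect_identical(c1$force_pN, c2$force_pN)
  expect_identical(c1$separation_nm, c2$separation_nm)
  c3 <- generate_fdc_cycles(m, noise_model(seed = 6), n_cycles = 4)
  expect_false(identical(c1$force_pN, c3$force_pN))
  # zero noise reproduces the model curve in every cycle
  nm0 <- noise_model(0, FALSE, seed = 1, offset_sigma_force = 0,
                     offset_sigma_distance = 0)
  cyc <- generate_fdc_cycles(m, nm0, n_cycles = 2)
  base <- equilibrium_fdc(m, default_separations(m, step = 0.25))
  one <- cyc[cyc$cycle == 1L, ]
  expect_equal(one$force_pN, base$force_pN, tolerance = 1e-12)
  two <- cyc[cyc$cycle == 2L, ]  # relax sweep runs backwards
  expect_identical(two$direction[1], "relax")
  expect_equal(rev(two$force_pN), base$force_pN, tolerance = 1e-12)
  expect_identical(sort(unique(cyc$direction)), c("relax", "stretch"))
})

test_that("plateau noise exceeds linker-branch noise (fast fluctuations)", {
  m <- toy_rv5_model()
  nm <- noise_model(seed = 5, offset_sigma_force = 0,
                    offset_sigma_distance = 0)
  cyc <- generate_fdc_cycles(m, nm, n_cycles = 20)
  base <- equilibrium_fdc(m, default_separations(m, step = 0.25),
                          detail = TRUE)
  w <- detect_plateau_window(base)
  str_c <- cyc[cyc$direction == "stretch", ]
  resid <- str_c$force_pN - rep(base$force_pN, length(unique(str_c$cycle)))
  plat <- str_c$separation_nm > w[1] & str_c$separation_nm < w[2]
  pre <- str_c$separation_nm < w[1] - 15 & str_c$force_pN > 2
  expect_gt(sd(resid[plat]), sd(resid[pre]))
})

test_that("denaturation generator: smooth sigmoids with ordered midpoints", {
  rp <- repeat_params(0.20, -6.8)
  dn <- generate_denaturation(rp, m_unit = 2.2, lengths = c(3L, 5L, 10L),
                              sigma = 0, seed = 2)
  expect_true(all(dn$fraction_folded >= 0 & dn$fraction_folded <= 1))
  # monotone decay in denaturant for every length
  for (n in unique(dn$n_repeats)) {
    phi <- dn$fraction_folded[dn$n_repeats == n]
    expect_true(all(diff(phi) < 1e-8))
  }
  # reproducibility by seed
  dn2 <- generate_denaturation(rp, m_unit = 2.2, lengths = c(3L, 5L, 10L),
                               sigma = 0.01, seed = 7)
  dn3 <- generate_denaturation(rp, m_unit = 2.2, lengths = c(3L, 5L, 10L),
                               sigma = 0.01, seed = 7)
  expect_identical(dn2$signal, dn3$signal)
  # the transfer-matrix recursion used for long arrays agrees with exact
  # enumeration where both apply (the switch sits at N = 15)
  phi15 <- repeatspring:::ising_fraction_folded(-0.5, -4, 15L)
  phi16 <- repeatspring:::ising_fraction_folded(-0.5, -4, 16L)
  expect_lt(abs(phi15 - phi16), 0.02)
})

test_that("FDC round trips through delimited text", {
  m <- toy_rv5_model()
  cyc <- generate_fdc_cycles(m, noise_model(seed = 2), n_cycles = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fdc(cyc, path)
  back <- read_fdc(path)
  expect_equal(back$force_pN, cyc$force_pN, tolerance = 1e-9)
  expect_identical(back$direction, cyc$direction)
})
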