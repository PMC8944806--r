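test_that("limiting curves: always-unfolded and deeply folded branches", {
  m <- toy_rv5_model()
  d <- default_separations(m, step = 2)
  # all states forced unfolded: handle + full chain response
  ref <- unfolded_reference_fdc(m, d)
  direct <- vapply(d, function(x) {
    series_force_balance(x, m$network, 0, max(m$lc_unfolded))
  }, numeric(1))
  expect_equal(ref$force_pN, direct, tolerance = 1e-6)
  # fold energies -> -Inf limit: handle + rigid rod (fully folded branch)
  deep <- ctpr_model(5, helix_params(-20, -20, -20, -20),
                     geometry = m$geometry, approximation = "zipper")
  dlo <- d[d > deep$xi_max + 1 & d < min(d) + 40]
  fdeep <- equilibrium_fdc(deep, dlo)$force_pN
  rigid <- vapply(dlo, function(x) {
    series_force_balance(x, m$network, deep$xi_max, 0)
  }, numeric(1))
  expect_equal(fdeep, rigid, tolerance = 1e-4)
})

test_that("zipper and full enumerations agree for short arrays", {
  hp <- helix_params_from_repeat(repeat_params(-1.9, -12.7),
                                 split = "asymmetric")
  g <- superhelix_geometry()
  for (n in 2:3) {
    mz <- ctpr_model(n, hp, geometry = g, approximation = "zipper")
    mf <- ctpr_model(n, hp, geometry = g, approximation = "full")
    ms <- ctpr_model(n, hp, geometry = g, approximation = "skip")
    d <- default_separations(mf, step = 1)
    fz <- equilibrium_fdc(mz, d)$force_pN
    ff <- equilibrium_fdc(mf, d)$force_pN
    fs <- equilibrium_fdc(ms, d)$force_pN
    expect_lt(max(abs(fz - ff)), 0.05)
    expect_lt(max(abs(fs - ff)), 0.05)
  }
})

test_that("total configuration energy composes the module energies", {
  m <- ctpr_model(2, helix_params_from_repeat(repeat_params(-1.9, -12.7)),
                  approximation = "full")
  slack <- m$xi_max * 0  # fully unfolded has no rigid extension
  expect_equal(configuration_total_energy(m, rep(0, 4), slack), 0)
  s <- c(1, 1, 0, 0)
  d0 <- 800
  e <- configuration_total_energy(m, s, d0)
  # composition oracle from the public module operations
  xi <- extension_for_configuration(s, m$geometry)
  lc <- (2 * 17 * 0.365)  # two unfolded helices
  f <- series_force_balance(d0, m$network, xi, lc)
  chain <- wlc_chain(m$network$chain_Lp, lc, m$network$kT)
  mech <- 2 * stretch_free_energy(f, harmonic_element(0.3)) +
    stretch_free_energy(f, m$network$handle) +
    stretch_free_energy(f, chain)
  oracle <- config_fold_energy(s, m$params) + mech / m$network$kT
  expect_equal(e, oracle, tolerance = 1e-4)
})

test_that("ensemble snapshots: normalization, extremes, brute-force marginals", {
  hp <- helix_params_from_repeat(repeat_params(-1.9, -12.7),
                                 split = "asymmetric")
  m <- ctpr_model(3, hp, approximation = "full")
  d <- default_separations(m, step = 1)
  lo <- ensemble_snapshot(m, d[3])
  expect_identical(lo$configurations$fold_state[1], paste(rep(1, 6),
                                                          collapse = ""))
  expect_gt(lo$configurations$probability[1], 0.95)
  hi <- ensemble_snapshot(m, d[length(d) - 2])
  expect_identical(hi$configurations$fold_state[1], paste(rep(0, 6),
                                                          collapse = ""))
  dmid <- unfolded_midpoint_separation(m, 0.2)
  snap <- ensemble_snapshot(m, dmid, k = 64)
  expect_equal(sum(snap$configurations$probability), 1, tolerance = 1e-9)
  # marginalization oracle over all 64 states via the public energy op
  states <- enumerate_configurations(6, "full")
  e <- apply(states, 1, function(s) configuration_total_energy(m, s, dmid))
  w <- exp(-(e - min(e)))
  p <- w / sum(w)
  marg_oracle <- as.numeric(crossprod(states, p))
  expect_equal(snap$marginals$p_folded, marg_oracle, tolerance = 1e-4)
})

test_that("force integral equals the free-energy difference (thermo identity)", {
  m <- toy_rv5_model()
  d <- default_separations(m, step = 0.25)
  fdc <- equilibrium_fdc(m, d)
  a <- fdc_free_energy(m, d)$free_energy_kT
  n <- length(d)
  w_quad <- sum((fdc$force_pN[-1] + fdc$force_pN[-n]) / 2 * diff(d)) /
    m$network$kT
  expect_equal(w_quad, a[n] - a[1], tolerance = 1e-3)
  # force-averaging and free-energy-derivative routes coincide
  f2 <- fdc_from_free_energy(m, d)
  expect_lt(max(abs(f2$force_pN - fdc$force_pN[2:(n - 1)])), 0.05)
})

test_that("seed size: two-state toy and array-length invariance", {
  toy <- ctpr_model(1, helix_params(0, 0, -30, -30), approximation = "full")
  expect_equal(seed_size(toy), 2, tolerance = 1e-3)
  m10 <- ctpr_model_preset("ctprrv", n_repeats = 10, approximation = "zipper")
  m20 <- ctpr_model_preset("ctprrv", n_repeats = 20, approximation = "zipper")
  s10 <- seed_size(m10)
  s20 <- seed_size(m20)
  expect_lt(abs(s10 - s20), 0.3)
  expect_gt(s10, 3)  # a multi-helix marginal ensemble, not a lone repeat
})

test_that("unzipping starts at the C-terminal helix in preset models", {
  for (preset in c("ctpra5", "ctprrv5")) {
    m <- ctpr_model_preset(preset, approximation = "skip")
    pr <- helix_fold_profile(m)
    expect_true(all(pr$p_folded >= 0 & pr$p_folded <= 1))
    first_below <- function(h) {
      sub <- pr[pr$helix == h, ]
      sub$separation_nm[which(sub$p_folded < 0.5)[1]]
    }
    expect_lt(first_below(0), first_below(max(pr$helix)))
    # everything folded at small separations
    d1 <- min(pr$separation_nm)
    expect_true(all(pr$p_folded[pr$separation_nm == d1] > 0.95))
  }
})

test_that("apparatus stiffness controls the sawtooth signature", {
  mank <- ctpr_model(5, repeat_params(-10, -2), approximation = "zipper",
                     extension_model = "beads",
                     geometry = superhelix_geometry(radius = 0,
                                                    rise_per_repeat = 1.2,
                                                    terminal_offset = 1))
  soft <- equilibrium_fdc(mank)
  expect_identical(nrow(find_force_peaks(soft, 0.25)), 0L)
  stiff100 <- simulate_apparatus_stiffness(mank, 100)
  pk100 <- find_force_peaks(stiff100, 1)
  expect_identical(nrow(pk100), 5L)
  # prominence grows further towards the rigid limit
  stiff400 <- simulate_apparatus_stiffness(mank, 400)
  pk400 <- find_force_peaks(stiff400, 1)
  expect_identical(nrow(pk400), 5L)
  expect_gt(min(pk400$prominence), min(pk100$prominence))
})

test_that("superhelical plateau oscillations and the beads comparison", {
  m20 <- ctpr_model_preset("ctprrv20", approximation = "zipper")
  f20 <- equilibrium_fdc(m20)
  expect_identical(count_plateau_oscillations(f20), 2L)
  m26 <- ctpr_model_preset("ctprrv26", approximation = "zipper")
  f26 <- equilibrium_fdc(m26)
  expect_identical(count_plateau_oscillations(f26), 3L)
  # beads-on-string extension flattens the plateau
  m20b <- ctpr_model_preset("ctprrv20", approximation = "zipper",
                            extension_model = "beads")
  f20b <- equilibrium_fdc(m20b, f20$separation_nm)
  w <- detect_plateau_window(f20)
  amp <- function(f) sd(detrend_plateau(f, w)$residual_pN)
  expect_lt(amp(f20b), amp(f20))
})
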