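test_that("Marko-Siggia force law: zero point, mid-chain value, monotonicity", {
  ch <- wlc_chain(0.9, 100, 4.114)
  expect_identical(wlc_force(0, ch), 0)
  # direct evaluation at x/Lc = 1/2: 1.25 kT/Lp
  expect_equal(wlc_force(50, ch), 1.25 * 4.114 / 0.9, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    chain <- wlc_chain(runif(1, 0.5, 50), runif(1, 50, 400))
    expect_gt(wlc_force(0.6 * chain$contour_length, chain),
              wlc_force(0.5 * chain$contour_length, chain))
  }
  expect_error(wlc_force(100, ch), "contour_length")
})

test_that("extension laws invert the force laws and obey limits", {
  kT <- 4.114
  forces <- c(0.1, 0.5, 2, 10, 30, 60)
  ch <- wlc_chain(0.9, 120, kT)
  x <- element_extension(ch, forces)
  expect_equal(wlc_force(x, ch), forces, tolerance = 1e-6)

  ew <- ewlc_chain(40, 350, 1200, kT)
  expect_identical(element_extension(ew, 0), 0)
  # independent inversion of the interpolation formula via uniroot
  r_oracle <- vapply(forces * 40 / kT, function(fh) {
    uniroot(function(r) 0.25 / (1 - r)^2 - 0.25 + r - fh,
            c(0, 1 - 1e-12), tol = 1e-14)$root
  }, numeric(1))
  expect_equal(ewlc_extension(forces, ew),
               350 * (r_oracle + forces / 1200), tolerance = 1e-8)
  expect_equal(ewlc_extension(10, ew), 335.1049, tolerance = 1e-4)
  # stiff limit reduces to the inextensible chain
  ew_inf <- ewlc_chain(40, 350, 1e12, kT)
  wl <- wlc_chain(40, 350, kT)
  expect_equal(ewlc_extension(forces, ew_inf),
               element_extension(wl, forces), tolerance = 1e-8)
  expect_error(element_extension(ew, -1), "non-negative")

  ha <- harmonic_element(0.3)
  expect_equal(element_extension(ha, 6), 20)
})

test_that("stretching free energy matches closed forms and quadrature oracle", {
  expect_identical(stretch_free_energy(0, harmonic_element(0.5)), 0)
  expect_equal(stretch_free_energy(6, harmonic_element(0.3)), 36 / 0.6,
               tolerance = 1e-12)
  ch <- wlc_chain(0.9, 80)
  g <- stretch_free_energy(c(5, 12), ch)
  expect_equal(g[1], richardson_stretch_energy(ch, 5), tolerance = 1e-5)
  expect_gt(g[2], g[1])  # increasing in force
  ew <- ewlc_chain(40, 350, 1200)
  expect_equal(stretch_free_energy(10, ew),
               richardson_stretch_energy(ew, 10), tolerance = 1e-5)
})

test_that("series force balance: springs in series, slack, dense-scan oracle", {
  # near-rigid handle isolates the two traps: F = d / (1/k1 + 1/k2)
  springs <- elastic_network(trap_stiffness = 0.3,
                             handle = ewlc_chain(40, 1e-9, 1e9))
  expect_equal(series_force_balance(40, springs), 40 / (2 / 0.3),
               tolerance = 1e-6)
  net <- elastic_network()
  expect_identical(series_force_balance(12, net, folded_extension = 12), 0)
  f <- series_force_balance(900, net, folded_extension = 10,
                            unfolded_contour = 100)
  expect_equal(f, dense_scan_balance(net, 900, 10, 100, f_max = 100),
               tolerance = 1e-3)
  # monotone in separation, anti-monotone in unfolded contour
  f2 <- series_force_balance(920, net, folded_extension = 10,
                             unfolded_contour = 100)
  f3 <- series_force_balance(900, net, folded_extension = 10,
                             unfolded_contour = 160)
  expect_gt(f2, f)
  expect_lt(f3, f)
  expect_error(series_force_balance(1e5, net, f_max = 50), "bracket")
})
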