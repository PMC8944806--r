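test_that("configuration fold energies match term-by-term summation", {
  hp <- helix_params(g_A = -1.2, g_B = 0.8, g_AB = -3.5, g_BA = -9.1)
  expect_identical(config_fold_energy(rep(0, 6), hp), 0)
  expect_equal(config_fold_energy(c(0, 1, 0, 0), hp), hp$g_A)  # index 1 = A
  expect_equal(config_fold_energy(c(1, 0, 0, 0), hp), hp$g_B)  # index 0 = B
  # fully folded 2-repeat array: 2 g_A + 2 g_B + 2 g_AB + g_BA
  expect_equal(config_fold_energy(rep(1, 4), hp),
               2 * hp$g_A + 2 * hp$g_B + 2 * hp$g_AB + hp$g_BA)
  set.seed(11)
  nn <- helix_params(0.5, 1.5, -4, -8, g_AA = -0.7, g_BB = -0.3,
                     variant = "heteropolymer_helix_nnn")
  for (i in 1:20) {
    s <- sample(0:1, 8, replace = TRUE)
    expect_equal(config_fold_energy(s, hp), brute_force_fold_energy(s, hp))
    expect_equal(config_fold_energy(s, nn), brute_force_fold_energy(s, nn))
  }
  expect_error(config_fold_energy(rep(1, 5), hp), "even")
})

test_that("repeat/helix energy algebra round-trips and matches the total", {
  zero_intrinsic <- helix_params(0, 0, -1.9, -12.7)
  rp <- repeat_params_from_helix(zero_intrinsic)
  expect_equal(c(rp$dG_unit, rp$dG_nn), c(-1.9, -12.7))
  # symmetric-split defaults reproduce the combined rv values
  hp <- helix_params_from_repeat(repeat_params(1.1, -11.0))
  rp2 <- repeat_params_from_helix(hp)
  expect_equal(c(rp2$dG_unit, rp2$dG_nn), c(1.1, -11.0), tolerance = 1e-12)
  # asymmetric split preserves both sums
  hpa <- helix_params_from_repeat(repeat_params(1.1, -11.0),
                                  split = "asymmetric", delta = 0.5)
  rpa <- repeat_params_from_helix(hpa)
  expect_equal(c(rpa$dG_unit, rpa$dG_nn), c(1.1, -11.0), tolerance = 1e-12)
  # energy-algebra consistency: fully folded N-repeat state equals the
  # closed-form total free energy
  for (n in c(1, 3, 6)) {
    expect_equal(config_fold_energy(rep(1, 2 * n), hpa),
                 total_free_energy(rpa, n_repeats = n), tolerance = 1e-12)
  }
  expect_equal(total_free_energy(repeat_params(2.5, -7), n_repeats = 1), 2.5)
  expect_error(total_free_energy(repeat_params(1, -1), n_repeats = 0), ">= 1")
})

test_that("configuration enumeration matches combinatorial counts and filters", {
  for (n in 1:6) {
    expect_identical(nrow(enumerate_configurations(n, "full")),
                     as.integer(2^n))
    expect_identical(nrow(enumerate_configurations(n, "zipper")),
                     as.integer(n * (n + 1) / 2 + 1))
    skip_set <- enumerate_configurations(n, "skip")
    oracle <- brute_force_skip_states(n)
    expect_identical(
      sort(apply(skip_set, 1, paste, collapse = "")),
      sort(apply(oracle, 1, paste, collapse = "")))
  }
  # n = 4: exactly the three short internal nuclei are eliminated
  skip4 <- apply(enumerate_configurations(4, "skip"), 1, paste, collapse = "")
  expect_identical(nrow(enumerate_configurations(4, "skip")), 13L)
  expect_identical(setdiff(apply(enumerate_configurations(4, "full"), 1,
                                 paste, collapse = ""), skip4) |> sort(),
                   c("0010", "0100", "0110"))
  # zipper states with >= 3 folded helices or terminal contact survive skip
  zip5 <- enumerate_configurations(5, "zipper")
  skip5 <- apply(enumerate_configurations(5, "skip"), 1, paste, collapse = "")
  keep <- rowSums(zip5) >= 3 | zip5[, 1] == 1 | zip5[, 5] == 1 |
    rowSums(zip5) == 0
  expect_true(all(apply(zip5[keep, ], 1, paste, collapse = "") %in% skip5))
  expect_error(enumerate_configurations(30, "full"), "cap")
})

test_that("zero-force statistics: unfolded fraction and minimal stable unit", {
  expect_equal(fraction_unfolded(0), 0.5)
  expect_equal(fraction_unfolded(-1.9), 0.130, tolerance = 1e-3)
  expect_equal(fraction_unfolded(1.1), 0.750, tolerance = 1e-3)
  expect_true(all(fraction_unfolded(c(-20, 0, 20)) > 0 &
                    fraction_unfolded(c(-20, 0, 20)) < 1))
  # uniform-interface decomposition of the combined Table values
  expect_identical(minimal_stable_unit(repeat_params(1.1, -11.0)), 3L)
  expect_identical(minimal_stable_unit(repeat_params(-1.9, -12.7)), 2L)
  # a stable lone helix folds by itself
  expect_identical(minimal_stable_unit(helix_params(-0.2, 4, -1, -1)), 1L)
  # nothing stable -> NA
  expect_true(is.na(minimal_stable_unit(helix_params(5, 5, 1, 1),
                                        n_helices = 8L)))
})

test_that("single-repeat partition function reduces to the two-state form", {
  for (dg in c(-1.9, 0, 1.1)) {
    m <- ctpr_model(1, repeat_params(dg, -10), approximation = "full")
    w <- exp(-m$e_fold)
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
    p_unf <- w[m$n_folded == 0] / sum(w)
    expect_equal(p_unf, fraction_unfolded(dg), tolerance = 1e-12)
  }
})
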