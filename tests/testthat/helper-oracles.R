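# Independent oracles, kept deliberately naive: plain loops and generic
# solvers that do not share code paths with the package internals.

# Term-by-term Ising energy: loop over units and interfaces.
brute_force_fold_energy <- function(state, params) {
  n <- length(state)
  e <- 0
  for (i in seq_len(n)) {
    if (state[i] == 1) {
      idx0 <- i - 1L  # 0-based, C-terminal first; even index = B-helix
      e <- e + if (idx0 %% 2L == 0L) params$g_B else params$g_A
    }
  }
  for (i in seq_len(n - 1L)) {
    if (state[i] == 1 && state[i + 1L] == 1) {
      idx0 <- i - 1L
      e <- e + if (idx0 %% 2L == 0L) params$g_AB else params$g_BA
    }
  }
  if (identical(params$variant, "heteropolymer_helix_nnn")) {
    for (i in seq_len(max(n - 2L, 0L))) {
      if (state[i] == 1 && state[i + 2L] == 1) {
        idx0 <- i - 1L
        e <- e + if (idx0 %% 2L == 0L) params$g_BB else params$g_AA
      }
    }
  }
  e
}

# Skip filter applied as a string test over the full enumeration.
brute_force_skip_states <- function(n) {
  full <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n), drop = FALSE]
  keep <- apply(full, 1L, function(s) {
    nf <- sum(s)
    !(nf >= 1 && nf <= 2 && s[1] == 0 && s[n] == 0)
  })
  full[keep, , drop = FALSE]
}

# Segment-walk folded extension: explicit scan for maximal folded runs.
segment_walk_extension <- function(state, geom, units_per_repeat = 2) {
  total <- 0
  run <- 0
  for (s in c(state, 0)) {
    if (s == 1) {
      run <- run + 1
    } else if (run > 0) {
      total <- total + folded_extension(run / units_per_repeat, geom)
      run <- 0
    }
  }
  total
}

# Dense-scan force balance: tabulate the extension sum on a fine force grid
# and interpolate the crossing.
dense_scan_balance <- function(network, trap_separation, folded_extension = 0,
                               unfolded_contour = 0, f_max = 60) {
  fs <- seq(0, f_max, by = 1e-3)
  ext <- network$n_traps * fs / network$trap_stiffness +
    vapply(fs, function(f) element_extension(network$handle, f), numeric(1))
  if (unfolded_contour > 0) {
    chain <- wlc_chain(network$chain_Lp, unfolded_contour, network$kT)
    ext <- ext + vapply(fs, function(f) element_extension(chain, f), numeric(1))
  }
  approx(ext + folded_extension, fs, xout = trap_separation)$y
}

# Richardson-refined trapezoidal quadrature of F dx along the element's own
# extension law (integrates force over extension directly).
richardson_stretch_energy <- function(element, force) {
  xf <- element_extension(element, force)
  grid_integral <- function(n) {
    xs <- seq(0, xf, length.out = n)
    fs <- vapply(xs, function(x) {
      uniroot(function(f) element_extension(element, f) - x,
              c(0, max(force * 2, 1)), tol = 1e-12)$root
    }, numeric(1))
    sum((fs[-1] + fs[-n]) / 2) * (xf / (n - 1))
  }
  i1 <- grid_integral(201)
  i2 <- grid_integral(401)
  (4 * i2 - i1) / 3
}

# Small rv5-like model used across tests.
toy_rv5_model <- function(approximation = "zipper", ...) {
  ctpr_model_preset("ctprrv5", approximation = approximation, ...)
}
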