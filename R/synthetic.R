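## Instrument emulation with known ground truth: stretch/relax FDC cycles
## around the equilibrium model curve, and chemical-denaturation curves from
## the repeat-level Ising partition function. All randomness flows from one
## seed so every dataset is exactly reproducible.

#' Noise model for synthetic FDC cycles
#'
#' Additive Gaussian force noise with variance
#' `instrument_sigma^2 + thermal`, where the thermal part (when enabled) is
#' the equilibrium force variance of the configuration mixture plus
#' `kT x k_eff` of the elastic network - large across the plateau and dip
#' (fast unfolding/refolding fluctuations), small on the pure linker
#' branches. Each cycle additionally receives a rigid force/distance offset
#' emulating per-molecule miscalibration.
#'
#' @param instrument_sigma Instrument force noise SD, pN.
#' @param thermal_from_stiffness Add the state-mixture/thermal variance.
#' @param seed Integer seed; identical seeds give identical output.
#' @param offset_sigma_force Per-cycle force offset SD, pN.
#' @param offset_sigma_distance Per-cycle distance offset SD, nm.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(instrument_sigma = 0.3, thermal_from_stiffness = TRUE,
                        seed = 1L, offset_sigma_force = 0.2,
                        offset_sigma_distance = 1) {
  stopifnot(instrument_sigma >= 0, offset_sigma_force >= 0,
            offset_sigma_distance >= 0)
  structure(list(instrument_sigma = instrument_sigma,
                 thermal_from_stiffness = thermal_from_stiffness,
                 seed = as.integer(seed),
                 offset_sigma_force = offset_sigma_force,
                 offset_sigma_distance = offset_sigma_distance),
            class = "noise_model")
}

## Local effective stiffness of the elastic network (pN/nm) at force F with
## unfolded contour Lc: forward difference of the force-extension relation.
network_stiffness <- function(network, force, unfolded_contour) {
  h <- 1e-3
  dx <- network_extension(network, force + h, unfolded_contour) -
    network_extension(network, force, unfolded_contour)
  h / pmax(dx, 1e-9)
}

#' Generate synthetic stretch/relax FDC cycles
#'
#' Evaluates the equilibrium model curve once and emits `n_cycles`
#' noisy copies, alternating stretch and relax sweeps (equilibrium: both
#' follow the same curve). Reproducible via the noise model's seed.
#'
#' @param model A [ctpr_model()].
#' @param noise A [noise_model()].
#' @param n_cycles Number of cycles (>= 1).
#' @param pulling_speed Metadata only, nm/s (equilibrium curves are
#'   speed-independent at <= 100 nm/s).
#' @param separations Optional grid; [default_separations()] otherwise.
#' @return A stacked `fdc` tibble with `cycle` and `direction` columns and
#'   attributes `ground_truth` (model parameters) and `offsets`.
#' @export
generate_fdc_cycles <- function(model, noise = noise_model(), n_cycles = 30,
                                pulling_speed = 100, separations = NULL) {
  stopifnot(n_cycles >= 1)
  separations <- separations %||% default_separations(model, step = 0.25)
  base <- equilibrium_fdc(model, separations, detail = TRUE)
  sd_tot <- noise$instrument_sigma
  if (noise$thermal_from_stiffness) {
    kx <- network_stiffness(model$network, pmax(base$force_pN, 0.1),
                            mean(model$group_lc))
    sd_tot <- sqrt(noise$instrument_sigma^2 + base$force_sd_thermal^2 +
                     model$network$kT * kx)
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code()
  }
  withr_seed(function() {
    offs <- tibble(
      cycle = seq_len(n_cycles),
      force_offset = rnorm(n_cycles, 0, noise$offset_sigma_force),
      distance_offset = rnorm(n_cycles, 0, noise$offset_sigma_distance))
    out <- purrr::map(seq_len(n_cycles), function(i) {
      dirn <- if (i %% 2L == 1L) "stretch" else "relax"
      f <- base$force_pN + rnorm(nrow(base), 0, sd_tot) + offs$force_offset[i]
      s <- base$separation_nm + offs$distance_offset[i]
      if (dirn == "relax") {
        f <- rev(f); s <- rev(s)
      }
      tibble(separation_nm = s, force_pN = f, cycle = i, direction = dirn)
    })
    res <- as_fdc(dplyr::bind_rows(out), pulling_speed = pulling_speed)
    attr(res, "ground_truth") <- list(
      params = model$params,
      repeat_params = if (inherits(model$params, "helix_params") &&
                          model$params$variant != "homopolymer_helix")
        repeat_params_from_helix(model$params) else model$params,
      n_repeats = model$n_repeats, seed = noise$seed)
    attr(res, "offsets") <- offs
    res
  })
}

## Mean folded fraction of an N-repeat homopolymer Ising chain with
## per-repeat energy g and coupling j (kT): exact enumeration for short
## arrays, transfer matrix with numerical derivative beyond.
ising_fraction_folded <- function(g, j, n) {
  if (n <= 15) {
    states <- enumerate_configurations(n, "full")
    e <- states_fold_energy(states, repeat_params(g, j))
    w <- exp(-(e - min(e)))
    sum(w * rowSums(states)) / (sum(w) * n)
  } else {
    ## open-chain recursion on partition sums ending unfolded/folded,
    ## log-rescaled each step to avoid overflow
    lz <- function(gg) {
      zu <- 1; zf <- exp(-gg); acc <- 0
      for (i in seq_len(n - 1)) {
        nu <- zu + zf
        nf <- exp(-gg) * zu + exp(-(gg + j)) * zf
        s <- nu + nf
        acc <- acc + log(s)
        zu <- nu / s; zf <- nf / s
      }
      acc + log(zu + zf)
    }
    h <- 1e-5
    -(lz(g + h) - lz(g - h)) / (2 * h) / n
  }
}

#' Generate synthetic chemical-denaturation curves
#'
#' Fraction folded from the repeat-level homopolymer Ising partition
#' function with linear denaturant dependence of the intrinsic energy
#' (`dG_unit(D) = dG_unit + m_unit x D`), mapped through per-curve sloping
#' folded/unfolded baselines, plus Gaussian noise.
#'
#' @param rp A [repeat_params()] (zero-denaturant values).
#' @param m_unit Denaturant m-value per repeat, kT/M (> 0 destabilizes).
#' @param lengths Integer vector of array lengths (repeats).
#' @param denaturant Denaturant concentration grid, M.
#' @param sigma Gaussian noise SD on the signal.
#' @param seed Integer seed.
#' @param baselines List with `folded = c(intercept, slope)` and
#'   `unfolded = c(intercept, slope)` applied to every curve.
#' @return Tibble (`n_repeats`, `denaturant_M`, `signal`, `fraction_folded`).
#' @export
generate_denaturation <- function(rp, m_unit = 2.2, lengths = c(2L, 5L, 10L),
                                  denaturant = seq(0, 8, by = 0.25),
                                  sigma = 0.01, seed = 1L,
                                  baselines = list(folded = c(1, -0.01),
                                                   unfolded = c(0, 0.01))) {
  stopifnot(inherits(rp, "repeat_params"), length(lengths) >= 1)
  set.seed(seed)
  purrr::map_dfr(lengths, function(n) {
    phi <- vapply(denaturant, function(D) {
      ising_fraction_folded(rp$dG_unit + m_unit * D, rp$dG_nn, n)
    }, numeric(1))
    bf <- baselines$folded[1] + baselines$folded[2] * denaturant
    bu <- baselines$unfolded[1] + baselines$unfolded[2] * denaturant
    tibble(n_repeats = n, denaturant_M = denaturant,
           signal = bf * phi + bu * (1 - phi) +
             rnorm(length(denaturant), 0, sigma),
           fraction_folded = phi)
  })
}

#' Denaturation midpoint of a synthetic curve family
#'
#' Denaturant concentration at which the fraction folded crosses one half,
#' by linear interpolation.
#'
#' @param rp A [repeat_params()].
#' @param m_unit m-value, kT/M.
#' @param n Array length in repeats.
#' @param d_max Upper end of the scan, M.
#' @return Concentration in M.
#' @export
denaturation_midpoint <- function(rp, m_unit, n, d_max = 12) {
  ds <- seq(0, d_max, by = 0.02)
  phi <- vapply(ds, function(D) {
    ising_fraction_folded(rp$dG_unit + m_unit * D, rp$dG_nn, n)
  }, numeric(1))
  if (phi[1] < 0.5) return(0)
  i <- which(phi < 0.5)[1]
  if (is.na(i)) return(NA_real_)
  ds[i - 1] + (0.5 - phi[i - 1]) * (ds[i] - ds[i - 1]) / (phi[i] - phi[i - 1])
}
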