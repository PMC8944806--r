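## Equilibrium force-distance curves and configuration ensembles. At a fixed
## trap separation every configuration carries its own balanced tension; the
## observable force is the Boltzmann average of those tensions weighted by
## the total stored free energy (fold energy + elastic energy of traps,
## handle and unfolded chain at that tension).

#' Force-distance curve container
#'
#' Light tibble subclass with columns `separation_nm`, `force_pN`, `cycle`
#' and `direction` (`"stretch"`, `"relax"` or `"model"`).
#'
#' @param x A data frame with at least `separation_nm` and `force_pN`.
#' @param pulling_speed Optional pulling speed metadata, nm/s.
#' @return An `fdc` tibble.
#' @export
as_fdc <- function(x, pulling_speed = NA_real_) {
  x <- as_tibble(x)
  if (!all(c("separation_nm", "force_pN") %in% names(x))) {
    abort("An FDC needs `separation_nm` and `force_pN` columns.")
  }
  if (!"cycle" %in% names(x)) x$cycle <- 1L
  if (!"direction" %in% names(x)) x$direction <- "stretch"
  class(x) <- c("fdc", class(tibble()))
  attr(x, "pulling_speed") <- pulling_speed
  x
}

## Per-group balanced forces and mechanical energies over a separation grid.
## Returns list(F, E_mech) of n_groups x n_d matrices (E_mech in kT).
group_mechanics <- function(model, separations) {
  net <- model$network
  ng <- length(model$group_lc)
  nd <- length(separations)
  gap <- pmax(as.numeric(outer(model$group_xi, separations,
                               function(xi, d) d - xi)), 0)
  lc <- as.numeric(matrix(model$group_lc, ng, nd))
  Fm <- balance_force_vec(net, gap, lc)
  Em <- mech_energy_vec(net, Fm, lc) / net$kT
  ## states whose elements cannot span the gap even at the force bracket top
  ## are sterically excluded: infinite stored energy, zero weight
  unreachable <- network_extension_vec(net, rep(200, ng * nd), lc) < gap
  Em[unreachable] <- Inf
  list(F = matrix(Fm, ng, nd), E_mech = matrix(Em, ng, nd))
}

## Vectorized closed-form elastic energy (pN nm) for force/contour vectors.
mech_energy_vec <- function(network, force, unfolded_contour) {
  en <- network$n_traps * force^2 / (2 * network$trap_stiffness) +
    element_energy_closed(network$handle, force)
  pos <- unfolded_contour > 0
  if (any(pos)) {
    fhat <- force[pos] * network$chain_Lp / network$kT
    r <- wlc_relext(fhat)
    en[pos] <- en[pos] + wlc_energy_closed(r, network$chain_Lp,
                                           unfolded_contour[pos], network$kT)
  }
  en
}

## Boltzmann statistics at each separation. Returns a list of per-separation
## summaries; the workhorse behind the public engine functions. `gm` and
## `e_fold` can be supplied to reuse the (parameter-independent) mechanics
## across fit iterations.
ensemble_stats <- function(model, separations, gm = NULL, e_fold = NULL) {
  gm <- gm %||% group_mechanics(model, separations)
  nd <- length(separations)
  e_fold <- e_fold %||% model$e_fold
  grp <- model$group
  nf <- model$n_folded
  out <- vector("list", nd)
  for (j in seq_len(nd)) {
    E <- e_fold + gm$E_mech[grp, j]
    Fc <- gm$F[grp, j]
    m <- min(E)
    if (!is.finite(m)) {
      abort(sprintf(
        "No configuration can span separation %.2f nm within the force bracket.",
        separations[j]))
    }
    w <- exp(-(E - m))
    Z <- sum(w)
    p <- w / Z
    fbar <- sum(p * Fc)
    out[[j]] <- list(
      p = p, force = fbar,
      force_var = sum(p * (Fc - fbar)^2),
      p_unfolded = sum(p[nf == 0L]),
      free_energy_kT = m - log(Z),
      F_states = Fc
    )
  }
  out
}

#' Equilibrium force-distance curve of a model
#'
#' At each trap separation, solves the per-configuration force balance and
#' Boltzmann-averages the configuration tensions with weights given by the
#' total stored free energy. Deterministic; for long arrays with the
#' superhelix extension the plateau exhibits the characteristic force
#' oscillations.
#'
#' @param model A [ctpr_model()].
#' @param separations Increasing trap separations in nm; default
#'   [default_separations()].
#' @param detail Add `p_unfolded`, `force_sd_thermal` (configuration-mixture
#'   force SD) and `free_energy_kT` columns.
#' @return An [as_fdc()] tibble with `direction = "model"`.
#' @export
equilibrium_fdc <- function(model, separations = NULL, detail = FALSE) {
  separations <- separations %||% default_separations(model)
  if (is.unsorted(separations, strictly = TRUE)) {
    abort("`separations` must be strictly increasing.")
  }
  st <- ensemble_stats(model, separations)
  out <- tibble(
    separation_nm = separations,
    force_pN = vapply(st, `[[`, numeric(1), "force"),
    cycle = 0L,
    direction = "model"
  )
  if (detail) {
    out$p_unfolded <- vapply(st, `[[`, numeric(1), "p_unfolded")
    out$force_sd_thermal <- sqrt(vapply(st, `[[`, numeric(1), "force_var"))
    out$free_energy_kT <- vapply(st, `[[`, numeric(1), "free_energy_kT")
  }
  as_fdc(out)
}

#' Total system free energy profile
#'
#' `A(d) = -kT ln Z(d)` over the configuration ensemble, in kT.
#'
#' @inheritParams equilibrium_fdc
#' @return Tibble with `separation_nm`, `free_energy_kT`.
#' @export
fdc_free_energy <- function(model, separations) {
  st <- ensemble_stats(model, separations)
  tibble(separation_nm = separations,
         free_energy_kT = vapply(st, `[[`, numeric(1), "free_energy_kT"))
}

#' Force-distance curve from the free-energy derivative
#'
#' Alternative route to the equilibrium FDC: central finite differences of
#' the total free energy with respect to trap separation. Agrees with the
#' Boltzmann-averaged force on dense grids (equilibrium identity).
#'
#' @inheritParams equilibrium_fdc
#' @return An `fdc` tibble on the interior grid points.
#' @export
fdc_from_free_energy <- function(model, separations) {
  a <- fdc_free_energy(model, separations)$free_energy_kT * model$network$kT
  n <- length(separations)
  if (n < 3) abort("Need at least 3 separations for the derivative route.")
  force <- (a[-(1:2)] - a[1:(n - 2)]) /
    (separations[-(1:2)] - separations[1:(n - 2)])
  as_fdc(tibble(separation_nm = separations[2:(n - 1)], force_pN = force,
                cycle = 0L, direction = "model"))
}

#' Total stored free energy of one configuration at a trap separation
#'
#' Fold energy of the configuration plus the elastic energy of traps, handle
#' and unfolded chain at the configuration's balanced tension, in kT. The
#' fully unfolded configuration at slack separation defines zero.
#'
#' @param model A [ctpr_model()].
#' @param config 0-1 fold-state vector (C-terminus first) over the model's
#'   units.
#' @param trap_separation Trap separation in nm.
#' @return Energy in kT.
#' @export
configuration_total_energy <- function(model, config, trap_separation) {
  s <- as.integer(as.logical(config))
  if (length(s) != model$n_units) abort("Fold-state length must match the model.")
  e_fold <- config_fold_energy(s, model$params)
  lc <- ((model$n_units - sum(s)) *
           model$residues_per_repeat / model$units_per_repeat +
           model$extra_residues) * model$network$nm_per_residue
  xi <- if (model$extension_model == "beads") {
    beads_on_string_extension(sum(s), model$n_units, model$xi_max)
  } else {
    extension_for_configuration(s, model$geometry, model$units_per_repeat)
  }
  f <- series_force_balance(max(trap_separation, xi), model$network,
                            folded_extension = xi, unfolded_contour = lc)
  e_fold + network_energy(model$network, f, lc) / model$network$kT
}

#' Ranked configuration ensemble at one trap separation
#'
#' Top-`k` configurations by Boltzmann probability (ties broken by
#' `n_folded` descending, then lexicographic fold-state string), per-helix
#' fold-probability marginals, and the population of the fully unfolded
#' state.
#'
#' @param model A [ctpr_model()]; the skip approximation is the natural
#'   choice here since it does not enforce unfolding from the ends.
#' @param trap_separation Trap separation in nm.
#' @param k Number of ranked configurations to keep.
#' @return An object of class `ensemble_snapshot`.
#' @export
ensemble_snapshot <- function(model, trap_separation, k = 10L) {
  stopifnot(k >= 1)
  st <- ensemble_stats(model, trap_separation)[[1]]
  keys <- apply(model$states, 1L, paste, collapse = "")
  ord <- order(-st$p, -model$n_folded, keys)
  top <- head(ord, k)
  marg <- as.numeric(crossprod(model$states, st$p))
  structure(
    list(
      trap_separation = trap_separation,
      configurations = tibble(
        rank = seq_along(top),
        fold_state = keys[top],
        n_folded = model$n_folded[top],
        probability = st$p[top],
        force_pN = st$F_states[top]
      ),
      marginals = tibble(helix = seq_len(model$n_units) - 1L,
                         p_folded = marg),
      p_unfolded = st$p_unfolded,
      mean_force = st$force
    ),
    class = "ensemble_snapshot"
  )
}

#' @export
print.ensemble_snapshot <- function(x, ...) {
  cat(sprintf("<ensemble_snapshot> d = %.2f nm, P(unfolded) = %.3f\n",
              x$trap_separation, x$p_unfolded))
  print(x$configurations)
  invisible(x)
}

#' Write an ensemble snapshot as JSON
#' @param snapshot An [ensemble_snapshot()].
#' @param path Output file.
#' @export
write_snapshot_json <- function(snapshot, path) {
  jsonlite::write_json(
    list(trap_separation_nm = snapshot$trap_separation,
         p_unfolded = snapshot$p_unfolded,
         mean_force_pN = snapshot$mean_force,
         configurations = snapshot$configurations,
         per_helix_fold_probability = snapshot$marginals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-helix fold probability across trap separations
#'
#' @param model A [ctpr_model()].
#' @param separations Trap separations in nm.
#' @return Long tibble (`helix` 0-based from the C-terminus,
#'   `separation_nm`, `p_folded`).
#' @export
helix_fold_profile <- function(model, separations = NULL) {
  separations <- separations %||% default_separations(model)
  st <- ensemble_stats(model, separations)
  marg <- vapply(st, function(s) as.numeric(crossprod(model$states, s$p)),
                 numeric(model$n_units))
  marg <- matrix(marg, nrow = model$n_units)
  tibble(
    helix = rep(seq_len(model$n_units) - 1L, times = length(separations)),
    separation_nm = rep(separations, each = model$n_units),
    p_folded = as.numeric(marg)
  )
}

#' Separation at which a state population crosses one half
#'
#' Bisects the trap separation at which the fully unfolded configuration
#' reaches the given probability (default 0.5).
#'
#' @param model A [ctpr_model()].
#' @param target Probability level.
#' @param interval Optional search interval in nm; defaults to the span of
#'   [default_separations()].
#' @param tol Bisection tolerance in nm.
#' @return Separation in nm.
#' @export
unfolded_midpoint_separation <- function(model, target = 0.5,
                                         interval = NULL, tol = 0.01) {
  if (is.null(interval)) {
    s <- default_separations(model, step = 2)
    interval <- range(s)
  }
  pu <- function(d) ensemble_stats(model, d)[[1]]$p_unfolded - target
  lo <- pu(interval[1]); hi <- pu(interval[2])
  if (lo * hi > 0) {
    abort(sprintf(
      "P(unfolded) does not cross %.2f in [%.1f, %.1f] nm (values %.3f, %.3f).",
      target, interval[1], interval[2], lo + target, hi + target))
  }
  uniroot(pu, interval, tol = tol)$root
}

#' Seed size: mean folded-helix count where the unfolded state reaches 50%
#'
#' Finds the trap separation at which the fully unfolded configuration has
#' probability 0.5 and returns the expected number of folded units over the
#' remaining (partially folded) configurations at that separation. For long
#' arrays this is independent of array length.
#'
#' @param model A [ctpr_model()].
#' @param interval,tol Passed to [unfolded_midpoint_separation()].
#' @return Real-valued unit count (helices for helix-level lattices).
#' @export
seed_size <- function(model, interval = NULL, tol = 0.01) {
  dstar <- unfolded_midpoint_separation(model, 0.5, interval, tol)
  st <- ensemble_stats(model, dstar)[[1]]
  folded <- model$n_folded > 0L
  sum(st$p[folded] * model$n_folded[folded]) / sum(st$p[folded])
}

#' Force-distance curve under a stiffened apparatus
#'
#' Recomputes the equilibrium FDC after multiplying the effective spring
#' constant of the probe (traps and handle) by `factor`. Stiff probes
#' resolve repeat-by-repeat unfolding as a sawtooth; the default soft assay
#' produces a smooth plateau.
#'
#' @param model A [ctpr_model()].
#' @param factor Stiffening factor (>= 1) applied via [stiffen_network()].
#' @param separations Optional grid; defaults to the stiffened model's
#'   [default_separations()].
#' @param step Grid step in nm for the default grid.
#' @return An `fdc` tibble.
#' @export
simulate_apparatus_stiffness <- function(model, factor, separations = NULL,
                                         step = 0.25) {
  stiff <- model
  stiff$network <- stiffen_network(model$network, factor)
  ## extend the upper end: under a stiff probe the final unfolding tooth
  ## peaks well above the soft-assay plateau force
  separations <- separations %||%
    default_separations(stiff, step = step,
                        f_hi = 2.5 * plateau_force_estimate(stiff))
  equilibrium_fdc(stiff, separations)
}

#' Rough analytic plateau-force estimate
#'
#' Force at which the per-repeat folding free energy equals the mechanical
#' free energy released by converting one folded repeat into unfolded
#' contour (constant-force thermodynamic balance). Used to choose default
#' separation grids.
#'
#' @param model A [ctpr_model()].
#' @return Force in pN.
#' @export
plateau_force_estimate <- function(model) {
  net <- model$network
  dg_rep <- (model$e_fold[which.max(model$n_folded)] / model$n_repeats) *
    net$kT  # pN nm, negative for stable folds
  if (dg_rep >= 0) return(1)
  lc_rep <- model$residues_per_repeat * net$nm_per_residue
  xi_rep <- model$xi_max / model$n_repeats
  bal <- function(f) {
    fhat <- f * net$chain_Lp / net$kT
    r <- wlc_relext(fhat)
    ix_dF <- lc_rep * (f * r - wlc_energy_closed(r, net$chain_Lp, 1, net$kT))
    ix_dF - xi_rep * f + dg_rep
  }
  if (bal(150) < 0) return(150)
  uniroot(bal, c(1e-3, 150), tol = 1e-4)$root
}

#' Default separation grid spanning folded to unfolded branches
#'
#' Starts on the fully folded branch at a fraction of the estimated plateau
#' force and ends on the fully unfolded branch safely above it.
#'
#' @param model A [ctpr_model()].
#' @param step Grid step in nm (default 0.25).
#' @param f_lo Force on the folded branch at the first separation, pN.
#' @param f_hi Force on the unfolded branch at the last separation, pN.
#' @return Numeric vector of separations in nm.
#' @export
default_separations <- function(model, step = 0.25, f_lo = NULL, f_hi = NULL) {
  fp <- plateau_force_estimate(model)
  f_lo <- f_lo %||% max(0.5, 0.3 * fp)
  f_hi <- f_hi %||% (fp + max(4, 0.5 * fp))
  lc_min <- min(model$group_lc)
  lc_max <- max(model$group_lc)
  d_lo <- network_extension(model$network, f_lo, lc_min) + model$xi_max
  d_hi <- network_extension(model$network, f_hi, lc_max)
  seq(d_lo, d_hi, by = step)
}
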