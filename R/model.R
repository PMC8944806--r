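## The ctpr_model object bundles everything needed to evaluate the
## equilibrium statistical mechanics of one construct at a fixed trap
## separation: the Ising parameters (helix- or repeat-level lattice), the
## enumerated configuration space under the chosen approximation, the
## superhelix geometry and the elastic network. The state table caches, per
## configuration, the fold energy (kT), the unfolded contour length (nm) and
## the rigid folded extension (nm); configurations sharing (contour,
## extension) share one mechanical force balance.

#' Assemble a mechanical Ising model of a repeat array
#'
#' @param n_repeats Number of repeats in the array.
#' @param params [helix_params()] (helix-resolution lattice, 2 units per
#'   repeat) or [repeat_params()] (repeat-resolution lattice).
#' @param geometry A [superhelix_geometry()]; default CTPRa preset.
#' @param network An [elastic_network()]; default assay constants.
#' @param approximation Configuration-space restriction passed to
#'   [enumerate_configurations()].
#' @param extension_model `"superhelix"` (chord of each folded segment) or
#'   `"beads"` (linear beads-on-a-string interpolation).
#' @param residues_per_repeat Residues per repeat (34 for CTPRs; 17 per
#'   helix unit).
#' @param extra_residues Constant unfolded contour offset in residues
#'   (tags, solvating helix); not part of the foldable lattice.
#' @param cap Enumeration cap forwarded to [enumerate_configurations()].
#' @return An object of class `ctpr_model`.
#' @export
ctpr_model <- function(n_repeats, params,
                       geometry = superhelix_geometry(),
                       network = elastic_network(),
                       approximation = c("zipper", "skip", "full"),
                       extension_model = c("superhelix", "beads"),
                       residues_per_repeat = 34,
                       extra_residues = 0,
                       cap = 24L) {
  approximation <- match.arg(approximation)
  extension_model <- match.arg(extension_model)
  stopifnot(n_repeats >= 1)
  repeat_level <- inherits(params, "repeat_params")
  units_per_repeat <- if (repeat_level) 1L else 2L
  n_units <- n_repeats * units_per_repeat
  res_per_unit <- residues_per_repeat / units_per_repeat

  states <- enumerate_configurations(n_units, approximation, cap = cap)
  e_fold <- states_fold_energy(states, params)
  n_folded <- rowSums(states)
  lc_unfolded <- ((n_units - n_folded) * res_per_unit + extra_residues) *
    network$nm_per_residue

  xi_max <- folded_extension(n_repeats, geometry)
  if (extension_model == "beads") {
    xi <- beads_on_string_extension(n_folded, n_units, xi_max)
  } else {
    xi <- apply(states, 1L, extension_for_configuration, geom = geometry,
                units_per_repeat = units_per_repeat)
  }

  key <- paste(round(lc_unfolded, 9), round(xi, 9))
  group <- match(key, unique(key))
  g_lc <- lc_unfolded[!duplicated(key)]
  g_xi <- xi[!duplicated(key)]

  structure(
    list(n_repeats = n_repeats, params = params, geometry = geometry,
         network = network, approximation = approximation,
         extension_model = extension_model,
         units_per_repeat = units_per_repeat, n_units = n_units,
         residues_per_repeat = residues_per_repeat,
         extra_residues = extra_residues,
         states = states, e_fold = e_fold, n_folded = n_folded,
         lc_unfolded = lc_unfolded, xi = xi,
         group = group, group_lc = g_lc, group_xi = g_xi,
         xi_max = xi_max),
    class = "ctpr_model"
  )
}

## Vectorized fold energies for a 0-1 state matrix (rows = configurations).
states_fold_energy <- function(states, params) {
  n <- ncol(states)
  if (inherits(params, "repeat_params")) {
    e <- params$dG_unit * rowSums(states)
    if (n > 1) {
      e <- e + params$dG_nn *
        rowSums(states[, -n, drop = FALSE] * states[, -1, drop = FALSE])
    }
    return(as.numeric(e))
  }
  gi <- helix_intrinsic_vector(n, params)
  e <- as.numeric(states %*% gi)
  if (n > 1) {
    w <- helix_interface_vector(n, params)
    e <- e + as.numeric((states[, -n, drop = FALSE] *
                           states[, -1, drop = FALSE]) %*% w)
  }
  if (params$variant == "heteropolymer_helix_nnn" && n > 2) {
    idx <- seq_len(n - 2L) - 1L
    w2 <- ifelse(idx %% 2L == 0L, params$g_BB, params$g_AA)
    e <- e + as.numeric((states[, seq_len(n - 2L), drop = FALSE] *
                           states[, seq_len(n - 2L) + 2L, drop = FALSE]) %*% w2)
  }
  e
}

#' @export
print.ctpr_model <- function(x, ...) {
  cat(sprintf(
    "<ctpr_model> %d repeats, %s lattice (%d units), %s approximation (%d states), %s extension\n",
    x$n_repeats,
    if (x$units_per_repeat == 2L) "helix" else "repeat",
    x$n_units, x$approximation, nrow(x$states), x$extension_model))
  invisible(x)
}

#' Homopolymer helix parameters
#'
#' Convenience constructor for the homopolymer helix model variant: every
#' helix has intrinsic energy `g` and every interface energy `g_nn`.
#'
#' @param g Intrinsic helix energy, kT.
#' @param g_nn Interface energy, kT.
#' @return A [helix_params()] object with variant `"homopolymer_helix"`.
#' @export
homopolymer_helix_params <- function(g, g_nn) {
  helix_params(g, g, g_nn, g_nn, variant = "homopolymer_helix")
}
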