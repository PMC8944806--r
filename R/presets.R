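## Prefilled parameter sets for the constructs studied mechanically:
## zipper-approximation repeat energetics per array length, plus the
## variant-combined values used for zero-force statistics.

#' Repeat-level energy presets
#'
#' Zipper-approximation intrinsic and coupling energies per construct,
#' plus the combined (`"ctprrv"`, `"ctpra"`) values pooled over all array
#' lengths of each variant. All energies in kT.
#'
#' @return Tibble with `preset`, `type`, `n_repeats`, `dG_unit`, `dG_nn`.
#' @export
ctpr_presets <- function() {
  tibble::tribble(
    ~preset,    ~type, ~n_repeats, ~dG_unit, ~dG_nn,
    "ctprrv3",  "rv",   3L,         1.0,     -10.0,
    "ctprrv5",  "rv",   5L,         1.5,     -11.8,
    "ctprrv10", "rv",  10L,         1.2,     -11.0,
    "ctprrv20", "rv",  20L,         1.0,     -10.2,
    "ctprrv26", "rv",  26L,         0.5,     -10.0,
    "ctpra5",   "a",    5L,        -2.4,     -12.4,
    "ctpra9",   "a",    9L,        -1.3,     -13.3,
    "ctprrv",   "rv",  NA_integer_, 1.1,     -11.0,
    "ctpra",    "a",   NA_integer_, -1.9,    -12.7
  )
}

#' Build a mechanical Ising model from a preset
#'
#' Looks up the repeat-level energies of the named construct, expands them
#' to the helix lattice (asymmetric split: the exposed C-terminal B-helix
#' is `delta` kT less stable than the A-helix, sums preserved) and attaches
#' the matching superhelix geometry preset and default elastic network.
#'
#' @param preset Preset name, see [ctpr_presets()].
#' @param n_repeats Repeat count; required for the variant-combined presets
#'   (`"ctprrv"`, `"ctpra"`), otherwise defaults to the construct length.
#' @param split Helix decomposition (`"asymmetric"` default for pathway
#'   realism; `"uniform"` for the symmetric bookkeeping split).
#' @param delta Helix asymmetry in kT.
#' @param ... Passed on to [ctpr_model()] (approximation, network, ...).
#' @return A [ctpr_model()].
#' @export
ctpr_model_preset <- function(preset, n_repeats = NULL,
                              split = c("asymmetric", "uniform"),
                              delta = 0.5, ...) {
  split <- match.arg(split)
  tab <- ctpr_presets()
  row <- tab[tab$preset == preset, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown preset '%s'. Available: %s.", preset,
                  paste(tab$preset, collapse = ", ")))
  }
  n_repeats <- n_repeats %||% row$n_repeats
  if (is.na(n_repeats)) {
    abort(sprintf("Preset '%s' is a combined parameter set; give `n_repeats`.",
                  preset))
  }
  hp <- helix_params_from_repeat(
    repeat_params(row$dG_unit, row$dG_nn), split = split, delta = delta)
  geom <- superhelix_geometry(preset = if (row$type == "a") "ctpra" else "ctprrv")
  args <- list(...)
  if (is.null(args$geometry)) args$geometry <- geom
  do.call(ctpr_model, c(list(n_repeats = n_repeats, params = hp), args))
}
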