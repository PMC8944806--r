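## End-to-end extension of the folded portion of the array. The folded
## solenoid is treated as a rigid circular helix; its end-to-end distance is
## the chord between the first and last folded repeat, which flattens and
## steepens periodically as the folded remainder shrinks. That chord
## modulation is what produces the force oscillations across the plateau.

#' Superhelix geometry
#'
#' Circular-helix parameterization of the folded solenoid plus a constant
#' terminal offset capturing the finite size of the first/last repeat along
#' the pulling axis. The radius refers to the superhelical axis traced by
#' the repeat centroids, not the outer envelope of the solenoid. Presets:
#' `"ctpra"` (radius 2.2 nm, rise 0.95 nm/repeat, 45 degrees/repeat,
#' offset 1 nm; ~8 repeats per superhelical turn) and `"ctprrv"` (wider,
#' slightly shorter solenoid: radius 2.6 nm, rise 0.85 nm/repeat).
#'
#' @param radius Superhelix radius in nm (>= 0).
#' @param rise_per_repeat Axial rise per repeat in nm (> 0).
#' @param phase_per_repeat Angular advance per repeat in degrees, (0, 360].
#' @param terminal_offset Constant end-cap extension in nm.
#' @param preset Optional preset name; explicit arguments override it.
#' @return An object of class `superhelix_geometry`.
#' @export
superhelix_geometry <- function(radius = NULL, rise_per_repeat = NULL,
                                phase_per_repeat = NULL, terminal_offset = NULL,
                                preset = c("ctpra", "ctprrv")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    ctpra  = list(radius = 2.2, rise_per_repeat = 0.95,
                  phase_per_repeat = 45, terminal_offset = 1.0),
    ctprrv = list(radius = 2.6, rise_per_repeat = 0.85,
                  phase_per_repeat = 45, terminal_offset = 1.0))
  out <- list(
    radius = radius %||% def$radius,
    rise_per_repeat = rise_per_repeat %||% def$rise_per_repeat,
    phase_per_repeat = phase_per_repeat %||% def$phase_per_repeat,
    terminal_offset = terminal_offset %||% def$terminal_offset
  )
  stopifnot(out$radius >= 0, out$rise_per_repeat > 0,
            out$phase_per_repeat > 0, out$phase_per_repeat <= 360)
  structure(out, class = "superhelix_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End-to-end extension of a folded block
#'
#' Chord length of a circular helix spanning `m` repeats:
#' `sqrt((m rise)^2 + (2 R sin(m phi / 2))^2) + offset` (offset only for
#' `m > 0`). `m` may be fractional; a lone folded helix counts as half a
#' repeat. With a full superhelical turn (`m phi = 360`) the chord collapses
#' to the pure axial rise, producing one flattening per turn.
#'
#' @param folded_repeat_equivalents Number of folded repeats spanned
#'   (real-valued, >= 0; vectorized).
#' @param geom A [superhelix_geometry()].
#' @return Extension in nm.
#' @export
folded_extension <- function(folded_repeat_equivalents, geom) {
  stopifnot(inherits(geom, "superhelix_geometry"))
  m <- folded_repeat_equivalents
  if (any(m < 0)) abort("`folded_repeat_equivalents` must be >= 0.")
  half_angle <- m * geom$phase_per_repeat * pi / 360
  chord <- sqrt((m * geom$rise_per_repeat)^2 +
                  (2 * geom$radius * sin(half_angle))^2)
  chord + geom$terminal_offset * (m > 0)
}

#' Beads-on-a-string extension (rejected alternative)
#'
#' Linear interpolation `xi = (n_folded / n_total) xi_max` between zero and
#' the fully folded end-to-end distance, as if the repeats were beads on a
#' string. Kept as the explicit comparison model: it reproduces the terminal
#' dip but produces a flat plateau without force oscillations.
#'
#' @param n_folded Number of folded units (0..n_total).
#' @param n_total Total number of units (> 0).
#' @param xi_max End-to-end distance of the fully folded protein, nm.
#' @return Extension in nm.
#' @export
beads_on_string_extension <- function(n_folded, n_total, xi_max) {
  if (n_total <= 0) abort("`n_total` must be positive.")
  if (any(n_folded < 0) || any(n_folded > n_total)) {
    abort("`n_folded` must lie in [0, n_total].")
  }
  n_folded / n_total * xi_max
}

#' Folded extension of an arbitrary configuration
#'
#' Each maximal folded segment is an independent helical arc contributing
#' its own chord; segment extensions add. Helices count as half repeats.
#'
#' @param config 0-1 fold-state vector over helices (C-terminus first).
#' @param geom A [superhelix_geometry()].
#' @param units_per_repeat 2 for helix-level lattices, 1 for repeat-level.
#' @return Extension in nm.
#' @export
extension_for_configuration <- function(config, geom, units_per_repeat = 2) {
  seg <- fold_segments(config)
  if (length(seg$length) == 0) return(0)
  sum(folded_extension(seg$length / units_per_repeat, geom))
}
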