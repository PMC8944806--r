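## Helix-resolution nearest-neighbor Ising energetics of CTPR arrays.
## Convention throughout: fold-state vectors index helices from the
## C-terminus (element 1 of the R vector = helix index 0 = C-terminal
## B-helix). A repeat contributes an A-helix followed by a B-helix along
## the N->C sequence, so from the C-terminal end the helix types alternate
## B, A, B, A, ... Energies are folding free energies in kT: unfolded
## units contribute exactly zero, negative values stabilize the fold.

#' Helix-level Ising parameters
#'
#' Intrinsic free energies of the A- and B-helices and interfacial free
#' energies between adjacent folded helices: `g_AB` couples the A- and
#' B-helix within a repeat, `g_BA` couples the B-helix of repeat i to the
#' A-helix of repeat i+1. The optional next-nearest-neighbor terms `g_AA`
#' and `g_BB` couple like helices in adjacent repeats and enter only in the
#' `heteropolymer_helix_nnn` variant. Interfaces contribute only when both
#' flanking helices are folded.
#'
#' @param g_A,g_B Intrinsic helix energies, kT.
#' @param g_AB Intra-repeat A-B interface energy, kT.
#' @param g_BA Inter-repeat B-A interface energy, kT.
#' @param g_AA,g_BB Optional next-nearest-neighbor energies, kT.
#' @param variant One of `"homopolymer_repeat"`, `"homopolymer_helix"`,
#'   `"heteropolymer_helix"`, `"heteropolymer_helix_nnn"`.
#' @return An object of class `helix_params`.
#' @export
helix_params <- function(g_A, g_B, g_AB, g_BA, g_AA = 0, g_BB = 0,
                         variant = c("heteropolymer_helix",
                                     "homopolymer_helix",
                                     "heteropolymer_helix_nnn",
                                     "homopolymer_repeat")) {
  variant <- match.arg(variant)
  stopifnot(is.finite(c(g_A, g_B, g_AB, g_BA, g_AA, g_BB)))
  structure(
    list(g_A = g_A, g_B = g_B, g_AB = g_AB, g_BA = g_BA,
         g_AA = g_AA, g_BB = g_BB, variant = variant),
    class = "helix_params"
  )
}

#' Repeat-level Ising parameters
#'
#' @param dG_unit Intrinsic folding free energy of one repeat, kT.
#' @param dG_nn Nearest-neighbor coupling between adjacent folded repeats, kT.
#' @param n_repeats Number of repeats in the array (>= 1).
#' @return An object of class `repeat_params`.
#' @export
repeat_params <- function(dG_unit, dG_nn, n_repeats = NA_integer_) {
  stopifnot(is.finite(dG_unit), is.finite(dG_nn))
  structure(list(dG_unit = dG_unit, dG_nn = dG_nn, n_repeats = n_repeats),
            class = "repeat_params")
}

#' Collapse helix-level parameters to repeat-level parameters
#'
#' Repeat stability and nearest-neighbor coupling extrapolated from the
#' helix-level description: `dG_unit = g_A + g_B + g_AB` (everything inside
#' one repeat) and `dG_nn = g_BA` (the inter-repeat interface).
#'
#' @param params A [helix_params()] object (heteropolymer helix variant).
#' @return A [repeat_params()] object.
#' @export
repeat_params_from_helix <- function(params) {
  stopifnot(inherits(params, "helix_params"))
  repeat_params(params$g_A + params$g_B + params$g_AB, params$g_BA)
}

#' Expand repeat-level parameters to helix level
#'
#' Distributes the repeat energetics over two helices per repeat. The
#' `"uniform"` split assigns every adjacent-helix interface the repeat
#' coupling (`g_AB = g_BA = dG_nn`) and divides the remainder equally
#' between the helices (`g_A = g_B = (dG_unit - dG_nn)/2`), preserving
#' `dG_unit = g_A + g_B + g_AB` and `dG_nn = g_BA`. The `"asymmetric"`
#' split additionally destabilizes the B-helix by `delta` and stabilizes
#' the A-helix by the same amount (sums unchanged), reflecting the exposed
#' C-terminal B-helix that unzips first under load.
#'
#' @param rp A [repeat_params()] object (or `dG_unit` as a number).
#' @param dG_nn Coupling, kT; ignored when `rp` is a `repeat_params`.
#' @param split `"uniform"` or `"asymmetric"`.
#' @param delta Helix asymmetry in kT for the asymmetric split.
#' @return A [helix_params()] object.
#' @export
helix_params_from_repeat <- function(rp, dG_nn = NULL,
                                     split = c("uniform", "asymmetric"),
                                     delta = 0.5) {
  split <- match.arg(split)
  if (inherits(rp, "repeat_params")) {
    dG_unit <- rp$dG_unit
    dG_nn <- rp$dG_nn
  } else {
    dG_unit <- rp
  }
  g <- (dG_unit - dG_nn) / 2
  d <- if (split == "asymmetric") delta else 0
  helix_params(g_A = g - d, g_B = g + d, g_AB = dG_nn, g_BA = dG_nn,
               variant = "heteropolymer_helix")
}

## Type of helix at 0-based index i counted from the C-terminus:
## even -> B, odd -> A. Interface between indices i and i+1: i even -> AB
## (intra-repeat), i odd -> BA (inter-repeat).
helix_intrinsic_vector <- function(n_helices, params) {
  idx <- seq_len(n_helices) - 1L
  ifelse(idx %% 2L == 0L, params$g_B, params$g_A)
}

helix_interface_vector <- function(n_helices, params) {
  idx <- seq_len(n_helices - 1L) - 1L
  ifelse(idx %% 2L == 0L, params$g_AB, params$g_BA)
}

#' Folding free energy of a configuration
#'
#' Sum of the intrinsic energies of all folded units plus the interface
#' energies of all adjacent folded pairs (plus next-nearest-neighbor pairs
#' for the `heteropolymer_helix_nnn` variant). The all-unfolded state is
#' the zero of energy.
#'
#' @param config Integer/logical 0-1 vector, element 1 = C-terminal unit
#'   (helix index 0). For helix-level parameters the length must be even.
#' @param params A [helix_params()] or [repeat_params()] object.
#' @return Energy in kT.
#' @export
config_fold_energy <- function(config, params) {
  s <- as.integer(as.logical(config))
  n <- length(s)
  if (inherits(params, "repeat_params")) {
    e <- params$dG_unit * sum(s)
    if (n > 1) e <- e + params$dG_nn * sum(s[-n] * s[-1])
    return(e)
  }
  stopifnot(inherits(params, "helix_params"))
  if (n %% 2L != 0L) {
    abort("Helix-level fold-state vectors must have even length (2 per repeat).")
  }
  e <- sum(s * helix_intrinsic_vector(n, params))
  if (n > 1) e <- e + sum(s[-n] * s[-1] * helix_interface_vector(n, params))
  if (params$variant == "heteropolymer_helix_nnn" && n > 2) {
    idx <- seq_len(n - 2L) - 1L  # 0-based index of the left member of each pair
    w <- ifelse(idx %% 2L == 0L, params$g_BB, params$g_AA)
    e <- e + sum(s[seq_len(n - 2L)] * s[seq_len(n - 2L) + 2L] * w)
  }
  e
}

#' Total folding free energy of an N-repeat array
#'
#' `dG_tot = N dG_unit + (N - 1) dG_nn`: each repeat contributes its
#' intrinsic energy and each of the N-1 junctions the coupling.
#'
#' @param rp A [repeat_params()] object, or `dG_unit` as a number.
#' @param dG_nn Coupling in kT when `rp` is numeric.
#' @param n_repeats Number of repeats (>= 1); defaults to `rp$n_repeats`.
#' @return Total energy in kT.
#' @export
#' @examples
#' total_free_energy(repeat_params(1.5, -11.8), n_repeats = 5)
total_free_energy <- function(rp, dG_nn = NULL, n_repeats = NULL) {
  if (inherits(rp, "repeat_params")) {
    dG_unit <- rp$dG_unit
    dG_nn <- rp$dG_nn
    if (is.null(n_repeats)) n_repeats <- rp$n_repeats
  } else {
    dG_unit <- rp
  }
  if (is.null(n_repeats) || any(is.na(n_repeats)) || any(n_repeats < 1)) {
    abort("`n_repeats` must be >= 1.")
  }
  n_repeats * dG_unit + (n_repeats - 1) * dG_nn
}

#' Enumerate fold configurations under an approximation
#'
#' * `"full"`: all `2^n` fold states.
#' * `"zipper"`: the empty state plus every single contiguous folded block
#'   (`n(n+1)/2 + 1` states); unfolding proceeds from the ends.
#' * `"skip"`: the full set minus configurations whose folded content is
#'   only one or two helices, none of which touches a terminus (short
#'   isolated nuclei in the interior are eliminated; terminal frays are
#'   retained).
#'
#' @param n_helices Number of units (>= 1).
#' @param approximation `"full"`, `"skip"` or `"zipper"`.
#' @param cap Enumeration cap for `"full"`/`"skip"` (default 24 units).
#' @return Integer 0-1 matrix, one row per configuration; column j holds
#'   helix index j-1 (C-terminus first).
#' @export
enumerate_configurations <- function(n_helices,
                                     approximation = c("zipper", "skip", "full"),
                                     cap = 24L) {
  approximation <- match.arg(approximation)
  stopifnot(n_helices >= 1)
  if (approximation != "zipper" && n_helices > cap) {
    abort(sprintf(paste0(
      "Enumeration of %d units under the '%s' approximation exceeds the cap ",
      "of %d; use the zipper approximation for long arrays."),
      n_helices, approximation, cap))
  }
  if (approximation == "zipper") {
    states <- list(integer(n_helices))
    for (len in seq_len(n_helices)) {
      for (start in seq_len(n_helices - len + 1L)) {
        s <- integer(n_helices)
        s[start:(start + len - 1L)] <- 1L
        states[[length(states) + 1L]] <- s
      }
    }
    return(do.call(rbind, states))
  }
  m <- as.matrix(expand.grid(rep(list(0:1), n_helices)))
  dimnames(m) <- NULL
  m <- m[, seq_len(n_helices), drop = FALSE]
  if (approximation == "skip") {
    nf <- rowSums(m)
    internal_only <- m[, 1] == 0 & m[, n_helices] == 0
    m <- m[!(nf >= 1 & nf <= 2 & internal_only), , drop = FALSE]
  }
  m
}

## Maximal folded segments of a 0-1 vector: tibble-free helper returning a
## list with start indices (1-based) and lengths, ordered along the vector.
fold_segments <- function(config) {
  s <- as.integer(as.logical(config))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  list(start = starts[keep], length = r$lengths[keep])
}

#' Serialize a configuration as a 0/1 string (C-terminus first)
#' @param config 0-1 vector.
#' @return Character scalar.
#' @export
config_to_string <- function(config) {
  paste(as.integer(as.logical(config)), collapse = "")
}

#' Equilibrium unfolded fraction of a two-state unit
#'
#' For a unit with folding free energy `dG_fold` (folded minus unfolded,
#' kT) the unfolded population is `1 / (1 + exp(-dG_fold))`.
#'
#' @param dG_fold Folding free energy, kT (negative = stable fold).
#' @return Probability in (0, 1).
#' @export
#' @examples
#' fraction_unfolded(-1.9)  # a single CTPRa repeat, ~13% unfolded
fraction_unfolded <- function(dG_fold) {
  stopifnot(all(is.finite(dG_fold)))
  1 / (1 + exp(-dG_fold))
}

#' Minimal stable unit at zero force
#'
#' Smallest number `m` of consecutive folded helices whose folding free
#' energy is negative, minimized over all placements of the block along
#' the array. Returns `NA` if no block up to the array length is stable.
#'
#' @param params A [helix_params()] object, or a [repeat_params()] object
#'   (expanded with the uniform-interface split).
#' @param n_helices Largest block length considered (default 20).
#' @return Integer helix count, or `NA_integer_`.
#' @export
#' @examples
#' minimal_stable_unit(helix_params_from_repeat(repeat_params(1.1, -11.0)))
minimal_stable_unit <- function(params, n_helices = 20L) {
  if (inherits(params, "repeat_params")) {
    params <- helix_params_from_repeat(params)
  }
  stopifnot(inherits(params, "helix_params"))
  n_lattice <- 2L * ceiling(n_helices / 2L)
  for (m in seq_len(n_helices)) {
    for (start in seq_len(n_lattice - m + 1L)) {
      s <- integer(n_lattice)
      s[start:(start + m - 1L)] <- 1L
      if (config_fold_energy(s, params) < 0) return(m)
    }
  }
  NA_integer_
}
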