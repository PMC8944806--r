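## Force-extension laws for the passive mechanical elements of the assay:
## optical traps (harmonic), dsDNA handle (extensible worm-like chain) and
## unfolded polypeptide (worm-like chain). All forces in pN, lengths in nm,
## energies in pN nm unless stated otherwise.

#' Worm-like chain element
#'
#' Inextensible worm-like chain (WLC) in the Marko-Siggia interpolation.
#' Used for the unfolded polypeptide; the relative extension saturates
#' below 1 at any finite force.
#'
#' @param persistence_length Persistence length in nm (> 0).
#' @param contour_length Contour length in nm (>= 0).
#' @param thermal_energy Thermal energy kT in pN nm (default 4.114, 25 C).
#' @return An object of class `wlc`.
#' @seealso [ewlc_chain()], [harmonic_element()], [wlc_force()]
#' @export
#' @examples
#' chain <- wlc_chain(0.9, 100)
#' wlc_force(50, chain)
wlc_chain <- function(persistence_length, contour_length,
                      thermal_energy = .kT_default) {
  stopifnot(persistence_length > 0, contour_length >= 0, thermal_energy > 0)
  structure(
    list(persistence_length = persistence_length,
         contour_length = contour_length,
         thermal_energy = thermal_energy),
    class = "wlc"
  )
}

#' Extensible worm-like chain element
#'
#' WLC with a linear enthalpic stretching term `force / stretch_modulus`
#' added to the relative extension; the standard model for double-stranded
#' DNA handles. Reduces to [wlc_chain()] as `stretch_modulus` grows.
#'
#' @inheritParams wlc_chain
#' @param stretch_modulus Stretch modulus K in pN (> 0).
#' @return An object of class `c("ewlc", "wlc")`.
#' @export
ewlc_chain <- function(persistence_length, contour_length, stretch_modulus,
                       thermal_energy = .kT_default) {
  stopifnot(stretch_modulus > 0)
  obj <- wlc_chain(persistence_length, contour_length, thermal_energy)
  obj$stretch_modulus <- stretch_modulus
  class(obj) <- c("ewlc", "wlc")
  obj
}

#' Harmonic (Hookean) element
#'
#' Linear spring, used for each optical trap: extension = force / stiffness.
#'
#' @param stiffness Spring constant in pN/nm (> 0).
#' @return An object of class `harmonic`.
#' @export
harmonic_element <- function(stiffness) {
  stopifnot(stiffness > 0)
  structure(list(stiffness = stiffness), class = "harmonic")
}

## Relative WLC extension at reduced force fhat = F * Lp / kT.
## Marko-Siggia: fhat = 1/(4 (1-r)^2) - 1/4 + r, solved for r by vectorized
## bisection (20 halvings bracket the root to ~1e-6) followed by clamped
## Newton polish to machine precision. The residual is increasing and convex
## in r, so the clamped Newton steps cannot leave the bracket.
wlc_relext <- function(fhat) {
  out <- numeric(length(fhat))
  pos <- which(fhat > 0)
  if (!length(pos)) return(out)
  f <- fhat[pos]
  lo <- numeric(length(f))
  hi <- rep(1 - 1e-15, length(f))
  for (i in seq_len(13)) {
    mid <- 0.5 * (lo + hi)
    neg <- (0.25 / (1 - mid)^2 - 0.25 + mid) < f
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  r <- 0.5 * (lo + hi)
  for (i in seq_len(5)) {
    g <- 0.25 / (1 - r)^2 - 0.25 + r - f
    dg <- 0.5 / (1 - r)^3 + 1
    r <- pmin(pmax(r - g / dg, lo), hi)
  }
  out[pos] <- r
  out
}

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation formula. Strictly increasing in extension,
#' zero at zero extension, divergent as the extension approaches the
#' contour length.
#'
#' @param extension End-to-end extension in nm, `0 <= extension < contour_length`.
#' @param chain A [wlc_chain()] object.
#' @return Force in pN (vectorized over `extension`).
#' @export
wlc_force <- function(extension, chain) {
  stopifnot(inherits(chain, "wlc"))
  if (any(extension < 0) || any(extension >= chain$contour_length)) {
    abort("`extension` must lie in [0, contour_length).")
  }
  r <- extension / chain$contour_length
  chain$thermal_energy / chain$persistence_length *
    (0.25 / (1 - r)^2 - 0.25 + r)
}

#' Extension of an elastic element at a given force
#'
#' Inverts the force-extension law of the element. For the WLC this is the
#' numerical inversion of the Marko-Siggia formula; for the extensible WLC
#' the enthalpic term `force/K * Lc` is added; for a harmonic element it is
#' `force / stiffness`.
#'
#' @param element A `wlc`, `ewlc` or `harmonic` object.
#' @param force Force in pN (>= 0, vectorized).
#' @return Extension in nm.
#' @export
element_extension <- function(element, force) {
  if (any(force < 0)) abort("`force` must be non-negative.")
  UseMethod("element_extension")
}

#' @export
element_extension.wlc <- function(element, force) {
  fhat <- force * element$persistence_length / element$thermal_energy
  element$contour_length * wlc_relext(fhat)
}

#' @export
element_extension.ewlc <- function(element, force) {
  fhat <- force * element$persistence_length / element$thermal_energy
  element$contour_length * (wlc_relext(fhat) + force / element$stretch_modulus)
}

#' @export
element_extension.harmonic <- function(element, force) {
  force / element$stiffness
}

#' Extension of an extensible WLC at a given force
#'
#' Convenience wrapper around [element_extension()] for `ewlc` objects,
#' mirroring the handle model used when fitting DNA tethers.
#'
#' @param force Force in pN (>= 0).
#' @param chain An [ewlc_chain()] object.
#' @return Extension in nm.
#' @export
ewlc_extension <- function(force, chain) {
  stopifnot(inherits(chain, "ewlc"))
  element_extension(chain, force)
}

## Closed-form stored stretching energy of a Marko-Siggia WLC at relative
## extension r (per the antiderivative of the interpolation formula), pN nm.
## Used as the engine's fast path; the public stretch_free_energy() computes
## the same quantity by adaptive quadrature.
wlc_energy_closed <- function(r, Lp, Lc, kT) {
  kT / Lp * Lc * (r^2 / 2 - r / 4 + 0.25 / (1 - r) - 0.25)
}

element_energy_closed <- function(element, force) {
  if (inherits(element, "harmonic")) return(force^2 / (2 * element$stiffness))
  fhat <- force * element$persistence_length / element$thermal_energy
  r <- wlc_relext(fhat)
  g <- wlc_energy_closed(r, element$persistence_length,
                         element$contour_length, element$thermal_energy)
  if (inherits(element, "ewlc")) {
    g <- g + element$contour_length * force^2 / (2 * element$stretch_modulus)
  }
  g
}

#' Stretching free energy stored in an element at a given force
#'
#' The reversible work `integral F dx` from zero extension to the extension
#' at `force`, computed by adaptive numerical quadrature of the extension
#' over force (integration by parts: `G = F x(F) - integral x dF`).
#' For a harmonic element this equals `F^2 / (2 k)`.
#'
#' @param force Force in pN (>= 0, scalar or vector).
#' @param element A `wlc`, `ewlc` or `harmonic` object.
#' @return Stored energy in pN nm.
#' @export
stretch_free_energy <- function(force, element) {
  if (any(force < 0)) abort("`force` must be non-negative.")
  vapply(force, function(f) {
    if (f == 0) return(0)
    xf <- element_extension(element, f)
    ixdF <- integrate(function(ff) element_extension(element, ff),
                      0, f, rel.tol = 1e-10, abs.tol = 1e-12)$value
    f * xf - ixdF
  }, numeric(1))
}

#' Serial elastic network of the dumbbell assay
#'
#' Bundles the passive mechanical elements connecting the two beads: two
#' optical traps, one DNA handle and the (configuration-dependent) unfolded
#' polypeptide. All elements carry the same tension at mechanical
#' equilibrium and their extensions add.
#'
#' @param trap_stiffness Stiffness of each trap in pN/nm (two traps assumed).
#' @param handle Handle element, default [ewlc_chain()] with Lc = 350 nm,
#'   Lp = 40 nm, K = 1200 pN.
#' @param chain_Lp Persistence length of the unfolded polypeptide in nm.
#' @param nm_per_residue Contour length per residue in nm.
#' @param kT Thermal energy in pN nm.
#' @return An object of class `elastic_network`.
#' @export
elastic_network <- function(trap_stiffness = 0.30,
                            handle = NULL,
                            chain_Lp = 0.9,
                            nm_per_residue = 0.365,
                            kT = .kT_default) {
  if (is.null(handle)) handle <- ewlc_chain(40, 350, 1200, kT)
  stopifnot(trap_stiffness > 0, chain_Lp > 0, nm_per_residue > 0)
  structure(
    list(trap_stiffness = trap_stiffness,
         n_traps = 2L,
         handle = handle,
         chain_Lp = chain_Lp,
         nm_per_residue = nm_per_residue,
         kT = kT),
    class = "elastic_network"
  )
}

#' Build an elastic network from flat configuration keys
#'
#' Accepts the documented flat keys `kT_pNnm`, `trap_stiffness_pN_per_nm`,
#' `handle.Lc_nm`, `handle.Lp_nm`, `handle.K_pN`, `chain.Lp_nm`,
#' `chain.nm_per_residue`; missing keys fall back to the defaults of
#' [elastic_network()].
#'
#' @param config Named list (e.g. from a parsed YAML file).
#' @return An `elastic_network`.
#' @export
network_from_config <- function(config = list()) {
  g <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  kT <- g("kT_pNnm", .kT_default)
  elastic_network(
    trap_stiffness = g("trap_stiffness_pN_per_nm", 0.30),
    handle = ewlc_chain(g("handle.Lp_nm", 40), g("handle.Lc_nm", 350),
                        g("handle.K_pN", 1200), kT),
    chain_Lp = g("chain.Lp_nm", 0.9),
    nm_per_residue = g("chain.nm_per_residue", 0.365),
    kT = kT
  )
}

## Total elastic extension of the network (both traps + handle + unfolded
## chain of contour Lc) at tension F. Vectorized over F.
network_extension <- function(network, force, unfolded_contour = 0) {
  ext <- network$n_traps * force / network$trap_stiffness +
    element_extension(network$handle, force)
  if (unfolded_contour > 0) {
    fhat <- force * network$chain_Lp / network$kT
    ext <- ext + unfolded_contour * wlc_relext(fhat)
  }
  ext
}

## Elastic energy stored in the network at tension F (pN nm), closed forms.
network_energy <- function(network, force, unfolded_contour = 0) {
  en <- network$n_traps * force^2 / (2 * network$trap_stiffness) +
    element_energy_closed(network$handle, force)
  if (unfolded_contour > 0) {
    fhat <- force * network$chain_Lp / network$kT
    r <- wlc_relext(fhat)
    en <- en + wlc_energy_closed(r, network$chain_Lp, unfolded_contour,
                                 network$kT)
  }
  en
}

#' Tension in the serial network at a fixed trap separation
#'
#' Solves the mechanical force balance: finds the unique tension `F` at which
#' the summed extensions of traps, handle and unfolded chain plus the rigid
#' folded extension equal the trap separation. Separations at or below the
#' folded extension (slack) return exactly 0.
#'
#' @param trap_separation Total trap separation in nm.
#' @param network An [elastic_network()].
#' @param folded_extension Rigid end-to-end extension of the folded portion, nm.
#' @param unfolded_contour Contour length of the unfolded polypeptide, nm.
#' @param f_max Upper root bracket in pN (default 200).
#' @param tol Force tolerance in pN (default 1e-6).
#' @return Tension in pN (vectorized over `trap_separation`).
#' @export
series_force_balance <- function(trap_separation, network,
                                 folded_extension = 0, unfolded_contour = 0,
                                 f_max = 200, tol = 1e-6) {
  stopifnot(inherits(network, "elastic_network"))
  if (any(trap_separation < folded_extension)) {
    abort("`trap_separation` must be >= `folded_extension`.")
  }
  vapply(trap_separation, function(d) {
    gap <- d - folded_extension
    if (gap <= 0) return(0)
    f <- function(ff) network_extension(network, ff, unfolded_contour) - gap
    hi <- f(f_max)
    if (hi < 0) {
      abort(sprintf(paste0(
        "No force bracket in [0, %g] pN for separation %.3f nm ",
        "(folded extension %.3f nm, unfolded contour %.3f nm; ",
        "extension deficit at bracket top %.3f nm)."),
        f_max, d, folded_extension, unfolded_contour, -hi))
    }
    uniroot(f, c(0, f_max), tol = tol)$root
  }, numeric(1))
}

## Elementwise network extension for force/contour vectors of equal length.
network_extension_vec <- function(network, force, unfolded_contour) {
  e <- network$n_traps * force / network$trap_stiffness +
    element_extension(network$handle, force)
  pos <- unfolded_contour > 0
  if (any(pos)) {
    fhat <- force[pos] * network$chain_Lp / network$kT
    e[pos] <- e[pos] + unfolded_contour[pos] * wlc_relext(fhat)
  }
  e
}

## Vectorized fixed-iteration bisection used by the FDC engine: solves the
## force balance simultaneously for vectors of target gaps and unfolded
## contours (recycled elementwise). 52 halvings of [0, f_max].
balance_force_vec <- function(network, gap, unfolded_contour, f_max = 200) {
  n <- max(length(gap), length(unfolded_contour))
  gap <- rep_len(gap, n)
  lc <- rep_len(unfolded_contour, n)
  lo <- numeric(n)
  hi <- rep(f_max, n)
  ext_at <- function(ff) {
    e <- network$n_traps * ff / network$trap_stiffness +
      element_extension(network$handle, ff)
    pos <- lc > 0
    if (any(pos)) {
      fhat <- ff[pos] * network$chain_Lp / network$kT
      e[pos] <- e[pos] + lc[pos] * wlc_relext(fhat)
    }
    e
  }
  for (i in seq_len(52)) {
    mid <- 0.5 * (lo + hi)
    under <- ext_at(mid) < gap
    lo[under] <- mid[under]
    hi[!under] <- mid[!under]
  }
  out <- 0.5 * (lo + hi)
  out[gap <= 0] <- 0
  out
}

## Multiply the effective stiffness of the apparatus: traps get factor-fold
## stiffer and the handle contour shrinks factor-fold (its local stiffness
## scales as 1/Lc). Emulates stiff AFM-like probes.
#' Stiffen the apparatus connected to the protein
#'
#' Returns a copy of the network in which both trap stiffnesses are
#' multiplied by `factor` and the handle contour length is divided by it,
#' raising the effective series spring constant roughly `factor`-fold.
#' Used to emulate stiff (AFM-like) probes.
#'
#' @param network An [elastic_network()].
#' @param factor Stiffening factor (>= 1).
#' @return An `elastic_network`.
#' @export
stiffen_network <- function(network, factor) {
  stopifnot(factor >= 1)
  network$trap_stiffness <- network$trap_stiffness * factor
  network$handle$contour_length <- network$handle$contour_length / factor
  network
}
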