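## Turning raw stretch/relax cycles into averaged equilibrium FDCs and
## scalar observables: plateau force, protein folding work, contour-length
## gain. Works identically on measured and synthetic curves.

#' Bin and average repeated stretch/relax cycles
#'
#' Pools all cycles and directions, bins the trap separation and averages
#' the force within each bin, yielding one equilibrium FDC per molecule.
#' Bins without samples are dropped.
#'
#' @param cycles An `fdc` tibble (multiple cycles stacked) or a list of
#'   `fdc` tibbles.
#' @param bin_width Separation bin width in nm (default 1).
#' @return An `fdc` tibble with one row per non-empty bin (`cycle = 0`,
#'   `direction = "average"`), plus `n_obs` and `force_se` columns.
#' @export
average_cycles <- function(cycles, bin_width = 1) {
  if (is.list(cycles) && !is.data.frame(cycles)) {
    cycles <- dplyr::bind_rows(cycles)
  }
  if (nrow(cycles) == 0) abort("`cycles` is empty.")
  stopifnot(bin_width > 0)
  cycles |>
    dplyr::mutate(.bin = floor(.data$separation_nm / bin_width)) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      separation_nm = mean(.data$separation_nm),
      force_pN = mean(.data$force_pN),
      n_obs = dplyr::n(),
      force_se = sd(.data$force_pN) / sqrt(dplyr::n()),
      .groups = "drop") |>
    dplyr::select(-".bin") |>
    dplyr::arrange(.data$separation_nm) |>
    dplyr::mutate(cycle = 0L, direction = "average") |>
    as_fdc()
}

## Penalized alignment objective at distance offset d_off, with the force
## offset profiled out analytically (it enters the squared loss linearly).
## Returns list(cost, f_off) or NULL without sufficient overlap.
alignment_profile <- function(ref, cur, d_off, noise_var,
                              prior_force, prior_distance) {
  s <- cur$separation_nm + d_off
  lo <- max(min(ref$separation_nm), min(s))
  hi <- min(max(ref$separation_nm), max(s))
  if (hi <= lo) return(NULL)
  sel <- ref$separation_nm >= lo & ref$separation_nm <= hi
  if (sum(sel) < 5) return(NULL)
  grid <- ref$separation_nm[sel]
  fi <- approx(s, cur$force_pN, xout = grid)$y
  r <- ref$force_pN[sel] - fi
  n <- length(r)
  f_off <- sum(r) / (n + noise_var / prior_force^2)
  cost <- mean((r - f_off)^2) +
    noise_var * ((f_off / prior_force)^2 + (d_off / prior_distance)^2) / n
  list(cost = cost, f_off = f_off)
}

#' Rigid force/distance alignment of a set of FDCs
#'
#' Estimates one rigid offset pair per curve that minimizes the summed
#' squared force difference to the first curve (the fixed reference, offsets
#' 0/0) on the overlapping separation grid: a 0.5 nm scan over the distance
#' offset with the force offset profiled out in closed form, followed by
#' continuous refinement. Removes common per-molecule instrumental offsets
#' before averaging.
#'
#' Because the branches of an FDC are locally straight, a pure
#' least-squares offset is nearly degenerate along the direction
#' `d_force = slope x d_distance`; noisy curves wander along that valley.
#' The objective therefore includes a weak Gaussian prior on the offsets
#' (scales `prior_force`, `prior_distance`, weighted by the estimated
#' high-frequency noise variance), which vanishes for noiseless curves and
#' shrinks the degenerate direction toward zero otherwise.
#'
#' @param fdcs A list of `fdc` tibbles, or one stacked `fdc` tibble (split
#'   by `cycle`).
#' @param distance_window Half-range of the distance offset search, nm.
#' @param prior_force,prior_distance Prior SDs of the instrumental offsets
#'   (pN, nm).
#' @return Tibble with `curve`, `force_offset`, `distance_offset`; adding
#'   the offsets to a curve's columns aligns it to the reference.
#' @export
align_fdcs <- function(fdcs, distance_window = 6,
                       prior_force = 0.2, prior_distance = 1) {
  if (is.data.frame(fdcs)) {
    ids <- unique(fdcs$cycle)
    fdcs <- lapply(ids, function(i) fdcs[fdcs$cycle == i, ])
  } else {
    ids <- seq_along(fdcs)
  }
  if (length(fdcs) < 2) abort("Alignment needs at least 2 curves.")
  ref <- fdcs[[1]]
  ## high-frequency noise variance of the reference (first differences)
  noise_var <- var(diff(ref$force_pN[order(ref$separation_nm)])) / 2
  res <- purrr::map(seq_along(fdcs), function(i) {
    if (i == 1) return(c(0, 0))
    cur <- fdcs[[i]]
    dos <- seq(-distance_window, distance_window, by = 0.5)
    profs <- purrr::map(dos, function(b) {
      alignment_profile(ref, cur, b, noise_var, prior_force, prior_distance)
    })
    costs <- vapply(profs, function(p) if (is.null(p)) NA_real_ else p$cost,
                    numeric(1))
    if (all(is.na(costs))) abort("No overlapping separation grid between curves.")
    b0 <- dos[which.min(costs)]
    opt <- stats::optimize(function(b) {
      p <- alignment_profile(ref, cur, b, noise_var, prior_force,
                             prior_distance)
      if (is.null(p)) 1e6 else p$cost
    }, interval = c(b0 - 0.5, b0 + 0.5), tol = 1e-6)
    best <- alignment_profile(ref, cur, opt$minimum, noise_var, prior_force,
                              prior_distance)
    c(best$f_off, opt$minimum)
  })
  tibble(curve = ids,
         force_offset = vapply(res, `[`, numeric(1), 1),
         distance_offset = vapply(res, `[`, numeric(1), 2))
}

#' Apply alignment offsets to stacked cycles
#'
#' @param fdc Stacked `fdc` tibble.
#' @param offsets Output of [align_fdcs()].
#' @return The aligned `fdc` tibble.
#' @export
apply_alignment <- function(fdc, offsets) {
  idx <- match(fdc$cycle, offsets$curve)
  fdc$force_pN <- fdc$force_pN + offsets$force_offset[idx]
  fdc$separation_nm <- fdc$separation_nm + offsets$distance_offset[idx]
  fdc
}

#' Auto-detect the plateau window of an FDC
#'
#' Longest run of separations where the local slope of the smoothed curve
#' is below `slope_tol`. The slope is estimated by local linear regression
#' over `+- smooth_nm`, after which sub-threshold runs separated by short
#' excursions (superhelical force oscillations) are merged when the gap is
#' below `merge_nm`.
#'
#' @param fdc An `fdc` tibble.
#' @param slope_tol Slope threshold in pN/nm (default 0.02).
#' @param smooth_nm Half-width of the local slope regression, nm.
#' @param merge_nm Maximum gap between sub-threshold runs to merge, nm.
#' @return Numeric length-2 vector, the separation window in nm.
#' @export
detect_plateau_window <- function(fdc, slope_tol = 0.02, smooth_nm = 5,
                                  merge_nm = 50) {
  d <- fdc$separation_nm
  f <- fdc$force_pN
  slope <- vapply(seq_along(d), function(i) {
    sel <- abs(d - d[i]) <= smooth_nm
    if (sum(sel) < 3) return(NA_real_)
    stats::coef(stats::lm.fit(cbind(1, d[sel]), f[sel]))[2]
  }, numeric(1))
  flat <- !is.na(slope) & abs(slope) < slope_tol
  ## drop the slack/low-force region: a plateau lives above half the median
  flat <- flat & f > stats::median(f[f > 0.5]) * 0.5
  if (!any(flat)) abort("No plateau detected (no flat region).")
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  ## merge runs separated by short steep excursions (oscillations)
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- d[runs$start[i]] - d[merged$end[nrow(merged)]]
      if (gap <= merge_nm) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  span <- d[runs$end] - d[runs$start]
  best <- runs[which.max(span), ]
  c(d[best$start], d[best$end])
}

#' Plateau force from a Gaussian fit to the force histogram
#'
#' Histograms the force samples inside the plateau window (bin width
#' 0.1 pN) and fits a single Gaussian to the bin counts by nonlinear least
#' squares, as done for experimental FDCs. Returns the fitted center and
#' width.
#'
#' For noiseless model curves carrying a `force_sd_thermal` column (see
#' [equilibrium_fdc()] with `detail = TRUE`), each sample is spread over the
#' histogram with its thermal force SD, reproducing the histogram an
#' instrument would record; raw counts are used otherwise.
#'
#' @param fdc An `fdc` tibble.
#' @param window Optional separation window (length-2, nm); auto-detected
#'   via [detect_plateau_window()] when missing.
#' @param bin_pN Histogram bin width in pN.
#' @return Tibble with `plateau_force_pN`, `plateau_sigma_pN`, `window_lo`,
#'   `window_hi`, `n_obs`.
#' @export
plateau_force <- function(fdc, window = NULL, bin_pN = 0.1) {
  window <- window %||% detect_plateau_window(fdc)
  sel <- fdc$separation_nm >= window[1] & fdc$separation_nm <= window[2]
  if (!any(sel)) abort("Plateau window contains no data.")
  f <- fdc$force_pN[sel]
  breaks <- seq(floor(min(f) / bin_pN) * bin_pN - 2,
                ceiling(max(f) / bin_pN) * bin_pN + 2, by = bin_pN)
  mids <- breaks[-1] - bin_pN / 2
  if ("force_sd_thermal" %in% names(fdc)) {
    sds <- pmax(fdc$force_sd_thermal[sel], bin_pN / 2)
    counts <- rowSums(vapply(seq_along(f), function(i) {
      stats::dnorm(mids, f[i], sds[i]) * bin_pN
    }, numeric(length(mids))))
    dat <- data.frame(x = mids, y = counts)
  } else {
    h <- graphics::hist(f, breaks = breaks, plot = FALSE)
    dat <- data.frame(x = h$mids, y = h$counts)
  }
  start <- list(a = max(dat$y), mu = dat$x[which.max(dat$y)],
                sig = max(sd(f), bin_pN))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sig^2)), data = dat,
                      start = start,
                      lower = c(a = 0, mu = min(f), sig = bin_pN / 2),
                      upper = c(a = Inf, mu = max(f), sig = diff(range(f)) + 1),
                      control = list(maxiter = 200)),
    error = function(e) {
      abort(paste0("Gaussian plateau fit failed: ", conditionMessage(e),
                   "\nHistogram counts: ",
                   paste(dat$y, collapse = " ")))
    })
  co <- stats::coef(fit)
  tibble(plateau_force_pN = unname(co["mu"]),
         plateau_sigma_pN = abs(unname(co["sig"])),
         window_lo = window[1], window_hi = window[2], n_obs = sum(sel))
}

#' Protein folding work from the area under the curve
#'
#' Trapezoidal integral of the observed force over separation minus the
#' same integral for the always-unfolded reference curve of the identical
#' construct, over the shared separation range. Isolates the protein
#' contribution from linker and trap stretching. Sign convention: folding
#' work is negative.
#'
#' @param fdc An `fdc` tibble spanning the folded branch through the fully
#'   unfolded branch.
#' @param model A [ctpr_model()] providing the unfolded reference.
#' @return Work in kT (negative for a stable protein).
#' @export
unfolding_work <- function(fdc, model) {
  d <- fdc$separation_nm
  ref <- unfolded_reference_fdc(model, d)
  diff_f <- fdc$force_pN - ref$force_pN
  n <- length(d)
  tail_sel <- d >= d[n] - 0.05 * (d[n] - d[1])
  if (mean(abs(diff_f[tail_sel])) > 0.5) {
    abort(paste0("FDC does not reach the fully unfolded branch within its ",
                 "separation span; extend the grid."))
  }
  -trapz(d, diff_f) / model$network$kT
}

#' Always-unfolded reference force-distance curve
#'
#' Handle + traps + fully unfolded polypeptide, no folded extension: the
#' mechanical response of the construct with folding switched off.
#'
#' @param model A [ctpr_model()].
#' @param separations Trap separations, nm.
#' @return An `fdc` tibble.
#' @export
unfolded_reference_fdc <- function(model, separations) {
  lc <- max(model$group_lc)
  f <- balance_force_vec(model$network, separations, lc)
  as_fdc(tibble(separation_nm = separations, force_pN = f,
                cycle = 0L, direction = "model"))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2
}

#' Contour-length gain across the unfolding transition
#'
#' Fits the unfolded polypeptide contour length on the post-transition
#' branch after subtracting the known network (traps + handle) response,
#' and a rigid folded-extension offset on the pre-transition branch. The
#' difference in chain contour is the contour-length gain; dividing by the
#' repeat count gives the per-repeat gain.
#'
#' @param fdc An `fdc` tibble.
#' @param network The assay's [elastic_network()].
#' @param window Optional plateau window (nm); auto-detected otherwise.
#' @param f_min Minimum force for branch points, pN (avoids slack data).
#' @return Tibble with `contour_gain_nm`, `folded_offset_nm`, and the
#'   branch point counts.
#' @export
contour_length_gain <- function(fdc, network, window = NULL, f_min = 2) {
  window <- window %||% detect_plateau_window(fdc)
  pre <- fdc$separation_nm < window[1] & fdc$force_pN > f_min
  post <- fdc$separation_nm > window[2] & fdc$force_pN > f_min
  if (sum(pre) < 3 || sum(post) < 3) {
    abort("Too few points on the pre- or post-transition branch.")
  }
  resid_pre <- fdc$separation_nm[pre] -
    network_extension(network, fdc$force_pN[pre])
  xi0 <- mean(resid_pre)
  ## post-transition: d - x_network(F) = Lc * relext(F) (chain fully unfolded)
  r <- wlc_relext(fdc$force_pN[post] * network$chain_Lp / network$kT)
  resid_post <- fdc$separation_nm[post] -
    network_extension(network, fdc$force_pN[post])
  lc <- sum(resid_post * r) / sum(r^2)
  tibble(contour_gain_nm = lc, folded_offset_nm = xi0,
         n_pre = sum(pre), n_post = sum(post))
}

#' Locate force peaks in an FDC
#'
#' Local maxima of the force trace with at least the requested prominence
#' (height above the higher of the two flanking valleys, each valley taken
#' between the peak and the nearest higher terrain).
#'
#' @param fdc An `fdc` tibble (or any tibble with the two columns).
#' @param prominence Minimum prominence in pN.
#' @return Tibble of peaks (`separation_nm`, `force_pN`, `prominence`).
#' @export
find_force_peaks <- function(fdc, prominence = 0.25) {
  f <- fdc$force_pN
  n <- length(f)
  if (n < 3) return(tibble(separation_nm = numeric(), force_pN = numeric(),
                           prominence = numeric()))
  is_max <- which(f[2:(n - 1)] > f[1:(n - 2)] & f[2:(n - 1)] >= f[3:n]) + 1L
  prom <- vapply(is_max, function(i) {
    left <- f[1:i]
    higher_l <- which(left > f[i])
    lmin <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- f[i:n]
    higher_r <- which(right > f[i])
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    f[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence
  tibble(separation_nm = fdc$separation_nm[is_max[keep]],
         force_pN = f[is_max[keep]],
         prominence = prom[keep])
}

#' Detrended plateau oscillations
#'
#' Restricts the curve to the plateau window, removes a linear trend and
#' lightly smooths the residual (running mean over `smooth_nm`). Used to
#' count superhelical force-oscillation periods.
#'
#' @param fdc An `fdc` tibble.
#' @param window Optional window; auto-detected otherwise.
#' @param smooth_nm Running-mean width in nm.
#' @return Tibble (`separation_nm`, `residual_pN`).
#' @export
detrend_plateau <- function(fdc, window = NULL, smooth_nm = 4) {
  window <- window %||% detect_plateau_window(fdc)
  sel <- fdc$separation_nm >= window[1] & fdc$separation_nm <= window[2]
  d <- fdc$separation_nm[sel]
  f <- fdc$force_pN[sel]
  res <- stats::residuals(stats::lm(f ~ d))
  if (length(d) > 5) {
    k <- max(1L, round(smooth_nm / stats::median(diff(d))))
    if (k > 1) {
      kern <- rep(1 / k, k)
      res <- as.numeric(stats::filter(res, kern, sides = 2))
      keep <- !is.na(res)
      d <- d[keep]; res <- res[keep]
    }
  }
  tibble(separation_nm = d, residual_pN = res)
}

#' Count superhelical oscillation periods of an FDC
#'
#' Each completed superhelical turn of the shrinking folded remainder
#' produces one force valley across the plateau; the count of prominent
#' local force minima is therefore the number of oscillation periods (the
#' linker branches are monotone and contribute none). The curve is lightly
#' smoothed first so the counter also works on averaged noisy data.
#'
#' @param fdc An `fdc` tibble.
#' @param prominence Minimum valley prominence in pN.
#' @param smooth_nm Running-mean width in nm.
#' @return Integer period count.
#' @export
count_plateau_oscillations <- function(fdc, prominence = 0.1, smooth_nm = 3) {
  d <- fdc$separation_nm
  f <- fdc$force_pN
  k <- max(1L, round(smooth_nm / stats::median(diff(d))))
  if (k > 1) {
    f <- as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
    keep <- !is.na(f)
    d <- d[keep]; f <- f[keep]
  }
  nrow(find_force_peaks(tibble(separation_nm = d, force_pN = -f), prominence))
}
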