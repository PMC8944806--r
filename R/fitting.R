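## Parameter estimation: nonlinear least squares of model force-distance
## curves against averaged data, model-variant comparison by AIC, and the
## global Ising fit to chemical-denaturation curve families.

variant_parameterization <- function(variant, constrain, delta = 0.5) {
  switch(variant,
    homopolymer_helix = list(
      terms = c("g", "g_nn"),
      start = c(g = 0, g_nn = -5),
      lower = c(-10, -20), upper = c(10, 5),
      build = function(p) homopolymer_helix_params(p[["g"]], p[["g_nn"]])),
    heteropolymer_helix = if (constrain) list(
      terms = c("dG_unit", "dG_nn"),
      start = c(dG_unit = 0, dG_nn = -10),
      lower = c(-10, -25), upper = c(10, 0),
      build = function(p) helix_params_from_repeat(
        repeat_params(p[["dG_unit"]], p[["dG_nn"]]),
        split = "asymmetric", delta = delta)
    ) else list(
      terms = c("g_A", "g_B", "g_AB", "g_BA"),
      start = c(g_A = 3, g_B = 3, g_AB = -8, g_BA = -8),
      lower = c(-10, -10, -25, -25), upper = c(15, 15, 5, 5),
      build = function(p) helix_params(p[["g_A"]], p[["g_B"]],
                                       p[["g_AB"]], p[["g_BA"]])),
    ## next-nearest-neighbor couplings are additional interfacial contacts:
    ## they stabilize or are absent, so they are bounded above by zero
    heteropolymer_helix_nnn = list(
      terms = c("g_A", "g_B", "g_AB", "g_BA", "g_AA", "g_BB"),
      start = c(g_A = 3, g_B = 3, g_AB = -8, g_BA = -8, g_AA = 0, g_BB = 0),
      lower = c(-10, -10, -25, -25, -8, -8), upper = c(15, 15, 5, 5, 0, 0),
      build = function(p) helix_params(p[["g_A"]], p[["g_B"]], p[["g_AB"]],
                                       p[["g_BA"]], p[["g_AA"]], p[["g_BB"]],
                                       variant = "heteropolymer_helix_nnn")),
    abort(sprintf("Unknown model variant '%s'.", variant)))
}

#' Fit Ising energetics to an averaged force-distance curve
#'
#' Bounded Levenberg-Marquardt least squares of the equilibrium model force
#' against the observed force over the curve's separation grid. Geometry and
#' elastic-network constants stay fixed (identifiability); only the folding
#' energetics are estimated. Standard errors come from the residual-scaled
#' curvature (Gauss-Newton covariance); a seedable residual bootstrap is
#' available via `n_boot`.
#'
#' @param fdc An averaged `fdc` tibble.
#' @param n_repeats Number of repeats of the construct.
#' @param variant `"heteropolymer_helix"` (default), `"homopolymer_helix"`
#'   or `"heteropolymer_helix_nnn"`.
#' @param approximation Configuration-space approximation.
#' @param geometry,network Fixed mechanical model parts.
#' @param constrain For the heteropolymer variant: estimate the two
#'   repeat-level sums (`dG_unit`, `dG_nn`) through the preset helix split
#'   (default) instead of four free helix energies.
#' @param delta Helix asymmetry used by the constrained split, kT.
#' @param start,lower,upper Optional named overrides of the default
#'   starting values and box bounds.
#' @param fixed Named vector of parameters to hold fixed.
#' @param extension_model Passed to [ctpr_model()].
#' @param multistart Run the optimizer from a small grid of starting points
#'   and keep the best minimum (recommended; the RSS valley is curved).
#' @param fit_offsets Estimate rigid distance/force offsets alongside the
#'   energetics, absorbing residual instrumental miscalibration (zero
#'   distance, force baseline) left after cycle alignment.
#' @param weighted Weight residuals by the inverse per-bin standard error
#'   (`force_se` column from [average_cycles()]) when available; the
#'   plateau is noisier than the linker branches.
#' @param n_boot Residual-bootstrap draws for standard errors (0 = use
#'   curvature only).
#' @param boot_seed Seed for the bootstrap.
#' @return A `ctpr_fit` object with [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
fit_fdc <- function(fdc, n_repeats,
                    variant = c("heteropolymer_helix", "homopolymer_helix",
                                "heteropolymer_helix_nnn"),
                    approximation = "zipper",
                    geometry = superhelix_geometry(),
                    network = elastic_network(),
                    constrain = TRUE, delta = 0.5,
                    start = NULL, lower = NULL, upper = NULL, fixed = NULL,
                    extension_model = "superhelix",
                    multistart = TRUE, fit_offsets = TRUE, weighted = TRUE,
                    n_boot = 0, boot_seed = 1L) {
  variant <- match.arg(variant)
  pz <- variant_parameterization(variant, constrain, delta)
  p0 <- pz$start
  lo <- setNames(pz$lower, pz$terms)
  hi <- setNames(pz$upper, pz$terms)
  if (!is.null(start)) p0[names(start)] <- start
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (fit_offsets) {
    pz$terms <- c(pz$terms, "d_offset", "f_offset")
    pz$start <- c(pz$start, d_offset = 0, f_offset = 0)
    lo <- c(lo, d_offset = -10, f_offset = -1.5)
    hi <- c(hi, d_offset = 10, f_offset = 1.5)
    p0 <- c(p0, d_offset = 0, f_offset = 0)
  }
  free <- setdiff(pz$terms, names(fixed))
  d <- fdc$separation_nm
  y <- fdc$force_pN
  ## inverse-variance weights from the per-bin standard errors of the cycle
  ## average (the plateau fluctuates more than the linker branches)
  w <- rep(1, length(y))
  if (weighted && "force_se" %in% names(fdc) &&
      all(is.finite(fdc$force_se)) && all(fdc$force_se > 0)) {
    w <- 1 / fdc$force_se
    w <- w / sqrt(mean(w^2))  # unit mean square: RSS keeps its force scale
  }

  ## The state space, folded extensions and force balances do not depend on
  ## the Ising energies: build the model skeleton and the per-group
  ## mechanics once, and only re-score fold energies per iteration. The
  ## rigid instrumental offsets enter through interpolation of the model
  ## curve computed on a padded grid.
  skeleton <- ctpr_model(n_repeats, pz$build(p0), geometry = geometry,
                         network = network, approximation = approximation,
                         extension_model = extension_model)
  step <- stats::median(diff(d))
  dgrid <- if (fit_offsets) {
    seq(min(d) - 10.5, max(d) + 10.5, by = min(step, 1))
  } else d
  gm <- group_mechanics(skeleton, dgrid)
  model_force <- function(p_free) {
    p <- c(p_free, fixed)[pz$terms]
    names(p) <- pz$terms
    ef <- states_fold_energy(skeleton$states,
                             pz$build(p[setdiff(pz$terms,
                                                c("d_offset", "f_offset"))]))
    st <- ensemble_stats(skeleton, dgrid, gm = gm, e_fold = ef)
    fm <- vapply(st, `[[`, numeric(1), "force")
    if (!fit_offsets) return(fm)
    stats::spline(dgrid, fm, xout = d + p[["d_offset"]])$y + p[["f_offset"]]
  }
  resid_fn <- function(p_free) w * (y - model_force(setNames(p_free, free)))

  ## The RSS surface has a curved, shallow valley along the direction that
  ## trades intrinsic against interfacial stability (the diagonal scatter of
  ## per-molecule fits); a single LM run can stall partway along it. Run LM
  ## from a small grid of starting points and keep the best minimum.
  starts <- list(p0[free])
  if (multistart) {
    base_grid <- switch(variant,
      homopolymer_helix = expand.grid(g = c(-2, 4), g_nn = c(-12, -4)),
      heteropolymer_helix = if (constrain) {
        expand.grid(dG_unit = c(-3, 0, 3), dG_nn = c(-14, -11, -8))
      } else {
        expand.grid(g_A = c(1, 5), g_B = 3, g_AB = c(-12, -7),
                    g_BA = c(-14, -9))
      },
      heteropolymer_helix_nnn = expand.grid(g_A = c(1, 5), g_B = 3,
                                            g_AB = c(-12, -7),
                                            g_BA = c(-14, -9),
                                            g_AA = 0, g_BB = 0))
    starts <- c(starts, purrr::map(seq_len(nrow(base_grid)), function(i) {
      s <- p0
      s[names(base_grid)] <- as.numeric(base_grid[i, ])
      s[free]
    }))
  }
  runs <- purrr::map(starts, function(s) {
    tryCatch(minpack.lm::nls.lm(
      par = s, lower = lo[free], upper = hi[free], fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-10)),
      error = function(e) NULL)
  })
  runs <- purrr::compact(runs)
  if (!length(runs)) abort("All FDC fit starts failed.")
  res <- runs[[which.min(vapply(runs, `[[`, numeric(1), "deviance"))]]
  if (res$info == 0 || res$info == 9) {
    abort(paste0("FDC fit did not converge: ", res$message,
                 "\nTrace: par = ", paste(round(res$par, 4), collapse = ", "),
                 "; deviance = ", signif(res$deviance, 6)))
  }
  est <- res$par
  n <- length(y)
  k <- length(free)
  rss <- res$deviance
  sigma2 <- rss / max(n - k, 1)
  vc <- tryCatch(sigma2 * solve(res$hessian / 2), error = function(e) {
    matrix(NA_real_, k, k)
  })
  se <- sqrt(pmax(diag(vc), 0))

  boot <- NULL
  fitted0 <- y - res$fvec / w
  if (n_boot > 0) {
    set.seed(boot_seed)
    r0 <- res$fvec - mean(res$fvec)  # standardized (weighted) residuals
    draws <- purrr::map(seq_len(n_boot), function(b) {
      yb <- fitted0 + sample(r0, n, replace = TRUE) / w
      rb <- minpack.lm::nls.lm(
        par = est, lower = lo[free], upper = hi[free],
        fn = function(p) w * (yb - model_force(setNames(p, free))),
        control = minpack.lm::nls.lm.control(maxiter = 100))
      rb$par
    })
    boot <- do.call(rbind, draws)
    se <- apply(boot, 2, sd)
  }

  structure(
    list(estimates = tibble(term = free, estimate = unname(est),
                            std.error = unname(se)),
         vcov = vc, rss = rss, sigma = sqrt(sigma2), n = n, k = k,
         variant = variant, approximation = approximation,
         constrain = constrain, delta = delta, n_repeats = n_repeats,
         data = fdc, fitted = fitted0,
         geometry = geometry, network = network,
         extension_model = extension_model,
         convergence = res$info, message = res$message,
         bootstrap = boot),
    class = "ctpr_fit")
}

#' @export
print.ctpr_fit <- function(x, ...) {
  cat(sprintf("<ctpr_fit> %s (%s approximation), N = %d repeats\n",
              x$variant, x$approximation, x$n_repeats))
  print(x$estimates)
  cat(sprintf("RSS %.4g on %d points (sigma %.3g pN)\n", x$rss, x$n, x$sigma))
  invisible(x)
}

#' @rdname fit_fdc
#' @param x A `ctpr_fit` object.
#' @param ... Unused.
#' @method tidy ctpr_fit
#' @export
tidy.ctpr_fit <- function(x, ...) x$estimates

#' @rdname fit_fdc
#' @method glance ctpr_fit
#' @export
glance.ctpr_fit <- function(x, ...) {
  tibble(variant = x$variant, approximation = x$approximation,
         n = x$n, k = x$k, rss = x$rss, sigma = x$sigma,
         aic = aic_ls(x$n, x$rss, x$k))
}

#' Remove fitted instrumental offsets from an FDC
#'
#' Applies the rigid distance/force offsets estimated by [fit_fdc()]
#' (`fit_offsets = TRUE`) to the curve, putting it on the model's absolute
#' force and separation scales. Recommended before computing areas under
#' the curve or contour-length gains.
#'
#' @param fdc The `fdc` tibble that was fitted.
#' @param fit The corresponding `ctpr_fit`.
#' @return The corrected `fdc` tibble.
#' @export
apply_fit_offsets <- function(fdc, fit) {
  p <- setNames(fit$estimates$estimate, fit$estimates$term)
  if ("d_offset" %in% names(p)) {
    fdc$separation_nm <- fdc$separation_nm + p[["d_offset"]]
  }
  if ("f_offset" %in% names(p)) {
    fdc$force_pN <- fdc$force_pN - p[["f_offset"]]
  }
  fdc
}

#' Repeat-level summary of a fitted heteropolymer model
#'
#' Collapses the fitted helix energies to `dG_unit`/`dG_nn` via the adopted
#' energy algebra and evaluates the total free energy of the construct.
#'
#' @param fit A `ctpr_fit`.
#' @return Tibble with `dG_unit`, `dG_nn`, `dG_tot`.
#' @export
fit_repeat_energies <- function(fit) {
  p <- setNames(fit$estimates$estimate, fit$estimates$term)
  rp <- if (fit$variant == "homopolymer_helix") {
    repeat_params(2 * p[["g"]] + p[["g_nn"]], p[["g_nn"]])
  } else if (fit$constrain && all(c("dG_unit", "dG_nn") %in% names(p))) {
    repeat_params(p[["dG_unit"]], p[["dG_nn"]])
  } else {
    repeat_params(p[["g_A"]] + p[["g_B"]] + p[["g_AB"]], p[["g_BA"]])
  }
  tibble(dG_unit = rp$dG_unit, dG_nn = rp$dG_nn,
         dG_tot = total_free_energy(rp, n_repeats = fit$n_repeats))
}

## Gaussian-residual AIC for least-squares fits.
aic_ls <- function(n, rss, k) n * log(rss / n) + 2 * k

#' Compare model variants fitted to the same data by AIC
#'
#' `AIC = n ln(RSS/n) + 2k` (Gaussian residuals), ranked ascending with
#' differences to the best model.
#'
#' @param ... `ctpr_fit` objects, or a single list of them.
#' @return Tibble ranked by AIC with `delta_aic`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "ctpr_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "ctpr_fit")))
  ref <- fits[[1]]$data
  same <- vapply(fits, function(f) {
    nrow(f$data) == nrow(ref) &&
      isTRUE(all.equal(f$data$separation_nm, ref$separation_nm)) &&
      isTRUE(all.equal(f$data$force_pN, ref$force_pN))
  }, logical(1))
  if (!all(same)) abort("All fits must be to identical data.")
  out <- purrr::map_dfr(fits, glance)
  out <- dplyr::arrange(out, .data$aic)
  out$delta_aic <- out$aic - out$aic[1]
  out
}

#' Global Ising fit to chemical-denaturation curves
#'
#' Fits a repeat-level homopolymer Ising model jointly to denaturation
#' curves of several array lengths: the intrinsic repeat energy varies
#' linearly with denaturant (`dG_unit(D) = dG_unit + m_unit D`), the
#' coupling is denaturant-independent, and each curve carries linear folded
#' and unfolded baselines.
#'
#' @param data Tibble with columns `n_repeats`, `denaturant_M`, `signal`.
#' @param start Optional named starting values (`dG_unit`, `m_unit`,
#'   `dG_nn`).
#' @param shared_baselines Share one folded/unfolded baseline pair across
#'   curves (default) or fit per-curve baselines.
#' @return A `denat_fit` object with [tidy()] and [glance()] methods.
#' @export
fit_denaturation <- function(data, start = NULL, shared_baselines = TRUE) {
  stopifnot(all(c("n_repeats", "denaturant_M", "signal") %in% names(data)))
  lengths <- sort(unique(data$n_repeats))
  if (length(lengths) < 2) {
    warn("Fewer than 2 array lengths: dG_unit and dG_nn are degenerate.")
  }
  p0 <- c(dG_unit = 0, m_unit = 1.5, dG_nn = -5)
  if (!is.null(start)) p0[names(start)] <- start
  nbl <- if (shared_baselines) 1L else length(lengths)
  bl0 <- rep(c(1, 0, 0, 0), nbl)
  names(bl0) <- paste0(rep(c("bf0", "bf1", "bu0", "bu1"), nbl),
                       rep(seq_len(nbl), each = 4))
  par0 <- c(p0, bl0)

  predict_signal <- function(p) {
    unlist(purrr::map(seq_along(lengths), function(li) {
      n <- lengths[li]
      idx <- if (shared_baselines) 1L else li
      b <- p[paste0(c("bf0", "bf1", "bu0", "bu1"), idx)]
      d <- data$denaturant_M[data$n_repeats == n]
      phi <- vapply(d, function(D) {
        ising_fraction_folded(p[["dG_unit"]] + p[["m_unit"]] * D,
                              p[["dG_nn"]], n)
      }, numeric(1))
      (b[1] + b[2] * d) * phi + (b[3] + b[4] * d) * (1 - phi)
    }))
  }
  y <- unlist(purrr::map(lengths, function(n) data$signal[data$n_repeats == n]))
  res <- minpack.lm::nls.lm(
    par = par0, fn = function(p) y - predict_signal(p),
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12))
  n <- length(y); k <- length(par0)
  sigma2 <- res$deviance / max(n - k, 1)
  se <- tryCatch(sqrt(pmax(diag(sigma2 * solve(res$hessian / 2)), 0)),
                 error = function(e) rep(NA_real_, k))
  totals <- tibble(
    n_repeats = lengths,
    dG_tot = total_free_energy(repeat_params(res$par[["dG_unit"]],
                                             res$par[["dG_nn"]]),
                               n_repeats = lengths))
  structure(
    list(estimates = tibble(term = names(par0), estimate = unname(res$par),
                            std.error = unname(se)),
         rss = res$deviance, n = n, k = k, lengths = lengths,
         totals = totals, data = data, fitted = predict_signal(res$par),
         shared_baselines = shared_baselines, convergence = res$info),
    class = "denat_fit")
}

#' @export
print.denat_fit <- function(x, ...) {
  cat(sprintf("<denat_fit> global Ising fit to %d lengths (N = %s)\n",
              length(x$lengths), paste(x$lengths, collapse = ", ")))
  print(head(x$estimates, 3))
  print(x$totals)
  invisible(x)
}

#' @rdname fit_denaturation
#' @param x A `denat_fit`.
#' @param ... Unused.
#' @method tidy denat_fit
#' @export
tidy.denat_fit <- function(x, ...) x$estimates

#' @rdname fit_denaturation
#' @method glance denat_fit
#' @export
glance.denat_fit <- function(x, ...) {
  tibble(n = x$n, k = x$k, rss = x$rss,
         aic = aic_ls(x$n, x$rss, x$k),
         dG_unit = x$estimates$estimate[x$estimates$term == "dG_unit"],
         dG_nn = x$estimates$estimate[x$estimates$term == "dG_nn"],
         m_unit = x$estimates$estimate[x$estimates$term == "m_unit"])
}
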