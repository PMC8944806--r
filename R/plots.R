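## ggplot2 views of the package's result types.

#' Plot a force-distance curve
#' @param object An `fdc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdc
#' @export
autoplot.fdc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$separation_nm, y = .data$force_pN,
                               colour = .data$direction,
                               group = .data$cycle)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Trap separation (nm)", y = "Force (pN)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an FDC fit
#' @param object A `ctpr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctpr_fit
#' @export
autoplot.ctpr_fit <- function(object, ...) {
  dat <- object$data
  dat$fitted <- object$fitted
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$separation_nm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$force_pN),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d55e00") +
    ggplot2::labs(x = "Trap separation (nm)", y = "Force (pN)",
                  title = sprintf("%s fit (%s approximation)",
                                  object$variant, object$approximation)) +
    ggplot2::theme_minimal()
}

#' Plot a ranked configuration ensemble
#' @param object An `ensemble_snapshot`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_snapshot
#' @export
autoplot.ensemble_snapshot <- function(object, ...) {
  cfg <- object$configurations
  grid <- purrr::map_dfr(seq_len(nrow(cfg)), function(i) {
    s <- as.integer(strsplit(cfg$fold_state[i], "")[[1]])
    tibble(rank = cfg$rank[i], helix = seq_along(s) - 1L, folded = s,
           probability = cfg$probability[i])
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$helix, y = .data$rank)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$folded * .data$probability),
                       colour = "grey80") +
    ggplot2::scale_y_reverse(breaks = cfg$rank) +
    ggplot2::scale_fill_gradient(low = "white", high = "#0072b2",
                                 name = "P(folded)") +
    ggplot2::labs(x = "Helix index (0 = C-terminal)", y = "Rank",
                  title = sprintf("d = %.1f nm, P(unfolded) = %.2f",
                                  object$trap_separation, object$p_unfolded)) +
    ggplot2::theme_minimal()
}

#' Plot a denaturation fit
#' @param object A `denat_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot denat_fit
#' @export
autoplot.denat_fit <- function(object, ...) {
  dat <- object$data
  dat$fitted <- NA_real_
  pos <- 1L
  for (n in object$lengths) {
    sel <- dat$n_repeats == n
    dat$fitted[sel] <- object$fitted[pos:(pos + sum(sel) - 1L)]
    pos <- pos + sum(sel)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$denaturant_M,
                                    colour = factor(.data$n_repeats))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "Denaturant (M)", y = "Normalized signal",
                  colour = "Repeats") +
    ggplot2::theme_minimal()
}

#' Heatmap of the per-helix fold-probability profile
#'
#' @param profile Output of [helix_fold_profile()].
#' @return A ggplot object.
#' @export
plot_fold_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$separation_nm,
                                        y = .data$helix,
                                        fill = .data$p_folded)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "P(folded)", limits = c(0, 1)) +
    ggplot2::labs(x = "Trap separation (nm)",
                  y = "Helix index (0 = C-terminal)") +
    ggplot2::theme_minimal()
}
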