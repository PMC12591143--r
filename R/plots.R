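#' Plot a composition phase diagram
#'
#' Tiles the `F_ab` x `F_A` plane with the phase classification of each
#' feasible composition, the standard view of the mixing behaviour of the
#' nanostar-linker system.
#'
#' @param data A composition tibble with `F_A`, `F_ab` and `phase`
#'   columns, e.g. from [composition_grid()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$F_A, .data$F_ab,
    fill = .data$phase
  )) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(biphasic = "#5e3c99", monophasic = "#e66101")
    ) +
    ggplot2::labs(x = expression(F[A]), y = expression(F[ab])) +
    ggplot2::theme_minimal()
}

#' Plot simulation snapshots
#'
#' @param object An `fh_sim` object from [fh_run()].
#' @param ... Unused.
#' @return A ggplot showing `phi_A - phi_B` for each checkpoint, faceted
#'   by simulation time (blue = B-rich, red = A-rich).
#' @export
autoplot.fh_sim <- function(object, ...) {
  df <- purrr::map_dfr(seq_along(object$states), function(i) {
    s <- object$states[[i]]
    d <- s$phi_A - s$phi_B
    tibble::tibble(
      time = s$time,
      row = as.vector(row(d)), col = as.vector(col(d)),
      diff = as.vector(d)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$diff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = expression(phi[A] - phi[B]))
}

#' Plot a chi sweep with its boundary extrapolation
#'
#' @param sweep A [sweep_chi_ab()] table.
#' @param boundary Optionally, the matching [estimate_boundary()] result;
#'   computed if missing.
#' @return A ggplot of median `cos(theta/2)` versus `chi_AB` with the
#'   linear fit and its zero crossing.
#' @export
plot_chi_sweep <- function(sweep, boundary = NULL) {
  boundary <- boundary %||% estimate_boundary(sweep)
  ggplot2::ggplot(sweep, ggplot2::aes(.data$chi_AB, .data$cos_half_theta)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = boundary$fit$slope, intercept = boundary$fit$intercept,
      linetype = "dashed"
    ) +
    ggplot2::geom_vline(xintercept = boundary$chi_star, colour = "grey50") +
    ggplot2::labs(x = expression(chi[AB]), y = expression(cos(theta / 2))) +
    ggplot2::theme_minimal()
}
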