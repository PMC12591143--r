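#' Coefficient-of-variation trace of an image stack
#'
#' For each frame and channel, computes the ratio of the standard
#' deviation to the mean of the pixel values over the full field of view.
#' The trace is high while bright condensates stand out of the background
#' and collapses when they dissolve, so slope breaks locate the
#' assembly/melting transition. Zero-mean frames yield a masked (`NA`)
#' point.
#'
#' @param frames A `melt_stack` object, or a list of
#'   [two_channel_image()] frames.
#' @param temperatures One temperature per frame (taken from the stack if
#'   omitted).
#' @param direction `"heating"` or `"cooling"` (taken from the stack if
#'   omitted).
#' @return A tibble of class `melt_trace` with columns `temperature`,
#'   `cv_A`, `cv_B`, `direction`.
#' @export
cv_trace <- function(frames, temperatures = NULL, direction = NULL) {
  if (inherits(frames, "melt_stack")) {
    temperatures <- temperatures %||% frames$temperatures
    direction <- direction %||% frames$direction
    frames <- frames$frames
  }
  direction <- direction %||% "heating"
  if (length(frames) != length(temperatures)) {
    rlang::abort("Need exactly one temperature per frame.")
  }
  dims <- dim(frames[[1]]$channel_A)
  cv <- function(x) {
    if (!all(dim(x) == dims)) rlang::abort("Stack frames must share shape.")
    m <- mean(x)
    if (m == 0) {
      return(NA_real_)
    }
    sd(x) / m
  }
  out <- tibble::tibble(
    temperature = temperatures,
    cv_A = vapply(frames, function(f) cv(f$channel_A), numeric(1)),
    cv_B = vapply(frames, function(f) cv(f$channel_B), numeric(1)),
    direction = direction
  )
  class(out) <- c("melt_trace", class(out))
  out
}

# continuous piecewise-linear least squares with hinge knots
pw_fit <- function(t, y, brks) {
  X <- cbind(t, vapply(brks, function(b) pmax(t - b, 0), numeric(length(t))))
  fit <- lm(y ~ X)
  slopes <- cumsum(coef(fit)[-1])
  list(sse = sum(resid(fit)^2), slopes = slopes)
}

detect_tm_channel <- function(t, y, min_improvement = 0.5,
                              min_slope_ratio = 3) {
  ok <- is.finite(y)
  t <- t[ok]
  y <- y[ok]
  if (length(t) < 8) {
    rlang::abort("Need at least 8 temperature points for breakpoint detection.")
  }
  o <- order(t)
  t <- t[o]
  y <- y[o]
  sse0 <- sum(resid(lm(y ~ t))^2)
  # scan all interior knot pairs, then refine continuously: the middle
  # segment brackets the transition, and T_m is its midpoint
  cands <- t[2:(length(t) - 1)]
  pairs <- which(
    outer(cands, cands, function(a, b) b > a),
    arr.ind = TRUE
  )
  sses <- vapply(seq_len(nrow(pairs)), function(k) {
    pw_fit(t, y, c(cands[pairs[k, 1]], cands[pairs[k, 2]]))$sse
  }, numeric(1))
  b0 <- cands[pairs[which.min(sses), ]]
  step <- diff(range(t)) / (length(t) - 1)
  opt <- stats::optim(
    b0,
    function(b) {
      if (b[1] >= b[2] - 1e-9) {
        return(Inf)
      }
      pw_fit(t, y, b)$sse
    },
    method = "L-BFGS-B",
    lower = pmax(min(t), b0 - step), upper = pmin(max(t), b0 + step)
  )
  best <- pw_fit(t, y, opt$par)
  improvement <- if (sse0 > 0) 1 - best$sse / sse0 else 0
  slope_ratio <- abs(best$slopes[2]) /
    max(abs(best$slopes[c(1, 3)]), .Machine$double.eps)
  # the middle-segment drop must carry most of the trace variation, and
  # the variation itself must be non-trivial relative to the cv level --
  # otherwise the "transition" is just structure in the residuals
  drop <- abs(best$slopes[2]) * diff(opt$par)
  y_range <- diff(range(y))
  rel_range <- y_range / max(abs(y), .Machine$double.eps)
  tibble::tibble(
    t_m = mean(opt$par),
    residual = sqrt(best$sse / length(t)),
    transition = improvement >= min_improvement &&
      slope_ratio >= min_slope_ratio &&
      drop >= 0.5 * y_range && rel_range >= 0.2,
    improvement = improvement
  )
}

#' Detect melting temperatures from a CV trace
#'
#' Fits a continuous three-segment piecewise-linear model to each
#' channel's coefficient-of-variation trace (plateau, transition, plateau),
#' scanning both knots over the observed temperatures and refining them
#' continuously. The transition temperature is the midpoint of the steep
#' middle segment. A trace on which the segmented fit does not
#' substantially improve over a single line, or whose middle segment is
#' not markedly steeper than the plateaus (no sharp slope change), is
#' flagged as having no transition.
#'
#' @param trace A [cv_trace()] tibble.
#' @param min_improvement Minimum fractional reduction in squared error of
#'   the segmented fit over a single line for a transition to be called
#'   (default 0.5).
#' @return A tibble with one row per channel: `channel`, `direction`,
#'   `t_m`, fit `residual`, and logical `transition`.
#' @export
detect_tm <- function(trace, min_improvement = 0.5) {
  dplyr::bind_rows(
    dplyr::mutate(
      detect_tm_channel(trace$temperature, trace$cv_A, min_improvement),
      channel = "A", .before = 1
    ),
    dplyr::mutate(
      detect_tm_channel(trace$temperature, trace$cv_B, min_improvement),
      channel = "B", .before = 1
    )
  ) |>
    dplyr::mutate(direction = trace$direction[1], .after = "channel")
}

#' Plot a melting trace
#'
#' @param object A [cv_trace()] tibble.
#' @param ... Unused.
#' @return A ggplot of cv versus temperature for both channels, with the
#'   detected breakpoints as dashed lines.
#' @export
autoplot.melt_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("cv_A", "cv_B"),
    names_to = "channel", values_to = "cv", names_prefix = "cv_"
  )
  tm <- tryCatch(detect_tm(object), error = function(e) NULL)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    .data$temperature, .data$cv,
    colour = .data$channel
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "temperature (°C)", y = expression(sigma / mu),
      colour = "channel"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(tm) && any(tm$transition)) {
    p <- p + ggplot2::geom_vline(
      data = tm[tm$transition, ],
      ggplot2::aes(xintercept = .data$t_m, colour = .data$channel),
      linetype = "dashed"
    )
  }
  p
}
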