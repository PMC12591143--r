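#' Linear fit with an optional constraint point
#'
#' Ordinary least-squares line, or a fit constrained to pass exactly
#' through a fixed point (as used for the reduced-tension trend, which is
#' pinned to `cos(theta/2) = 1` at order parameter 0).
#'
#' @param data A data frame.
#' @param x,y Column names (strings or bare names via `{{ }}` are not
#'   needed; pass strings) of the abscissa and ordinate.
#' @param constrain Either `NULL` (unconstrained) or a length-2 numeric
#'   `c(x0, y0)` the line must pass through.
#' @return An object of class `lin_fit`: `slope`, `intercept`,
#'   `zero_crossing` (`-intercept / slope`), `constrained`, `residual`
#'   (RMS), `n`.
#' @examples
#' d <- data.frame(x = 0:5, y = 1 - 2 * (0:5))
#' fit_line(d, "x", "y")
#' @export
fit_line <- function(data, x = "x", y = "y", constrain = NULL) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (is.null(constrain)) {
    if (length(unique(xv)) < 2) {
      rlang::abort("Singular fit: need at least two distinct x values.",
        class = "starphase_singular_fit"
      )
    }
    fit <- lm(yv ~ xv)
    slope <- coef(fit)[["xv"]]
    intercept <- coef(fit)[["(Intercept)"]]
    rms <- sqrt(mean(resid(fit)^2))
  } else {
    dx <- xv - constrain[1]
    dy <- yv - constrain[2]
    if (sum(dx^2) == 0) {
      rlang::abort("Singular fit: no spread away from the constraint point.",
        class = "starphase_singular_fit"
      )
    }
    slope <- sum(dx * dy) / sum(dx^2)
    intercept <- constrain[2] - slope * constrain[1]
    rms <- sqrt(mean((dy - slope * dx)^2))
  }
  structure(
    list(
      slope = slope, intercept = intercept,
      zero_crossing = if (slope != 0) -intercept / slope else NA_real_,
      constrained = !is.null(constrain), residual = rms, n = length(xv)
    ),
    class = "lin_fit"
  )
}

#' @export
print.lin_fit <- function(x, ...) {
  cat(
    "<lin_fit> y =", signif(x$slope, 4), "* x +", signif(x$intercept, 4),
    if (x$constrained) "(constrained)" else "",
    "\n  zero crossing:", signif(x$zero_crossing, 4),
    " rms:", signif(x$residual, 4), " n:", x$n, "\n"
  )
  invisible(x)
}

#' Tidiers for linear-fit objects
#'
#' @param x A `lin_fit` object from [fit_line()].
#' @param ... Unused.
#' @return `tidy()` returns one row per coefficient; `glance()` a one-row
#'   summary with the zero crossing and RMS residual.
#' @export
tidy.lin_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.lin_fit
#' @export
glance.lin_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    zero_crossing = x$zero_crossing, residual = x$residual,
    constrained = x$constrained, n = x$n
  )
}

#' Calibrate the order-parameter-to-chi mapping from two linear fits
#'
#' Given the simulated trend of `cos(theta/2)` against `chi_AB` and the
#' experimental trend against the order parameter, finds the affine change
#' of variables `chi_AB = c0 + c1 * order` that maps one line onto the
#' other (matching slopes and zero crossings simultaneously; unique when
#' both slopes are nonzero): `c1 = exp_slope / sim_slope` and
#' `c0 = (exp_intercept - sim_intercept) / sim_slope`.
#'
#' @param sim_fit A [fit_line()] of `cos(theta/2)` versus `chi_AB`.
#' @param exp_fit A [fit_line()] of `cos(theta/2)` versus the order
#'   parameter.
#' @return An object of class `chi_mapping`: `c0`, `c1` and the two fits.
#' @export
calibrate_mapping <- function(sim_fit, exp_fit) {
  if (sim_fit$slope == 0 || exp_fit$slope == 0) {
    rlang::abort("Degenerate calibration: both fits need nonzero slope.",
      class = "starphase_degenerate"
    )
  }
  structure(
    list(
      c0 = (exp_fit$intercept - sim_fit$intercept) / sim_fit$slope,
      c1 = exp_fit$slope / sim_fit$slope,
      sim_fit = sim_fit, exp_fit = exp_fit
    ),
    class = "chi_mapping"
  )
}

#' @export
print.chi_mapping <- function(x, ...) {
  cat(
    "<chi_mapping> order = (chi_AB -", signif(x$c0, 4), ") / (",
    signif(x$c1, 4), ")\n"
  )
  invisible(x)
}

#' Sweep the cross-interaction parameter and measure morphology
#'
#' Runs one condensate simulation per `chi_AB` value (all other parameters
#' fixed), processes the final snapshot with the morphometry pipeline, and
#' collects population medians of the reduced interfacial tension and
#' partition coefficients.
#'
#' @param chi_values Vector of `chi_AB` values.
#' @param chi_AA,chi_BB,phi_A0,phi_B0,grid_n,dt,noise_amp Simulation
#'   conditions (defaults: 4, 4, 0.23, 0.23, 128, 0.05, 0.01).
#' @param total_steps Steps per simulation (default 18000; near the
#'   demixing boundary the internal domains coarsen slowly, and the
#'   measured reduced tension is still rising at 6000-12000 steps).
#' @param seed Base seed; replicate `r` of run `i` uses
#'   `seed + 100 * r + i`.
#' @param min_area Minimum condensate area for segmentation (default 30).
#' @param n_reps Independent replicate simulations per `chi_AB`, pooled
#'   before taking medians (default 1).
#' @param measure_last Number of late checkpoints pooled per run (default
#'   2: the final snapshot and the one at ~85% of the run), enlarging the
#'   interface sample at negligible cost.
#' @param max_fit_rms Quality gate: interfaces whose three circle fits do
#'   not all have RMS residuals below this many pixels are excluded from
#'   the angle medians (default 1; branched or poorly resolved geometries
#'   fail it).
#' @return A tibble with one row per `chi_AB`: condensate and interface
#'   counts, `frac_biphasic`, and medians of `cos_half_theta`, `rho_A`,
#'   `rho_B` (NA where no biphasic interface was measurable).
#' @export
sweep_chi_ab <- function(chi_values, chi_AA = 4, chi_BB = 4,
                         phi_A0 = 0.23, phi_B0 = 0.23, grid_n = 128,
                         dt = 0.05, noise_amp = 0.01,
                         total_steps = 18000, seed = 1, min_area = 30,
                         n_reps = 1, measure_last = 2, max_fit_rms = 1) {
  schedule <- unique(round(c(0.7, 0.85, 1) * total_steps))
  measure_at <- utils::tail(seq_along(schedule), measure_last)
  purrr::map_dfr(seq_along(chi_values), function(i) {
    cond_all <- list()
    ifc_all <- list()
    for (r in seq_len(n_reps)) {
      p <- fh_params(
        chi_AB = chi_values[i], chi_AA = chi_AA, chi_BB = chi_BB,
        phi_A0 = phi_A0, phi_B0 = phi_B0, grid_n = grid_n, dt = dt,
        noise_amp = noise_amp, seed = seed + 100 * r + i
      )
      sim <- fh_run(p, snapshot_steps = schedule)
      for (k in measure_at) {
        img <- recenter_periodic(render_snapshot(sim$states[[k]]))
        m <- condensate_morphometry(img, min_area = min_area)
        cond_all[[length(cond_all) + 1]] <- m$condensates
        ifc_all[[length(ifc_all) + 1]] <- m$interfaces
      }
    }
    cond <- dplyr::bind_rows(cond_all)
    ifc <- dplyr::bind_rows(ifc_all)
    ifc <- dplyr::filter(
      ifc, .data$flag == "ok",
      .data$rms_A < max_fit_rms, .data$rms_B < max_fit_rms,
      .data$rms_interface < max_fit_rms
    )
    bi <- dplyr::filter(cond, .data$phase == "biphasic")
    tibble::tibble(
      chi_AB = chi_values[i],
      n_condensates = nrow(cond),
      n_interfaces = nrow(ifc),
      frac_biphasic = if (nrow(cond)) {
        mean(cond$phase == "biphasic")
      } else {
        NA_real_
      },
      cos_half_theta = if (nrow(ifc)) median(ifc$cos_half_theta) else NA_real_,
      theta_A = if (nrow(ifc)) median(ifc$theta_A) else NA_real_,
      theta_B = if (nrow(ifc)) median(ifc$theta_B) else NA_real_,
      rho_A = if (nrow(bi)) median(bi$rho_A) else NA_real_,
      rho_B = if (nrow(bi)) median(bi$rho_B) else NA_real_
    )
  })
}

#' Locate the mixing boundary from a chi sweep
#'
#' Fits `cos(theta/2)` versus `chi_AB` linearly over the biphasic range of
#' a [sweep_chi_ab()] table, extrapolates to the zero crossing `chi*`
#' (where the A-B interfacial tension vanishes), and converts it to an
#' order parameter through the mapping constants.
#'
#' @param sweep A [sweep_chi_ab()] result (or any tibble with `chi_AB`,
#'   `cos_half_theta`, `n_interfaces`).
#' @param c0,c1 Mapping constants (defaults: the calibrated 4.1, -3.4).
#' @param min_interfaces Minimum measured interfaces for a sweep point to
#'   enter the fit (default 1).
#' @return A list: `fit` (the [fit_line()]), `chi_star` (zero crossing)
#'   and `order_at_boundary`.
#' @export
estimate_boundary <- function(sweep, c0 = 4.1, c1 = -3.4,
                              min_interfaces = 1) {
  use <- dplyr::filter(
    sweep,
    .data$n_interfaces >= min_interfaces, is.finite(.data$cos_half_theta)
  )
  fit <- fit_line(use, "chi_AB", "cos_half_theta")
  list(
    fit = fit, chi_star = fit$zero_crossing,
    order_at_boundary = order_from_chi(fit$zero_crossing, c0 = c0, c1 = c1)
  )
}

#' Predict condensate morphology from mixture composition
#'
#' End-to-end prediction: composition to order parameter, order parameter
#' to `chi_AB` through the calibrated mapping, a seeded Flory-Huggins
#' simulation at that `chi_AB`, and morphometry of the rendered final
#' snapshot. Fully deterministic given the seed.
#'
#' @param data A composition table with `F_A`, `F_ab` columns (see
#'   [mixture()]).
#' @param c0,c1 Mapping constants (defaults: the calibrated 4.1, -3.4).
#' @param grid_n,total_steps,seed Simulation controls (smaller defaults
#'   than [sweep_chi_ab()] since one run per composition is needed).
#' @param ... Passed to [fh_params()].
#' @return The input tibble with columns `order_param`, `chi_AB`,
#'   `phase_pred`, `cos_half_theta`, `rho_A`, `rho_B` added.
#' @export
predict_morphology <- function(data, c0 = 4.1, c1 = -3.4, grid_n = 96,
                               total_steps = 1500, seed = 1, ...) {
  comp <- order_parameter(mixture(data$F_A, data$F_ab))
  res <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    chi <- chi_from_order(comp$order_param[i], c0 = c0, c1 = c1)
    p <- fh_params(chi_AB = chi, grid_n = grid_n, seed = seed + i, ...)
    sim <- fh_run(p, total_steps = total_steps)
    img <- recenter_periodic(render_snapshot(sim$states[[length(sim$states)]]))
    m <- condensate_morphometry(img, min_area = 30)
    ifc <- dplyr::filter(m$interfaces, .data$flag == "ok")
    bi <- dplyr::filter(m$condensates, .data$phase == "biphasic")
    any_bi <- nrow(m$condensates) > 0 && mean(m$condensates$phase == "biphasic") > 0.5
    tibble::tibble(
      chi_AB = chi,
      phase_pred = if (any_bi) "biphasic" else "monophasic",
      cos_half_theta = if (nrow(ifc)) median(ifc$cos_half_theta) else NA_real_,
      rho_A = if (nrow(bi)) median(bi$rho_A) else NA_real_,
      rho_B = if (nrow(bi)) median(bi$rho_B) else NA_real_
    )
  })
  dplyr::bind_cols(
    dplyr::select(
      comp, "F_A", "F_ab", "ns_total", "linker_total", "order_param"
    ),
    res
  )
}
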