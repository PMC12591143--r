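#' Build a nanostar-linker mixture composition table
#'
#' A binary nanostar condensate mixture is described by five species: two
#' tetravalent nanostars (A, B) and three divalent linkers (aa, bb, ab).
#' Under the sticky-end neutrality constraint (every alpha* on a linker is
#' matched by an alpha on a nanostar, and likewise for beta/beta*), the
#' composition space collapses to two free parameters: `F_A`, the molar
#' fraction of A among nanostars, and `F_ab`, the molar fraction of the
#' cross-species ab linker among linkers.
#'
#' Feasibility requires `F_ab <= 2 * F_A` and `F_ab <= 2 * (1 - F_A)`;
#' otherwise the implied aa or bb linker fraction would be negative.
#' Neutrality fixes the total linker concentration at twice the total
#' nanostar concentration.
#'
#' @param F_A Molar fraction of nanostar A among nanostars, in \[0, 1\].
#' @param F_ab Molar fraction of ab linker among linkers, in \[0, 1\].
#' @param ns_total Total nanostar concentration in uM (default 0.5).
#' @param linker_total Total linker concentration in uM; defaults to
#'   `2 * ns_total`, the value imposed by neutrality.
#' @return A tibble with one row per composition and columns `F_A`, `F_ab`,
#'   `ns_total`, `linker_total`.
#' @examples
#' mixture(0.5, 0.25)
#' mixture(F_A = c(0.25, 0.5), F_ab = 0.1)
#' @export
mixture <- function(F_A, F_ab, ns_total = 0.5, linker_total = 2 * ns_total) {
  out <- tibble::tibble(
    F_A = as.numeric(F_A), F_ab = as.numeric(F_ab),
    ns_total = ns_total, linker_total = linker_total
  )
  check_composition(out$F_A, out$F_ab)
  out
}

check_composition <- function(F_A, F_ab) {
  if (any(F_A < 0 | F_A > 1, na.rm = TRUE)) {
    rlang::abort("`F_A` must lie in [0, 1].", class = "starphase_infeasible")
  }
  if (any(F_ab < 0 | F_ab > 1, na.rm = TRUE)) {
    rlang::abort("`F_ab` must lie in [0, 1].", class = "starphase_infeasible")
  }
  tol <- 1e-12
  bad_aa <- F_ab > 2 * F_A + tol
  bad_bb <- F_ab > 2 * (1 - F_A) + tol
  if (any(bad_aa, na.rm = TRUE)) {
    rlang::abort(
      paste0(
        "Infeasible composition: F_ab > 2 * F_A (F_aa would be negative), ",
        "first offender F_A = ", F_A[which(bad_aa)[1]],
        ", F_ab = ", F_ab[which(bad_aa)[1]]
      ),
      class = "starphase_infeasible"
    )
  }
  if (any(bad_bb, na.rm = TRUE)) {
    rlang::abort(
      paste0(
        "Infeasible composition: F_ab > 2 * (1 - F_A) (F_bb would be ",
        "negative), first offender F_A = ", F_A[which(bad_bb)[1]],
        ", F_ab = ", F_ab[which(bad_bb)[1]]
      ),
      class = "starphase_infeasible"
    )
  }
  invisible(TRUE)
}

#' Component molar fractions of a mixture
#'
#' Adds the dependent molar fractions to a composition table: the B nanostar
#' fraction `F_B = 1 - F_A` and the same-species linker fractions
#' `F_aa = F_A - F_ab / 2` and `F_bb = (1 - F_A) - F_ab / 2`, which follow
#' from sticky-end neutrality. The three linker fractions always sum to one.
#'
#' @param data A data frame with columns `F_A` and `F_ab`, e.g. from
#'   [mixture()].
#' @return The input tibble with columns `F_B`, `F_aa`, `F_bb` added.
#' @examples
#' component_fractions(mixture(0.6, 0.2))
#' @export
component_fractions <- function(data) {
  check_composition(data$F_A, data$F_ab)
  dplyr::mutate(
    tibble::as_tibble(data),
    F_B = 1 - .data$F_A,
    F_aa = .data$F_A - .data$F_ab / 2,
    F_bb = (1 - .data$F_A) - .data$F_ab / 2
  )
}

#' Species concentrations of a mixture
#'
#' Converts molar fractions into concentrations of the five species, in the
#' units of `ns_total` (uM by default). The outputs satisfy the neutrality
#' relations `4 [A] = 2 [aa] + [ab]` and `4 [B] = 2 [bb] + [ab]` exactly,
#' which is verified internally.
#'
#' @inheritParams component_fractions
#' @return The input tibble with columns `conc_A`, `conc_B`, `conc_aa`,
#'   `conc_bb`, `conc_ab` added.
#' @examples
#' component_concentrations(mixture(0.5, 0))
#' @export
component_concentrations <- function(data) {
  out <- component_fractions(data)
  out <- dplyr::mutate(
    out,
    conc_A = .data$F_A * .data$ns_total,
    conc_B = .data$F_B * .data$ns_total,
    conc_aa = .data$F_aa * .data$linker_total,
    conc_bb = .data$F_bb * .data$linker_total,
    conc_ab = .data$F_ab * .data$linker_total
  )
  neutral <- abs(out$linker_total - 2 * out$ns_total) < 1e-12
  errA <- abs(4 * out$conc_A - (2 * out$conc_aa + out$conc_ab))
  errB <- abs(4 * out$conc_B - (2 * out$conc_bb + out$conc_ab))
  if (any(neutral & (errA > 1e-9 | errB > 1e-9))) {
    rlang::abort("Internal error: neutrality constraint violated.")
  }
  out
}

#' Sticky-end fractions and the mixing order parameter
#'
#' For each composition, computes the fraction of alpha* sticky ends carried
#' by ab linkers, `f_alpha_ab = [ab] / (4 [A])`, the analogous beta*
#' fraction `f_beta_ab = [ab] / (4 [B])`, and their sum `order_param`. The
#' sum is the empirical order parameter for the monophasic/biphasic
#' transition: condensates mix fully once it reaches about 0.5. Under
#' neutrality the fractions reduce to `F_ab / (2 F_A)` and
#' `F_ab / (2 (1 - F_A))`.
#'
#' @inheritParams component_fractions
#' @return The input tibble with columns `f_alpha_ab`, `f_beta_ab`,
#'   `order_param` added.
#' @examples
#' order_parameter(mixture(0.5, 0.25))   # order_param = 0.5
#' @export
order_parameter <- function(data) {
  out <- component_concentrations(data)
  undef <- (out$F_A %in% c(0, 1)) & out$F_ab > 0
  if (any(undef)) {
    rlang::abort(
      paste0(
        "Order parameter undefined: F_A in {0, 1} with F_ab > 0 leaves a ",
        "sticky-end family absent (division by zero)."
      ),
      class = "starphase_undefined_order"
    )
  }
  dplyr::mutate(
    out,
    f_alpha_ab = ifelse(.data$F_ab == 0, 0,
      .data$conc_ab / (4 * .data$conc_A)
    ),
    f_beta_ab = ifelse(.data$F_ab == 0, 0,
      .data$conc_ab / (4 * .data$conc_B)
    ),
    order_param = .data$f_alpha_ab + .data$f_beta_ab
  )
}

#' Classify mixture phase from the order parameter
#'
#' Labels each composition `"biphasic"` when its order parameter is below
#' the empirical threshold and `"monophasic"` otherwise. The boundary value
#' itself is assigned to monophasic (closed on the mixed side) so that the
#' classification is deterministic.
#'
#' @param data A data frame with an `order_param` column (e.g. from
#'   [order_parameter()]), or with `F_A`/`F_ab` columns from which it can be
#'   computed.
#' @param threshold Order-parameter boundary; default 0.5, the empirical
#'   value for the monophasic-to-biphasic transition.
#' @return The input tibble with a `phase` character column added.
#' @examples
#' classify_phase(order_parameter(mixture(0.5, c(0.1, 0.25))))
#' @export
classify_phase <- function(data, threshold = 0.5) {
  if (!"order_param" %in% names(data)) data <- order_parameter(data)
  if (any(data$order_param < 0)) {
    rlang::abort("`order_param` must be non-negative.")
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    phase = ifelse(.data$order_param < threshold, "biphasic", "monophasic")
  )
}

#' Map between the order parameter and the simulation interaction parameter
#'
#' The calibration identified a linear relation between the Flory-Huggins
#' cross-interaction parameter and the experimental order parameter:
#' `order = (chi_AB - c0) / c1` with fitted constants `c0 = 4.1` and
#' `c1 = -3.4`. `chi_from_order()` is the inverse map
#' `chi_AB = c0 + c1 * order`.
#'
#' @param order_param,chi_AB Numeric vectors.
#' @param c0,c1 Mapping constants; defaults are the calibrated values.
#' @return Numeric vector of the mapped quantity.
#' @examples
#' chi_from_order(0)      # 4.1
#' order_from_chi(2.4)    # 0.5
#' @export
chi_from_order <- function(order_param, c0 = 4.1, c1 = -3.4) {
  c0 + c1 * order_param
}

#' @rdname chi_from_order
#' @export
order_from_chi <- function(chi_AB, c0 = 4.1, c1 = -3.4) {
  if (any(c1 == 0)) {
    rlang::abort("Degenerate mapping: `c1` must be nonzero.",
      class = "starphase_degenerate"
    )
  }
  (chi_AB - c0) / c1
}
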