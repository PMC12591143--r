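#' Combinatorial bond counts for a stoichiometric nanostar mixture
#'
#' Counts the linker-mediated nanostar-nanostar bonds available to a mixture
#' with equal nanostar populations (`N_A = N_B = N`) and a stoichiometrically
#' matched linker pool (`N_L = 4 N`), as a function of the ab-linker
#' fraction. The total is
#' `d_tot = 8 N^2 (F_ab^2 / 2 + (1 - F_ab)^2)`,
#' decomposed into same-species and cross-species contributions
#' `d_AA = d_BB = 4 N^2 (1 - F_ab)^2` and `d_AB = 4 N^2 F_ab^2`.
#' The total has its maximum at `F_ab = 0` and its minimum at `F_ab = 2/3`,
#' which mirrors the non-monotonic dependence of the condensate melting
#' temperature on linker composition.
#'
#' @param data A data frame with an `F_ab` column, or a numeric vector of
#'   ab-linker fractions.
#' @param N Nanostar count per species (default 1, giving counts per N^2).
#' @return A tibble with columns `F_ab`, `d_AA`, `d_BB`, `d_AB`, `d_tot`.
#' @examples
#' bond_counts(c(0, 2 / 3, 1))
#' @export
bond_counts <- function(data, N = 1) {
  if (is.numeric(data)) data <- tibble::tibble(F_ab = data)
  F_ab <- data$F_ab
  if (any(F_ab < 0 | F_ab > 1)) {
    rlang::abort("`F_ab` must lie in [0, 1].")
  }
  if (N < 1) rlang::abort("`N` must be >= 1.")
  dplyr::mutate(
    tibble::as_tibble(data),
    d_AA = 4 * N^2 * (1 - F_ab)^2,
    d_BB = 4 * N^2 * (1 - F_ab)^2,
    d_AB = 4 * N^2 * F_ab^2,
    d_tot = .data$d_AA + .data$d_BB + .data$d_AB
  )
}

#' Total bond count
#'
#' @inheritParams bond_counts
#' @param F_ab Numeric vector of ab-linker fractions in \[0, 1\].
#' @return Numeric vector `8 N^2 (F_ab^2 / 2 + (1 - F_ab)^2)`.
#' @examples
#' d_tot(0)       # 8 (per N^2)
#' d_tot(2 / 3)   # 8/3, the minimum
#' @export
d_tot <- function(F_ab, N = 1) {
  8 * N^2 * (F_ab^2 / 2 + (1 - F_ab)^2)
}

#' Stationary points of the total bond count
#'
#' The minimizer of `d_tot` over \[0, 1\] in closed form: setting the
#' derivative of `F^2/2 + (1 - F)^2` to zero gives `3 F - 2 = 0`, i.e.
#' `F_ab = 2/3`; the maximum sits at the boundary `F_ab = 0`.
#'
#' @return A list with elements `argmin` (2/3) and `argmax` (0).
#' @examples
#' argmin_dtot()
#' @export
argmin_dtot <- function() {
  list(argmin = 2 / 3, argmax = 0)
}

#' Normalized bond-count trend
#'
#' Min-max normalizes `d_tot` over a grid of ab-linker fractions to \[0, 1\]
#' for qualitative comparison against measured melting-temperature trends.
#'
#' @inheritParams bond_counts
#' @return A tibble with columns `F_ab`, `d_tot`, `trend` (normalized).
#' @examples
#' tm_trend_proxy(seq(0, 1, by = 0.1))
#' @export
tm_trend_proxy <- function(data, N = 1) {
  out <- bond_counts(data, N = N)
  rng <- range(out$d_tot)
  if (diff(rng) == 0) {
    return(dplyr::mutate(out, trend = 0))
  }
  dplyr::mutate(out, trend = (.data$d_tot - rng[1]) / (rng[2] - rng[1]))
}
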