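#' Parameters for the ternary Flory-Huggins condensate simulation
#'
#' The model describes two nanostar species (volume fractions `phi_A`,
#' `phi_B`) in implicit solvent with local free-energy density
#' \deqn{f = \phi_A \ln\phi_A + \phi_B \ln\phi_B + \phi_S \ln\phi_S
#'   + \chi_{AB}\phi_A\phi_B + \chi_{AA}\phi_A\phi_S + \chi_{BB}\phi_B\phi_S}
#' where \eqn{\phi_S = 1 - \phi_A - \phi_B}, plus square-gradient interface
#' energy \eqn{\tfrac12\lambda^2\chi_{AA}|\nabla\phi_A|^2 +
#' \tfrac12\lambda^2\chi_{BB}|\nabla\phi_B|^2}. The fields evolve by
#' conserved Cahn-Hilliard dynamics \eqn{\partial_t\phi_i = M\nabla^2\mu_i}
#' on a periodic square grid. Linkers are not explicit: their effect is
#' encoded in the three interaction parameters.
#'
#' @param chi_AB Cross-species interaction parameter (the control knob for
#'   internal demixing).
#' @param chi_AA,chi_BB Same-species interaction parameters (default 4, the
#'   value used for all condensate simulations here).
#' @param lam Interface width parameter lambda, grid units (default 1).
#' @param mobility Cahn-Hilliard mobility M (default 1, constant and equal
#'   for both species).
#' @param grid_n Lattice size per side (default 128, minimum 32).
#' @param dx Lattice spacing (default 1).
#' @param dt Timestep (default 0.05).
#' @param phi_A0,phi_B0 Initial mean volume fractions (default 0.23 each).
#' @param noise_amp Amplitude of the i.i.d. Gaussian perturbation seeding
#'   spinodal decomposition (default 0.01).
#' @param seed RNG seed for the initial noise (default 1).
#' @return A list of class `fh_params`.
#' @examples
#' p <- fh_params(chi_AB = 4, grid_n = 64)
#' @export
fh_params <- function(chi_AB, chi_AA = 4, chi_BB = 4, lam = 1, mobility = 1,
                      grid_n = 128, dx = 1, dt = 0.05,
                      phi_A0 = 0.23, phi_B0 = 0.23,
                      noise_amp = 0.01, seed = 1) {
  if (phi_A0 <= 0 || phi_B0 <= 0 || phi_A0 + phi_B0 >= 1) {
    rlang::abort("Need phi_A0, phi_B0 > 0 and phi_A0 + phi_B0 < 1.")
  }
  if (dt <= 0) rlang::abort("`dt` must be positive.")
  if (grid_n < 32) rlang::abort("`grid_n` must be at least 32.")
  structure(
    list(
      chi_AA = chi_AA, chi_BB = chi_BB, chi_AB = chi_AB,
      lam = lam, mobility = mobility, grid_n = as.integer(grid_n), dx = dx,
      dt = dt, phi_A0 = phi_A0, phi_B0 = phi_B0,
      noise_amp = noise_amp, seed = as.integer(seed)
    ),
    class = "fh_params"
  )
}

#' @export
print.fh_params <- function(x, ...) {
  cat(
    "<fh_params> chi_AA =", x$chi_AA, " chi_BB =", x$chi_BB,
    " chi_AB =", x$chi_AB, "\n  grid", x$grid_n, "x", x$grid_n,
    " dx =", x$dx, " dt =", x$dt,
    " phi0 = (", x$phi_A0, ",", x$phi_B0, ") seed =", x$seed, "\n"
  )
  invisible(x)
}

# clipping floor used when evaluating logarithms
.fh_eps <- 1e-6

#' Initialize a field state
#'
#' Uniform mean volume fractions plus seeded, zero-mean Gaussian noise.
#'
#' @param p An [fh_params()] object.
#' @return A list of class `fh_state` with matrices `phi_A`, `phi_B` and
#'   scalar `time`.
#' @export
fh_init <- function(p) {
  n <- p$grid_n
  withr::with_seed(p$seed, {
    nA <- matrix(rnorm(n * n, sd = p$noise_amp), n, n)
    nB <- matrix(rnorm(n * n, sd = p$noise_amp), n, n)
  })
  nA <- nA - mean(nA)
  nB <- nB - mean(nB)
  structure(
    list(phi_A = p$phi_A0 + nA, phi_B = p$phi_B0 + nB, time = 0),
    class = "fh_state"
  )
}

clip_fields <- function(phi_A, phi_B, eps = .fh_eps) {
  phi_A <- pmin(pmax(phi_A, eps), 1 - eps)
  phi_B <- pmin(pmax(phi_B, eps), 1 - eps)
  s <- phi_A + phi_B
  over <- which(s > 1 - eps) # NA-safe; non-finite values surface later
  if (length(over)) {
    scale <- (1 - eps) / s
    phi_A[over] <- (phi_A * scale)[over]
    phi_B[over] <- (phi_B * scale)[over]
  }
  list(phi_A = phi_A, phi_B = phi_B)
}

#' Local free-energy density
#'
#' Evaluates the gradient-free part of the ternary Flory-Huggins free
#' energy at given volume fractions. Limits are taken as `0 * log(0) = 0`.
#'
#' @param phi_A,phi_B Volume fractions (vectors or matrices) with
#'   `phi_A + phi_B <= 1`.
#' @param p An [fh_params()] object supplying the interaction parameters.
#' @return Free-energy density, same shape as the inputs.
#' @examples
#' p <- fh_params(chi_AB = 2, grid_n = 32)
#' free_energy_density(0.23, 0.23, p)  # about 0.0906
#' @export
free_energy_density <- function(phi_A, phi_B, p) {
  if (any(phi_A < 0 | phi_B < 0 | phi_A + phi_B > 1 + 1e-12)) {
    rlang::abort("Volume fractions must satisfy 0 <= phi and phi_A + phi_B <= 1.")
  }
  phi_S <- 1 - phi_A - phi_B
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  xlogx(phi_A) + xlogx(phi_B) + xlogx(phi_S) +
    p$chi_AB * phi_A * phi_B +
    p$chi_AA * phi_A * phi_S +
    p$chi_BB * phi_B * phi_S
}

# squared wavenumbers of the periodic grid, as a matrix
k2_grid <- function(n, dx) {
  k <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dx)
  outer(k^2, k^2, `+`)
}

# spectral laplacian
lap_spec <- function(x, k2) {
  Re(fft(-k2 * fft(x), inverse = TRUE)) / length(x)
}

#' Total free energy of a field state
#'
#' Grid sum of the local density plus the square-gradient interface energy
#' `(lam^2 chi_AA / 2) |grad phi_A|^2 + (lam^2 chi_BB / 2) |grad phi_B|^2`,
#' times the cell area. Gradients are evaluated spectrally, consistent with
#' the dynamics. Non-increasing along trajectories (gradient flow).
#'
#' @param s An `fh_state`.
#' @param p An [fh_params()] object.
#' @return A single number.
#' @export
total_free_energy <- function(s, p) {
  n <- p$grid_n
  cl <- clip_fields(s$phi_A, s$phi_B)
  f_loc <- free_energy_density(cl$phi_A, cl$phi_B, p)
  # gradient energy by Parseval on the same wavenumbers as the dynamics,
  # so the chemical potentials are the exact functional derivative
  k2 <- k2_grid(n, p$dx)
  grad2_sum <- function(x) sum(k2 * Mod(fft(x))^2) / (n * n)
  e_grad <- 0.5 * p$lam^2 *
    (p$chi_AA * grad2_sum(s$phi_A) + p$chi_BB * grad2_sum(s$phi_B))
  (sum(f_loc) + e_grad) * p$dx^2
}

#' Chemical potential fields
#'
#' Functional derivatives of the free energy:
#' `mu_i = d f_local / d phi_i - lam^2 chi_ii lap(phi_i)`, with the
#' Laplacian evaluated by the same spectral operator used in [fh_step()].
#' Fields at the clipping bounds are evaluated at the clipped values.
#'
#' @inheritParams total_free_energy
#' @return A list with matrices `mu_A`, `mu_B`.
#' @export
chemical_potentials <- function(s, p) {
  cl <- clip_fields(s$phi_A, s$phi_B)
  phi_S <- 1 - cl$phi_A - cl$phi_B
  dfA <- log(cl$phi_A) - log(phi_S) + p$chi_AB * cl$phi_B +
    p$chi_AA * (1 - 2 * cl$phi_A - cl$phi_B) - p$chi_BB * cl$phi_B
  dfB <- log(cl$phi_B) - log(phi_S) + p$chi_AB * cl$phi_A +
    p$chi_BB * (1 - 2 * cl$phi_B - cl$phi_A) - p$chi_AA * cl$phi_A
  k2 <- k2_grid(p$grid_n, p$dx)
  list(
    mu_A = dfA - p$lam^2 * p$chi_AA * lap_spec(s$phi_A, k2),
    mu_B = dfB - p$lam^2 * p$chi_BB * lap_spec(s$phi_B, k2)
  )
}

#' Advance the Cahn-Hilliard dynamics
#'
#' First-order semi-implicit Fourier-spectral scheme: the stiff
#' square-gradient term and a constant stabilization `S * phi` are treated
#' implicitly, the remaining (logarithmic and coupling) terms explicitly.
#' The k = 0 mode is untouched by the update, so spatial means are conserved
#' to machine precision. Any non-finite value raises an instability error
#' reporting the step at which it occurred.
#'
#' @inheritParams total_free_energy
#' @param n_steps Number of timesteps to take.
#' @return The advanced `fh_state`.
#' @export
fh_step <- function(s, p, n_steps) {
  n <- p$grid_n
  k2 <- k2_grid(n, p$dx)
  kap_A <- p$lam^2 * p$chi_AA
  kap_B <- p$lam^2 * p$chi_BB
  stab <- 2 * max(p$chi_AA, p$chi_BB, p$chi_AB) + 1
  den_A <- 1 + p$dt * p$mobility * (stab * k2 + kap_A * k2^2)
  den_B <- 1 + p$dt * p$mobility * (stab * k2 + kap_B * k2^2)
  phi_A <- s$phi_A
  phi_B <- s$phi_B
  for (i in seq_len(n_steps)) {
    cl <- clip_fields(phi_A, phi_B)
    phi_S <- 1 - cl$phi_A - cl$phi_B
    gA <- log(cl$phi_A) - log(phi_S) + p$chi_AB * cl$phi_B +
      p$chi_AA * (1 - 2 * cl$phi_A - cl$phi_B) - p$chi_BB * cl$phi_B -
      stab * phi_A
    gB <- log(cl$phi_B) - log(phi_S) + p$chi_AB * cl$phi_A +
      p$chi_BB * (1 - 2 * cl$phi_B - cl$phi_A) - p$chi_AA * cl$phi_A -
      stab * phi_B
    phiA_h <- (fft(phi_A) - p$dt * p$mobility * k2 * fft(gA)) / den_A
    phiB_h <- (fft(phi_B) - p$dt * p$mobility * k2 * fft(gB)) / den_B
    phi_A <- Re(fft(phiA_h, inverse = TRUE)) / (n * n)
    phi_B <- Re(fft(phiB_h, inverse = TRUE)) / (n * n)
    if (any(!is.finite(phi_A)) || any(!is.finite(phi_B))) {
      rlang::abort(
        paste0("Cahn-Hilliard instability: non-finite field at step ", i, "."),
        class = "starphase_instability"
      )
    }
  }
  structure(
    list(phi_A = phi_A, phi_B = phi_B, time = s$time + n_steps * p$dt),
    class = "fh_state"
  )
}

#' Run a condensate simulation with snapshots
#'
#' Initializes the fields from `p` and advances them, recording states at
#' the requested cumulative step counts. The default schedule is five
#' geometrically spaced checkpoints; the final one is the analysis
#' snapshot. Trajectories are deterministic given the seed.
#'
#' @param p An [fh_params()] object.
#' @param snapshot_steps Increasing integer vector of cumulative step
#'   counts; default five geometric checkpoints up to `total_steps`.
#' @param total_steps Total number of steps when `snapshot_steps` is not
#'   given (default 3000).
#' @return An object of class `fh_sim`: list with `params`, `states` (one
#'   `fh_state` per checkpoint) and `diagnostics` (tibble of time, energy,
#'   and field means per checkpoint).
#' @examples
#' \donttest{
#' sim <- fh_run(fh_params(chi_AB = 4, grid_n = 64, seed = 2),
#'   total_steps = 500
#' )
#' glance(sim)
#' }
#' @export
fh_run <- function(p, snapshot_steps = NULL, total_steps = 3000) {
  if (is.null(snapshot_steps)) {
    snapshot_steps <- unique(round(total_steps^(seq(0.2, 1, by = 0.2))))
  }
  if (is.unsorted(snapshot_steps, strictly = TRUE)) {
    rlang::abort("`snapshot_steps` must be strictly increasing.")
  }
  s <- fh_init(p)
  states <- vector("list", length(snapshot_steps))
  diag <- vector("list", length(snapshot_steps))
  prev <- 0
  for (i in seq_along(snapshot_steps)) {
    s <- fh_step(s, p, snapshot_steps[i] - prev)
    prev <- snapshot_steps[i]
    states[[i]] <- s
    diag[[i]] <- tibble::tibble(
      checkpoint = i, step = snapshot_steps[i], time = s$time,
      energy = total_free_energy(s, p),
      mean_phi_A = mean(s$phi_A), mean_phi_B = mean(s$phi_B)
    )
  }
  structure(
    list(params = p, states = states, diagnostics = dplyr::bind_rows(diag)),
    class = "fh_sim"
  )
}

#' @export
print.fh_sim <- function(x, ...) {
  cat(
    "<fh_sim>", length(x$states), "snapshots, chi_AB =", x$params$chi_AB,
    ", final time", x$states[[length(x$states)]]$time, "\n"
  )
  invisible(x)
}

#' Tidiers for simulation objects
#'
#' @param x An `fh_sim` object from [fh_run()].
#' @param ... Unused.
#' @return `tidy()` returns the per-checkpoint diagnostics (time, energy,
#'   field means); `glance()` a one-row summary with the conservation and
#'   energy-descent checks.
#' @export
tidy.fh_sim <- function(x, ...) x$diagnostics

#' @rdname tidy.fh_sim
#' @export
glance.fh_sim <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n_snapshots = nrow(d),
    final_time = d$time[nrow(d)],
    final_energy = d$energy[nrow(d)],
    energy_descent = all(diff(d$energy) <= abs(d$energy[-nrow(d)]) * 1e-6),
    mass_error_A = max(abs(d$mean_phi_A - x$params$phi_A0)),
    mass_error_B = max(abs(d$mean_phi_B - x$params$phi_B0))
  )
}

#' Render a field state as a two-channel image
#'
#' Channel A is `phi_A`, channel B is `phi_B`, each rescaled so its minimum
#' maps to 0 and maximum to 1 (matching min/max display rescaling of
#' micrographs). A constant field degenerates to a flat zero channel and is
#' flagged in the image metadata.
#'
#' @param s An `fh_state`.
#' @param pixel_size Physical size per pixel; defaults to the grid spacing.
#' @return A [two_channel_image()] object.
#' @export
render_snapshot <- function(s, pixel_size = 1) {
  rescale <- function(x) {
    r <- range(x)
    if (diff(r) == 0) {
      return(list(img = x * 0, flat = TRUE))
    }
    list(img = (x - r[1]) / (r[2] - r[1]), flat = FALSE)
  }
  a <- rescale(s$phi_A)
  b <- rescale(s$phi_B)
  img <- two_channel_image(a$img, b$img, pixel_size = pixel_size)
  attr(img, "flat_channels") <- c(A = a$flat, B = b$flat)
  img
}
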