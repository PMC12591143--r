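#' Specify synthetic droplets for rendering
#'
#' Builds a specification table for the synthetic-micrograph generator,
#' which emulates two-channel confocal images of condensates: round
#' monophasic discs or biphasic Janus doublets with circular-cap interface
#' geometry, controlled partition coefficients, blur, noise and
#' background.
#'
#' @param geometry `"biphasic"` or `"monophasic"`.
#' @param radius_px Cap radius in pixels.
#' @param theta_A,theta_B Target contact angles in radians (biphasic only;
#'   `theta_A + theta_B` in `(pi, 2 pi)`).
#' @param rho_A,rho_B Target partition coefficients in \[0, 1\]: the
#'   depleted-phase intensity of each channel is `rho * ` its enriched
#'   intensity by construction.
#' @param intensity_A,intensity_B Enriched-phase intensity per channel, in
#'   \[0, 1\].
#' @param cx,cy Center in pixels (`NA` = auto placement on a grid).
#' @param angle Rotation of the doublet axis, radians.
#' @return A one-row tibble; rows from repeated calls can be
#'   `dplyr::bind_rows()`-ed into a spec list.
#' @export
droplet_spec <- function(geometry = c("biphasic", "monophasic"),
                         radius_px = 25,
                         theta_A = 3 * pi / 4, theta_B = 3 * pi / 4,
                         rho_A = 0.2, rho_B = 0.2,
                         intensity_A = 1, intensity_B = 1,
                         cx = NA_real_, cy = NA_real_, angle = 0) {
  geometry <- match.arg(geometry)
  if (geometry == "biphasic") {
    ssum <- theta_A + theta_B
    if (ssum <= pi || ssum >= 2 * pi) {
      rlang::abort("Biphasic spec needs theta_A + theta_B in (pi, 2 pi).",
        class = "starphase_geometry"
      )
    }
  }
  if (any(c(rho_A, rho_B) < 0 | c(rho_A, rho_B) > 1)) {
    rlang::abort("`rho_A`, `rho_B` must lie in [0, 1].")
  }
  tibble::tibble(
    geometry = geometry, radius_px = radius_px,
    theta_A = ifelse(geometry == "biphasic", theta_A, NA_real_),
    theta_B = ifelse(geometry == "biphasic", theta_B, NA_real_),
    rho_A = ifelse(geometry == "biphasic", rho_A, 1),
    rho_B = ifelse(geometry == "biphasic", rho_B, 1),
    intensity_A = intensity_A, intensity_B = intensity_B,
    cx = cx, cy = cy, angle = angle
  )
}

droplet_extent <- function(spec) {
  if (spec$geometry == "monophasic") {
    return(spec$radius_px)
  }
  g <- doublet_geometry(spec$theta_A, spec$theta_B, spec$radius_px)
  max(
    abs(g$circle_A$xc) + g$circle_A$r,
    abs(g$circle_B$xc) + g$circle_B$r
  )
}

#' Render synthetic droplets with analytic ground truth
#'
#' Rasterizes each spec at its target intensities (channel A at
#' `intensity_A` in the A-rich region and `rho_A * intensity_A` in the
#' B-rich region, and symmetrically for B), applies Gaussian blur, then
#' additive Gaussian noise and optional Poisson shot noise. Ground truth
#' (masks, partition coefficients, contact angles) is recorded from the
#' analytic construction before blur and noise. Rendering is reproducible
#' bit-for-bit from the spec table and seed.
#'
#' @param specs A tibble of [droplet_spec()] rows.
#' @param canvas Image size, `c(rows, cols)` (default 256 x 256).
#' @param background Background intensity (default 0.05).
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 0 = none).
#' @param noise_sd Additive Gaussian noise standard deviation as a
#'   fraction of full scale (default 0 = none).
#' @param poisson_scale If non-`NULL`, photon count per unit intensity for
#'   Poisson shot noise.
#' @param seed RNG seed for noise and auto placement.
#' @param pixel_size Pixel size to attach to the image.
#' @return A list: `image` (a [two_channel_image()]) and `truth` (a tibble
#'   with one row per droplet: spec columns plus pixel-index list-columns
#'   `px`, `px_Arich`, `px_Brich`).
#' @examples
#' out <- render_droplet_image(droplet_spec("monophasic", radius_px = 20),
#'   canvas = c(64, 64)
#' )
#' @export
render_droplet_image <- function(specs, canvas = c(256, 256),
                                 background = 0.05, blur_sigma_px = 0,
                                 noise_sd = 0, poisson_scale = NULL,
                                 seed = 1, pixel_size = 1) {
  nr <- canvas[1]
  nc <- canvas[2]
  chA <- matrix(background, nr, nc)
  chB <- matrix(background, nr, nc)
  if (nrow(specs) > 0) {
    specs <- auto_place(specs, nr, nc)
    xg <- matrix(seq_len(nr), nr, nc)
    yg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    truth <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      # droplet-frame coordinates (rotated about the center)
      dx <- xg - sp$cx
      dy <- yg - sp$cy
      xr <- cos(sp$angle) * dx + sin(sp$angle) * dy
      yr <- -sin(sp$angle) * dx + cos(sp$angle) * dy
      if (sp$geometry == "monophasic") {
        inside <- xr^2 + yr^2 <= sp$radius_px^2
        chA[inside] <- sp$intensity_A
        chB[inside] <- sp$intensity_B
        pxA <- integer(0)
        pxB <- integer(0)
        px <- which(inside)
      } else {
        g <- doublet_geometry(sp$theta_A, sp$theta_B, sp$radius_px)
        regA <- in_circle(xr, yr, g$circle_A) &
          on_phase_side(xr, yr, g$interface, g$sigma_A)
        regB <- in_circle(xr, yr, g$circle_B) &
          on_phase_side(xr, yr, g$interface, -g$sigma_A) & !regA
        chA[regA] <- sp$intensity_A
        chA[regB] <- sp$rho_A * sp$intensity_A
        chB[regB] <- sp$intensity_B
        chB[regA] <- sp$rho_B * sp$intensity_B
        pxA <- which(regA)
        pxB <- which(regB)
        px <- which(regA | regB)
      }
      truth[[i]] <- dplyr::mutate(sp,
        id = i, px = list(px),
        px_Arich = list(pxA), px_Brich = list(pxB)
      )
    }
    truth <- dplyr::bind_rows(truth)
  } else {
    truth <- tibble::tibble()
  }
  if (blur_sigma_px > 0) {
    chA <- EBImage::gblur(chA, sigma = blur_sigma_px)
    chB <- EBImage::gblur(chB, sigma = blur_sigma_px)
  }
  withr::with_seed(seed, {
    if (!is.null(poisson_scale)) {
      chA <- stats::rpois(length(chA), pmax(chA, 0) * poisson_scale) / poisson_scale
      chB <- stats::rpois(length(chB), pmax(chB, 0) * poisson_scale) / poisson_scale
      chA <- matrix(chA, nr, nc)
      chB <- matrix(chB, nr, nc)
    }
    if (noise_sd > 0) {
      chA <- chA + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      chB <- chB + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    }
  })
  chA <- pmax(chA, 0)
  chB <- pmax(chB, 0)
  list(
    image = two_channel_image(chA, chB, pixel_size = pixel_size),
    truth = truth
  )
}

auto_place <- function(specs, nr, nc) {
  ext <- vapply(seq_len(nrow(specs)), function(i) {
    droplet_extent(specs[i, ])
  }, numeric(1))
  need <- which(is.na(specs$cx) | is.na(specs$cy))
  if (length(need)) {
    # shelf packing: fill rows left to right with per-droplet extents
    gap <- 4
    row_top <- gap
    shelf_h <- 0
    col <- gap
    for (i in need) {
      w <- 2 * ext[i] + gap
      if (col + w > nc) {
        row_top <- row_top + shelf_h + gap
        shelf_h <- 0
        col <- gap
      }
      if (row_top + w > nr || col + w > nc) {
        rlang::abort("Canvas too small for the requested droplets.",
          class = "starphase_capacity"
        )
      }
      specs$cx[i] <- row_top + ext[i]
      specs$cy[i] <- col + ext[i]
      shelf_h <- max(shelf_h, w)
      col <- col + w
    }
  }
  # overlap / bounds check
  for (i in seq_len(nrow(specs))) {
    if (specs$cx[i] - ext[i] < 1 || specs$cx[i] + ext[i] > nr ||
      specs$cy[i] - ext[i] < 1 || specs$cy[i] + ext[i] > nc) {
      rlang::abort("Droplet does not fit on the canvas.",
        class = "starphase_capacity"
      )
    }
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        d <- sqrt((specs$cx[i] - specs$cx[j])^2 + (specs$cy[i] - specs$cy[j])^2)
        if (d < ext[i] + ext[j] + 2) {
          rlang::abort("Droplet placement overlaps.",
            class = "starphase_capacity"
          )
        }
      }
    }
  }
  specs
}

#' Feasible composition grid
#'
#' Cartesian product of nanostar fractions and ab-linker fractions,
#' restricted to stoichiometrically feasible points and annotated with the
#' order parameter and phase classification. The defaults emulate the
#' experimental mapping: five `F_A` levels and 5% steps in `F_ab`.
#'
#' @param fa `F_A` levels (default `c(0.25, 0.375, 0.5, 0.625, 0.75)`).
#' @param fab_step Step in `F_ab` (default 0.05).
#' @param fab_max Largest `F_ab` (default 1).
#' @param threshold Order-parameter phase boundary (default 0.5).
#' @return A tibble of feasible compositions with stoichiometry, order
#'   parameter and phase columns.
#' @examples
#' nrow(composition_grid(fa = 0.5, fab_max = 0.5)) # 11
#' @export
composition_grid <- function(fa = c(0.25, 0.375, 0.5, 0.625, 0.75),
                             fab_step = 0.05, fab_max = 1,
                             threshold = 0.5) {
  grid <- tidyr::expand_grid(
    F_A = fa,
    F_ab = seq(0, fab_max, by = fab_step)
  )
  feasible <- grid$F_ab <= 2 * grid$F_A & grid$F_ab <= 2 * (1 - grid$F_A)
  grid <- grid[feasible, ]
  classify_phase(order_parameter(mixture(grid$F_A, grid$F_ab)),
    threshold = threshold
  )
}

#' Synthetic melting-ramp image stack
#'
#' Renders a temperature-indexed stack of two-channel frames in which
#' droplet contrast follows a sigmoid centered on the melting temperature
#' (shifted by half the hysteresis, up on heating and down on cooling),
#' dissolving to uniform background above the transition.
#'
#' @param temperatures Temperature list, one per frame (deg C; monotone
#'   within a ramp).
#' @param t_m True melting temperature (must lie inside the sampled range
#'   for a detectable transition).
#' @param hysteresis Heating-minus-cooling offset in deg C (default 0).
#' @param direction `"heating"` or `"cooling"`.
#' @param specs Droplet spec table (default: three monophasic discs).
#' @param width Sigmoid width in deg C (default 1).
#' @param canvas,background,noise_sd,seed Passed to the renderer.
#' @return A list of class `melt_stack`: `frames` (list of
#'   [two_channel_image()]), `temperatures`, `direction`, and the
#'   effective transition `t_m_effective` ground truth.
#' @export
melt_stack <- function(temperatures, t_m, hysteresis = 0,
                       direction = c("heating", "cooling"),
                       specs = NULL, width = 1, canvas = c(128, 128),
                       background = 0.05, noise_sd = 0.01, seed = 1) {
  direction <- match.arg(direction)
  if (is.null(specs)) {
    specs <- dplyr::bind_rows(
      droplet_spec("monophasic", radius_px = 12, cx = 32, cy = 32),
      droplet_spec("monophasic", radius_px = 15, cx = 40, cy = 90),
      droplet_spec("monophasic", radius_px = 13, cx = 95, cy = 60)
    )
  }
  t_m_eff <- t_m + ifelse(direction == "heating", 1, -1) * hysteresis / 2
  frames <- purrr::map(seq_along(temperatures), function(i) {
    amp <- stats::plogis((t_m_eff - temperatures[i]) / width)
    sp <- dplyr::mutate(specs,
      intensity_A = background + (.data$intensity_A - background) * amp,
      intensity_B = background + (.data$intensity_B - background) * amp
    )
    render_droplet_image(sp,
      canvas = canvas, background = background,
      blur_sigma_px = 1, noise_sd = noise_sd, seed = seed + i
    )$image
  })
  structure(
    list(
      frames = frames, temperatures = temperatures, direction = direction,
      t_m_effective = t_m_eff
    ),
    class = "melt_stack"
  )
}
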