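# shared fixtures: small droplet scenes with known ground truth

doublet_scene <- function(blur = 0, noise = 0, seed = 7) {
  specs <- dplyr::bind_rows(
    droplet_spec("biphasic",
      radius_px = 30, theta_A = 3 * pi / 4,
      theta_B = 3 * pi / 4, rho_A = 0.2, rho_B = 0.2
    ),
    droplet_spec("biphasic",
      radius_px = 25, theta_A = 140 * pi / 180,
      theta_B = 120 * pi / 180, rho_A = 0.4, rho_B = 0.3, angle = 0.5
    ),
    droplet_spec("monophasic", radius_px = 20)
  )
  render_droplet_image(specs,
    canvas = c(256, 256), blur_sigma_px = blur,
    noise_sd = noise, seed = seed
  )
}

small_sim <- function(chi_AB, grid_n = 64, steps = 800, seed = 3, ...) {
  fh_run(fh_params(chi_AB = chi_AB, grid_n = grid_n, seed = seed, ...),
    total_steps = steps
  )
}
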