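test_that("free energy density matches a term-by-term oracle", {
  p <- fh_params(chi_AB = 2, grid_n = 32)
  # independent evaluation of the mixing free energy, term by term
  oracle <- function(a, b) {
    s <- 1 - a - b
    xl <- function(x) if (x > 0) x * log(x) else 0
    xl(a) + xl(b) + xl(s) + 2 * a * b + 4 * a * s + 4 * b * s
  }
  expect_equal(free_energy_density(0.23, 0.23, p), oracle(0.23, 0.23))
  expect_equal(free_energy_density(0.23, 0.23, p), 0.0906, tolerance = 1e-3)
  expect_equal(free_energy_density(0, 0, p), 0) # pure solvent
  # A <-> B symmetry when chi_AA = chi_BB
  expect_equal(
    free_energy_density(0.1, 0.4, p),
    free_energy_density(0.4, 0.1, p)
  )
  expect_error(free_energy_density(0.7, 0.5, p))
})

test_that("total free energy reduces to area scaling for uniform fields", {
  p <- fh_params(chi_AB = 2, grid_n = 32, noise_amp = 0)
  s <- fh_init(p)
  expect_equal(
    total_free_energy(s, p),
    32^2 * free_energy_density(0.23, 0.23, p),
    tolerance = 1e-10
  )
  p2 <- fh_params(chi_AB = 2, grid_n = 32, noise_amp = 0, dx = 2)
  expect_equal(total_free_energy(s, p2), 4 * total_free_energy(s, p),
    tolerance = 1e-10
  )
})

test_that("chemical potentials agree with the functional-derivative oracle", {
  p <- fh_params(chi_AB = 3, grid_n = 48, seed = 5)
  sim <- small_sim(3, grid_n = 48, steps = 300, seed = 5)
  s <- sim$states[[length(sim$states)]]
  mu <- chemical_potentials(s, p)
  eps <- 1e-6
  set.seed(11)
  pts <- cbind(sample(48, 5), sample(48, 5))
  for (k in seq_len(nrow(pts))) {
    i <- pts[k, 1]
    j <- pts[k, 2]
    for (field in c("phi_A", "phi_B")) {
      sp <- s
      sp[[field]][i, j] <- sp[[field]][i, j] + eps
      sm <- s
      sm[[field]][i, j] <- sm[[field]][i, j] - eps
      num <- (total_free_energy(sp, p) - total_free_energy(sm, p)) /
        (2 * eps) / p$dx^2
      ana <- if (field == "phi_A") mu$mu_A[i, j] else mu$mu_B[i, j]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
  # symmetric homogeneous state: equal potentials everywhere
  p0 <- fh_params(chi_AB = 2, grid_n = 32, noise_amp = 0)
  mu0 <- chemical_potentials(fh_init(p0), p0)
  expect_equal(mu0$mu_A, mu0$mu_B)
  # entropy-only dilute limit
  pz <- fh_params(chi_AB = 0, chi_AA = 0, chi_BB = 0, grid_n = 32,
    phi_A0 = 0.01, phi_B0 = 0.01, noise_amp = 0
  )
  muz <- chemical_potentials(fh_init(pz), pz)
  expect_equal(muz$mu_A[1, 1], log(0.01) - log(0.98), tolerance = 1e-10)
})

test_that("dynamics conserve mass, descend in energy, and are deterministic", {
  sim <- small_sim(4, grid_n = 64, steps = 2000, seed = 9)
  g <- glance(sim)
  expect_lt(g$mass_error_A, 1e-8)
  expect_lt(g$mass_error_B, 1e-8)
  e <- tidy(sim)$energy
  expect_true(all(diff(e) <= abs(e[-length(e)]) * 1e-6))
  sim2 <- small_sim(4, grid_n = 64, steps = 2000, seed = 9)
  expect_identical(
    sim$states[[length(sim$states)]]$phi_A,
    sim2$states[[length(sim2$states)]]$phi_A
  )
})

test_that("a noiseless homogeneous state is a fixed point", {
  p <- fh_params(chi_AB = 4, grid_n = 32, noise_amp = 0)
  s <- fh_init(p)
  s2 <- fh_step(s, p, 50)
  expect_equal(s2$phi_A, s$phi_A, tolerance = 1e-12)
  expect_equal(s2$time, 50 * p$dt)
})

test_that("non-finite fields raise an instability error with step index", {
  p <- fh_params(chi_AB = 4, grid_n = 32)
  s <- fh_init(p)
  s$phi_A[1, 1] <- NaN
  expect_error(fh_step(s, p, 3),
    regexp = "step 1",
    class = "starphase_instability"
  )
})

test_that("snapshot rendering rescales channels to [0, 1]", {
  sim <- small_sim(4, grid_n = 48, steps = 600, seed = 2)
  s <- sim$states[[length(sim$states)]]
  img <- render_snapshot(s)
  expect_equal(range(img$channel_A), c(0, 1))
  expect_equal(range(img$channel_B), c(0, 1))
  # swapping fields swaps channels
  s_swap <- s
  s_swap$phi_A <- s$phi_B
  s_swap$phi_B <- s$phi_A
  img_swap <- render_snapshot(s_swap)
  expect_identical(img_swap$channel_A, img$channel_B)
  # flat field flagged
  flat <- structure(
    list(phi_A = matrix(0.2, 8, 8), phi_B = matrix(0.3, 8, 8), time = 0),
    class = "fh_state"
  )
  expect_true(attr(render_snapshot(flat), "flat_channels")[["A"]])
})

test_that("snapshot schedules are validated and honored", {
  p <- fh_params(chi_AB = 2, grid_n = 32, seed = 1)
  run <- fh_run(p, snapshot_steps = c(10, 20, 40))
  expect_equal(tidy(run)$step, c(10, 20, 40))
  expect_equal(tidy(run)$time, c(10, 20, 40) * p$dt)
  expect_error(fh_run(p, snapshot_steps = c(10, 10)))
  # default schedule has five checkpoints, the last at the final step
  run5 <- fh_run(p, total_steps = 200)
  expect_equal(nrow(tidy(run5)), 5)
  expect_equal(max(tidy(run5)$step), 200)
})
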