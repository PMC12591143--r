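test_that("exact lines are recovered with their zero crossing", {
  d <- data.frame(x = seq(0, 2, by = 0.25), y = 1 - 2 * seq(0, 2, by = 0.25))
  fit <- fit_line(d, "x", "y")
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$zero_crossing, 0.5)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
  expect_equal(tidy(fit)$estimate, c(1, -2))
  expect_equal(glance(fit)$zero_crossing, 0.5)
})

test_that("constrained fits pass exactly through the anchor point", {
  set.seed(3)
  x <- seq(0.1, 1.5, by = 0.1)
  y <- 1 - 2 * x + rnorm(length(x), 0, 0.05)
  fit <- fit_line(data.frame(x = x, y = y), constrain = c(0, 1))
  expect_equal(fit$intercept + fit$slope * 0, 1)
  expect_true(fit$constrained)
  expect_equal(fit$slope, -2, tolerance = 0.1)
})

test_that("degenerate abscissae raise a singular-fit error", {
  expect_error(
    fit_line(data.frame(x = c(1, 1), y = c(0, 1))),
    class = "starphase_singular_fit"
  )
  expect_error(
    fit_line(data.frame(x = 0, y = 5), constrain = c(0, 1)),
    class = "starphase_singular_fit"
  )
})

test_that("calibration recovers known mapping constants exactly", {
  # construct the unique sim/exp line pair consistent with (4.1, -3.4):
  # exp line anchored at (0, 1) with zero crossing at order = 0.5
  c0 <- 4.1
  c1 <- -3.4
  exp_slope <- -2
  exp_int <- 1
  sim_slope <- exp_slope / c1
  sim_int <- exp_int - sim_slope * c0
  sim_x <- c(2, 3, 4)
  exp_x <- c(0, 0.25, 0.5)
  sim_fit <- fit_line(data.frame(x = sim_x, y = sim_slope * sim_x + sim_int))
  exp_fit <- fit_line(data.frame(x = exp_x, y = exp_slope * exp_x + exp_int))
  map <- calibrate_mapping(sim_fit, exp_fit)
  expect_equal(map$c0, 4.1, tolerance = 1e-9)
  expect_equal(map$c1, -3.4, tolerance = 1e-9)
  # the mapping reproduces both fits: sim line evaluated at chi(order)
  ord <- seq(0, 1, by = 0.1)
  chi <- chi_from_order(ord, map$c0, map$c1)
  expect_equal(
    sim_fit$slope * chi + sim_fit$intercept,
    exp_fit$slope * ord + exp_fit$intercept,
    tolerance = 1e-9
  )
})

test_that("identity axes give the identity mapping", {
  pts <- data.frame(x = c(1, 2, 3), y = c(0.9, 0.5, 0.1))
  fit <- fit_line(pts)
  map <- calibrate_mapping(fit, fit)
  expect_equal(map$c0, 0, tolerance = 1e-9)
  expect_equal(map$c1, 1, tolerance = 1e-9)
})

test_that("scaling the experimental axis rescales c1 inversely", {
  sim_fit <- fit_line(data.frame(x = 1:4, y = 0.25 * (1:4) - 0.1))
  exp_d <- data.frame(x = seq(0, 1, by = 0.25))
  exp_d$y <- 1 - 1.8 * exp_d$x
  base <- calibrate_mapping(sim_fit, fit_line(exp_d))
  for (k in c(2, 0.5)) {
    scaled <- exp_d
    scaled$x <- scaled$x * k
    m2 <- calibrate_mapping(sim_fit, fit_line(scaled))
    expect_equal(m2$c1, base$c1 / k, tolerance = 1e-9)
    expect_equal(m2$c0, base$c0, tolerance = 1e-9)
  }
  flat <- fit_line(data.frame(x = 1:3, y = c(1, 1, 1)))
  flat$slope <- 0 # least squares leaves ~1e-17; force the exact case
  expect_error(
    calibrate_mapping(flat, fit_line(exp_d)),
    class = "starphase_degenerate"
  )
})

test_that("round-trip calibration reaches machine-level precision", {
  set.seed(8)
  for (k in 1:10) {
    c0 <- runif(1, 2, 6)
    c1 <- -runif(1, 1, 5)
    es <- -runif(1, 0.5, 3)
    ei <- runif(1, 0.5, 2)
    ss <- es / c1
    si <- ei - ss * c0
    sf <- fit_line(data.frame(x = 1:5, y = ss * (1:5) + si))
    ef <- fit_line(data.frame(x = seq(0, 1, 0.25), y = es * seq(0, 1, 0.25) + ei))
    m <- calibrate_mapping(sf, ef)
    expect_equal(m$c0, c0, tolerance = 1e-9)
    expect_equal(m$c1, c1, tolerance = 1e-9)
  }
})

test_that("morphology prediction is deterministic and composition-driven", {
  comp <- mixture(0.5, 0)
  p1 <- predict_morphology(comp, grid_n = 64, total_steps = 1200, seed = 4)
  p2 <- predict_morphology(comp, grid_n = 64, total_steps = 1200, seed = 4)
  expect_identical(p1, p2)
  expect_equal(p1$chi_AB, 4.1)
  expect_equal(p1$phase_pred, "biphasic")
  expect_lt(p1$rho_A, 0.7)
})
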