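test_that("blank images yield zero condensates without error", {
  img <- two_channel_image(matrix(0.1, 64, 64), matrix(0.1, 64, 64))
  labels <- segment_condensates(img)
  expect_equal(max(labels), 0)
  out <- measure_condensates(img, labels)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(measure_interfaces(img, condensates = out)), 0)
})

test_that("disjoint discs are segmented with areas near ground truth", {
  specs <- dplyr::bind_rows(
    droplet_spec("monophasic", radius_px = 18, cx = 40, cy = 40),
    droplet_spec("monophasic", radius_px = 22, cx = 40, cy = 130),
    droplet_spec("monophasic", radius_px = 15, cx = 130, cy = 85)
  )
  out <- render_droplet_image(specs, canvas = c(180, 180))
  labels <- segment_condensates(out$image, min_area = 50)
  expect_equal(max(labels), 3)
  got <- measure_condensates(out$image, labels)
  truth_areas <- sort(vapply(out$truth$px, length, integer(1)))
  expect_equal(sort(got$area), truth_areas, tolerance = 0.05)
})

test_that("condensate labeling uses 8-connectivity", {
  a <- matrix(0.02, 40, 40)
  a[10:18, 10:18] <- 1
  a[19:27, 19:27] <- 1 # touches only at the (18,18)/(19,19) diagonal
  img <- two_channel_image(a, a)
  labels <- segment_condensates(img, smooth_sigma = 0.5, min_area = 10)
  expect_equal(max(labels), 1)
})

test_that("uniform and biphasic droplets are classified and quantified", {
  scene <- doublet_scene()
  m <- condensate_morphometry(scene$image, min_area = 50)
  cond <- dplyr::arrange(m$condensates, .data$centroid_col)
  expect_equal(cond$phase, c("biphasic", "biphasic", "monophasic"))
  expect_equal(cond$rho_A[3], 1)
  expect_equal(cond$rho_B[3], 1)
  expect_equal(cond$n_domains[3], 1)
})

test_that("partition and angle recovery meets clean and noisy tolerances", {
  for (noisy in c(FALSE, TRUE)) {
    scene <- if (noisy) doublet_scene(blur = 1, noise = 0.05) else
      doublet_scene()
    tol_rho <- if (noisy) 0.05 else 0.02
    tol_th <- (if (noisy) 5 else 2) * pi / 180
    m <- condensate_morphometry(scene$image, min_area = 50)
    cond <- dplyr::arrange(m$condensates, .data$centroid_col)
    expect_equal(cond$rho_A[1:2], c(0.2, 0.4), tolerance = tol_rho)
    expect_equal(cond$rho_B[1:2], c(0.2, 0.3), tolerance = tol_rho)
    ifc <- dplyr::inner_join(
      m$interfaces,
      dplyr::select(m$condensates, "label", "centroid_col"),
      by = "label"
    ) |> dplyr::arrange(.data$centroid_col)
    expect_equal(nrow(ifc), 2)
    tgt_A <- c(3 * pi / 4, 140 * pi / 180)
    tgt_B <- c(3 * pi / 4, 120 * pi / 180)
    expect_true(all(abs(ifc$theta_A - tgt_A) < tol_th))
    expect_true(all(abs(ifc$theta_B - tgt_B) < tol_th))
  }
})

test_that("domain masks overlap ground truth with high Jaccard", {
  scene <- doublet_scene(blur = 1, noise = 0.05)
  m <- condensate_morphometry(scene$image, min_area = 50)
  cond <- dplyr::arrange(
    dplyr::filter(m$condensates, .data$phase == "biphasic"),
    .data$centroid_col
  )
  truth <- scene$truth[scene$truth$geometry == "biphasic", ]
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (i in 1:2) {
    expect_gt(jaccard(cond$px_Arich[[i]], truth$px_Arich[[i]]), 0.9)
    expect_gt(jaccard(cond$px_Brich[[i]], truth$px_Brich[[i]]), 0.9)
  }
})

test_that("morphometry is invariant to overall intensity scale", {
  scene <- doublet_scene(blur = 1, noise = 0.02)
  img <- scene$image
  scaled <- two_channel_image(7.3 * img$channel_A, 7.3 * img$channel_B)
  m1 <- condensate_morphometry(img, min_area = 50)
  m2 <- condensate_morphometry(scaled, min_area = 50)
  expect_equal(m1$condensates$rho_A, m2$condensates$rho_A)
  expect_equal(m1$condensates$rho_B, m2$condensates$rho_B)
  expect_equal(m1$interfaces$theta_A, m2$interfaces$theta_A)
  expect_equal(
    m1$interfaces$gammaA_over_gammaAB,
    m2$interfaces$gammaA_over_gammaAB
  )
})

test_that("swapping channels swaps the roles of A and B", {
  scene <- doublet_scene()
  img <- scene$image
  swapped <- two_channel_image(img$channel_B, img$channel_A)
  m1 <- condensate_morphometry(img, min_area = 50)
  m2 <- condensate_morphometry(swapped, min_area = 50)
  expect_equal(m1$condensates$rho_A, m2$condensates$rho_B)
  expect_equal(m1$interfaces$theta_A, m2$interfaces$theta_B,
    tolerance = 1e-6
  )
})

test_that("Neumann ratios match analytic values and close the triangle", {
  nr <- neumann_ratios(3 * pi / 4, 3 * pi / 4)
  expect_equal(nr$gammaA_over_gammaAB, sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(nr$gammaB_over_gammaAB, sqrt(2) / 2, tolerance = 1e-9)
  # symmetry
  nr2 <- neumann_ratios(2.2, 2.2)
  expect_equal(nr2$gammaA_over_gammaAB, nr2$gammaB_over_gammaAB)
  # force-triangle closure oracle: reassemble the three tension vectors
  set.seed(2)
  for (k in 1:25) {
    th_A <- runif(1, pi / 2 + 0.1, pi - 0.05)
    th_B <- runif(1, pi - th_A + 0.05, pi - 0.05)
    nr <- neumann_ratios(th_A, th_B)
    f <- rbind(
      c(1, 0), # interface tension, unit magnitude
      nr$gammaA_over_gammaAB * c(cos(th_A), sin(th_A)),
      nr$gammaB_over_gammaAB * c(cos(-th_B), sin(-th_B))
    )
    expect_lt(max(abs(colSums(f))), 1e-6)
  }
  expect_error(neumann_ratios(pi / 2, pi / 2), class = "starphase_singular")
})

test_that("reduced tension covers the de-mixed and mixed limits", {
  expect_equal(gamma_ab_reduced(pi, pi), 1)
  expect_equal(gamma_ab_reduced(pi / 2, pi / 2), 0, tolerance = 1e-12)
  expect_equal(gamma_ab_reduced(3 * pi / 4, 3 * pi / 4), sqrt(2) / 2)
  # consistency with the Neumann ratios under gamma_A = gamma_B
  th <- 2.4
  nr <- neumann_ratios(th, th)
  expect_equal(1 / nr$gammaA_over_gammaAB, 2 * gamma_ab_reduced(th, th),
    tolerance = 1e-9
  )
})

test_that("population summary computes grouped medians and counts", {
  d <- tibble::tibble(
    F_ab = c(0.1, 0.1, 0.1, 0.2),
    rho_A = c(0.1, 0.2, 0.9, 0.5),
    rho_B = c(0.2, 0.3, 0.8, 0.6)
  )
  out <- population_summary(d, F_ab)
  expect_equal(nrow(out), 2)
  expect_equal(out$median_rho_A, c(0.2, 0.5))
  expect_equal(out$n, c(3L, 1L))
  single <- population_summary(d[4, ], F_ab)
  expect_equal(single$median_rho_A, 0.5)
})

test_that("a flat interface is reported as a line with angles summing to pi", {
  # mixing-boundary limit: theta_A + theta_B ~ pi gives a straight chord
  eps <- 0.12
  specs <- droplet_spec("biphasic",
    radius_px = 32,
    theta_A = pi / 2 + eps, theta_B = pi / 2 + eps,
    rho_A = 0.6, rho_B = 0.6
  )
  out <- render_droplet_image(specs, canvas = c(128, 128))
  m <- condensate_morphometry(out$image, min_area = 50)
  expect_equal(nrow(m$interfaces), 1)
  expect_equal(m$interfaces$fit_interface[[1]]$type, "line")
  expect_equal(m$interfaces$theta_A + m$interfaces$theta_B,
    pi + 2 * eps,
    tolerance = 0.1
  )
})
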