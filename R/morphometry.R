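# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged with a union-find pass.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl < 2) {
    return(lab)
  }
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab)
  nc <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    r1 <- seq_len(nr - 1)
    c1 <- if (off[2] == 1) seq_len(nc - 1) else 2:nc
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1, c1 + off[2], drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      prs <- unique(cbind(as.vector(a[sel]), as.vector(b[sel])))
      for (i in seq_len(nrow(prs))) {
        ra <- find(prs[i, 1])
        rb <- find(prs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  new_id <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- new_id[lab[lab > 0]]
  out
}

#' Segment condensates in a two-channel image
#'
#' Removes background by an automatic (Otsu) threshold on the Gaussian-
#' smoothed sum of the two channels and labels the remaining 8-connected
#' components. Touching condensates are not split (branched morphologies
#' are genuine in this system).
#'
#' @param img A [two_channel_image()].
#' @param smooth_sigma Gaussian smoothing sigma in pixels before
#'   thresholding (default 2).
#' @param min_area Minimum condensate area in pixels (default 50).
#' @param threshold Manual background threshold on the normalized summed
#'   channels; `NULL` (default) uses Otsu's method.
#' @return An integer label matrix (0 = background) with attribute
#'   `params`.
#' @export
segment_condensates <- function(img, smooth_sigma = 2, min_area = 50,
                                threshold = NULL) {
  sA <- max(img$channel_A)
  sB <- max(img$channel_B)
  s <- img$channel_A / max(sA, .Machine$double.eps) +
    img$channel_B / max(sB, .Machine$double.eps)
  if (diff(range(s)) == 0) {
    lab <- matrix(0L, nrow(s), ncol(s))
    attr(lab, "params") <- list(threshold = NA_real_)
    return(lab)
  }
  sm <- EBImage::gblur(s, sigma = smooth_sigma)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- threshold %||% EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  lab <- label_components(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    new_id <- integer(length(sizes))
    new_id[keep] <- seq_along(keep)
    lab[lab > 0] <- new_id[lab[lab > 0]]
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  attr(lab, "params") <- list(
    threshold = thr, smooth_sigma = smooth_sigma, min_area = min_area
  )
  lab
}

erode_px_set <- function(mask, px) {
  if (px <= 0) {
    return(mask)
  }
  brush <- EBImage::makeBrush(2 * px + 1, shape = "disc")
  EBImage::erode(mask, brush) > 0
}

# split one condensate into A-rich / B-rich pixel sets.
split_domains_one <- function(smA, smB, idx, dims, min_domain_frac,
                              norm_quantile, min_contrast = 0.05) {
  qA <- quantile(smA[idx], norm_quantile, names = FALSE)
  qB <- quantile(smB[idx], norm_quantile, names = FALSE)
  if (qA <= 0 || qB <= 0) {
    return(list(A = integer(0), B = integer(0)))
  }
  d <- smA[idx] / qA - smB[idx] / qB
  # nearly-mixed droplets have no identifiable domains: require the two
  # putative sides to differ by a resolvable normalized contrast
  if (sum(d > 0) == 0 || sum(d <= 0) == 0 ||
    median(d[d > 0]) - median(d[d <= 0]) < min_contrast) {
    return(list(A = integer(0), B = integer(0)))
  }
  min_px <- max(1, ceiling(min_domain_frac * length(idx)))
  pick <- function(sel) {
    sub <- matrix(FALSE, dims[1], dims[2])
    sub[idx[sel]] <- TRUE
    lab <- label_components(sub)
    if (max(lab) == 0) {
      return(integer(0))
    }
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_px)
    if (!length(keep)) {
      return(integer(0))
    }
    which(matrix(lab %in% keep, dims[1], dims[2]))
  }
  list(A = pick(d > 0), B = pick(d <= 0))
}

#' Per-condensate domain splitting and partition coefficients
#'
#' Within each labeled condensate, pixels are assigned to the A-rich or
#' B-rich domain by comparing the two channels after per-condensate
#' quantile normalization (robust to unequal dye brightness). Domains
#' smaller than a minimum area fraction are discarded; if either domain is
#' then absent, or the raw partition coefficients exceed a contrast
#' ceiling (nearly-mixed domains are not resolvable), the condensate is
#' classified monophasic with `rho_A = rho_B = 1`.
#'
#' Partition coefficients are intensity ratios sampled on domain masks
#' eroded to suppress interface blur: `rho_A` is the mean channel-A
#' intensity in the B-rich (A-depleted) domain divided by the mean in the
#' A-rich domain, and symmetrically for `rho_B`. Raw ratios above 1 are
#' capped at 1 for reporting, with the raw values retained.
#'
#' @inheritParams segment_condensates
#' @param labels Label matrix from [segment_condensates()]; computed if
#'   missing.
#' @param erode_px Erosion radius in pixels for intensity sampling
#'   (default 2).
#' @param min_domain_frac Minimum domain area as a fraction of condensate
#'   area (default 0.02).
#' @param norm_quantile Within-condensate quantile used to normalize each
#'   channel for domain assignment (default 0.95).
#' @param rho_split_max Contrast ceiling: domain splits with both raw
#'   partition coefficients above this value are reclassified monophasic
#'   (default 0.95).
#' @param min_contrast Minimum difference in median quantile-normalized
#'   intensity between the two putative domains for a split to be
#'   attempted (default 0.05); below it the condensate is monophasic.
#' @param domain_smooth_sigma Gaussian sigma for the channels used in
#'   domain assignment (default 1; intensity sampling always uses the raw
#'   channels).
#' @param ... Passed to [segment_condensates()] when `labels` is missing.
#' @return A tibble, one row per condensate: `label`, `area`, `n_domains`,
#'   `phase`, `rho_A`, `rho_B`, `rho_A_raw`, `rho_B_raw`, `undefined_ratio`
#'   flag, centroid columns, and list-columns `px`, `px_Arich`, `px_Brich`
#'   of pixel indices.
#' @export
measure_condensates <- function(img, labels = NULL, erode_px = 2,
                                min_domain_frac = 0.02,
                                norm_quantile = 0.95,
                                rho_split_max = 0.95,
                                min_contrast = 0.05,
                                domain_smooth_sigma = 1, ...) {
  if (is.null(labels)) labels <- segment_condensates(img, ...)
  dims <- dim(labels)
  n <- max(labels)
  A <- img$channel_A
  B <- img$channel_B
  smA <- if (domain_smooth_sigma > 0) EBImage::gblur(A, domain_smooth_sigma) else A
  smB <- if (domain_smooth_sigma > 0) EBImage::gblur(B, domain_smooth_sigma) else B
  rows <- purrr::map(seq_len(n), function(lb) {
    idx <- which(labels == lb)
    dom <- split_domains_one(
      smA, smB, idx, dims, min_domain_frac, norm_quantile, min_contrast
    )
    rc <- arrayInd(idx, dims)
    out <- tibble::tibble(
      label = lb, area = length(idx),
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      n_domains = (length(dom$A) > 0) + (length(dom$B) > 0),
      phase = "monophasic",
      rho_A = 1, rho_B = 1, rho_A_raw = NA_real_, rho_B_raw = NA_real_,
      undefined_ratio = FALSE,
      px = list(idx), px_Arich = list(integer(0)),
      px_Brich = list(integer(0))
    )
    if (length(dom$A) > 0 && length(dom$B) > 0) {
      sample_px <- function(px_set) {
        m <- matrix(FALSE, dims[1], dims[2])
        m[px_set] <- TRUE
        er <- which(erode_px_set(m, erode_px))
        if (length(er) < 4) px_set else er
      }
      eA <- sample_px(dom$A)
      eB <- sample_px(dom$B)
      iA_in_A <- mean(A[eA])
      iA_in_B <- mean(A[eB])
      iB_in_B <- mean(B[eB])
      iB_in_A <- mean(B[eA])
      if (iA_in_A <= 0 || iB_in_B <= 0) {
        out$undefined_ratio <- TRUE
        out$n_domains <- 2L
        out$phase <- "biphasic"
        out$px_Arich <- list(dom$A)
        out$px_Brich <- list(dom$B)
        return(out)
      }
      raw_A <- iA_in_B / iA_in_A
      raw_B <- iB_in_A / iB_in_B
      if (min(raw_A, raw_B) <= rho_split_max) {
        out$phase <- "biphasic"
        out$n_domains <- 2L
        out$rho_A_raw <- raw_A
        out$rho_B_raw <- raw_B
        out$rho_A <- min(raw_A, 1)
        out$rho_B <- min(raw_B, 1)
        out$px_Arich <- list(dom$A)
        out$px_Brich <- list(dom$B)
      } else {
        out$n_domains <- 1L
      }
    } else {
      out$n_domains <- 1L # the whole condensate is one domain
    }
    out
  })
  if (!length(rows)) {
    return(tibble::tibble(
      label = integer(0), area = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      n_domains = integer(0), phase = character(0),
      rho_A = numeric(0), rho_B = numeric(0),
      rho_A_raw = numeric(0), rho_B_raw = numeric(0),
      undefined_ratio = logical(0),
      px = list(), px_Arich = list(), px_Brich = list()
    ))
  }
  dplyr::bind_rows(rows)
}

# boundary pixel sets (4-neighbourhood) for interface extraction
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

touches <- function(mask, other) {
  hit <- matrix(FALSE, nrow(mask), ncol(mask))
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    hit <- hit | shift_mat(other, off[1], off[2])
  }
  mask & hit
}

# subpixel boundary samples: midpoints between 4-adjacent pixel pairs with
# one pixel in `m_in` and the other in `m_out` (halves the half-pixel
# inset bias of using inside-pixel centers)
boundary_midpoints <- function(m_in, m_out) {
  pts <- list()
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sel <- which(m_in & shift_mat(m_out, -off[1], -off[2]))
    if (length(sel)) {
      rc <- arrayInd(sel, dim(m_in))
      pts[[length(pts) + 1]] <- cbind(
        rc[, 1] + off[1] / 2,
        rc[, 2] + off[2] / 2
      )
    }
  }
  if (!length(pts)) {
    return(matrix(numeric(0), 0, 2))
  }
  do.call(rbind, pts)
}

#' Interface geometry and Neumann analysis of biphasic condensates
#'
#' For every biphasic condensate, extracts three boundary arcs - the
#' solvent-facing contour of the A-rich domain, the same for B, and the
#' A-B interface - and fits each with an algebraic (Taubin) circle.
#' Interfaces whose fitted radius exceeds `line_radius_factor` times the
#' condensate equivalent radius are treated as straight lines. The two
#' triple points are located as the extremes of the interface arc along
#' its principal axis; at each, the interior contact angle of each dense
#' phase is the wedge angle between its solvent-facing boundary and the
#' interface (computed from the fitted normals), and the two per-point
#' values are averaged into `theta_A` and `theta_B`.
#'
#' From the angles, the external (solvent) angle is
#' `theta = 2 pi - theta_A - theta_B`, the reduced interfacial tension is
#' `cos(theta / 2) = gamma_AB / (2 gamma_0)` under the `gamma_A = gamma_B`
#' assumption, and the Neumann ratios follow from [neumann_ratios()].
#'
#' @param img A [two_channel_image()].
#' @param condensates Output of [measure_condensates()]; computed if
#'   missing.
#' @param labels Label matrix (used only when `condensates` is missing).
#' @param min_arc_px Minimum pixels per boundary arc for a fit (default 8).
#' @param line_radius_factor Interface radius cap in units of the
#'   condensate equivalent radius (default 10).
#' @param ... Passed to [measure_condensates()] when needed.
#' @return A tibble, one row per biphasic condensate with a fittable
#'   interface: angles (radians), `theta`, `cos_half_theta`, tension
#'   ratios, fit list-columns and RMS residuals, and a `flag` column
#'   (`"ok"`, `"unfittable"`, or `"singular"`).
#' @export
measure_interfaces <- function(img, condensates = NULL, labels = NULL,
                               min_arc_px = 8, line_radius_factor = 10, ...) {
  if (is.null(condensates)) {
    condensates <- measure_condensates(img, labels = labels, ...)
  }
  dims <- dim(img$channel_A)
  bi <- dplyr::filter(condensates, .data$phase == "biphasic")
  empty <- tibble::tibble(
    label = integer(0), theta_A = numeric(0), theta_B = numeric(0),
    theta = numeric(0), cos_half_theta = numeric(0),
    gammaA_over_gammaAB = numeric(0), gammaB_over_gammaAB = numeric(0),
    fit_A = list(), fit_B = list(), fit_interface = list(),
    rms_A = numeric(0), rms_B = numeric(0), rms_interface = numeric(0),
    flag = character(0)
  )
  if (nrow(bi) == 0) {
    return(empty)
  }
  rows <- purrr::map(seq_len(nrow(bi)), function(i) {
    px_all <- bi$px[[i]]
    pxA <- bi$px_Arich[[i]]
    pxB <- bi$px_Brich[[i]]
    cond <- matrix(FALSE, dims[1], dims[2])
    cond[px_all] <- TRUE
    mA <- matrix(FALSE, dims[1], dims[2])
    mA[pxA] <- TRUE
    mB <- matrix(FALSE, dims[1], dims[2])
    mB[pxB] <- TRUE
    outside <- !cond
    pa <- boundary_midpoints(mA, outside)
    pb <- boundary_midpoints(mB, outside)
    pi_ <- boundary_midpoints(mA, mB)
    base <- tibble::tibble(
      label = bi$label[i], theta_A = NA_real_, theta_B = NA_real_,
      theta = NA_real_, cos_half_theta = NA_real_,
      gammaA_over_gammaAB = NA_real_, gammaB_over_gammaAB = NA_real_,
      fit_A = list(NULL), fit_B = list(NULL), fit_interface = list(NULL),
      rms_A = NA_real_, rms_B = NA_real_, rms_interface = NA_real_,
      flag = "unfittable"
    )
    if (nrow(pa) < min_arc_px || nrow(pb) < min_arc_px ||
      nrow(pi_) < min_arc_px) {
      return(base)
    }
    r_eq <- sqrt(length(px_all) / pi)
    xy <- function(idx) arrayInd(idx, dims)
    # triple points: extremes of the interface arc along its principal axis
    ctr <- colMeans(pi_)
    cen <- sweep(pi_, 2, ctr)
    ax <- svd(cen)$v[, 1]
    proj <- cen %*% ax
    P1 <- pi_[which.min(proj), ]
    P2 <- pi_[which.max(proj), ]
    # pixels straddling a triple point contaminate all three arcs; drop a
    # small neighbourhood of each before fitting
    trim <- max(2, round(0.08 * r_eq))
    away <- function(pts) {
      d1 <- sqrt((pts[, 1] - P1[1])^2 + (pts[, 2] - P1[2])^2)
      d2 <- sqrt((pts[, 1] - P2[1])^2 + (pts[, 2] - P2[2])^2)
      kept <- pts[d1 > trim & d2 > trim, , drop = FALSE]
      if (nrow(kept) >= max(3, min_arc_px / 2)) kept else pts
    }
    pa <- away(pa)
    pb <- away(pb)
    pif <- away(pi_)
    fit_A <- fit_circle_taubin(pa[, 1], pa[, 2])
    fit_B <- fit_circle_taubin(pb[, 1], pb[, 2])
    fit_I <- fit_circle_taubin(pif[, 1], pif[, 2],
      radius_cap = line_radius_factor * r_eq
    )
    side <- function(fit, pts) {
      if (fit$type == "line") {
        s <- mean(sweep(pts, 2, fit$point) %*% fit$normal)
        if (s >= 0) 1 else -1
      } else {
        ins <- mean((pts[, 1] - fit$xc)^2 + (pts[, 2] - fit$yc)^2 < fit$r^2)
        if (ins >= 0.5) 1 else -1
      }
    }
    ptsA <- xy(pxA)
    ptsB <- xy(pxB)
    sA_out <- side(fit_A, ptsA)
    sB_out <- side(fit_B, ptsB)
    sA_int <- side(fit_I, ptsA)
    sB_int <- side(fit_I, ptsB)
    # evaluate each wedge at the analytic crossing of its two fitted
    # boundaries (snapped to the nearer pixel-estimated triple point);
    # falls back to the pixel estimate when the fits do not intersect
    snap <- function(fit_out, P) {
      ix <- boundary_intersections(fit_out, fit_I)
      if (nrow(ix) == 0) {
        return(P)
      }
      d2 <- (ix[, 1] - P[1])^2 + (ix[, 2] - P[2])^2
      ix[which.min(d2), ]
    }
    th_A <- mean(c(
      interior_angle(snap(fit_A, P1), fit_A, sA_out, fit_I, sA_int),
      interior_angle(snap(fit_A, P2), fit_A, sA_out, fit_I, sA_int)
    ))
    th_B <- mean(c(
      interior_angle(snap(fit_B, P1), fit_B, sB_out, fit_I, sB_int),
      interior_angle(snap(fit_B, P2), fit_B, sB_out, fit_I, sB_int)
    ))
    base$fit_A <- list(fit_A)
    base$fit_B <- list(fit_B)
    base$fit_interface <- list(fit_I)
    base$rms_A <- fit_A$rms
    base$rms_B <- fit_B$rms
    base$rms_interface <- fit_I$rms
    base$theta_A <- th_A
    base$theta_B <- th_B
    base$theta <- 2 * pi - th_A - th_B
    base$cos_half_theta <- cos(base$theta / 2)
    if (abs(sin(th_A + th_B)) < 1e-9) {
      base$flag <- "singular"
    } else {
      nr <- neumann_ratios(th_A, th_B)
      base$gammaA_over_gammaAB <- nr$gammaA_over_gammaAB
      base$gammaB_over_gammaAB <- nr$gammaB_over_gammaAB
      base$flag <- "ok"
    }
    base
  })
  dplyr::bind_rows(rows)
}

#' Interfacial-tension ratios from contact angles (Neumann criterion)
#'
#' At a triple junction the three tension vectors balance; resolving the
#' force triangle gives `gamma_A / gamma_AB = -sin(theta_B) /
#' sin(theta_A + theta_B)` and `gamma_B / gamma_AB = -sin(theta_A) /
#' sin(theta_A + theta_B)`. Ratios are positive when
#' `theta_A + theta_B` lies in `(pi, 2 pi)`.
#'
#' @param theta_A,theta_B Contact angles in radians (vectorized).
#' @return A tibble with columns `gammaA_over_gammaAB`,
#'   `gammaB_over_gammaAB`.
#' @examples
#' neumann_ratios(3 * pi / 4, 3 * pi / 4) # both 0.7071
#' @export
neumann_ratios <- function(theta_A, theta_B) {
  s <- sin(theta_A + theta_B)
  if (any(abs(s) < 1e-12)) {
    rlang::abort(
      "Singular configuration: theta_A + theta_B is a multiple of pi.",
      class = "starphase_singular"
    )
  }
  tibble::tibble(
    gammaA_over_gammaAB = -sin(theta_B) / s,
    gammaB_over_gammaAB = -sin(theta_A) / s
  )
}

#' Reduced A-B interfacial tension from contact angles
#'
#' Under the symmetric-tension assumption `gamma_A = gamma_B = gamma_0`,
#' the Neumann balance reduces to `gamma_AB = 2 gamma_0 cos(theta / 2)`
#' with `theta = 2 pi - theta_A - theta_B`. Returns `cos(theta / 2)`:
#' 1 for tangent fully de-mixed caps, 0 at the mixing boundary where the
#' A-B tension vanishes.
#'
#' @inheritParams neumann_ratios
#' @return Numeric vector `cos((2 pi - theta_A - theta_B) / 2)`.
#' @examples
#' gamma_ab_reduced(pi, pi) # 1
#' @export
gamma_ab_reduced <- function(theta_A, theta_B) {
  cos((2 * pi - theta_A - theta_B) / 2)
}

#' Population summary of condensate morphometry
#'
#' Medians, interquartile ranges and counts of the morphometric quantities,
#' grouped by any composition columns present.
#'
#' @param data A tibble of per-condensate or per-interface records.
#' @param ... Grouping columns (tidy-select), e.g. `F_A, F_ab` or `chi_AB`.
#' @return A tibble with one row per group: `n` plus `median_*` and
#'   `iqr_*` for each recognized metric column present in `data`.
#' @export
population_summary <- function(data, ...) {
  metrics <- intersect(
    c(
      "rho_A", "rho_B", "theta_A", "theta_B", "cos_half_theta",
      "gammaA_over_gammaAB", "gammaB_over_gammaAB"
    ),
    names(data)
  )
  grouped <- dplyr::group_by(data, ...)
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    dplyr::across(
      dplyr::all_of(metrics),
      list(
        median = ~ median(.x, na.rm = TRUE),
        iqr = ~ stats::IQR(.x, na.rm = TRUE)
      ),
      .names = "{.fn}_{.col}"
    ),
    .groups = "drop"
  )
}

#' Full morphometry of a two-channel image
#'
#' Convenience wrapper running segmentation, domain splitting, partition
#' coefficients and interface analysis with one configuration; the same
#' code path serves simulation snapshots and (synthetic) micrographs.
#'
#' @inheritParams measure_condensates
#' @param ... Passed to [segment_condensates()] and
#'   [measure_condensates()].
#' @return A list with elements `condensates` and `interfaces` (tibbles)
#'   and `labels` (the label matrix).
#' @export
condensate_morphometry <- function(img, ...) {
  labels <- segment_condensates(img, ...)
  args <- list(...)
  margs <- args[names(args) %in% names(formals(measure_condensates))]
  cond <- do.call(
    measure_condensates,
    c(list(img = img, labels = labels), margs)
  )
  list(
    condensates = cond,
    interfaces = measure_interfaces(img, condensates = cond),
    labels = labels
  )
}

#' Recenter a periodic image so condensates avoid the image border
#'
#' Simulation snapshots are periodic; a condensate wrapped across the
#' border would be segmented as two truncated pieces. This circularly
#' shifts both channels so that the border row and column carry the least
#' foreground mass.
#'
#' @param img A [two_channel_image()].
#' @return A shifted [two_channel_image()].
#' @export
recenter_periodic <- function(img) {
  s <- img$channel_A + img$channel_B
  s <- s - min(s)
  rshift <- which.min(rowSums(s)) # this row becomes row 1
  cshift <- which.min(colSums(s))
  roll <- function(m) {
    m[
      c(rshift:nrow(m), seq_len(rshift - 1))[seq_len(nrow(m))],
      c(cshift:ncol(m), seq_len(cshift - 1))[seq_len(ncol(m))]
    ]
  }
  two_channel_image(roll(img$channel_A), roll(img$channel_B),
    pixel_size = img$pixel_size
  )
}
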