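#' Algebraic (Taubin) circle fit
#'
#' Fits a circle to a point set by the Taubin algebraic least-squares
#' method (SVD formulation), which is nearly unbiased for partial arcs.
#' Near-degenerate fits (vanishing quadratic coefficient, i.e. radius far
#' beyond the data extent) are returned as straight lines fitted by total
#' least squares.
#'
#' @param x,y Point coordinates (length >= 3 for a circle).
#' @param radius_cap Radius above which the fit is represented as a line
#'   (default `Inf`: never).
#' @return A list: for a circle, `type = "circle"`, `xc`, `yc`, `r`, `rms`;
#'   for a line, `type = "line"`, `point`, `dir`, `normal`, `rms`.
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' fit_circle_taubin(3 + 2 * cos(th), 1 + 2 * sin(th))
#' @export
fit_circle_taubin <- function(x, y, radius_cap = Inf) {
  if (length(x) < 3) rlang::abort("Need at least 3 points for a circle fit.")
  mx <- mean(x)
  my <- mean(y)
  u <- x - mx
  v <- y - my
  z <- u^2 + v^2
  zm <- mean(z)
  if (zm == 0) rlang::abort("Degenerate point set (all points identical).")
  z0 <- (z - zm) / (2 * sqrt(zm))
  sv <- svd(cbind(z0, u, v))
  a <- sv$v[, 3]
  a1 <- a[1] / (2 * sqrt(zm))
  d <- -zm * a1
  # circle: a1 * (u^2 + v^2) + a[2] u + a[3] v + d = 0
  span <- sqrt(max(z)) # data extent around centroid
  if (abs(a1) < 1e-12 || sqrt(a[2]^2 + a[3]^2 - 4 * a1 * d) / (2 * abs(a1)) > radius_cap) {
    return(fit_line_tls(x, y))
  }
  xc <- -a[2] / (2 * a1) + mx
  yc <- -a[3] / (2 * a1) + my
  r <- sqrt(a[2]^2 + a[3]^2 - 4 * a1 * d) / (2 * abs(a1))
  rms <- sqrt(mean((sqrt((x - xc)^2 + (y - yc)^2) - r)^2))
  list(type = "circle", xc = xc, yc = yc, r = r, rms = rms, n = length(x))
}

#' @rdname fit_circle_taubin
#' @export
fit_line_tls <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  m <- cbind(x - mx, y - my)
  sv <- svd(m)
  dir <- sv$v[, 1]
  normal <- sv$v[, 2]
  rms <- sqrt(mean((m %*% normal)^2))
  list(
    type = "line", point = c(mx, my), dir = dir, normal = normal,
    rms = rms, n = length(x)
  )
}

unit <- function(v) v / sqrt(sum(v^2))

# Inward normal of a fitted boundary at point P, pointing into the phase.
# For a circle, sigma = +1 when the phase is inside the circle.
boundary_normal <- function(fit, P, sigma) {
  if (fit$type == "circle") {
    sigma * unit(c(fit$xc, fit$yc) - P)
  } else {
    sigma * fit$normal
  }
}

# Intersection points of two fitted boundaries (circle/circle,
# circle/line); empty matrix when they do not intersect.
boundary_intersections <- function(fit1, fit2) {
  none <- matrix(numeric(0), 0, 2)
  if (fit1$type == "line" && fit2$type == "line") {
    return(none)
  }
  if (fit1$type == "line") {
    return(boundary_intersections(fit2, fit1))
  }
  c1 <- c(fit1$xc, fit1$yc)
  if (fit2$type == "circle") {
    c2 <- c(fit2$xc, fit2$yc)
    d <- sqrt(sum((c2 - c1)^2))
    if (d < 1e-9 || d > fit1$r + fit2$r || d < abs(fit1$r - fit2$r)) {
      return(none)
    }
    a <- (fit1$r^2 - fit2$r^2 + d^2) / (2 * d)
    h2 <- fit1$r^2 - a^2
    if (h2 < 0) {
      return(none)
    }
    h <- sqrt(h2)
    u <- (c2 - c1) / d
    mid <- c1 + a * u
    perp <- c(-u[2], u[1])
    rbind(mid + h * perp, mid - h * perp)
  } else {
    # circle vs line: offset of center along the line normal
    off <- sum((c1 - fit2$point) * fit2$normal)
    h2 <- fit1$r^2 - off^2
    if (h2 < 0) {
      return(none)
    }
    h <- sqrt(h2)
    foot <- c1 - off * fit2$normal
    rbind(foot + h * fit2$dir, foot - h * fit2$dir)
  }
}

#' Interior wedge angle between two boundary arcs at a point
#'
#' For a phase bounded at a triple point by two circular (or straight)
#' interfaces, the interior angle is `pi - acos(n1 . n2)` where `n1`, `n2`
#' are the unit normals of the two boundaries pointing into the phase.
#'
#' @param P Numeric length-2 point.
#' @param fit1,fit2 Boundary fits from [fit_circle_taubin()].
#' @param sigma1,sigma2 Orientation signs: +1 when the phase lies on the
#'   side the circle center is on (inside the circle), -1 otherwise; for a
#'   line, +1 when the phase lies on the side its `normal` points to.
#' @return Angle in radians, in (0, pi).
#' @export
interior_angle <- function(P, fit1, sigma1, fit2, sigma2) {
  n1 <- boundary_normal(fit1, P, sigma1)
  n2 <- boundary_normal(fit2, P, sigma2)
  pi - acos(max(-1, min(1, sum(n1 * n2))))
}

#' Analytic Janus-droplet geometry from target contact angles
#'
#' Constructs the three-circle geometry of a biphasic (doublet) droplet:
#' two solvent-facing caps and the internal A-B interface arc, such that
#' the interior angles of the two dense phases at the triple points equal
#' the targets. The two triple points are placed at `(0, +/-h)`; each
#' boundary through them with tangent direction angle `phi` at `(0, h)` is
#' the circle with center `(h tan(phi), 0)` and radius `h / |cos(phi)|`.
#' The interface tangent offset `delta` (its curvature) is solved from the
#' Laplace pressure balance with tensions given by the Neumann relations,
#' so the construction is mechanically self-consistent; at
#' `theta_A = theta_B` the interface is a straight chord.
#'
#' @param theta_A,theta_B Target interior contact angles in radians;
#'   `theta_A + theta_B` must lie in (pi, 2 pi).
#' @param radius Radius of the larger of the two cap circles, pixels.
#' @return A list of class `doublet_geometry`: `circle_A`, `circle_B`,
#'   `interface` (circle or line fit structures), `triple_points` (2 x 2
#'   matrix), `h`, `delta`, side signs `sigma_A`, `sigma_B`, and interior
#'   reference points `q_A`, `q_B`.
#' @examples
#' g <- doublet_geometry(3 * pi / 4, 3 * pi / 4, radius = 30)
#' doublet_angles(g) # recovers the targets
#' @export
doublet_geometry <- function(theta_A, theta_B, radius = 30) {
  if (theta_A <= 0 || theta_B <= 0 || theta_A >= 2 * pi || theta_B >= 2 * pi) {
    rlang::abort("Contact angles must lie in (0, 2 pi).")
  }
  ssum <- theta_A + theta_B
  if (ssum <= pi || ssum >= 2 * pi) {
    rlang::abort("Need theta_A + theta_B in (pi, 2 pi) for a constructible doublet.",
      class = "starphase_geometry"
    )
  }
  s <- sin(ssum)
  gam_A <- -sin(theta_B) / s
  gam_B <- -sin(theta_A) / s
  # Laplace balance: gam_A |sin(delta - theta_A)| - gam_B |sin(delta + theta_B)|
  #                  = sin(delta)   (interface tension = 1)
  f <- function(delta) {
    gam_A * abs(sin(delta - theta_A)) - gam_B * abs(sin(delta + theta_B)) -
      sin(delta)
  }
  lim <- min(theta_A, 2 * pi - ssum, pi - 1e-6) * 0.98
  delta <- tryCatch(
    uniroot(f, c(-lim, lim), tol = 1e-12)$root,
    error = function(e) {
      gr <- seq(-lim, lim, length.out = 4001)
      gr[which.min(abs(f(gr)))]
    }
  )
  phi_I <- -pi / 2 + delta
  phi_A <- phi_I - theta_A
  phi_B <- phi_I + theta_B
  h <- radius * min(abs(cos(phi_A)), abs(cos(phi_B))) # larger cap = radius
  mk_circle <- function(phi) {
    list(
      type = "circle", xc = h * tan(phi), yc = 0, r = h / abs(cos(phi)),
      rms = 0
    )
  }
  circle_A <- mk_circle(phi_A)
  circle_B <- mk_circle(phi_B)
  straight <- abs(cos(phi_I)) < 1e-9
  interface <- if (straight) {
    list(
      type = "line", point = c(0, 0), dir = c(0, 1), normal = c(-1, 0),
      rms = 0
    )
  } else {
    mk_circle(phi_I)
  }
  q_A <- c((circle_A$xc - circle_A$r) / 2, 0)
  q_B <- c((circle_B$xc + circle_B$r) / 2, 0)
  side_sign <- function(fit, q) {
    if (fit$type == "line") {
      sign(sum((q - fit$point) * fit$normal))
    } else {
      if (sqrt(sum((q - c(fit$xc, fit$yc))^2)) < fit$r) 1 else -1
    }
  }
  structure(
    list(
      circle_A = circle_A, circle_B = circle_B, interface = interface,
      triple_points = rbind(c(0, h), c(0, -h)),
      h = h, delta = delta,
      sigma_A = side_sign(interface, q_A),
      sigma_B = side_sign(interface, q_B),
      q_A = q_A, q_B = q_B,
      theta_A_target = theta_A, theta_B_target = theta_B
    ),
    class = "doublet_geometry"
  )
}

#' Re-measure contact angles from an analytic doublet geometry
#'
#' Evaluates the interior angles at both triple points from the circle
#' geometry (independent of any rasterization); used as the
#' self-consistency oracle for [doublet_geometry()].
#'
#' @param geom A [doublet_geometry()] object.
#' @return A list with `theta_A`, `theta_B` (averaged over the two triple
#'   points, radians).
#' @export
doublet_angles <- function(geom) {
  angs <- apply(geom$triple_points, 1, function(P) {
    c(
      interior_angle(P, geom$circle_A, 1, geom$interface, geom$sigma_A),
      interior_angle(P, geom$circle_B, 1, geom$interface, geom$sigma_B)
    )
  })
  list(theta_A = mean(angs[1, ]), theta_B = mean(angs[2, ]))
}

# membership tests on a pixel grid (used by the renderer)
in_circle <- function(x, y, circ) {
  (x - circ$xc)^2 + (y - circ$yc)^2 <= circ$r^2
}

on_phase_side <- function(x, y, fit, sigma) {
  if (fit$type == "line") {
    sigma * ((x - fit$point[1]) * fit$normal[1] +
      (y - fit$point[2]) * fit$normal[2]) >= 0
  } else {
    inside <- (x - fit$xc)^2 + (y - fit$yc)^2 <= fit$r^2
    if (sigma > 0) inside else !inside
  }
}
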