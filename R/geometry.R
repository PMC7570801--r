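#' Volume of a chopped pyramid (frustum)
#'
#' Volume of the solid between two parallel cross-sections of areas `B` and
#' `Bp` separated by height `h`, using the classical prismatoid formula
#' \deqn{V = \frac{h}{3}\left(B + B' + \sqrt{B B'}\right).}
#' The formula is exact for any pyramid or cone frustum, i.e. whenever the
#' two faces are scaled copies of one another.
#'
#' @param B area of the top face (cm^2).
#' @param Bp area of the bottom face (cm^2).
#' @param h height between the faces (cm).
#' @return Volume in cm^3 (= mL).
#' @examples
#' frustum_volume(2, 2, 3)      # prism limit: B * h = 6
#' frustum_volume(3, 0, 3)      # cone limit: B * h / 3 = 3
#' @seealso [ellipse_area()], [cap_volume()], [estimate_volume()]
#' @export
frustum_volume <- function(B, Bp, h) {
  stopifnot(is.numeric(B), is.numeric(Bp), is.numeric(h))
  if (any(B < 0) || any(Bp < 0) || any(h < 0)) {
    stop("frustum_volume(): areas and height must be non-negative")
  }
  h / 3 * (B + Bp + sqrt(B * Bp))
}

#' Area of an elliptical cross-section
#'
#' Area of an ellipse given its two full diameters,
#' \eqn{A = \pi (d_1/2)(d_2/2)}.  The circular cross-section is the special
#' case `d1 == d2 == 2r`.
#'
#' @param d1,d2 full diameters of the ellipse (cm).
#' @return Area in cm^2.
#' @examples
#' ellipse_area(2, 2)   # unit circle, pi
#' ellipse_area(4, 2)   # semi-axes 2 and 1, 2*pi
#' @export
ellipse_area <- function(d1, d2) {
  stopifnot(is.numeric(d1), is.numeric(d2))
  if (any(d1 < 0) || any(d2 < 0)) stop("ellipse_area(): diameters must be non-negative")
  pi * (d1 / 2) * (d2 / 2)
}

#' Volume of a produce tip cap
#'
#' Volume of the rounded tip segment at either end of the produce, with
#' elliptical base of full diameters `d1`, `d2` and axial height `h`:
#' \deqn{V = \pi d_1 d_2 h / 6.}
#' Note this is numerically the volume of a semi-ellipsoid with those
#' diameters and half-axis `h` (an elliptical *cone* of the same base and
#' height would be half this, \eqn{\pi d_1 d_2 h / 12}); the semi-ellipsoid
#' form is the one used throughout the estimator.
#'
#' @param d1,d2 full diameters of the cap base (cm).
#' @param h axial height of the cap (cm).
#' @return Volume in cm^3.
#' @examples
#' cap_volume(2, 2, 3)  # 2*pi, equals semi-ellipsoid (2/3)*pi*1*1*3
#' @export
cap_volume <- function(d1, d2, h) {
  stopifnot(is.numeric(d1), is.numeric(d2), is.numeric(h))
  if (any(d1 < 0) || any(d2 < 0) || any(h < 0)) {
    stop("cap_volume(): diameters and height must be non-negative")
  }
  pi * d1 * d2 * h / 6
}

#' Elliptical disk area from two orthogonal views
#'
#' Cross-section area of one disk in the two-view disk method,
#' \eqn{A = \pi d z / 4}, where `z` is the width seen from the top view and
#' `d` the width seen from the side view.  With `d == z` it reduces to the
#' one-view circular disk \eqn{\pi (z/2)^2}.
#'
#' @param d side-view width of the disk (cm).
#' @param z top-view width of the disk (cm).
#' @return Area in cm^2.
#' @export
disk_area_two_view <- function(d, z) {
  stopifnot(is.numeric(d), is.numeric(z))
  if (any(d < 0) || any(z < 0)) stop("disk_area_two_view(): widths must be non-negative")
  pi * d * z / 4
}

#' Reference volume by the water displacement method
#'
#' Volume from the three mass readings of the submersion protocol:
#' `m_apparatus` (apparatus with water at the mark), `m_fruit` (the fruit in
#' air) and `m_submerged` (apparatus with the fruit held fully submerged,
#' water back at the mark):
#' \deqn{V = (M_1 + M_2 - M_3) / \rho_{water}.}
#'
#' @param m_apparatus,m_fruit,m_submerged masses in grams.
#' @param water_density density of the water in g/mL (default 1).
#' @return Volume in mL.
#' @export
wdm_volume <- function(m_apparatus, m_fruit, m_submerged, water_density = 1) {
  stopifnot(is.numeric(m_apparatus), is.numeric(m_fruit), is.numeric(m_submerged))
  if (any(water_density <= 0)) stop("wdm_volume(): water density must be positive")
  (m_apparatus + m_fruit - m_submerged) / water_density
}

#' Direct least-squares ellipse fit
#'
#' Fits the algebraic conic \eqn{a x^2 + b x y + c y^2 + d x + e y + f = 0}
#' to a set of points, constrained to be an ellipse (Fitzgibbon's direct
#' least-squares method: minimise algebraic distance subject to
#' \eqn{4ac - b^2 = 1}).  Used to check that measured produce cross-sections
#' are well described by ellipses and to read off their axis ratio.
#'
#' @param points two-column matrix (or data frame) of x, y coordinates; at
#'   least 6 non-collinear points.
#' @return An object of class `"conic_fit"`: a list with `coefficients`
#'   (named a..f, normalised to unit vector), `center`, `semi_axes`
#'   (major, minor), `angle` (radians of the major axis) and `axis_ratio`
#'   (minor/major, in \[0, 1\]).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' fit_ellipse(cbind(2 * cos(th), sin(th)))$axis_ratio  # 0.5
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2) {
    stop("fit_ellipse(): points must be a numeric n x 2 matrix")
  }
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 6) stop("fit_ellipse(): at least 6 points are required")
  # centre and scale for numerical conditioning
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  sc <- mean(sqrt((points[, 1] - mx)^2 + (points[, 2] - my)^2))
  if (sc < .Machine$double.eps) stop("fit_ellipse(): degenerate (coincident) points")
  x <- (points[, 1] - mx) / sc
  y <- (points[, 2] - my) / sc

  D1 <- cbind(x^2, x * y, y^2)       # quadratic part
  D2 <- cbind(x, y, 1)               # linear part
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("fit_ellipse(): degenerate point configuration")
  })
  M <- S1 + S2 %*% T1
  # premultiply by inv(C) for constraint 4ac - b^2 = 1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("fit_ellipse(): no elliptical solution (points may be collinear)")
  a1 <- evec[, ok[1]]
  coef_s <- c(a1, T1 %*% a1)  # (a b c d e f) in scaled frame

  # undo the normalisation: substitute x -> (x - mx)/sc, y -> (y - my)/sc
  A <- coef_s[1]; B <- coef_s[2]; C <- coef_s[3]
  D <- coef_s[4]; E <- coef_s[5]; F <- coef_s[6]
  a0 <- A / sc^2
  b0 <- B / sc^2
  c0 <- C / sc^2
  d0 <- -2 * A * mx / sc^2 - B * my / sc^2 + D / sc
  e0 <- -B * mx / sc^2 - 2 * C * my / sc^2 + E / sc
  f0 <- A * mx^2 / sc^2 + B * mx * my / sc^2 + C * my^2 / sc^2 - D * mx / sc - E * my / sc + F
  cf <- c(a = a0, b = b0, c = c0, d = d0, e = e0, f = f0)
  cf <- cf / sqrt(sum(cf^2))
  if (cf[2]^2 - 4 * cf[1] * cf[3] >= -1e-12) {
    stop("fit_ellipse(): fitted conic is not an ellipse")
  }

  geo <- .conic_to_geometric(cf)
  structure(c(list(coefficients = cf), geo,
              list(axis_ratio = geo$semi_axes[2] / geo$semi_axes[1])),
            class = "conic_fit")
}

# Convert algebraic conic coefficients (ellipse) to centre/axes/angle.
.conic_to_geometric <- function(cf) {
  a <- cf[[1]]; b <- cf[[2]] / 2; c <- cf[[3]]
  d <- cf[[4]] / 2; e <- cf[[5]] / 2; f <- cf[[6]]
  den <- a * c - b^2
  x0 <- (b * e - c * d) / den
  y0 <- (b * d - a * e) / den
  # value of the quadratic form at the centre
  mu <- a * x0^2 + 2 * b * x0 * y0 + c * y0^2 + 2 * d * x0 + 2 * e * y0 + f
  M <- matrix(c(a, b, b, c), 2)
  ev <- eigen(M, symmetric = TRUE)
  ax <- sqrt(-mu / ev$values)       # semi-axes, eigen returns decreasing values
  ord <- order(ax, decreasing = TRUE)
  axes <- ax[ord]
  v <- ev$vectors[, ord[1]]
  ang <- atan2(v[2], v[1]) %% pi
  list(center = c(x = x0, y = y0), semi_axes = axes, angle = ang)
}

#' @export
print.conic_fit <- function(x, ...) {
  cat("Direct least-squares ellipse fit\n")
  cat(sprintf("  center     : (%.4g, %.4g)\n", x$center[1], x$center[2]))
  cat(sprintf("  semi-axes  : %.4g x %.4g\n", x$semi_axes[1], x$semi_axes[2]))
  cat(sprintf("  axis ratio : %.4f\n", x$axis_ratio))
  invisible(x)
}
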