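# Synthetic silhouette generator: parametric axi-symmetric solids with
# closed-form volumes, rendered as calibrated top-view (and side-view)
# images.  Every pipeline stage can be validated against these fixtures
# without any real photographs.
#
# A shape is defined by its visible half-width profile a(t), t in [0, L]
# cm, in the top view.  The cross-section at t is an ellipse with in-plane
# diameter 2 a(t) and vertical diameter 2 a(t) / r (r = width/height
# aspect ratio), so the true volume is
#     V = (pi / r) * integral_0^L a(t)^2 dt,
# evaluated in closed form per shape family.

#' Parametric shape specification
#'
#' Constructs a solid of revolution (optionally squashed to elliptical
#' cross-section by `aspect_ratio`, optionally bent along a circular arc)
#' with a closed-form volume.
#'
#' Families and their half-width profiles over `u = t/L`:
#' \describe{
#'   \item{cylinder}{`a = W/2`}
#'   \item{cone}{`a = (W/2)(1-u)` (tip at `t = L`)}
#'   \item{ellipsoid}{`a = (W/2) sqrt(4u(1-u))` (prolate spheroid)}
#'   \item{spindle}{`a = (W/2) sin(pi u)^power`; `power = 1` is the classic
#'     spindle, small powers give a blunt, cucumber-like body}
#'   \item{tapered-carrot}{`a = (W/2) u^shoulder (1-u)^tip / c`, a blunt
#'     shoulder with a tapering tip (`c` normalises the peak to `W/2`)}
#'   \item{bent-spindle}{spindle profile along a circular arc of radius
#'     `bend_radius`; by the centroid (Pappus) rule its volume equals the
#'     straight spindle's, while its top-view silhouette is curved}
#' }
#'
#' @param kind shape family (see Details).
#' @param length axial length `L` in cm (arc length for bent shapes).
#' @param max_width maximum top-view width `W` in cm.
#' @param aspect_ratio width/height ratio `r` of the cross-section.
#' @param power spindle exponent (> 0).
#' @param shoulder,tip taper exponents of the carrot profile.
#' @param bend_radius arc radius (cm) for `bent-spindle`; must be at least
#'   `length / pi` (half circle) and comfortably above `max_width`.
#' @return Object of class `"shape_spec"`: list with the parameters, the
#'   vectorised profile function `profile(t)` (cm) and `analytic_volume`
#'   (mL).
#' @examples
#' make_shape("cone", length = 10, max_width = 4)$analytic_volume  # 41.89
#' @export
make_shape <- function(kind = c("cylinder", "cone", "ellipsoid", "spindle",
                                "tapered-carrot", "bent-spindle"),
                       length, max_width, aspect_ratio = 1,
                       power = 1, shoulder = 0.45, tip = 0.75,
                       bend_radius = NULL) {
  kind <- match.arg(kind)
  stopifnot(length > 0, max_width > 0, aspect_ratio > 0)
  L <- length; A <- max_width / 2
  # profile a(t) and the closed-form integral of a(t)^2 over [0, L]
  if (kind == "cylinder") {
    prof <- function(t) A * (t >= 0 & t <= L)
    int_a2 <- A^2 * L
  } else if (kind == "cone") {
    prof <- function(t) A * (1 - t / L) * (t >= 0 & t <= L)
    int_a2 <- A^2 * L / 3
  } else if (kind == "ellipsoid") {
    prof <- function(t) {
      u <- t / L
      A * sqrt(pmax.int(4 * u * (1 - u), 0))
    }
    int_a2 <- A^2 * L * 2 / 3
  } else if (kind %in% c("spindle", "bent-spindle")) {
    stopifnot(power > 0)
    p <- power
    prof <- function(t) {
      u <- pmin.int(pmax.int(t / L, 0), 1)
      A * sin(pi * u)^p
    }
    # (1/pi) * int_0^pi sin^(2p) = Gamma(p + 1/2) / (sqrt(pi) Gamma(p + 1))
    int_a2 <- A^2 * L * gamma(p + 0.5) / (sqrt(pi) * gamma(p + 1))
  } else {  # tapered-carrot
    stopifnot(shoulder > 0, tip > 0)
    al <- shoulder; be <- tip
    us <- al / (al + be)
    cnorm <- us^al * (1 - us)^be
    prof <- function(t) {
      u <- pmin.int(pmax.int(t / L, 0), 1)
      A * u^al * (1 - u)^be / cnorm
    }
    int_a2 <- A^2 * L * beta(2 * al + 1, 2 * be + 1) / cnorm^2
  }
  if (kind == "bent-spindle") {
    if (is.null(bend_radius)) bend_radius <- 2 * L / pi
    if (bend_radius < L / pi) stop("bend_radius too small: arc exceeds a half circle")
    if (bend_radius < max_width) stop("bend_radius must exceed max_width")
  } else {
    bend_radius <- NULL
  }
  structure(list(kind = kind, length = L, max_width = max_width,
                 aspect_ratio = aspect_ratio,
                 params = list(power = power, shoulder = shoulder, tip = tip,
                               bend_radius = bend_radius),
                 profile = prof,
                 analytic_volume = pi / aspect_ratio * int_a2),
            class = "shape_spec")
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("shape_spec '%s': L %.2f cm, W %.2f cm, r %.4f -> V %.2f mL\n",
              x$kind, x$length, x$max_width, x$aspect_ratio, x$analytic_volume))
  invisible(x)
}

#' Rendering noise settings
#'
#' @param jitter_sd_px standard deviation (px) of a smooth random
#'   perturbation of the silhouette boundary radius.
#' @param salt_pepper fraction of image pixels flipped to the opposite
#'   colour (isolated speckle; removed by the morphological cleanup).
#' @return list of class `"render_noise"`.
#' @export
render_noise <- function(jitter_sd_px = 0, salt_pepper = 0) {
  stopifnot(jitter_sd_px >= 0, salt_pepper >= 0, salt_pepper < 0.5)
  structure(list(jitter_sd_px = jitter_sd_px, salt_pepper = salt_pepper),
            class = "render_noise")
}

# Signed axial/lateral coordinates of pixel centres relative to the shape,
# handling straight and arc-bent axes.  xs, ys are px-centre coordinates
# relative to the object centre, already de-rotated; returns list(t, w) in px.
.shape_frame <- function(shape, xs, ys, ppc) {
  if (shape$kind == "bent-spindle") {
    R <- shape$params$bend_radius * ppc
    L <- shape$length * ppc
    half <- L / (2 * R)                      # half arc angle
    rho <- sqrt(xs^2 + (R - ys)^2)
    phi <- atan2(xs, R - ys)
    list(t = (phi + half) * R, w = R - rho)
  } else {
    L <- shape$length * ppc
    list(t = xs + L / 2, w = ys)
  }
}

# Canvas half-extents (px) needed for the shape at a given rotation.
.canvas_extent <- function(shape, ppc, rot_rad) {
  L <- shape$length * ppc
  A <- shape$max_width / 2 * ppc
  if (shape$kind == "bent-spindle") {
    R <- shape$params$bend_radius * ppc
    half <- L / (2 * R)
    xmax <- R * sin(min(half, pi / 2)) + A
    ylo <- -A
    yhi <- R * (1 - cos(half)) + A
    corners <- rbind(c(-xmax, ylo), c(xmax, ylo), c(-xmax, yhi), c(xmax, yhi))
  } else {
    corners <- rbind(c(-L / 2 - A, -A), c(L / 2 + A, -A),
                     c(-L / 2 - A, A), c(L / 2 + A, A))
  }
  ca <- cos(rot_rad); sa <- sin(rot_rad)
  rx <- corners[, 1] * ca - corners[, 2] * sa
  ry <- corners[, 1] * sa + corners[, 2] * ca
  c(x = max(abs(rx)), y = max(abs(ry)))
}

# Rasterise the shape: logical mask of the given canvas (H x W), object
# centred, rotated by rot_rad, with optional smooth boundary jitter.
.rasterise <- function(shape, ppc, rot_rad, H, W, jitter_sd_px = 0,
                       depth_view = FALSE, base_loss = 0) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- matrix(rep(seq_len(W) - 1 - cx, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 1 - cy, times = W), H, W)
  ca <- cos(rot_rad); sa <- sin(rot_rad)
  xr <- xs * ca + ys * sa
  yr <- -xs * sa + ys * ca
  fr <- .shape_frame(shape, xr, yr, ppc)
  L_px <- shape$length * ppc
  a_px <- shape$profile(fr$t / ppc) * ppc
  if (depth_view) a_px <- a_px / shape$aspect_ratio
  if (jitter_sd_px > 0) {
    # smooth radius perturbation: spline through ~2 knots per cm
    nk <- max(8, ceiling(shape$length * 2))
    kt <- seq(0, L_px, length.out = nk)
    kv <- stats::rnorm(nk, 0, jitter_sd_px)
    a_px <- a_px + stats::spline(kt, kv, xout = pmin.int(pmax.int(fr$t, 0), L_px))$y
  }
  lower <- -a_px
  if (base_loss > 0 && depth_view) {
    lower <- lower + base_loss * shape$max_width / shape$aspect_ratio * ppc
  }
  # half-open bounds: a pixel centre exactly on the upper edge stays out,
  # so a w-px-wide bar rasterises to w pixels whatever the grid parity
  fr$t >= 0 & fr$t < L_px & fr$w < a_px & fr$w >= lower
}

# Flip a fraction of pixels (salt on the background, pepper in the object).
.salt_pepper <- function(mask, rate) {
  if (rate <= 0) return(mask)
  flip <- stats::runif(length(mask)) < rate
  out <- mask
  out[flip] <- !mask[flip]
  out
}

#' Render the calibrated top view of a shape
#'
#' Rasterises the shape silhouette (half-width `a(t)` at axial position
#' `t`, in px via `px_per_cm`) onto a white background in the produce
#' colour, at arbitrary in-plane rotation, with optional boundary jitter
#' and salt-and-pepper noise, and returns the image together with its
#' ground-truth record.
#'
#' @param shape a [make_shape()].
#' @param px_per_cm calibration (px/cm).
#' @param rotation_deg in-plane rotation of the length axis.
#' @param noise a [render_noise()].
#' @param margin_cm background margin around the object.
#' @param canvas optional fixed canvas size `c(H, W)` px (object centred);
#'   an error is raised if the object does not fit.
#' @param fg,bg foreground/background RGB triples in \[0, 1\].
#' @param seed integer seed for the noise (ignored when noise-free).
#' @return list with `image` (a [calibrated_image()]), `mask` (the ideal
#'   noise-free logical mask) and `truth` (one-row data frame: kind,
#'   volume_ml, length_cm, max_width_cm, aspect_ratio, rotation_deg, seed).
#' @export
render_top_view <- function(shape, px_per_cm = 40, rotation_deg = 0,
                            noise = render_noise(), margin_cm = 0.8,
                            canvas = NULL,
                            fg = c(0.85, 0.40, 0.12), bg = c(1, 1, 1),
                            seed = 1L) {
  stopifnot(inherits(shape, "shape_spec"), px_per_cm > 0)
  rot <- rotation_deg * pi / 180
  ext <- .canvas_extent(shape, px_per_cm, rot)
  need <- ceiling(2 * (ext + margin_cm * px_per_cm)) + 1
  if (is.null(canvas)) {
    H <- max(need["y"], 32); W <- max(need["x"], 32)
  } else {
    H <- canvas[1]; W <- canvas[2]
    if (H < need["y"] || W < need["x"]) stop("object does not fit the requested canvas")
  }
  set.seed(as.integer(seed))
  ideal <- .rasterise(shape, px_per_cm, rot, H, W)
  mask <- if (noise$jitter_sd_px > 0) {
    .rasterise(shape, px_per_cm, rot, H, W, jitter_sd_px = noise$jitter_sd_px)
  } else ideal
  mask <- .salt_pepper(mask, noise$salt_pepper)
  img <- array(0, c(H, W, 3))
  for (k in 1:3) {
    ch <- matrix(bg[k], H, W)
    ch[mask] <- fg[k]
    img[, , k] <- ch
  }
  truth <- data.frame(kind = shape$kind,
                      volume_ml = shape$analytic_volume,
                      length_cm = shape$length,
                      max_width_cm = shape$max_width,
                      aspect_ratio = shape$aspect_ratio,
                      rotation_deg = rotation_deg,
                      seed = as.integer(seed))
  list(image = calibrated_image(img, px_per_cm), mask = ideal, truth = truth)
}

#' Render the side view of a shape
#'
#' The orthogonal side view of a straight shape: its half-height profile is
#' `a(t) / aspect_ratio`.  `base_loss` optionally truncates the bottom of
#' the silhouette by that fraction of the maximum height, emulating the
#' contact-surface loss of a side camera (the object resting on the
#' conveyor hides its lowest sliver); the 2% default magnitude is a guess,
#' chosen for realism, not measured.
#'
#' @inheritParams render_top_view
#' @param base_loss fraction of the maximum height removed at the bottom.
#' @return As [render_top_view()] (truth carries the untruncated volume).
#' @export
render_side_view <- function(shape, px_per_cm = 40, rotation_deg = 0,
                             noise = render_noise(), margin_cm = 0.8,
                             base_loss = 0,
                             fg = c(0.85, 0.40, 0.12), bg = c(1, 1, 1),
                             seed = 1L) {
  stopifnot(inherits(shape, "shape_spec"))
  if (shape$kind == "bent-spindle") {
    stop("side view is only defined for straight shapes")
  }
  rot <- rotation_deg * pi / 180
  ext <- .canvas_extent(shape, px_per_cm, rot)
  H <- max(ceiling(2 * (ext["y"] + margin_cm * px_per_cm)) + 1, 32)
  W <- max(ceiling(2 * (ext["x"] + margin_cm * px_per_cm)) + 1, 32)
  set.seed(as.integer(seed))
  mask <- .rasterise(shape, px_per_cm, rot, H, W,
                     jitter_sd_px = noise$jitter_sd_px,
                     depth_view = TRUE, base_loss = base_loss)
  mask <- .salt_pepper(mask, noise$salt_pepper)
  img <- array(0, c(H, W, 3))
  for (k in 1:3) {
    ch <- matrix(bg[k], H, W)
    ch[mask] <- fg[k]
    img[, , k] <- ch
  }
  list(image = calibrated_image(img, px_per_cm), mask = mask,
       truth = data.frame(kind = shape$kind, volume_ml = shape$analytic_volume,
                          length_cm = shape$length, max_width_cm = shape$max_width,
                          aspect_ratio = shape$aspect_ratio,
                          rotation_deg = rotation_deg, seed = as.integer(seed)))
}

# Geometric scale factor k such that V = (pi / r) * k * (W/2)^2 * L.
.shape_factor <- function(shape) {
  shape$analytic_volume /
    (pi / shape$aspect_ratio * (shape$max_width / 2)^2 * shape$length)
}

#' Generate a product-like synthetic population
#'
#' Draws `n` shapes emulating a grading cohort of the given product and
#' (optionally) renders their calibrated top views.  Sampling is
#' stratified over the product's size classes so every class is populated:
#' each sample first draws a class (round-robin), then a true mass inside
#' it, then body dimensions consistent with that mass within the realistic
#' ranges (carrot-like: length 12-22 cm, max width 2.5-4.5 cm, rounded
#' shoulder with a tapering tip, aspect ratio 0.9531; cucumber-like:
#' length 14-22 cm, width 3-5 cm, blunt spindle body with rounded ends,
#' aspect ratio 0.9677).
#' Where a class's upper masses are not reachable within those dimension
#' ranges (a 320 g carrot would need to be wider than 4.5 cm), the draw is
#' clipped to the attainable portion of the class.
#'
#' @param product a [product_profile()] (or `"carrot"` / `"cucumber"`).
#' @param n number of samples (>= 1).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param px_per_cm calibration for rendering.
#' @param noise a [render_noise()].
#' @param rotate draw a random in-plane rotation per sample (0-180 deg).
#' @param render rasterise images (set `FALSE` for shape lists only).
#' @param write_dir if given, write each image as binary PPM plus
#'   `ground_truth.csv` and `manifest.json` into this directory.
#' @return list with `shapes` (list of [make_shape()]), `truth` (data
#'   frame: file, kind, seed, volume_ml, mass_g, class, length_cm,
#'   max_width_cm, rotation_deg) and, when rendered, `images` (list of
#'   [calibrated_image()]).
#' @export
make_population <- function(product, n, seed = 1L, px_per_cm = 40,
                            noise = render_noise(), rotate = TRUE,
                            render = TRUE, write_dir = NULL) {
  if (is.character(product)) {
    product <- switch(product,
                      carrot = carrot_profile(),
                      cucumber = cucumber_profile(),
                      stop("unknown product '", product, "'"))
  }
  stopifnot(inherits(product, "product_profile"))
  if (!is.numeric(n) || n < 1) stop("make_population(): n must be >= 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  carrot_like <- product$aspect_ratio < 0.96   # carrot vs cucumber body plan
  Lrange <- if (carrot_like) c(12, 22) else c(14, 22)
  Wrange <- if (carrot_like) c(2.5, 4.5) else c(3, 5)
  ct <- product$class_table
  cls_idx <- rep(seq_len(nrow(ct)), length.out = n)[sample.int(n)]
  shapes <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # per-sample body-plan variation (kept mild so the family stays true)
    if (carrot_like) {
      sh <- stats::runif(1, 0.35, 0.55)
      tp <- stats::runif(1, 0.60, 0.90)
      proto <- make_shape("tapered-carrot", length = 1, max_width = 1,
                          aspect_ratio = product$aspect_ratio,
                          shoulder = sh, tip = tp)
    } else {
      pw <- stats::runif(1, 0.40, 0.60)
      proto <- make_shape("spindle", length = 1, max_width = 1,
                          aspect_ratio = product$aspect_ratio, power = pw)
    }
    kfac <- pi / product$aspect_ratio * .shape_factor(proto) / 4  # V = kfac W^2 L
    vol_lim <- kfac * c(Wrange[1]^2 * Lrange[1], Wrange[2]^2 * Lrange[2])
    m_lim <- vol_lim * product$density
    lo <- max(ct$low[cls_idx[i]], m_lim[1]) + 2
    hi <- min(ct$high[cls_idx[i]], m_lim[2]) - 2
    if (!is.finite(lo)) lo <- m_lim[1] + 2
    if (!is.finite(hi)) hi <- min(m_lim[2], ct$low[cls_idx[i]] + 80) - 2
    if (hi <= lo) { lo <- max(m_lim[1], hi - 10) }  # clip to attainable span
    mass <- stats::runif(1, lo, hi)
    vol <- mass / product$density
    Q <- vol / kfac                                  # required W^2 * L
    Lfeas <- c(max(Lrange[1], Q / Wrange[2]^2), min(Lrange[2], Q / Wrange[1]^2))
    L <- stats::runif(1, Lfeas[1], max(Lfeas))
    W <- sqrt(Q / L)
    shapes[[i]] <- if (carrot_like) {
      make_shape("tapered-carrot", length = L, max_width = W,
                 aspect_ratio = product$aspect_ratio,
                 shoulder = proto$params$shoulder, tip = proto$params$tip)
    } else {
      make_shape("spindle", length = L, max_width = W,
                 aspect_ratio = product$aspect_ratio, power = proto$params$power)
    }
    rows[[i]] <- data.frame(
      file = sprintf("%s_%03d.ppm", product$name, i),
      kind = shapes[[i]]$kind,
      seed = as.integer(seed),
      volume_ml = shapes[[i]]$analytic_volume,
      mass_g = shapes[[i]]$analytic_volume * product$density,
      class = classify(shapes[[i]]$analytic_volume * product$density, product),
      length_cm = L, max_width_cm = W,
      rotation_deg = if (rotate) stats::runif(1, 0, 180) else 0)
  }
  truth <- do.call(rbind, rows)
  out <- list(shapes = shapes, truth = truth)
  if (render || !is.null(write_dir)) {
    img_seeds <- sample.int(2^30, n)
    images <- vector("list", n)
    for (i in seq_len(n)) {
      images[[i]] <- render_top_view(shapes[[i]], px_per_cm = px_per_cm,
                                     rotation_deg = truth$rotation_deg[i],
                                     noise = noise, seed = img_seeds[i])$image
    }
    out$images <- images
    if (!is.null(write_dir)) {
      dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n)) {
        write_pnm(images[[i]], file.path(write_dir, truth$file[i]))
      }
      utils::write.csv(truth, file.path(write_dir, "ground_truth.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(product = product$name, n = n, seed = as.integer(seed),
             px_per_cm = px_per_cm,
             noise = unclass(noise),
             aspect_ratio = product$aspect_ratio,
             density_g_per_ml = product$density),
        file.path(write_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
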