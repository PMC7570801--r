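# Shared fixtures, all generated in code.

# Axis-aligned rectangular silhouette of w_px x h_px foreground pixels.
rect_silhouette <- function(w_px, h_px, ppc = 20, pad = 10, angle = 0) {
  if (angle == 0) {
    H <- h_px + 2 * pad; W <- w_px + 2 * pad
    mask <- matrix(FALSE, H, W)
    mask[pad + seq_len(h_px), pad + seq_len(w_px)] <- TRUE
  } else {
    # rasterise the rotated rectangle from its half-plane description
    diag <- sqrt(w_px^2 + h_px^2)
    H <- W <- ceiling(diag) + 2 * pad
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    xs <- matrix(rep(seq_len(W) - 1 - cx, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 1 - cy, times = W), H, W)
    a <- angle * pi / 180
    u <- xs * cos(a) + ys * sin(a)
    v <- -xs * sin(a) + ys * cos(a)
    mask <- abs(u) <= w_px / 2 & abs(v) <= h_px / 2
  }
  silhouette(mask, ppc)
}

# Bare width-profile object for estimator tests that bypass imaging.
profile_obj <- function(widths, length) {
  n <- length(widths) - 1L
  structure(list(n_slices = n,
                 stations = seq(0, length, length.out = n + 1L),
                 widths = widths,
                 length = length,
                 spacing = length / n,
                 px_per_cm = NA_real_),
            class = "width_profile")
}

# Render a shape and extract its silhouette (no border warnings expected).
render_sil <- function(shape, ppc = 30, rot = 0, noise = render_noise(), seed = 1) {
  r <- render_top_view(shape, px_per_cm = ppc, rotation_deg = rot,
                       noise = noise, seed = seed)
  extract_silhouette(r$image)
}

# Independent numeric volume oracle: V = (pi / r) * int a(t)^2 dt by
# quadrature on the profile function (never touches the estimator).
num_volume <- function(shape) {
  f <- function(t) shape$profile(t)^2
  pi / shape$aspect_ratio *
    stats::integrate(f, 0, shape$length, subdivisions = 2000L,
                     rel.tol = 1e-9)$value
}

# Points on an ellipse with the given semi-axes, rotation (rad) and centre.
ellipse_points <- function(n, a, b, phi = 0, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(cx + x * cos(phi) - y * sin(phi),
        cy + x * sin(phi) + y * cos(phi))
}

# The two printed grading confusion matrices (rows = truth).
carrot_cm <- matrix(c(24, 0, 0, 0,
                      2, 37, 0, 1,
                      0, 2, 33, 0,
                      0, 0, 1, 21), 4, 4, byrow = TRUE,
                    dimnames = list(c("S", "M", "L", "2L"),
                                    c("S", "M", "L", "2L")))
cucumber_cm <- matrix(c(19, 1, 0, 0,
                        0, 21, 1, 0,
                        0, 0, 25, 1,
                        0, 0, 0, 23), 4, 4, byrow = TRUE,
                      dimnames = list(c("S", "M", "L", "XL"),
                                      c("S", "M", "L", "XL")))
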