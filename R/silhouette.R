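# Binary-image primitives for single-object silhouette extraction.
#
# The whole pipeline works on logical H x W matrices.  Pixel (r, c) has its
# centre at continuous coordinates x = c - 1, y = r - 1 (0-based, origin at
# the top-left pixel centre, x along columns, y along rows).

# ---- low-level binary morphology (3 x 3 square element) ---------------------

.dilate3 <- function(m) {
  p <- m
  p[-1, ] <- p[-1, ] | m[-nrow(m), ]
  p[-nrow(m), ] <- p[-nrow(m), ] | m[-1, ]
  q <- p
  q[, -1] <- q[, -1] | p[, -ncol(p)]
  q[, -ncol(q)] <- q[, -ncol(q)] | p[, -1]
  q
}

.erode3 <- function(m) !.dilate3(!m)

.open3 <- function(m) .dilate3(.erode3(m))
.close3 <- function(m) .erode3(.dilate3(m))

# ---- connected components via run-length union-find -------------------------

# Returns a list of row runs (row, start, end) with a component label each.
# Pure R but O(runs), so fast even on multi-megapixel masks.
.label_runs <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  slack <- if (connectivity == 8) 1L else 0L
  rows <- vector("list", H)
  nrun <- 0L
  for (r in seq_len(H)) {
    v <- mask[r, ]
    d <- diff(c(FALSE, v, FALSE))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    if (length(st)) {
      rows[[r]] <- cbind(start = st, end = en, id = nrun + seq_along(st))
      nrun <- nrun + length(st)
    }
  }
  parent <- seq_len(max(nrun, 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(H)[-1]) {
    a <- rows[[r - 1]]; b <- rows[[r]]
    if (is.null(a) || is.null(b)) next
    i <- 1L; j <- 1L
    while (i <= nrow(a) && j <= nrow(b)) {
      if (a[i, "start"] <= b[j, "end"] + slack && a[i, "end"] >= b[j, "start"] - slack) {
        ra <- find(a[i, "id"]); rb <- find(b[j, "id"])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      if (a[i, "end"] < b[j, "end"]) i <- i + 1L else j <- j + 1L
    }
  }
  runs <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)], list(NULL)))
  if (is.null(runs)) {
    return(list(runs = NULL, row = integer(0), label = integer(0), n = 0L))
  }
  rowidx <- rep(seq_len(H), vapply(rows, function(x) if (is.null(x)) 0L else nrow(x), 1L))
  lab <- vapply(runs[, "id"], find, 1L)
  lab <- match(lab, sort(unique(lab)))
  list(runs = runs, row = rowidx, label = lab, n = max(lab))
}

# Keep only the largest 8-connected foreground component.
.largest_component <- function(mask) {
  cc <- .label_runs(mask, 8)
  if (cc$n <= 1L) return(mask)
  len <- cc$runs[, "end"] - cc$runs[, "start"] + 1L
  sizes <- tapply(len, cc$label, sum)
  keep <- as.integer(names(sizes)[which.max(sizes)])
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  sel <- cc$label == keep
  for (k in which(sel)) {
    out[cc$row[k], cc$runs[k, "start"]:cc$runs[k, "end"]] <- TRUE
  }
  out
}

# Fill background holes: any 4-connected background component that does not
# touch the image border becomes foreground.
.fill_holes <- function(mask) {
  bg <- !mask
  cc <- .label_runs(bg, 4)
  if (cc$n == 0L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  touches <- logical(cc$n)
  for (k in seq_along(cc$label)) {
    r <- cc$row[k]
    if (r == 1L || r == H || cc$runs[k, "start"] == 1L || cc$runs[k, "end"] == W) {
      touches[cc$label[k]] <- TRUE
    }
  }
  out <- mask
  for (k in which(!touches[cc$label])) {
    out[cc$row[k], cc$runs[k, "start"]:cc$runs[k, "end"]] <- TRUE
  }
  out
}

# ---- thresholding -----------------------------------------------------------

# Otsu's threshold on a vector of values in [0, 1] (256-bin histogram).
.otsu <- function(v) {
  h <- tabulate(pmin(pmax(as.integer(v * 255) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mt <- mu[256]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  (which.max(sb) - 1) / 255
}

#' Colour-threshold configuration
#'
#' Settings for [extract_silhouette()].  Thresholding runs in HSV space:
#' a pixel is foreground if its hue lies inside `hue_range` (if given;
#' the range may wrap past 1, e.g. `c(0.9, 0.1)` for reds), its saturation
#' is at least `sat_min` and its value lies in `val_range`.  When `sat_min`
#' is `NULL` (the default) it is chosen automatically by Otsu's method on
#' the saturation channel, which cleanly separates coloured produce from a
#' white/grey background without manual tuning.
#'
#' @param hue_range optional hue interval in \[0, 1\] (may wrap).
#' @param sat_min minimum saturation, or `NULL` for Otsu.
#' @param val_range value (brightness) interval in \[0, 1\].
#' @return list of class `"threshold_config"`.
#' @export
threshold_config <- function(hue_range = NULL, sat_min = NULL, val_range = c(0, 1)) {
  structure(list(hue_range = hue_range, sat_min = sat_min, val_range = val_range),
            class = "threshold_config")
}

#' Extract the object silhouette from a calibrated image
#'
#' Segments a single piece of produce from a contrasting background:
#' HSV threshold (see [threshold_config()]), 3x3 morphological opening then
#' closing to remove speckle, retention of the largest connected component,
#' and hole filling.  Warns (and flags the result) if the object touches the
#' image border, since the bounding box is then unreliable.
#'
#' @param image a [calibrated_image()].
#' @param config a [threshold_config()].
#' @return A [silhouette()] object.
#' @export
extract_silhouette <- function(image, config = threshold_config()) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  d <- dim(px)
  # HSV channels computed directly (much faster than rgb2hsv on megapixel frames)
  mx <- pmax.int(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin.int(px[, , 1], px[, , 2], px[, , 3])
  sat <- 1 - mn / mx
  sat[mx == 0] <- 0       # pure black: no chroma
  val <- mx
  sat_min <- config$sat_min
  if (is.null(sat_min)) sat_min <- .otsu(sat)
  # Otsu convention: background <= threshold < object
  fg <- sat > sat_min &
    val >= config$val_range[1] & val <= config$val_range[2]
  if (!is.null(config$hue_range)) {
    chroma <- mx - mn
    hue <- matrix(0, d[1], d[2])
    nz <- chroma > 0
    r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
    isr <- nz & mx == r; isg <- nz & !isr & mx == g; isb <- nz & !isr & !isg
    hue[isr] <- (((g - b) / chroma)[isr] / 6) %% 1
    hue[isg] <- (((b - r) / chroma)[isg] + 2) / 6
    hue[isb] <- (((r - g) / chroma)[isb] + 4) / 6
    hr <- config$hue_range
    hue_ok <- if (hr[1] <= hr[2]) hue >= hr[1] & hue <= hr[2]
              else hue >= hr[1] | hue <= hr[2]
    fg <- fg & hue_ok
  }
  mask <- matrix(fg, d[1], d[2])
  mask <- .close3(.open3(mask))
  if (!any(mask)) stop("no object detected")
  mask <- .largest_component(mask)
  mask <- .fill_holes(mask)
  touch <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
           any(mask[, 1]) || any(mask[, ncol(mask)])
  if (touch) warning("foreground touches the image border; measurements may be clipped")
  silhouette(mask, image$px_per_cm, border_touch = touch)
}

# ---- rotated minimum-area bounding box --------------------------------------

# Boundary points of the mask as pixel *corner* coordinates, so that a w x h
# pixel rectangle measures exactly w x h.  Row-wise extreme pixels suffice:
# a convex-hull vertex is necessarily the leftmost or rightmost pixel of its
# row.
.boundary_corners <- function(mask) {
  H <- nrow(mask)
  pts <- vector("list", H)
  for (r in seq_len(H)) {
    w <- which(mask[r, ])
    if (!length(w)) next
    xs <- c(min(w), max(w)) - 1  # pixel-centre x
    y <- r - 1
    pts[[r]] <- cbind(x = rep(c(xs[1] - 0.5, xs[1] + 0.5, xs[2] - 0.5, xs[2] + 0.5), 2),
                      y = rep(c(y - 0.5, y + 0.5), each = 4))
  }
  do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
}

#' Minimum-area rotated bounding box
#'
#' Encloses the silhouette in the smallest-area rotated rectangle (convex
#' hull + rotating calipers: the optimal rectangle has one side collinear
#' with a hull edge).  The longer side is reported as the object length.
#' Because the box is computed from the hull, its dimensions are invariant
#' to in-plane rotation of the object up to rasterisation error.
#'
#' @param sil a [silhouette()].
#' @return Object of class `"rotated_box"`: list with `center` (px,
#'   x/y), `length` and `width` (cm), `angle` (degrees of the length axis,
#'   in \[0, 180)), `corners` (4 x 2 px matrix, consecutive corners with the
#'   first edge running along the length axis) and `px_per_cm`.
#' @export
min_area_box <- function(sil) {
  stopifnot(inherits(sil, "silhouette"))
  if (sum(sil$mask) < 3) stop("min_area_box(): mask too small (< 3 px)")
  pts <- .boundary_corners(sil$mask)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  edges <- hull[c(2:nh, 1), ] - hull
  ang <- unique(round(atan2(edges[, 2], edges[, 1]) %% pi, 12))
  best <- NULL
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    u <- hull[, 1] * ca + hull[, 2] * sa       # along edge direction
    v <- -hull[, 1] * sa + hull[, 2] * ca      # perpendicular
    du <- max(u) - min(u); dv <- max(v) - min(v)
    if (is.null(best) || du * dv < best$area - 1e-12) {
      best <- list(area = du * dv, a = a, u = c(min(u), max(u)), v = c(min(v), max(v)))
    }
  }
  a <- best$a
  # report the angle of the *long* side, normalised to [0, 180)
  if (diff(best$v) > diff(best$u)) a <- (a + pi / 2) %% pi
  # recompute the extents in the final angle's frame so that corners, angle
  # and side lengths stay mutually consistent
  ca <- cos(a); sa <- sin(a)
  u <- hull[, 1] * ca + hull[, 2] * sa
  v <- -hull[, 1] * sa + hull[, 2] * ca
  ur <- range(u); vr <- range(v)
  du <- diff(ur); dv <- diff(vr)
  # rectangle corners in rotated frame -> image frame; first edge runs
  # from (umin, vmin) along +u, the length axis
  uc <- c(ur[1], ur[2], ur[2], ur[1])
  vc <- c(vr[1], vr[1], vr[2], vr[2])
  corners <- cbind(x = uc * ca - vc * sa, y = uc * sa + vc * ca)
  center <- colMeans(corners)
  structure(list(center = center,
                 length = du / sil$px_per_cm,
                 width = dv / sil$px_per_cm,
                 angle = a * 180 / pi,
                 corners = corners,
                 px_per_cm = sil$px_per_cm),
            class = "rotated_box")
}

#' @export
print.rotated_box <- function(x, ...) {
  cat(sprintf("rotated_box: %.3f x %.3f cm at %.1f deg, center (%.1f, %.1f) px\n",
              x$length, x$width, x$angle, x$center[1], x$center[2]))
  invisible(x)
}

# ---- scan-line width measurement --------------------------------------------

# Cross-widths (cm) of the silhouette measured perpendicular to the box's
# length axis at the given axial stations (px from the first end face).
# Each scan line is sampled at sub-pixel `step` (px); the width is the span
# between the two extreme foreground samples (caliper convention).
.scan_widths <- function(sil, box, stations_px, step = 0.5) {
  ppc <- sil$px_per_cm
  a <- box$angle * pi / 180
  u <- c(cos(a), sin(a))
  v <- c(-sin(a), cos(a))
  origin <- box$corners[1, ]
  W_px <- box$width * ppc
  tt <- seq(-0.5, W_px + 0.5, by = step)
  H <- nrow(sil$mask); Wc <- ncol(sil$mask)
  vapply(stations_px, function(s) {
    xs <- origin[1] + u[1] * s + v[1] * tt
    ys <- origin[2] + u[2] * s + v[2] * tt
    cc <- as.integer(round(xs)) + 1L
    rr <- as.integer(round(ys)) + 1L
    ok <- cc >= 1L & cc <= Wc & rr >= 1L & rr <= H
    hit <- logical(length(tt))
    hit[ok] <- sil$mask[cbind(rr[ok], cc[ok])]
    if (!any(hit)) return(0)
    rng <- range(tt[hit])
    # the extreme hits undershoot the true edges by up to half a sample
    # step on each side; add one step so a w-px bar measures w px
    (rng[2] - rng[1] + step) / ppc
  }, numeric(1))
}

#' Width profile along the major axis
#'
#' Divides the bounding box into `n_slices` equal slices along its length
#' axis and measures the silhouette cross-width (cm) on each of the
#' `n_slices + 1` slice-boundary lines, which run parallel to the box's
#' short side.  Widths are measured as the full span between the extreme
#' foreground pixels on each scan line, matching what a physical caliper
#' would read.
#'
#' @param sil a [silhouette()].
#' @param box the [min_area_box()] of `sil`.
#' @param n_slices number of slices (>= 3).
#' @param step sub-pixel sampling step along each scan line, in px (<= 0.5).
#' @return Object of class `"width_profile"`: list with `n_slices`,
#'   `stations` (cm from the first end face, length `n_slices + 1`),
#'   `widths` (cm), `length` (cm), `spacing` (cm) and `px_per_cm`.
#' @export
width_profile <- function(sil, box, n_slices, step = 0.5) {
  stopifnot(inherits(sil, "silhouette"), inherits(box, "rotated_box"))
  if (!is.numeric(n_slices) || n_slices < 3) {
    stop("width_profile(): n_slices must be at least 3")
  }
  n_slices <- as.integer(n_slices)
  L_px <- box$length * sil$px_per_cm
  stations_px <- seq(0, L_px, length.out = n_slices + 1L)
  # the two end stations sit exactly on the box faces, where rounding can
  # fall just outside the mask; sample them a quarter pixel inward (the
  # reported station coordinates stay nominal)
  sample_px <- stations_px
  sample_px[1] <- 0.25
  sample_px[n_slices + 1L] <- L_px - 0.25
  widths <- .scan_widths(sil, box, sample_px, step = step)
  structure(list(n_slices = n_slices,
                 stations = stations_px / sil$px_per_cm,
                 widths = widths,
                 length = box$length,
                 spacing = box$length / n_slices,
                 px_per_cm = sil$px_per_cm),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("width_profile: %d slices over %.2f cm (h = %.3f cm)\n",
              x$n_slices, x$length, x$spacing))
  cat("  widths (cm):", paste(sprintf("%.2f", x$widths), collapse = " "), "\n")
  invisible(x)
}

#' Write a debug overlay image
#'
#' Renders the silhouette with its bounding box and slice-boundary lines
#' burnt in, as a PPM file, for visual inspection of the measurement
#' geometry.
#'
#' @param sil a [silhouette()].
#' @param box its [min_area_box()].
#' @param path output path (binary PPM).
#' @param n_slices slice lines to draw.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(sil, box, path, n_slices = 8) {
  H <- nrow(sil$mask); W <- ncol(sil$mask)
  img <- array(0, c(H, W, 3))
  img[, , 1][sil$mask] <- 0.9
  img[, , 2][sil$mask] <- 0.5
  stamp <- function(xs, ys, chan) {
    rr <- as.integer(round(ys)) + 1L
    cc <- as.integer(round(xs)) + 1L
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    for (k in 1:3) {
      m <- img[, , k]
      m[cbind(rr[ok], cc[ok])] <- if (k == chan) 1 else 0
      img[, , k] <<- m
    }
  }
  seg <- function(p, q, chan) {
    n <- max(2, ceiling(sqrt(sum((q - p)^2)) * 2))
    t <- seq(0, 1, length.out = n)
    stamp(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]), chan)
  }
  cs <- box$corners
  for (i in 1:4) seg(cs[i, ], cs[(i %% 4) + 1, ], 3)
  a <- box$angle * pi / 180
  u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
  L_px <- box$length * sil$px_per_cm
  W_px <- box$width * sil$px_per_cm
  for (s in seq(0, L_px, length.out = n_slices + 1)) {
    p <- cs[1, ] + u * s
    seg(p, p + v * W_px, 2)
  }
  write_pnm(img, path)
}
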