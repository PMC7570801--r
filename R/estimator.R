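#' Product profile: per-product constants for volume and mass estimation
#'
#' Bundles the constants a product line needs: the cross-section aspect
#' ratio (top-view-visible width divided by the unseen vertical height of
#' the cross-section ellipse), the average density used to convert volume
#' to mass, the commercial size-class table, and the default slice count.
#'
#' The unseen depth diameter of every cross-section is reconstructed as
#' `width / aspect_ratio`, so `aspect_ratio = 1` means circular sections.
#'
#' @param name product name.
#' @param aspect_ratio width/height ratio of the cross-section ellipse,
#'   in (0, 2].
#' @param density average density in g/mL.
#' @param class_table data frame with columns `label`, `low`, `high`
#'   (grams) and optionally `incl_high` (logical).  Intervals are half-open
#'   `[low, high)` by default: a mass exactly on a shared boundary belongs
#'   to the upper class.  Setting `incl_high = TRUE` closes the upper bound
#'   instead (the next class then opens strictly above it), as in the
#'   cucumber table where 200 g is still L and XL means strictly more than
#'   200 g.  Use `-Inf`/`Inf` for open-ended classes.  Masses outside all
#'   intervals classify as `"out-of-range"`.
#' @param n_slices default number of slices for [estimate_volume()].
#' @return Object of class `"product_profile"`.
#' @examples
#' carrot_profile()
#' cucumber_profile()
#' @export
product_profile <- function(name, aspect_ratio, density, class_table,
                            n_slices = 8L) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(aspect_ratio) || aspect_ratio <= 0 || aspect_ratio > 2) {
    stop("aspect_ratio must lie in (0, 2]")
  }
  if (!is.numeric(density) || density <= 0) stop("density must be positive")
  class_table <- as.data.frame(class_table)
  stopifnot(all(c("label", "low", "high") %in% names(class_table)))
  if (is.null(class_table$incl_high)) class_table$incl_high <- FALSE
  ct <- class_table[order(class_table$low), ]
  if (nrow(ct) > 1 && any(ct$high[-nrow(ct)] > ct$low[-1] + 1e-9)) {
    stop("class intervals overlap")
  }
  structure(list(name = name, aspect_ratio = aspect_ratio, density = density,
                 class_table = ct, n_slices = as.integer(n_slices)),
            class = "product_profile")
}

#' @export
print.product_profile <- function(x, ...) {
  cat(sprintf("product_profile '%s': aspect ratio %.4f, density %.4f g/mL, %d slices\n",
              x$name, x$aspect_ratio, x$density, x$n_slices))
  print(x$class_table, row.names = FALSE)
  invisible(x)
}

#' @rdname product_profile
#' @details `carrot_profile()` and `cucumber_profile()` return the built-in
#'   profiles: carrot aspect ratio 0.9531, density 1.0987 g/mL, classes
#'   S 80-125 g, M 125-200 g, L 200-250 g, 2L 250-320 g; cucumber aspect
#'   ratio 0.9677, density 1.019 g/mL, classes S < 100 g, M 100-150 g,
#'   L 150-200 g, XL > 200 g (200 g itself falls in L under the half-open
#'   convention... the XL interval is open at 200).
#' @export
carrot_profile <- function() {
  product_profile(
    "carrot", aspect_ratio = 0.9531, density = 1.0987,
    class_table = data.frame(
      label = c("S", "M", "L", "2L"),
      low = c(80, 125, 200, 250),
      high = c(125, 200, 250, 320)),
    n_slices = 8L)
}

#' @rdname product_profile
#' @export
cucumber_profile <- function() {
  product_profile(
    "cucumber", aspect_ratio = 0.9677, density = 1.019,
    class_table = data.frame(
      label = c("S", "M", "L", "XL"),
      low = c(-Inf, 100, 150, 200),
      high = c(100, 150, 200, Inf),
      incl_high = c(FALSE, FALSE, TRUE, FALSE)),
    n_slices = 8L)
}

#' Load product profiles from a JSON config file
#'
#' Reads a JSON file describing one or more products.  Each entry uses
#' keys `name`, `aspect_ratio`, `density_g_per_ml`, `n_slices` and
#' `classes` (a list of `{label, low, high}` with `null` for open bounds).
#'
#' @param path JSON file path.
#' @return Named list of [product_profile()] objects.
#' @export
read_product_profiles <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(cfg, function(p) {
    ct <- do.call(rbind, lapply(p$classes, function(cl) {
      data.frame(label = cl$label,
                 low = if (is.null(cl$low)) -Inf else cl$low,
                 high = if (is.null(cl$high)) Inf else cl$high,
                 incl_high = isTRUE(cl$incl_high))
    }))
    product_profile(p$name, p$aspect_ratio, p$density_g_per_ml, ct,
                    n_slices = if (is.null(p$n_slices)) 8L else p$n_slices)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Estimate volume from a width profile
#'
#' The core single-view estimator.  The object of length `L` is divided
#' into `n` equal axial slices of height `h = L/n`.  The first and last
#' slices are modelled as elliptical end caps of volume
#' \eqn{\pi d_1 d_2 h / 6}, with base diameters taken from the adjacent
#' interior station (the measured tip width itself may be zero).  Each
#' interior slice is a chopped pyramid (frustum) between elliptical
#' cross-sections: the visible top-view width `w` at a station gives the
#' in-plane diameter and `w / aspect_ratio` the unseen depth diameter, so
#' the face area is \eqn{\pi (w/2)(w/(2r))}.  Total volume is the sum of
#' the two caps and all frustums.
#'
#' @param profile a [width_profile()] (or any list with `widths`,
#'   `spacing` and `n_slices`).
#' @param product a [product_profile()].
#' @return Object of class `"volume_estimate"`: list with `total` (mL),
#'   `cap_top`, `cap_bottom`, `frustums` (length `n - 2`), `n_slices`.
#' @export
estimate_volume <- function(profile, product) {
  stopifnot(inherits(product, "product_profile"))
  w <- profile$widths
  n <- profile$n_slices
  h <- profile$spacing
  if (length(w) != n + 1) stop("estimate_volume(): widths must have n_slices + 1 entries")
  if (n < 3) stop("estimate_volume(): need at least 3 slices")
  if (any(w < 0)) stop("estimate_volume(): negative width")
  r <- product$aspect_ratio
  # stations are 0-based: w[k + 1] is the width at station k
  cap_top <- cap_volume(w[2], w[2] / r, h)
  cap_bottom <- cap_volume(w[n], w[n] / r, h)
  ks <- seq_len(n - 2)  # interior slices between stations ks and ks + 1
  frustums <- frustum_volume(ellipse_area(w[ks + 1], w[ks + 1] / r),
                             ellipse_area(w[ks + 2], w[ks + 2] / r), h)
  structure(list(total = cap_top + cap_bottom + sum(frustums),
                 cap_top = cap_top, cap_bottom = cap_bottom,
                 frustums = frustums, n_slices = n),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("volume_estimate: %.2f mL (%d slices; caps %.2f + %.2f, body %.2f)\n",
              x$total, x$n_slices, x$cap_top, x$cap_bottom, sum(x$frustums)))
  invisible(x)
}

#' Estimate mass and size class from a volume
#'
#' Mass is volume times the product's average density,
#' \eqn{M = V \times d_{avg}}; the size class is read off the product's
#' class table.
#'
#' @param vol a [estimate_volume()] result, or a numeric volume in mL.
#' @param product a [product_profile()].
#' @return Object of class `"mass_estimate"`: list with `mass` (g),
#'   `volume` (mL), `density_used` (g/mL) and `class_label`.
#' @export
estimate_mass <- function(vol, product) {
  stopifnot(inherits(product, "product_profile"))
  v <- if (inherits(vol, "volume_estimate")) vol$total else as.numeric(vol)
  m <- v * product$density
  structure(list(mass = m, volume = v, density_used = product$density,
                 class_label = classify(m, product)),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("mass_estimate: %.1f g (%.1f mL x %.4f g/mL) -> class %s\n",
              x$mass, x$volume, x$density_used, x$class_label))
  invisible(x)
}

#' Assign a mass to a commercial size class
#'
#' Classes are half-open intervals `[low, high)` (boundary mass goes to the
#' upper class), unless a class sets `incl_high = TRUE`, in which case its
#' upper bound is included and the next class opens strictly above it.
#' Masses outside every interval return `"out-of-range"`.
#'
#' @param mass mass in grams (vectorised).
#' @param product a [product_profile()].
#' @return Character vector of class labels.
#' @export
classify <- function(mass, product) {
  stopifnot(inherits(product, "product_profile"))
  if (any(mass < 0)) stop("classify(): negative mass")
  ct <- product$class_table
  nL <- nrow(ct)
  low_open <- c(FALSE, ct$incl_high[-nL])  # class below closed its top bound
  vapply(mass, function(m) {
    lo <- ifelse(low_open, m > ct$low, m >= ct$low)
    hi <- ifelse(ct$incl_high, m <= ct$high, m < ct$high)
    hit <- which(lo & hi)
    if (length(hit)) ct$label[hit[1]] else "out-of-range"
  }, character(1))
}

#' Slice-count sweep: estimation error versus number of slices
#'
#' Re-estimates every silhouette in a set at each slice count and reports
#' the mean and SD of the absolute percentage volume error against the
#' reference volumes.  Used to choose the working slice count (the error
#' flattens once the slices resolve the object's taper; eight suffices for
#' carrot- and cucumber-shaped produce).
#'
#' @param silhouettes list of [silhouette()] objects.
#' @param reference_volumes reference volumes (mL), same length.
#' @param product a [product_profile()].
#' @param n_range integer vector of slice counts, within \[3, 15\].
#' @return data frame with columns `n_slices`, `mean_abs_pct_error`,
#'   `sd_pct_error`.
#' @export
sweep_slices <- function(silhouettes, reference_volumes, product,
                         n_range = 3:15) {
  if (length(silhouettes) == 0) stop("sweep_slices(): empty silhouette set")
  if (length(silhouettes) != length(reference_volumes)) {
    stop("sweep_slices(): silhouettes and references differ in length")
  }
  if (length(n_range) == 0) stop("sweep_slices(): empty n_range")
  if (any(n_range < 3 | n_range > 15)) stop("sweep_slices(): n_range must lie in [3, 15]")
  boxes <- lapply(silhouettes, min_area_box)
  rows <- lapply(as.integer(n_range), function(n) {
    est <- mapply(function(s, b) {
      estimate_volume(width_profile(s, b, n), product)$total
    }, silhouettes, boxes)
    pe <- 100 * abs(est - reference_volumes) / reference_volumes
    data.frame(n_slices = n, mean_abs_pct_error = mean(pe), sd_pct_error = stats::sd(pe))
  })
  do.call(rbind, rows)
}

#' Full single-image measurement
#'
#' Convenience wrapper running the whole pipeline on one image:
#' segmentation, bounding box, width profile, volume, mass and class.
#'
#' @param image a [calibrated_image()] or a [silhouette()].
#' @param product a [product_profile()].
#' @param n_slices slice count (default from the profile).
#' @param config a [threshold_config()] for segmentation.
#' @return list with `box`, `profile`, `volume`, `mass` and a one-row
#'   `summary` data frame (`length_cm`, `max_width_cm`, `volume_ml`,
#'   `mass_g`, `class`).
#' @export
measure_produce <- function(image, product, n_slices = product$n_slices,
                            config = threshold_config()) {
  sil <- if (inherits(image, "silhouette")) image
         else extract_silhouette(image, config)
  box <- min_area_box(sil)
  prof <- width_profile(sil, box, n_slices)
  vol <- estimate_volume(prof, product)
  mass <- estimate_mass(vol, product)
  list(box = box, profile = prof, volume = vol, mass = mass,
       summary = data.frame(length_cm = box$length,
                            max_width_cm = max(prof$widths),
                            volume_ml = vol$total,
                            mass_g = mass$mass,
                            class = mass$class_label))
}
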