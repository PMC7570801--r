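# Baseline estimators: the 1-pixel disk method (one and two views) and
# multiple linear regression on simple geometric features.

#' Disk-method volume from width lists
#'
#' Volume as a stack of thin elliptical (or circular) disks.  With only the
#' top view, each disk of width `z` is assumed circular,
#' \eqn{A = \pi (z/2)^2}; with a second orthogonal side view supplying `d`,
#' \eqn{A = \pi d z / 4}.  Volume is \eqn{\sum_i A_i x} with `x` the
#' per-disk thickness (1 pixel converted to cm in image use).
#'
#' @param top_widths top-view disk widths `z_i` (cm).
#' @param thickness per-disk thickness `x` (cm).
#' @param side_widths optional side-view widths `d_i` (cm), same length;
#'   omitted means circular disks.
#' @return Volume in mL.
#' @export
disk_volume <- function(top_widths, thickness, side_widths = NULL) {
  if (any(top_widths < 0)) stop("disk_volume(): negative width")
  if (thickness <= 0) stop("disk_volume(): thickness must be positive")
  if (is.null(side_widths)) {
    side_widths <- top_widths
  } else {
    if (length(side_widths) != length(top_widths)) {
      stop("disk_volume(): top and side width lists differ in length")
    }
    if (any(side_widths < 0)) stop("disk_volume(): negative width")
  }
  sum(disk_area_two_view(side_widths, top_widths)) * thickness
}

#' Disk-method volume from silhouettes
#'
#' Runs the disk method directly on a segmented top view (and optionally a
#' side view): the silhouette is scanned perpendicular to its bounding-box
#' length axis at one-pixel intervals, each scan width becoming one disk.
#' When a side view is present, its width sequence is resampled to the top
#' view's stations (both cameras are assumed calibrated to the same scale
#' and the object axially aligned across views).
#'
#' @param sil top-view [silhouette()].
#' @param side optional side-view [silhouette()].
#' @return Volume in mL.
#' @export
disk_volume_silhouette <- function(sil, side = NULL) {
  box <- min_area_box(sil)
  ppc <- sil$px_per_cm
  L_px <- box$length * ppc
  stations <- seq(0.5, L_px - 0.5, by = 1)
  z <- .scan_widths(sil, box, stations)
  d <- NULL
  if (!is.null(side)) {
    sbox <- min_area_box(side)
    sL <- sbox$length * side$px_per_cm
    sstations <- seq(0.5, sL - 0.5, by = 1)
    ds <- .scan_widths(side, sbox, sstations)
    # resample side widths onto the top view's relative stations
    d <- stats::approx(sstations / sL, ds, xout = stations / L_px, rule = 2)$y
  }
  disk_volume(z, thickness = 1 / ppc, side_widths = d)
}

#' Fit the multiple-linear-regression volume model
#'
#' Ordinary least squares for \eqn{y = b_0 + \sum_i b_i x_i} predicting
#' volume from geometric features (conventionally the object length and
#' five parallel widths).
#'
#' @param features numeric matrix or data frame, one row per sample.
#' @param volumes reference volumes (mL).
#' @return Object of class `"mlr_model"`: list with `coefficients`
#'   (intercept first) and `feature_names`.
#' @export
fit_mlr <- function(features, volumes) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("fit_mlr(): features must be numeric")
  if (nrow(X) != length(volumes)) stop("fit_mlr(): feature/volume length mismatch")
  if (nrow(X) < ncol(X) + 1) {
    stop("fit_mlr(): rank-deficient design (need more samples than features)")
  }
  D <- cbind(1, X)
  if (qr(D)$rank < ncol(D)) stop("fit_mlr(): rank-deficient design")
  fit <- stats::lsfit(X, volumes, intercept = TRUE)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  structure(list(coefficients = unname(fit$coefficients),
                 feature_names = nm,
                 residuals = unname(fit$residuals)),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("mlr_model: volume ~", paste(x$feature_names, collapse = " + "), "\n")
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients), collapse = " "), "\n")
  invisible(x)
}

#' Predict volumes from a fitted MLR model
#'
#' @param object an [fit_mlr()] model.
#' @param features matrix/data frame with the same columns used in fitting
#'   (or a single feature vector).
#' @param ... unused.
#' @return Predicted volumes (mL).
#' @export
predict.mlr_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) == 1 && length(object$feature_names) > 1) X <- t(X)
  if (ncol(X) != length(object$feature_names)) {
    stop("predict.mlr_model(): feature count mismatch")
  }
  as.numeric(cbind(1, X) %*% object$coefficients)
}

#' Geometric features for the MLR baseline
#'
#' Extracts the standard feature vector from a silhouette: the box length
#' and five parallel cross-widths sampled at fractions 1/6 ... 5/6 of the
#' length (equally spaced interior stations).
#'
#' @param sil a [silhouette()].
#' @param box optional precomputed [min_area_box()].
#' @return Named numeric vector `length`, `w1` ... `w5` (cm).
#' @export
mlr_features <- function(sil, box = min_area_box(sil)) {
  prof <- width_profile(sil, box, n_slices = 6L)
  c(length = box$length,
    stats::setNames(prof$widths[2:6], paste0("w", 1:5)))
}
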