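test_that("disk_volume handles cylinders, view equivalence and length mismatches", {
  expect_equal(disk_volume(rep(2, 100), 0.05), 100 * pi * 0.05)
  set.seed(4)
  z <- runif(50, 1, 3)
  expect_equal(disk_volume(z, 0.1), disk_volume(z, 0.1, side_widths = z))
  expect_error(disk_volume(z, 0.1, side_widths = z[-1]), "differ in length")
  expect_error(disk_volume(z, 0), "positive")
  expect_error(disk_volume(-z, 0.1), "negative")
})

test_that("disk stacks converge to the solid of revolution as thickness shrinks", {
  a <- function(t) 1 + 0.4 * sin(t)            # smooth positive profile
  L <- 10
  oracle <- pi * stats::integrate(function(t) a(t)^2, 0, L)$value
  vol_at <- function(x) {
    st <- seq(x / 2, L - x / 2, by = x)
    disk_volume(2 * a(st), x)
  }
  err1 <- abs(vol_at(0.01) - oracle)
  err4 <- abs(vol_at(0.04) - oracle)
  expect_lte(err1, err4 + 1e-9)
  expect_lt(err1 / oracle, 0.005)
})

test_that("one-view disk method on a rendered cone matches the analytic volume", {
  cone <- make_shape("cone", length = 12, max_width = 3.6)
  sil <- render_sil(cone, ppc = 50, seed = 6)
  expect_equal(disk_volume_silhouette(sil), cone$analytic_volume, tolerance = 0.01)
})

test_that("two-view disk method is exact for an aligned ellipsoid of revolution", {
  # squashed ellipsoid: top view sees diameters 2a(t), side view 2a(t)/r
  r <- 0.8
  sh <- make_shape("ellipsoid", length = 10, max_width = 4, aspect_ratio = r)
  st <- seq(0.005, 9.995, by = 0.01)
  top <- 2 * sh$profile(st)
  side <- top / r
  expect_equal(disk_volume(top, 0.01, side_widths = side), sh$analytic_volume,
               tolerance = 0.001)
  # rendered pair of views
  tsil <- render_sil(sh, ppc = 40, seed = 7)
  ssil <- extract_silhouette(render_side_view(sh, px_per_cm = 40, seed = 8)$image)
  expect_equal(disk_volume_silhouette(tsil, side = ssil), sh$analytic_volume,
               tolerance = 0.02)
})

test_that("side-view base loss lowers the two-view estimate slightly", {
  sh <- make_shape("ellipsoid", length = 10, max_width = 4, aspect_ratio = 0.95)
  tsil <- render_sil(sh, ppc = 40, seed = 7)
  clean <- extract_silhouette(render_side_view(sh, px_per_cm = 40, seed = 8)$image)
  lossy <- extract_silhouette(render_side_view(sh, px_per_cm = 40, seed = 8,
                                               base_loss = 0.02)$image)
  v_clean <- disk_volume_silhouette(tsil, side = clean)
  v_lossy <- disk_volume_silhouette(tsil, side = lossy)
  expect_lt(v_lossy, v_clean)
  expect_gt(v_lossy, 0.9 * v_clean)
})

test_that("fit_mlr recovers exact linear relations and flags rank deficiency", {
  set.seed(10)
  X <- cbind(x1 = runif(10, 0, 5), x2 = runif(10, 0, 5), x3 = runif(10, 0, 5))
  y <- 2 + 3 * X[, "x1"]
  fit <- fit_mlr(X, y)
  expect_equal(fit$coefficients, c(2, 3, 0, 0), tolerance = 1e-9)
  # OLS residuals orthogonal to the design columns
  y2 <- 1 + X %*% c(1, -2, 0.5) + rnorm(10, 0, 0.3)
  fit2 <- fit_mlr(X, as.numeric(y2))
  expect_lt(max(abs(crossprod(cbind(1, X), fit2$residuals))), 1e-8)
  # round trip reproduces fitted values
  expect_equal(predict(fit2, X), as.numeric(y2) - fit2$residuals, tolerance = 1e-10)
  expect_error(fit_mlr(matrix(rnorm(18), 3, 6), rnorm(3)), "rank")
  dup <- cbind(X, x4 = X[, 1])                 # collinear column
  expect_error(fit_mlr(dup, rnorm(10)), "rank")
})

test_that("predict.mlr_model computes b0 + sum(bi xi)", {
  m <- structure(list(coefficients = c(1, 2), feature_names = "x1"),
                 class = "mlr_model")
  expect_equal(predict(m, matrix(3)), 7)
  m0 <- structure(list(coefficients = c(5, 0, 0), feature_names = c("a", "b")),
                  class = "mlr_model")
  expect_equal(predict(m0, matrix(c(4, 9), 1)), 5)
  expect_error(predict(m, matrix(1, 1, 3)), "mismatch")
})

test_that("MLR generalises on a synthetic spindle population", {
  prod <- carrot_profile()
  pop <- make_population(prod, 40, seed = 31, render = FALSE)
  # analytic features: length + five widths at 1/6 .. 5/6 of the length
  feats <- t(vapply(pop$shapes, function(s) {
    c(s$length, 2 * s$profile(s$length * (1:5) / 6))
  }, numeric(6)))
  colnames(feats) <- c("length", paste0("w", 1:5))
  vols <- pop$truth$volume_ml
  train <- 1:25; test <- 26:40
  fit <- fit_mlr(feats[train, ], vols[train])
  pred <- predict(fit, feats[test, ])
  r2 <- stats::cor(pred, vols[test])^2
  expect_gte(r2, 0.8)
})

test_that("mlr_features extracts length plus five interior widths", {
  sil <- rect_silhouette(180, 60, ppc = 20)
  f <- mlr_features(sil)
  expect_named(f, c("length", "w1", "w2", "w3", "w4", "w5"))
  expect_equal(unname(f["length"]), 9)
  expect_equal(unname(f[2:6]), rep(3, 5), tolerance = 0.02)
})
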