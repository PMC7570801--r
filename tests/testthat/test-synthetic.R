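test_that("make_shape closed-form volumes match the textbook solids", {
  expect_equal(make_shape("cone", length = 10, max_width = 4)$analytic_volume,
               pi * 4 * 10 / 3, tolerance = 1e-12)          # 41.888
  expect_equal(make_shape("ellipsoid", length = 10, max_width = 4)$analytic_volume,
               4 / 3 * pi * 5 * 2 * 2, tolerance = 1e-12)   # 83.776
  expect_equal(make_shape("spindle", length = 10, max_width = 4)$analytic_volume,
               pi * 4 * 10 / 2, tolerance = 1e-12)          # 62.832: int sin^2 = L/2
  expect_equal(make_shape("cylinder", length = 10, max_width = 4,
                          aspect_ratio = 0.8)$analytic_volume,
               pi / 0.8 * 4 * 10, tolerance = 1e-12)
  expect_error(make_shape("torus", 1, 1), "arg")
  expect_error(make_shape("bent-spindle", 10, 3, bend_radius = 2), "half circle")
})

test_that("every closed-form volume agrees with an independent numeric oracle", {
  shapes <- list(
    make_shape("cylinder", length = 9, max_width = 3, aspect_ratio = 0.9),
    make_shape("cone", length = 11, max_width = 3.5, aspect_ratio = 1.1),
    make_shape("ellipsoid", length = 8, max_width = 4, aspect_ratio = 0.95),
    make_shape("spindle", length = 14, max_width = 3.2, aspect_ratio = 0.97, power = 0.45),
    make_shape("tapered-carrot", length = 16, max_width = 4, aspect_ratio = 0.9531,
               shoulder = 0.5, tip = 0.8))
  for (sh in shapes) {
    expect_equal(sh$analytic_volume, num_volume(sh), tolerance = 0.005,
                 info = sh$kind)
  }
  # bent spindle: oracle integrates column heights over the image plane
  # (Pappus is the package's rule; this check is independent of it)
  sh <- make_shape("bent-spindle", length = 12, max_width = 3,
                   aspect_ratio = 0.95, bend_radius = 9)
  g <- 0.02
  xs <- seq(-10, 10, by = g); ys <- seq(-4, 10, by = g)
  X <- matrix(rep(xs, each = length(ys)), length(ys))
  Y <- matrix(rep(ys, times = length(xs)), length(ys))
  rho <- sqrt(X^2 + (9 - Y)^2)
  tt <- (atan2(X, 9 - Y) + 12 / 18) * 9
  w <- 9 - rho
  h2 <- pmax.int(sh$profile(tt)^2 - w^2, 0)
  v_num <- sum(2 * sqrt(h2) / 0.95) * g^2
  expect_equal(sh$analytic_volume, v_num, tolerance = 0.005)
})

test_that("rendered masks have the right area and rotation leaves it unchanged", {
  cyl <- make_shape("cylinder", length = 8, max_width = 2.5)
  r0 <- render_top_view(cyl, px_per_cm = 30, seed = 1)
  expect_equal(sum(r0$mask), 8 * 2.5 * 30^2, tolerance = 0.005)
  r90 <- render_top_view(cyl, px_per_cm = 30, rotation_deg = 90, seed = 1)
  expect_equal(sum(r90$mask), sum(r0$mask), tolerance = 0.002)
  expect_error(render_top_view(cyl, px_per_cm = 30, canvas = c(50, 50)),
               "does not fit")
})

test_that("renders are deterministic: same seed gives byte-identical files", {
  sh <- make_shape("spindle", length = 6, max_width = 2, power = 0.6)
  noise <- render_noise(jitter_sd_px = 1.5, salt_pepper = 5e-4)
  f1 <- tempfile(fileext = ".ppm"); f2 <- tempfile(fileext = ".ppm")
  write_pnm(render_top_view(sh, px_per_cm = 20, noise = noise, seed = 77)$image, f1)
  write_pnm(render_top_view(sh, px_per_cm = 20, noise = noise, seed = 77)$image, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # and a different seed changes the noise realisation
  f3 <- tempfile(fileext = ".ppm")
  write_pnm(render_top_view(sh, px_per_cm = 20, noise = noise, seed = 78)$image, f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("noise-free rendered widths match the profile within a pixel", {
  sh <- make_shape("spindle", length = 15, max_width = 4, aspect_ratio = 0.9531)
  ppc <- 30
  r <- render_top_view(sh, px_per_cm = ppc, seed = 2)
  # renderer contract: per-column foreground counts track 2 a(t) within 1 px
  counts <- colSums(r$mask)
  W <- ncol(r$mask); L_px <- sh$length * ppc
  t_px <- (seq_len(W) - 1) - (W - 1) / 2 + L_px / 2
  expected_px <- 2 * sh$profile(t_px / ppc) * ppc
  expect_lt(max(abs(counts - expected_px)), 1)

  # through the measurement pipeline another half pixel of scan rounding
  # and of box registration may each stack on top
  sil <- extract_silhouette(r$image)
  box <- min_area_box(sil)
  prof <- width_profile(sil, box, 8)
  t0 <- (sh$length - box$length) / 2           # box face vs analytic tip
  expected <- 2 * sh$profile(t0 + prof$stations)
  expect_lt(max(abs(prof$widths - expected)[2:8]), 1.5 / ppc)
  expect_lt(max(abs(prof$widths - expected)[c(1, 9)]), 2.5 / ppc)
})

test_that("side views are squashed by the aspect ratio", {
  sh <- make_shape("ellipsoid", length = 10, max_width = 4, aspect_ratio = 0.8)
  ssil <- extract_silhouette(render_side_view(sh, px_per_cm = 30, seed = 3)$image)
  sbox <- min_area_box(ssil)
  expect_equal(sbox$length, 10, tolerance = 0.02)
  expect_equal(sbox$width, 4 / 0.8, tolerance = 0.02)
  expect_error(render_side_view(make_shape("bent-spindle", 10, 2)), "straight")
})

test_that("make_population is deterministic, spans the class table and keeps invariants", {
  prod <- carrot_profile()
  a <- make_population(prod, 50, seed = 13, render = FALSE)
  b <- make_population(prod, 50, seed = 13, render = FALSE)
  expect_identical(a$truth, b$truth)
  expect_setequal(unique(a$truth$class), prod$class_table$label)
  expect_equal(a$truth$mass_g, a$truth$volume_ml * prod$density, tolerance = 1e-12)
  expect_true(all(a$truth$length_cm >= 12 & a$truth$length_cm <= 22))
  expect_true(all(a$truth$max_width_cm >= 2.5 & a$truth$max_width_cm <= 4.5 + 1e-9))

  cuc <- make_population(cucumber_profile(), 50, seed = 14, render = FALSE)
  expect_setequal(unique(cuc$truth$class), cucumber_profile()$class_table$label)

  expect_error(make_population(prod, 0, seed = 1), "n must be")
  expect_error(make_population("durian", 5), "unknown product")
})
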