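test_that("estimate_volume reproduces the hand-computed cylinder-profile value", {
  # constant width 2.5 cm, length 10 cm, n = 8, circular sections:
  # 2 caps pi*2.5*2.5*1.25/6 + 6 frustums pi*1.5625*1.25
  prod <- product_profile("round", 1, 1, data.frame(label = "A", low = 0, high = 1e6))
  v <- estimate_volume(profile_obj(rep(2.5, 9), 10), prod)
  expect_equal(v$total, 2 * pi * 2.5 * 2.5 * 1.25 / 6 + 6 * pi * 1.5625 * 1.25)
  expect_equal(v$total, 44.997, tolerance = 1e-4)
  expect_equal(v$total, v$cap_top + v$cap_bottom + sum(v$frustums))
  expect_length(v$frustums, 6)

  expect_equal(estimate_volume(profile_obj(rep(0, 9), 10), prod)$total, 0)
  expect_error(estimate_volume(profile_obj(c(rep(1, 8), -1), 10), prod), "negative")
})

test_that("estimate_volume recovers analytic volumes of rendered spindles", {
  prod <- carrot_profile()
  sh <- make_shape("spindle", length = 16, max_width = 3.8,
                   aspect_ratio = prod$aspect_ratio, power = 0.6)
  # >= 1000 px object length
  sil <- render_sil(sh, ppc = 63, seed = 21)
  v <- estimate_volume(width_profile(sil, min_area_box(sil), 8), prod)
  expect_equal(v$total, sh$analytic_volume, tolerance = 0.03)
})

test_that("volume estimate obeys additivity, monotonicity, scaling and 1/r laws", {
  prod1 <- product_profile("p1", 1, 1, data.frame(label = "A", low = 0, high = 1e6))
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    w <- runif(n + 1, 0.5, 4)
    L <- runif(1, 8, 20)
    v <- estimate_volume(profile_obj(w, L), prod1)
    expect_equal(v$total, v$cap_top + v$cap_bottom + sum(v$frustums), tolerance = 1e-12)
    # pointwise-larger profile -> no smaller volume
    w2 <- w + runif(n + 1, 0, 0.5)
    expect_gte(estimate_volume(profile_obj(w2, L), prod1)$total, v$total)
    # doubling widths and length scales volume by 8
    expect_equal(estimate_volume(profile_obj(2 * w, 2 * L), prod1)$total,
                 8 * v$total, tolerance = 1e-12)
    # volume proportional to 1 / aspect_ratio
    r <- runif(1, 0.5, 1.5)
    prodr <- product_profile("pr", r, 1, data.frame(label = "A", low = 0, high = 1e6))
    expect_equal(estimate_volume(profile_obj(w, L), prodr)$total,
                 v$total / r, tolerance = 1e-12)
  }
})

test_that("at high slice counts the estimator agrees with quadrature of the profile", {
  # truncated fixture (nonzero ends) so the caps are asymptotically negligible
  prod <- product_profile("p", 0.9, 1, data.frame(label = "A", low = 0, high = 1e6))
  L <- 12
  a <- function(t) 1.5 + 0.5 * sin(pi * t / L)   # smooth, strictly positive
  n <- 500
  st <- seq(0, L, length.out = n + 1)
  v <- estimate_volume(profile_obj(2 * a(st), L), prod)
  oracle <- pi / 0.9 * stats::integrate(function(t) a(t)^2, 0, L)$value
  expect_equal(v$total, oracle, tolerance = 0.005)
})

test_that("mass estimation and classification follow the product tables", {
  carrot <- carrot_profile()
  cucumber <- cucumber_profile()

  m <- estimate_mass(100, carrot)
  expect_equal(m$mass, 109.87)
  expect_equal(estimate_mass(150, cucumber)$mass, 152.85)
  expect_equal(estimate_mass(150, cucumber)$class_label, "L")
  z <- estimate_mass(0, carrot)
  expect_equal(z$mass, 0)
  expect_equal(z$class_label, "out-of-range")

  # carrot boundaries: shared endpoints go to the upper class
  expect_equal(classify(c(125, 200, 250), carrot), c("M", "L", "2L"))
  expect_equal(classify(60, carrot), "out-of-range")
  expect_equal(classify(320, carrot), "out-of-range")
  # cucumber: S < 100; 200 g is still L, XL strictly above
  expect_equal(classify(c(99.9, 100, 200, 200.5), cucumber), c("S", "M", "L", "XL"))
  expect_error(classify(-5, carrot), "negative")
})

test_that("product profiles validate their inputs", {
  expect_error(product_profile("x", 0, 1, data.frame(label = "A", low = 0, high = 1)),
               "aspect_ratio")
  expect_error(product_profile("x", 1, -2, data.frame(label = "A", low = 0, high = 1)),
               "density")
  expect_error(product_profile("x", 1, 1,
                               data.frame(label = c("A", "B"), low = c(0, 50),
                                          high = c(60, 100))),
               "overlap")
  profs <- read_product_profiles(system.file("extdata", "products.json",
                                             package = "slendervol"))
  expect_equal(profs$carrot$density, 1.0987)
  expect_equal(profs$cucumber$aspect_ratio, 0.9677)
  expect_equal(classify(200, profs$cucumber), "L")
})

test_that("sweep_slices shows convergence for tapered shapes and indifference for cylinders", {
  prod <- carrot_profile()
  set.seed(8)
  shapes <- lapply(1:6, function(i) {
    make_shape("spindle", length = runif(1, 12, 18), max_width = runif(1, 2.8, 4),
               aspect_ratio = prod$aspect_ratio, power = runif(1, 0.5, 1))
  })
  sils <- lapply(seq_along(shapes), function(i) render_sil(shapes[[i]], ppc = 25, seed = i))
  refs <- vapply(shapes, `[[`, numeric(1), "analytic_volume")
  tab <- sweep_slices(sils, refs, prod, n_range = c(3, 8))
  expect_equal(tab$n_slices, c(3, 8))
  expect_lte(tab$mean_abs_pct_error[2], tab$mean_abs_pct_error[1])

  # cylinder: the only error is the end-cap deficit; the semi-ellipsoid cap
  # carries 2/3 of its slice's true volume, so the relative error is
  # exactly 2 / (3n) and shrinks with n
  cyl <- make_shape("cylinder", length = 14, max_width = 3, aspect_ratio = prod$aspect_ratio)
  csil <- render_sil(cyl, ppc = 25, seed = 99)
  ctab <- sweep_slices(list(csil), cyl$analytic_volume, prod, n_range = c(4, 8, 12))
  expect_equal(ctab$mean_abs_pct_error, 100 * 2 / (3 * c(4, 8, 12)),
               tolerance = 0.15)

  expect_error(sweep_slices(list(), numeric(0), prod), "empty")
  expect_error(sweep_slices(sils, refs, prod, n_range = integer(0)), "empty")
  expect_error(sweep_slices(sils, refs, prod, n_range = 2:5), "\\[3, 15\\]")
})

test_that("measure_produce runs the whole pipeline on one image", {
  prod <- cucumber_profile()
  sh <- make_shape("spindle", length = 15, max_width = 4,
                   aspect_ratio = prod$aspect_ratio, power = 0.5)
  r <- render_top_view(sh, px_per_cm = 30, rotation_deg = 20, seed = 4)
  m <- measure_produce(r$image, prod)
  expect_equal(m$summary$volume_ml, sh$analytic_volume, tolerance = 0.03)
  expect_equal(m$summary$mass_g, m$summary$volume_ml * prod$density)
  expect_equal(m$summary$length_cm, 15, tolerance = 0.02)
  expect_true(m$summary$class %in% c(prod$class_table$label, "out-of-range"))
})
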