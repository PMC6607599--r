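test_that("fit_ellipse recovers exact parametric points to 1e-6", {
  e0 <- ellipse_params(c(50, 50), 30, 15, 30 * pi / 180)
  pts <- ellipse_points(e0, 20)
  fit <- fit_ellipse(pts)
  expect_equal(fit$center, e0$center, tolerance = 1e-6)
  expect_equal(fit$a, e0$a, tolerance = 1e-6)
  expect_equal(fit$b, e0$b, tolerance = 1e-6)
  expect_equal(fit$theta, e0$theta, tolerance = 1e-6)
})

test_that("fit_ellipse handles circles and degenerate input", {
  circ <- ellipse_points(ellipse_params(c(20, 30), 10, 10), 12)
  fit <- fit_ellipse(circ)
  expect_equal(fit$a, 10, tolerance = 1e-6)
  expect_equal(fit$b, 10, tolerance = 1e-6)

  expect_error(fit_ellipse(circ[1:4, ]), class = "stomapore_fit_failed")
  line <- cbind(row = 1:10, col = 2 * (1:10))
  expect_error(fit_ellipse(line), class = "stomapore_fit_failed")
})

test_that("fit is invariant to translation, rotation and scaling", {
  e0 <- ellipse_params(c(0, 0), 8, 3, 0.7)
  pts <- ellipse_points(e0, 24)
  base <- fit_ellipse(pts)
  # translation
  fitt <- fit_ellipse(pts + matrix(c(120, -35), nrow(pts), 2, byrow = TRUE))
  expect_equal(fitt$a, base$a, tolerance = 1e-6)
  expect_equal(fitt$b, base$b, tolerance = 1e-6)
  expect_equal(fitt$theta, base$theta, tolerance = 1e-6)
  # rotation by alpha about the origin (row = y, col = x)
  alpha <- 0.4
  R <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
  xy <- cbind(pts[, "col"], pts[, "row"]) %*% t(R)
  fitr <- fit_ellipse(cbind(row = xy[, 2], col = xy[, 1]))
  expect_equal(fitr$a, base$a, tolerance = 1e-6)
  expect_equal(fitr$b, base$b, tolerance = 1e-6)
  expect_equal(fitr$theta, (base$theta + alpha) %% pi, tolerance = 1e-6)
  # uniform scaling
  fits <- fit_ellipse(pts * 3.5)
  expect_equal(fits$a, base$a * 3.5, tolerance = 1e-6)
  expect_equal(fits$b, base$b * 3.5, tolerance = 1e-6)
})

test_that("boundary extraction plus conic fit recovers rasterized ellipses within 3%", {
  cases <- list(
    c(a = 10, r = 0.30), c(a = 20, r = 0.15), c(a = 30, r = 0.10),
    c(a = 40, r = 0.60), c(a = 60, r = 0.50), c(a = 25, r = 1.00)
  )
  for (cs in cases) {
    a <- cs[["a"]]; b <- a * cs[["r"]]
    n <- 2L * ceiling(a) + 16L
    th <- 0.5  # oblique so rasterization phase varies along the boundary
    truth <- raster_ellipse(c(n, n), c(n, n) / 2, a, b, th)
    fit <- fit_ellipse(extract_boundary(truth))
    expect_equal(fit$a, a, tolerance = 0.03 * a)
    expect_equal(fit$b, b, tolerance = 0.03 * b)
  }
})

test_that("moment-based ellipse matches rasterized geometry", {
  disk <- raster_ellipse(c(64, 64), c(32, 32), 20, 20)
  em <- ellipse_from_moments(disk)
  expect_equal(em$a, 20, tolerance = 0.02 * 20)
  expect_equal(em$b, 20, tolerance = 0.02 * 20)

  ell <- raster_ellipse(c(96, 96), c(48, 48), 40, 10, 0)
  em2 <- ellipse_from_moments(ell)
  expect_equal(em2$a, 40, tolerance = 0.02 * 40)
  expect_equal(em2$b, 10, tolerance = 0.02 * 10)
  expect_lte(min(em2$theta, pi - em2$theta), 2 * pi / 180)

  tiny <- matrix(FALSE, 16, 16); tiny[8, 7:10] <- TRUE
  expect_error(ellipse_from_moments(tiny), class = "stomapore_too_small_region")
})

test_that("conic fit and moment fit agree on clean rasterized ellipses", {
  for (s in 1:5) {
    set.seed(s)
    a <- runif(1, 15, 40); b <- runif(1, 0.3, 0.9) * a; th <- runif(1, 0, pi)
    n <- 2L * ceiling(a) + 16L
    m <- raster_ellipse(c(n, n), c(n, n) / 2, a, b, th)
    f1 <- fit_ellipse(extract_boundary(m))
    f2 <- ellipse_from_moments(m)
    expect_equal(f1$a, f2$a, tolerance = 0.05 * f1$a)
    expect_equal(f1$b, f2$b, tolerance = 0.05 * f1$b)
  }
})

test_that("ellipse_params normalizes axis order and orientation", {
  e <- ellipse_params(c(0, 0), a = 3, b = 7, theta = 0.2)
  expect_equal(e$a, 7)
  expect_equal(e$b, 3)
  expect_equal(e$theta, (0.2 + pi / 2) %% pi)
  expect_error(ellipse_params(c(0, 0), 5, 0), class = "stomapore_invalid_argument")
})
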