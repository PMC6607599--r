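test_that("initialize_phi builds a signed circle with the stated geometry", {
  phi <- initialize_phi(c(64, 64), center = c(32, 32), radius = 8)
  expect_equal(phi[33, 33], 8)         # centre (0-based 32,32)
  expect_equal(phi[33, 41], 0)         # on the circle
  expect_equal(phi[33, 49], -8)        # 16 px out
  # exactly one connected positive region
  expect_equal(max(label_components(phi > 0)), 1L)

  expect_error(initialize_phi(c(64, 64), center = c(0, 0), radius = 40),
               class = "stomapore_invalid_argument")
  expect_error(initialize_phi(c(64, 64), center = c(70, 10)),
               class = "stomapore_invalid_argument")
  expect_error(initialize_phi(c(64, 64), radius = 1),
               class = "stomapore_invalid_argument")
})

test_that("region_means follows the outside-c1 / inside-c2 convention", {
  img <- matrix(100, 32, 32)
  phi <- initialize_phi(c(32, 32), radius = 6)
  s <- region_means(img, phi)
  expect_equal(s$c1, 100)
  expect_equal(s$c2, 100)

  img2 <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
  phi2 <- cbind(matrix(-1, 32, 16), matrix(1, 32, 16))
  s2 <- region_means(img2, phi2)
  expect_equal(s2$c2, 255)  # inside = right half
  expect_equal(s2$c1, 0)

  expect_error(region_means(img, matrix(1, 32, 32)),
               class = "stomapore_degenerate_level_set")
})

test_that("cv_energy matches a direct grid summation of the functional", {
  # two-valued image partitioned exactly by phi, mu = nu = 0 -> energy 0
  img <- cbind(matrix(0, 64, 32), matrix(255, 64, 32))
  phi <- cbind(matrix(-2, 64, 32), matrix(2, 64, 32))
  expect_equal(cv_energy(img, phi, cv_params(mu = 0, nu = 0)), 0)

  # constant image, nu = 0 -> energy = mu * smoothed-Heaviside perimeter,
  # checked against an independent direct summation of |grad H_eps(phi)|
  eps <- 1
  p <- cv_params(mu = 1, nu = 0, epsilon = eps)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  nr <- nrow(H); nc <- ncol(H)
  len_direct <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      hx <- (H[i, min(j + 1, nc)] - H[i, max(j - 1, 1)]) / 2
      hy <- (H[min(i + 1, nr), j] - H[max(i - 1, 1), j]) / 2
      len_direct <- len_direct + sqrt(hx^2 + hy^2)
    }
  }
  imgc <- matrix(128, 64, 64)
  expect_equal(cv_energy(imgc, phi, p), len_direct, tolerance = 1e-12)

  # two-valued partition with mu = 1: length term plus zero residuals
  p2 <- cv_params(mu = 1, nu = 0)
  expect_equal(cv_energy(img, phi, p2), len_direct, tolerance = 1e-12)
})

test_that("evolve_step moves the contour by the region forces", {
  # stationary: exact two-phase partition, mu = nu = 0 keeps the sign set
  img <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
  phi <- cbind(matrix(-5, 32, 16), matrix(5, 32, 16))
  p <- cv_params(mu = 0, nu = 0)
  phi1 <- evolve_step(img, phi, p)
  expect_equal(phi1 > 0, phi > 0)

  # dark disk on bright field, small seed strictly inside: inside grows
  img2 <- matrix(220, 64, 64)
  img2[raster_ellipse(c(64, 64), c(32, 32), 20, 20)] <- 30
  phi2 <- initialize_phi(c(64, 64), center = c(32, 32), radius = 6)
  phi2n <- evolve_step(img2, phi2, cv_params(mu = 1))
  expect_gte(sum(phi2n > 0), sum(phi2 > 0))

  # dt = 0 is the identity
  expect_identical(evolve_step(img2, phi2, cv_params(dt = 0)), phi2)
})

test_that("cv_segment recovers a filled ellipse to high IoU", {
  truth <- raster_ellipse(c(128, 128), c(64, 64), 40, 20)
  img <- matrix(200, 128, 128)
  img[truth] <- 40
  seg <- cv_segment(img)
  expect_s3_class(seg, "cv_segmentation")
  expect_gte(iou(seg$mask, truth), 0.98)
  expect_true(is.data.frame(seg$trace))
  expect_named(seg$trace, c("iteration", "energy", "c1", "c2", "area_inside"))

  set.seed(99)
  imgn <- pmin(pmax(img + matrix(rnorm(128^2, 0, 10), 128, 128), 0), 255)
  expect_gte(iou(cv_segment(imgn)$mask, truth), 0.95)

  expect_error(cv_segment(matrix(128, 64, 64)),
               class = "stomapore_empty_segmentation")
  expect_error(cv_segment(matrix(1:10, 5, 2)),
               class = "stomapore_invalid_argument")
})

test_that("segmentation energy descends and is shift-equivariant", {
  for (s in 1:4) {
    f <- make_blob_image(s)
    seg <- cv_segment(f$image)
    e <- seg$trace$energy
    expect_lte(e[length(e)], e[1])
  }
  # intensity-shift equivariance with nu = 0
  f <- make_blob_image(7)
  m1 <- cv_segment(f$image)$mask
  m2 <- cv_segment(f$image + 30)$mask
  expect_identical(m1, m2)
})

test_that("two-valued blobs are segmented exactly with mu = nu = 0", {
  p <- cv_params(mu = 0, nu = 0)
  for (s in 1:5) {
    f <- make_blob_image(s + 100)
    seg <- cv_segment(f$image, p)
    expect_identical(seg$mask, f$mask)
  }
})
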