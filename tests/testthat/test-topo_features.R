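random_barcode <- function(seed, n0 = 10, n1 = 5) {
  set.seed(seed)
  b0 <- rep(0, n0)
  d0 <- runif(n0, 0.01, 0.5)
  b1 <- runif(n1, 0, 0.4)
  d1 <- b1 + runif(n1, 0.001, 0.4)
  topocyto:::new_barcode(c(rep(0L, n0), rep(1L, n1)), c(b0, b1), c(d0, d1))
}

test_that("descriptor vector matches direct arithmetic and stats oracle", {
  bc <- topocyto:::new_barcode(c(0L, 0L, 1L), c(0, 0, 0.2), c(1, 3, 0.7))
  v <- descriptor_vector(bc)
  expect_equal(unname(v), c(3, 1, 2, 1, 0.5, 0.5, 0.5, 0))  # population sd

  # empty dim-1 block is zero with a warning
  bc0 <- topocyto:::new_barcode(0L, 0, 2)
  expect_warning(v0 <- descriptor_vector(bc0), "empty dimension-1")
  expect_equal(unname(v0[5:8]), rep(0, 4))

  # random barcodes against an independent one-pass oracle
  for (s in 1:5) {
    bc <- random_barcode(s)
    v <- descriptor_vector(bc)
    for (d in 0:1) {
      p <- bc$death[bc$dimension == d] - bc$birth[bc$dimension == d]
      expect_equal(unname(v[d * 4 + 1:4]),
                   c(max(p), min(p), mean(p), sqrt(mean((p - mean(p))^2))),
                   tolerance = 1e-12)
    }
    expect_true(v[1] >= v[3] && v[3] >= v[2] && v[2] >= 0 && v[4] >= 0)
  }
})

test_that("PT curves count strictly-exceeding bars with correct percentages", {
  bc <- topocyto:::new_barcode(rep(1L, 3), c(0, 0, 0), c(0.5, 0.2, 0.05))
  cv <- pt_curve(bc, dim = 1, tau_range = c(0.1, 0.1 + 1e-9), n_points = 2)
  expect_equal(cv$count[1], 2)
  expect_equal(cv$percentage[1], 2 / 3)

  cv2 <- pt_curve(bc, dim = 1, tau_range = c(0.001, 0.002), n_points = 2)
  expect_equal(cv2$count, c(3, 3))
  expect_equal(cv2$percentage, c(1, 1))

  # strictness: persistence exactly equal to tau is not counted
  bc_eq <- topocyto:::new_barcode(1L, 0, 0.1)
  expect_equal(pt_curve(bc_eq, 1, c(0.1, 0.2), 2)$count[1], 0)

  expect_error(pt_curve(bc, 1, c(0.2, 0.1)), "lo < hi")

  # empty barcode: percentage defined as 0
  cv3 <- pt_curve(topocyto:::new_barcode(integer(0), numeric(0), numeric(0)),
                  1, c(0, 1), 5)
  expect_equal(cv3$count, rep(0, 5))
  expect_equal(cv3$percentage, rep(0, 5))
})

test_that("PT counts are non-increasing and start at the finite-bar count", {
  for (s in 1:10) {
    bc <- random_barcode(s + 20)
    cv <- pt_curve(bc, dim = 1, tau_range = c(1e-9, 0.9), n_points = 37)
    expect_true(all(diff(cv$count) <= 0))
    pers <- bc$death[bc$dimension == 1] - bc$birth[bc$dimension == 1]
    expect_equal(cv$count[1], sum(pers > 1e-9))
    # brute-force per-tau recount
    expect_equal(cv$count,
                 vapply(cv$tau, function(t) sum(pers > t), numeric(1)))
  }
})

test_that("mean PT curve is the pointwise average and checks grids", {
  c1 <- pt_curve(random_barcode(1), 1, c(0.01, 0.5), 10)
  c2 <- pt_curve(random_barcode(2), 1, c(0.01, 0.5), 10)
  m <- mean_pt_curve(list(c1, c2))
  expect_equal(m$count, (c1$count + c2$count) / 2)
  expect_equal(m$percentage, (c1$percentage + c2$percentage) / 2)
  expect_equal(mean_pt_curve(list(c1, c1))$count, c1$count)

  c3 <- pt_curve(random_barcode(3), 1, c(0.01, 0.6), 10)
  expect_error(mean_pt_curve(list(c1, c3)), "grid mismatch")

  # oracle average of n random curves
  curves <- lapply(4:9, function(s) pt_curve(random_barcode(s), 1,
                                             c(0.01, 0.5), 10))
  m2 <- mean_pt_curve(curves)
  expect_equal(m2$count,
               colMeans(do.call(rbind, lapply(curves, `[[`, "count"))),
               tolerance = 1e-12)
})

test_that("persistence images: empty, additive, mass concentration, total mass", {
  empty <- topocyto:::new_barcode(integer(0), numeric(0), numeric(0))
  expect_equal(persistence_image(empty, 1)$pixels, matrix(0, 25, 25))

  # additivity in bars
  b1 <- topocyto:::new_barcode(1L, 0.1, 0.4)
  b2 <- topocyto:::new_barcode(1L, 0.5, 0.8)
  both <- topocyto:::new_barcode(c(1L, 1L), c(0.1, 0.5), c(0.4, 0.8))
  expect_equal(persistence_image(both, 1, 10, 0.05)$pixels,
               persistence_image(b1, 1, 10, 0.05)$pixels +
                 persistence_image(b2, 1, 10, 0.05)$pixels,
               tolerance = 1e-12)

  # sigma << pixel width: >= 99% of the bar's mass lands in its pixel
  g <- 5L  # pixel width 0.2
  bar <- topocyto:::new_barcode(1L, 0.5, 0.8)  # centre of pixel (3, 2)
  im <- persistence_image(bar, 1, g, spread = 0.01)
  w <- 0.3  # linear weight p / p_max with p = 0.3, p_max = 1
  expect_gte(im$pixels[3, 2], 0.99 * w)
  expect_equal(sum(im$pixels), w, tolerance = 1e-6)

  # total mass approaches w(p) as the domain grows (Gaussian CDF oracle)
  bar2 <- topocyto:::new_barcode(1L, 0.02, 0.06)
  dom <- list(birth = c(-1, 2), pers = c(-1, 2))
  im2 <- persistence_image(bar2, 1, 25, 0.05, domain = dom)
  w2 <- 0.04 / dom$pers[2]
  expect_equal(sum(im2$pixels), w2, tolerance = 1e-9)

  expect_error(persistence_image(b1, 1, 25, spread = 0), "positive")
  expect_error(persistence_image(b1, 1, 7), "grid_size")
})

test_that("persistence image is numerically stable under small bar moves", {
  bar <- function(b, d) topocyto:::new_barcode(1L, b, d)
  base <- persistence_image(bar(0.3, 0.6), 1, 25, 0.05)$pixels
  eps <- 1e-3
  moved <- persistence_image(bar(0.3 + eps, 0.6 + eps), 1, 25, 0.05)$pixels
  # change bounded by constant(sigma, w) * eps; constant ~ 2/sigma here
  expect_lt(sum(abs(moved - base)), (2 / 0.05) * eps * 2)
})

test_that("pi_feature flattens row-major and concatenates by dimension", {
  bc <- random_barcode(33)
  im0 <- persistence_image(bc, 0, 5, 0.05)
  im1 <- persistence_image(bc, 1, 5, 0.05)
  v <- pi_feature(list(im1, im0))  # order normalised to dim0 first
  expect_length(v, 50)
  expect_equal(v[1:25], as.vector(t(im0$pixels)))
  expect_equal(v[26:50], as.vector(t(im1$pixels)))
  # flatten-reshape identity
  expect_equal(matrix(v[26:50], 5, 5, byrow = TRUE), im1$pixels)

  im_bad <- persistence_image(bc, 1, 5, 0.01)
  expect_error(pi_feature(list(im0, im_bad)), "mismatch")

  ims <- lapply(0:2, function(d) persistence_image(bc, d, 10, 0.05))
  expect_length(pi_feature(ims), 300)
})
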