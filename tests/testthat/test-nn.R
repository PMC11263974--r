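test_that("bilinear rotation matches exact array rotation at multiples of 90 degrees", {
  spec <- tiny_molecule()
  img <- render_conformation(spec, c(0.3, -0.2))
  d <- spec$image_size
  flat <- matrix(as.vector(img), 1)
  for (k in 0:3) {
    out <- rotate_bilinear_fwd(flat, k * pi / 2, d)$out
    expect_close(matrix(out, d, d), rotate_image_90(img, k), 1e-12)
  }
})

test_that("rotation round trip is accurate on band-limited images away from borders", {
  d <- 32
  g <- asNamespace("conformscape")$grid_coords(d)
  # band-limited test pattern: one broad off-centre Gaussian (std ~7.7 px;
  # bilinear round-trip error scales with curvature, so sharper content
  # fails this absolute bound)
  smooth <- exp(-((g$x - 2)^2 + (g$y + 1)^2) / 60)
  flat <- matrix(smooth, 1)
  for (a in c(0.6, 1.9, -2.4)) {
    once <- rotate_bilinear_fwd(flat, a, d)$out
    back <- rotate_bilinear_fwd(once, -a, d)$out
    interior <- matrix(back - flat, d, d)[9:24, 9:24]
    expect_lt(max(abs(interior)), 0.02)
  }
})

test_that("rotation gradients match finite differences at generic angles", {
  set.seed(71)
  d <- 12
  g <- asNamespace("conformscape")$grid_coords(d)
  img <- matrix(exp(-((g$x - 1)^2 + (g$y + 2)^2) / 8) +
    0.5 * exp(-((g$x + 2)^2 + g$y^2) / 6), 1)
  gout <- matrix(rnorm(d * d), 1)
  h <- 1e-6
  for (a in c(0.35, -1.2, 2.6)) {
    fwd <- rotate_bilinear_fwd(img, a, d)
    bwd <- rotate_bilinear_bwd(fwd$cache, gout)
    num_dphi <- (sum(gout * rotate_bilinear_fwd(img, a + h, d)$out) -
      sum(gout * rotate_bilinear_fwd(img, a - h, d)$out)) / (2 * h)
    expect_close(bwd$dphi, num_dphi, 1e-5 * max(1, abs(num_dphi)))
    for (i in c(30, 77, 101)) {
      ip <- img
      ip[i] <- ip[i] + h
      im <- img
      im[i] <- im[i] - h
      num <- (sum(gout * rotate_bilinear_fwd(ip, a, d)$out) -
        sum(gout * rotate_bilinear_fwd(im, a, d)$out)) / (2 * h)
      expect_close(bwd$dimages[i], num, 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("the image-gradient path is the exact adjoint of the forward map", {
  # <A x, y> == <x, A^T y> for random x, y and angles
  set.seed(72)
  d <- 10
  for (a in c(0.9, -2.1)) {
    x <- matrix(rnorm(d * d), 1)
    y <- matrix(rnorm(d * d), 1)
    fwd <- rotate_bilinear_fwd(x, a, d)
    bwd <- rotate_bilinear_bwd(fwd$cache, y)
    expect_close(sum(fwd$out * y), sum(x * bwd$dimages), 1e-9)
  }
})

test_that("scatter_add accumulates duplicate indices like an explicit loop", {
  ns <- asNamespace("conformscape")
  set.seed(73)
  v <- runif(2000)
  idx <- sample(150, 2000, replace = TRUE)
  ref <- numeric(150)
  for (i in seq_along(v)) ref[idx[i]] <- ref[idx[i]] + v[i]
  expect_equal(ns$scatter_add(v, idx, 150), ref)
})

test_that("the Adam optimizer minimizes a simple quadratic", {
  ns <- asNamespace("conformscape")
  params <- list(w = c(3, -2))
  state <- ns$adam_init(params)
  for (i in 1:800) {
    upd <- ns$adam_step(params, list(w = 2 * params$w), state, lr = 0.05)
    params <- upd$params
    state <- upd$state
  }
  expect_lt(max(abs(params$w)), 1e-3)
})

test_that("gradient clipping rescales only above the threshold", {
  ns <- asNamespace("conformscape")
  g <- list(a = c(3, 4)) # norm 5
  expect_identical(ns$clip_grads(g, 10), g)
  clipped <- ns$clip_grads(g, 1)
  expect_close(sqrt(sum(clipped$a^2)), 1, 1e-12)
  expect_close(clipped$a / sqrt(sum(clipped$a^2)), c(3, 4) / 5, 1e-12)
})
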