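test_that("particle generation adds calibrated Gaussian noise after posing", {
  spec <- tiny_molecule()
  z <- c(0.2, -0.4)
  phi <- 1.1
  clean <- apply_pose(spec, z, phi)
  with_test_seed(3, {
    p0 <- generate_particle(spec, z, phi, 0)
    expect_identical(p0$pixels, clean)
  })
  # per-pixel noise std over many particles with identical latents
  n <- 20000
  resid <- with_test_seed(4, {
    vapply(
      seq_len(n),
      function(i) generate_particle(spec, z, phi, 0.1)$pixels - clean,
      matrix(0, spec$image_size, spec$image_size)
    )
  })
  sds <- apply(matrix(resid, ncol = n), 1, stats::sd)
  expect_close(sds, 0.1, 0.002) # within 2% of 0.1
  expect_error(generate_particle(spec, z, phi, -0.1), ">= 0")
})

test_that("identical seeds give bit-identical stacks, different seeds differ", {
  spec <- tiny_molecule()
  s1 <- sample_iid_dataset(spec, 20, 0.1, seed = 7)
  s2 <- sample_iid_dataset(spec, 20, 0.1, seed = 7)
  s3 <- sample_iid_dataset(spec, 20, 0.1, seed = 8)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$latents, s2$latents)
  expect_false(identical(s1$latents$z1, s3$latents$z1))
})

test_that("i.i.d. factors are pairwise uncorrelated at the Monte Carlo bound", {
  spec <- tiny_molecule()
  stack <- sample_iid_dataset(spec, 1000, 0, seed = 5)
  lat <- stack$latents
  expect_lt(abs(stats::cor(lat$z1, lat$z2)), 0.1)
  expect_lt(abs(stats::cor(lat$z1, cos(lat$phi))), 0.1)
  expect_lt(abs(stats::cor(lat$z2, cos(lat$phi))), 0.1)
  expect_true(all(lat$phi >= 0 & lat$phi < 2 * pi))
  expect_true(all(abs(lat$z1) <= spec$z_max))
})

test_that("temporal increments follow the stated Laplace law", {
  ns <- asNamespace("conformscape")
  # distributional oracle at large n: variance 2 / rate^2, excess kurtosis 3
  x <- with_test_seed(6, ns$rlaplace(1e5, 0, rate = 1))
  expect_close(stats::var(x), 2, 0.05 * 2)
  exkurt <- mean((x - mean(x))^4) / stats::var(x)^2 - 3
  expect_close(exkurt, 3, 0.1 * 3)
  # independence of component increments
  y <- with_test_seed(61, ns$rlaplace(1e5, 0, rate = 1))
  expect_lt(abs(stats::cor(x, y)), 0.02)

  # stack-level: increments observed in a generated dataset reproduce the
  # law (wide articulation range so no clamping interferes)
  spec <- tiny_molecule()
  spec$z_max <- 20
  stack <- sample_temporal_dataset(spec, temporal_params(1, 1, 3000), 0, seed = 9)
  lat <- stack$latents
  d1 <- lat$z1[lat$t == 1] - lat$z1[lat$t == 0]
  d2 <- lat$z2[lat$t == 1] - lat$z2[lat$t == 0]
  expect_equal(stack$prior_params$n_clamped, 0)
  expect_close(stats::var(c(d1, d2)), 2, 0.15 * 2)
  expect_lt(abs(stats::cor(d1, d2)), 0.05)
})

test_that("a very high rate freezes the dynamics", {
  spec <- tiny_molecule()
  stack <- sample_temporal_dataset(spec, temporal_params(1e3, 1e3, 60), 0, seed = 10)
  x0 <- stack$images[, , stack$latents$t == 0]
  x1 <- stack$images[, , stack$latents$t == 1]
  expect_lt(mean(abs(x1 - x0)), 0.01)
})

test_that("clamping at the articulation boundary is counted", {
  spec <- tiny_molecule() # z_max = pi/2, rate 1 increments clamp often
  stack <- sample_temporal_dataset(spec, temporal_params(1, 1, 400), 0, seed = 11)
  expect_gt(stack$prior_params$n_clamped, 0)
  expect_true(all(abs(stack$latents$z1) <= spec$z_max + 1e-12))
})

test_that("temperature-conditioned sampling matches its schedule", {
  spec <- tiny_molecule()
  sched <- temperature_schedule(
    levels = c(1, 10),
    sigma_per_factor = rbind(c(0.3, 0.01), c(0.3, 0.35))
  )
  stack <- sample_temperature_dataset(spec, 5000, sched, 0, seed = 12)
  lat <- stack$latents
  lo <- lat[lat$tau == 1, ]
  hi <- lat[lat$tau == 10, ]
  # at low temperature one factor is frozen relative to the other
  expect_gt(stats::sd(lo$z1) / stats::sd(lo$z2), 10)
  # per-level sample stds match the schedule within 5% (untruncated regime)
  expect_close(stats::sd(lo$z1), 0.3, 0.05 * 0.3)
  expect_close(stats::sd(lo$z2), 0.01, 0.05 * 0.01)
  expect_close(stats::sd(hi$z2), 0.35, 0.05 * 0.35)
  # non-separating schedules are rejected
  expect_error(
    temperature_schedule(c(1, 10), rbind(c(0.3, 0.3), c(0.3, 0.3))),
    "separating"
  )
})
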