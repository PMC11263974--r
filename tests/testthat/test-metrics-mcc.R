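test_that("MCC is 1 on the identity and on its benign equivalence class", {
  set.seed(51)
  z <- matrix(rnorm(500 * 3), ncol = 3)
  expect_equal(as.numeric(mcc(z, z)), 1.0, tolerance = 1e-12)
  # permuted, sign-flipped, rescaled copies are equivalent
  twisted <- cbind(-2.5 * z[, 3], 0.1 * z[, 1], 7 * z[, 2] + 1)
  expect_equal(as.numeric(mcc(twisted, z)), 1.0, tolerance = 1e-12)
  pairs <- attr(mcc(twisted, z), "pairs")
  expect_equal(pairs[order(pairs[, "latent"]), "factor"], c(3L, 1L, 2L),
    ignore_attr = TRUE
  )
})

test_that("MCC of 45-degree mixed Gaussians equals 1/sqrt(2)", {
  set.seed(52)
  z <- matrix(rnorm(1e5 * 2), ncol = 2)
  r <- sqrt(2) / 2
  mixed <- cbind(r * z[, 1] - r * z[, 2], r * z[, 1] + r * z[, 2])
  expect_close(as.numeric(mcc(mixed, z)), 1 / sqrt(2), 0.01)
})

test_that("the assignment solver agrees with brute-force enumeration on random matrices", {
  set.seed(53)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    f <- k + sample.int(7 - k, 1) - 1L
    cm <- matrix(runif(k * f), k, f)
    z <- matrix(rnorm(40 * k), ncol = k) # unused; direct matrix route below
    a <- solve_assignment(-cm)
    best_assign <- mean(cm[cbind(seq_len(k), a)])
    maps <- asNamespace("conformscape")$injective_maps(k, f)
    best_brute <- max(apply(maps, 1, function(mp) mean(cm[cbind(seq_len(k), mp)])))
    expect_close(best_assign, best_brute, 1e-12)
  }
})

test_that("both MCC matching routes agree end to end", {
  set.seed(54)
  for (i in 1:20) {
    n <- 80
    k <- sample(2:4, 1)
    z <- matrix(rnorm(n * k), ncol = k)
    mixer <- matrix(rnorm(k * k), k, k)
    learned <- z %*% mixer
    expect_equal(
      as.numeric(mcc(learned, z, matching = "assignment")),
      as.numeric(mcc(learned, z, matching = "brute_force")),
      tolerance = 1e-12
    )
  }
})

test_that("MCC is invariant to per-column affine maps and handles unequal counts", {
  set.seed(55)
  z <- matrix(rnorm(300 * 2), ncol = 2)
  m0 <- as.numeric(mcc(z + 0.3 * matrix(rnorm(600), ncol = 2), z))
  affine <- sweep(z + 0.3 * matrix(rnorm(600), ncol = 2), 2, c(2, -0.5), `*`)
  set.seed(55)
  z2 <- matrix(rnorm(300 * 2), ncol = 2)
  m1 <- as.numeric(mcc(
    sweep(z2 + 0.3 * matrix(rnorm(600), ncol = 2), 2, c(2, -0.5), `*`), z2
  ))
  expect_close(m0, m1, 1e-12)
  # more latents than factors: best min(K, F) pairs are scored
  extra <- cbind(z, rnorm(300))
  expect_equal(as.numeric(mcc(extra, z)), 1.0, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  z <- matrix(rnorm(100 * 2), ncol = 2)
  zc <- z
  zc[, 2] <- 3
  colnames(zc) <- c("ok", "flat")
  expect_error(mcc(zc, z), "flat")
  expect_error(mcc(z[1:5, ], z[1:5, ]), "at least 10")
  # spearman option runs and is invariant to monotone transforms
  warped <- cbind(z[, 1]^3, exp(z[, 2]))
  expect_equal(as.numeric(mcc(warped, z, method = "spearman")), 1.0,
    tolerance = 1e-12
  )
})
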