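# Shared fixtures and independent oracles, built in code at test time.

# Small fast geometry for tests that need many renders.
tiny_molecule <- function() {
  toy_molecule_spec(
    image_size = 16,
    core_blobs = data.frame(
      x = c(0, 1), y = c(0, -0.5), amp = c(1, 0.5), width = c(1.2, 0.8)
    ),
    arm_joints = rbind(c(-1.5, 0), c(1.5, 0)),
    arm_length = 2,
    blobs_per_arm = 3,
    blob_width = 0.9,
    rest_angles = c(3 * pi / 4, pi / 4)
  )
}

# Geometry whose blob centres all sit on integer pixel offsets at the rest
# conformation, so 90-degree pose rotations are exact array rotations.
pixel_centred_molecule <- function() {
  toy_molecule_spec(
    image_size = 33,
    core_blobs = data.frame(
      x = c(0, 3, -2), y = c(0, 1, 4), amp = c(1, 0.6, 0.8),
      width = c(2, 1.2, 1.5)
    ),
    arm_joints = rbind(c(-3, 0), c(3, 0)),
    arm_length = 4,
    blobs_per_arm = 4,
    blob_width = 1.5,
    rest_angles = c(pi, 0)
  )
}

# Mirror-symmetric geometry about the vertical axis (for the mirror oracle).
mirror_molecule <- function() {
  toy_molecule_spec(
    image_size = 24,
    core_blobs = data.frame(
      x = c(0, 0), y = c(0, 1.3), amp = c(1, 0.5), width = c(1.5, 0.9)
    ),
    arm_joints = rbind(c(-2, 0), c(2, 0)),
    arm_length = 3,
    blobs_per_arm = 4,
    blob_width = 1.1,
    rest_angles = c(3 * pi / 4, pi / 4)
  )
}

# Independent array-rotation oracle: new[r, c] = old[D + 1 - c, r], derived
# directly from the coordinate convention (x along columns, y along rows,
# counter-clockwise positive).
oracle_rot90 <- function(m) {
  d <- nrow(m)
  out <- matrix(0, d, d)
  for (r in seq_len(d)) {
    for (co in seq_len(d)) {
      out[r, co] <- m[d + 1 - co, r]
    }
  }
  out
}

# Brute-force blob-sum renderer (independent of render_blobs' outer-product
# vectorization): plain double loop over pixels.
oracle_render <- function(spec, z, phi = 0) {
  ns <- asNamespace("conformscape")
  tab <- ns$blob_table(spec, z, phi)
  d <- spec$image_size
  ctr <- (d + 1) / 2
  img <- matrix(0, d, d)
  for (r in seq_len(d)) {
    for (co in seq_len(d)) {
      x <- co - ctr
      y <- r - ctr
      img[r, co] <- sum(
        tab$amp * exp(-((x - tab$x)^2 + (y - tab$y)^2) / (2 * tab$width^2))
      )
    }
  }
  img
}

# A tiny trained_model-shaped object with freshly initialized parameters.
tiny_model <- function(d = 16, K = 2, seed = 1, ...) {
  ns <- asNamespace("conformscape")
  config <- model_config(K = K, hidden_enc = 24, hidden_dec = 24, seed = seed, ...)
  params <- with_test_seed(seed, ns$init_params(d, config))
  ns$new_trained_model(params, config, d, NULL, "vae")
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

expect_close <- function(actual, expected, tol) {
  expect_true(
    all(abs(actual - expected) <= tol),
    label = sprintf(
      "max |actual - expected| = %.3g (tol %.3g)",
      max(abs(actual - expected)), tol
    )
  )
}
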