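# Pose-consistency score (the intervention loss as an evaluation metric),
# the rotation-invariance probe, and a simulator-wired oracle autoencoder
# used as the self-consistency reference for both.

#' Simulator-wired oracle autoencoder
#'
#' A reference autoencoder built directly from the generative model: its
#' decoder is the analytic renderer ([apply_pose()], no interpolation
#' error) and its encoder inverts the renderer by nearest-neighbour lookup
#' in a render library followed by local least-squares refinement. Used as
#' the ground-truth fixture for [pose_consistency_score()] and
#' [rotation_invariance_probe()]: a perfectly pose/conformation-consistent
#' model.
#'
#' @param spec a [toy_molecule_spec()].
#' @param z_grid grid points per conformation axis for the lookup library.
#' @param phi_grid pose grid points for the lookup library.
#' @return an object of class `oracle_autoencoder`.
#' @export
oracle_autoencoder <- function(spec, z_grid = 7, phi_grid = 48) {
  zs <- seq(-spec$z_max, spec$z_max, length.out = z_grid)
  phis <- seq(0, 2 * pi, length.out = phi_grid + 1)[seq_len(phi_grid)]
  grid <- expand.grid(z1 = zs, z2 = zs, phi = phis)
  d <- spec$image_size
  lib <- matrix(0, nrow(grid), d * d)
  for (i in seq_len(nrow(grid))) {
    lib[i, ] <- as.vector(apply_pose(
      spec, c(grid$z1[i], grid$z2[i]), grid$phi[i]
    ))
  }
  structure(
    list(spec = spec, grid = grid, lib = lib, lib_sq = rowSums(lib^2)),
    class = "oracle_autoencoder"
  )
}

oracle_encode_one <- function(oracle, x) {
  spec <- oracle$spec
  # nearest library entry
  d2 <- oracle$lib_sq - 2 * as.vector(oracle$lib %*% x)
  i0 <- which.min(d2)
  z0 <- c(oracle$grid$z1[i0], oracle$grid$z2[i0])
  phi0 <- oracle$grid$phi[i0]
  # refine by least squares; z reparameterized through tanh to stay in range
  clip <- function(v) pmin(pmax(v, -0.999), 0.999)
  par0 <- c(atanh(clip(z0 / spec$z_max)), phi0)
  obj <- function(p) {
    z <- spec$z_max * tanh(p[1:2])
    sum((as.vector(apply_pose(spec, z, p[3])) - x)^2)
  }
  fit <- stats::optim(par0, obj,
    method = "Nelder-Mead",
    control = list(maxit = 600, reltol = 1e-14)
  )
  c(spec$z_max * tanh(fit$par[1:2]), wrap_angle(fit$par[3]))
}

# ---- autoencoder interface ----------------------------------------------
# Both trained models and the oracle expose encode/decode closures over
# flattened image matrices, so the evaluation loops are shared.

ae_interface <- function(x) UseMethod("ae_interface")

#' @export
ae_interface.trained_model <- function(x) {
  model <- x
  d <- model$image_size
  list(
    d = d,
    encode = function(xm) {
      fwd <- encoder_fwd(model$params, xm, model$config)
      list(z = fwd$mu, phi = fwd$phi)
    },
    decode = function(z, phi) {
      dec <- decoder_fwd(model$params, z)
      rotate_bilinear_fwd(dec$canon, phi, d)$out
    }
  )
}

#' @export
ae_interface.oracle_autoencoder <- function(x) {
  oracle <- x
  d <- oracle$spec$image_size
  list(
    d = d,
    encode = function(xm) {
      est <- t(apply(xm, 1, function(row) oracle_encode_one(oracle, row)))
      list(z = est[, 1:2, drop = FALSE], phi = est[, 3])
    },
    decode = function(z, phi) {
      out <- matrix(0, nrow(z), d * d)
      for (i in seq_len(nrow(z))) {
        out[i, ] <- as.vector(apply_pose(oracle$spec, z[i, ], phi[i]))
      }
      out
    }
  )
}

#' Pose-consistency score
#'
#' Evaluation-mode intervention loss: encode a batch, shuffle the poses
#' across the batch, decode the (conformation, shuffled-pose) pairs,
#' re-encode, and average the Euclidean conformation distance plus the
#' geodesic pose distance between intended and recovered latents; gradients
#' are never taken. Averaged over `n_batches` random batches from the
#' stack. Units: latent units + radians; 0 is perfect consistency.
#'
#' Note: a constant encoder trivially zeroes this score, so it is always
#' reported alongside reconstruction error in the benchmark reports.
#'
#' @param model a `trained_model` or [oracle_autoencoder()].
#' @param stack a [particle_stack()] from the same geometry.
#' @param n_batches number of evaluation batches.
#' @param batch_size images per batch (>= 2).
#' @param add_noise add observation noise to the intervened decodes.
#' @param noise_sigma noise std when `add_noise` is `TRUE`.
#' @param seed RNG seed for batch choice and permutations.
#' @return scalar score (>= 0), with per-batch values as attribute
#'   `"per_batch"`.
#' @export
pose_consistency_score <- function(model, stack, n_batches = 20,
                                   batch_size = 32, add_noise = FALSE,
                                   noise_sigma = stack$noise_sigma,
                                   seed = 1) {
  ae <- ae_interface(model)
  if (ae$d != stack$spec$image_size) {
    stop(
      "image-size mismatch between model (", ae$d, ") and stack (",
      stack$spec$image_size, ")"
    )
  }
  x_all <- t(stack_matrix(stack))
  n <- nrow(x_all)
  batch_size <- min(batch_size, n)
  if (batch_size < 2) stop("need at least 2 particles")
  with_seed(seed, {
    vals <- vapply(seq_len(n_batches), function(b) {
      take <- sample.int(n, batch_size)
      xm <- x_all[take, , drop = FALSE]
      enc <- ae$encode(xm)
      perm <- sample.int(batch_size)
      phi_p <- enc$phi[perm]
      xt <- ae$decode(enc$z, phi_p)
      if (add_noise && noise_sigma > 0) {
        xt <- xt + matrix(stats::rnorm(length(xt), 0, noise_sigma), nrow(xt))
      }
      enc2 <- ae$encode(xt)
      mean(sqrt(rowSums((enc2$z - enc$z)^2))) +
        mean(circular_distance(enc2$phi, phi_p))
    }, numeric(1))
    structure(mean(vals), per_batch = vals)
  })
}

#' Rotation-invariance probe
#'
#' Measures how much the conformation representation moves when the input
#' image is rotated by an exact multiple of 90 degrees (no interpolation):
#' the mean conformation-latent displacement normalized by the mean latent
#' norm, and the pose-angle shift error
#' `mean |wrap(phi(rot(x)) - phi(x) - angle)|`. A pose-consistent encoder
#' shows near-zero displacement and near-zero shift error; an encoder with
#' (near-)constant conformation output is flagged `degenerate` because its
#' zero displacement is vacuous.
#'
#' @param model a `trained_model` or [oracle_autoencoder()].
#' @param stack a [particle_stack()].
#' @param k number of 90-degree steps (rotation angle = `k * pi/2`).
#' @param max_images cap on the number of images probed.
#' @return list with `displacement` (dimensionless), `pose_shift_error`
#'   (radians) and `degenerate` (logical).
#' @export
rotation_invariance_probe <- function(model, stack, k = 1, max_images = 512) {
  ae <- ae_interface(model)
  d <- stack$spec$image_size
  n <- min(n_particles(stack), max_images)
  x <- stack$images[, , seq_len(n), drop = FALSE]
  xm <- t(matrix(x, nrow = d * d))
  xr <- vapply(
    seq_len(n),
    function(i) as.vector(rotate_image_90(x[, , i], k)),
    numeric(d * d)
  )
  xrm <- t(xr)
  enc <- ae$encode(xm)
  enc_r <- ae$encode(xrm)
  mean_norm <- mean(sqrt(rowSums(enc$z^2)))
  disp_raw <- mean(sqrt(rowSums((enc_r$z - enc$z)^2)))
  # an encoder with (near-)constant conformation output is vacuously
  # invariant; flag it rather than reward it
  degenerate <- max(apply(enc$z, 2, stats::sd)) < 1e-6
  displacement <- if (mean_norm < 1e-12) 0 else disp_raw / mean_norm
  angle <- k * pi / 2
  pose_shift_error <- mean(circular_distance(enc_r$phi, enc$phi + angle))
  list(
    displacement = displacement,
    pose_shift_error = pose_shift_error,
    degenerate = degenerate
  )
}
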