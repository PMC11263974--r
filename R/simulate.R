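#' Particle stack container
#'
#' Bundles simulated particle images with their ground-truth latents and the
#' generating configuration. Images are stored as a `D x D x n` array;
#' latents as a data.frame with one row per image and columns `z1`, `z2`
#' (conformation angles, radians), `phi` (pose, radians in `[0, 2pi)`) and,
#' depending on the regime, `t` (frame index), `pair` (pair id) and `tau`
#' (temperature label).
#'
#' @param images `D x D x n` array.
#' @param latents data.frame, `n` rows.
#' @param spec the generating [toy_molecule_spec()].
#' @param seed integer seed the stack was generated with (recorded for
#'   provenance; regeneration with the same seed is bit-identical).
#' @param mode one of `"iid"`, `"temporal"`, `"temperature"`.
#' @param noise_sigma pixel-noise std used.
#' @param prior_params list of the sampling parameters.
#' @return an object of class `particle_stack`.
#' @export
particle_stack <- function(images, latents, spec, seed, mode, noise_sigma,
                           prior_params = list()) {
  stopifnot(
    is.array(images), length(dim(images)) == 3,
    dim(images)[3] == nrow(latents),
    mode %in% c("iid", "temporal", "temperature")
  )
  structure(
    list(
      images = images,
      latents = latents,
      spec = spec,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      mode = mode,
      noise_sigma = noise_sigma,
      prior_params = prior_params
    ),
    class = "particle_stack"
  )
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(
    "particle_stack:", d[3], "images of", d[1], "x", d[2],
    "| mode:", x$mode, "| noise_sigma:", x$noise_sigma,
    "| seed:", x$seed, "\n"
  )
  invisible(x)
}

#' Number of particles in a stack
#' @param stack a `particle_stack`.
#' @export
n_particles <- function(stack) dim(stack$images)[3]

# Images flattened to an n x D^2 matrix (row-major per image by column-major
# pixel order; the same order everywhere, including the models).
stack_matrix <- function(stack) {
  d <- dim(stack$images)
  matrix(stack$images, nrow = d[1] * d[2], ncol = d[3])
}

render_stack <- function(spec, lat, noise_sigma) {
  n <- nrow(lat)
  d <- spec$image_size
  images <- array(0, dim = c(d, d, n))
  for (i in seq_len(n)) {
    images[, , i] <- generate_particle(
      spec, c(lat$z1[i], lat$z2[i]), lat$phi[i], noise_sigma
    )$pixels
  }
  images
}

#' Sample an i.i.d. particle dataset
#'
#' Conformation angles are drawn i.i.d. per component from a truncated
#' normal prior (default `N(0, (pi/6)^2)` truncated to `[-z_max, z_max]`),
#' the pose uniformly on `[0, 2pi)`; all factors mutually independent.
#'
#' @param spec a [toy_molecule_spec()].
#' @param n number of particles (>= 1).
#' @param noise_sigma pixel-noise std.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param z_sd std of the (untruncated) conformation prior, radians.
#' @return a [particle_stack()] with `mode = "iid"`.
#' @export
sample_iid_dataset <- function(spec, n, noise_sigma = 0.1, seed = 1,
                               z_sd = pi / 6) {
  stopifnot(n >= 1, z_sd > 0)
  with_seed(seed, {
    lat <- data.frame(
      z1 = rtruncnorm(n, 0, z_sd, -spec$z_max, spec$z_max),
      z2 = rtruncnorm(n, 0, z_sd, -spec$z_max, spec$z_max),
      phi = stats::runif(n, 0, 2 * pi)
    )
    images <- render_stack(spec, lat, noise_sigma)
    particle_stack(images, lat, spec, seed, "iid", noise_sigma,
      prior_params = list(z_sd = z_sd)
    )
  })
}

#' Temporal sampling parameters
#'
#' @param lap_rate Laplace rate for conformation increments (density
#'   `(rate/2) exp(-rate |d|)`; variance `2 / rate^2`).
#' @param pose_rate Laplace rate for pose increments.
#' @param n_pairs number of frame pairs.
#' @return a list of class `temporal_params`.
#' @export
temporal_params <- function(lap_rate = 1, pose_rate = 1, n_pairs = 1000) {
  stopifnot(lap_rate > 0, pose_rate > 0, n_pairs >= 1)
  structure(
    list(
      lap_rate = lap_rate, pose_rate = pose_rate,
      n_pairs = as.integer(n_pairs)
    ),
    class = "temporal_params"
  )
}

#' Sample a temporal particle dataset of frame pairs
#'
#' Generates `n_pairs` independent pairs `(x_t, x_{t+1})`. The first frame's
#' factors follow the i.i.d. prior; the second frame adds, independently per
#' conformation component, a Laplace increment with rate `lap_rate` (clamped
#' to the articulation range) and a Laplace pose increment with rate
#' `pose_rate` (wrapped to the circle). Clamping events are counted in
#' `prior_params$n_clamped`.
#'
#' Images are interleaved: pair `i` occupies slices `2i - 1` (frame `t = 0`)
#' and `2i` (frame `t = 1`); latents carry `t` and `pair`.
#'
#' @inheritParams sample_iid_dataset
#' @param params a [temporal_params()].
#' @return a [particle_stack()] with `mode = "temporal"`.
#' @export
sample_temporal_dataset <- function(spec, params, noise_sigma = 0.1,
                                    seed = 1, z_sd = pi / 6) {
  stopifnot(inherits(params, "temporal_params"))
  n <- params$n_pairs
  with_seed(seed, {
    z1_0 <- rtruncnorm(n, 0, z_sd, -spec$z_max, spec$z_max)
    z2_0 <- rtruncnorm(n, 0, z_sd, -spec$z_max, spec$z_max)
    phi_0 <- stats::runif(n, 0, 2 * pi)
    d1 <- rlaplace(n, 0, params$lap_rate)
    d2 <- rlaplace(n, 0, params$lap_rate)
    dphi <- rlaplace(n, 0, params$pose_rate)
    z1_1 <- pmin(pmax(z1_0 + d1, -spec$z_max), spec$z_max)
    z2_1 <- pmin(pmax(z2_0 + d2, -spec$z_max), spec$z_max)
    phi_1 <- wrap_angle_2pi(phi_0 + dphi)
    n_clamped <- sum(z1_1 != z1_0 + d1) + sum(z2_1 != z2_0 + d2)
    idx <- rep(seq_len(n), each = 2)
    frame <- rep(c(0L, 1L), n)
    lat <- data.frame(
      z1 = ifelse(frame == 0L, z1_0[idx], z1_1[idx]),
      z2 = ifelse(frame == 0L, z2_0[idx], z2_1[idx]),
      phi = ifelse(frame == 0L, phi_0[idx], phi_1[idx]),
      t = frame,
      pair = idx
    )
    images <- render_stack(spec, lat, noise_sigma)
    particle_stack(images, lat, spec, seed, "temporal", noise_sigma,
      prior_params = list(
        lap_rate = params$lap_rate, pose_rate = params$pose_rate,
        n_pairs = n, z_sd = z_sd, n_clamped = n_clamped
      )
    )
  })
}

#' Temperature schedule for temperature-conditioned sampling
#'
#' Per temperature level, each conformation component is drawn from a
#' zero-mean normal with a level-specific std. The schedule must be
#' separating: at the lowest level at least one component's std is less than
#' a tenth of its std at the highest level, so the levels genuinely isolate
#' degrees of freedom.
#'
#' @param levels numeric vector of temperature labels (ascending order,
#'   arbitrary units; at least two).
#' @param sigma_per_factor matrix with one row per level and one column per
#'   conformation component; entries are stds (radians).
#' @return a list of class `temperature_schedule`.
#' @export
temperature_schedule <- function(levels, sigma_per_factor) {
  stopifnot(
    length(levels) >= 2, !is.unsorted(levels),
    is.matrix(sigma_per_factor),
    nrow(sigma_per_factor) == length(levels),
    all(sigma_per_factor >= 0)
  )
  lo <- sigma_per_factor[1, ]
  hi <- sigma_per_factor[nrow(sigma_per_factor), ]
  if (!any(lo < 0.1 * hi)) {
    stop(
      "schedule is not separating: no factor std at the lowest level is ",
      "< 0.1 x its std at the highest level"
    )
  }
  structure(
    list(levels = levels, sigma_per_factor = sigma_per_factor),
    class = "temperature_schedule"
  )
}

#' Sample a temperature-conditioned particle dataset
#'
#' For each temperature level, conformation components are drawn from
#' zero-mean truncated normals with the level's per-factor stds; the pose is
#' uniform. The temperature label is stored per particle (column `tau`),
#' supporting conditional (auxiliary-variable) training schemes downstream.
#'
#' @inheritParams sample_iid_dataset
#' @param n_per_level particles per temperature level.
#' @param schedule a [temperature_schedule()].
#' @return a [particle_stack()] with `mode = "temperature"`.
#' @export
sample_temperature_dataset <- function(spec, n_per_level, schedule,
                                       noise_sigma = 0.1, seed = 1) {
  stopifnot(inherits(schedule, "temperature_schedule"), n_per_level >= 1)
  with_seed(seed, {
    parts <- lapply(seq_along(schedule$levels), function(l) {
      s <- schedule$sigma_per_factor[l, ]
      data.frame(
        z1 = rtruncnorm(n_per_level, 0, s[1], -spec$z_max, spec$z_max),
        z2 = rtruncnorm(n_per_level, 0, s[2], -spec$z_max, spec$z_max),
        phi = stats::runif(n_per_level, 0, 2 * pi),
        tau = schedule$levels[l]
      )
    })
    lat <- do.call(rbind, parts)
    images <- render_stack(spec, lat, noise_sigma)
    particle_stack(images, lat, spec, seed, "temperature", noise_sigma,
      prior_params = list(
        levels = schedule$levels,
        sigma_per_factor = schedule$sigma_per_factor,
        n_per_level = n_per_level
      )
    )
  })
}
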