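#' Articulated toy-particle geometry
#'
#' Defines the simulated molecule used throughout the benchmark: a rigid core
#' of Gaussian blobs plus two arms that articulate independently about fixed
#' joints. The two arm angles are the molecule's conformational degrees of
#' freedom; a single in-plane rotation of the whole scene is its pose.
#'
#' Coordinates are in pixels relative to the image centre at
#' `((D+1)/2, (D+1)/2)` in 1-indexed matrix coordinates, with `x` along
#' columns and `y` along rows. Angles are counter-clockwise radians in that
#' frame.
#'
#' @param image_size pixels per side of the square image (>= 16).
#' @param core_blobs data.frame with columns `x`, `y` (px offsets from
#'   centre), `amp` (peak amplitude) and `width` (Gaussian std, px). Must
#'   contain at least one blob that breaks 180-degree rotational symmetry of
#'   the whole scene, so that pose is identifiable from a noise-free image.
#' @param arm_joints 2x2 matrix; row i is the (x, y) anchor of arm i.
#' @param arm_length arm length in px.
#' @param blobs_per_arm number of blobs spaced evenly along each arm.
#' @param blob_width Gaussian std (px) of the arm blobs.
#' @param arm_amp peak amplitude of each arm blob.
#' @param rest_angles length-2 vector; direction (radians) of each arm at
#'   conformation (0, 0).
#' @param z_max articulation limit: conformations satisfy `|z_i| <= z_max`.
#'
#' @return an object of class `toy_molecule_spec`.
#' @seealso [default_molecule()], [render_conformation()], [apply_pose()]
#' @export
toy_molecule_spec <- function(image_size,
                              core_blobs,
                              arm_joints,
                              arm_length,
                              blobs_per_arm,
                              blob_width,
                              arm_amp = 0.7,
                              rest_angles = c(3 * pi / 4, pi / 4),
                              z_max = pi / 2) {
  stopifnot(
    is.numeric(image_size), length(image_size) == 1, image_size >= 16,
    is.data.frame(core_blobs),
    all(c("x", "y", "amp", "width") %in% names(core_blobs)),
    nrow(core_blobs) >= 1,
    is.matrix(arm_joints), all(dim(arm_joints) == c(2, 2)),
    arm_length > 0, blobs_per_arm >= 1, blob_width > 0,
    length(rest_angles) == 2, z_max > 0
  )
  if (all(arm_joints[1, ] == arm_joints[2, ])) {
    stop("arm joints must be distinct")
  }
  spec <- structure(
    list(
      image_size = as.integer(image_size),
      core_blobs = core_blobs,
      arm_joints = arm_joints,
      arm_length = arm_length,
      blobs_per_arm = as.integer(blobs_per_arm),
      blob_width = blob_width,
      arm_amp = arm_amp,
      rest_angles = rest_angles,
      z_max = z_max
    ),
    class = "toy_molecule_spec"
  )
  # Whole-scene reach at the most extreme articulation; arms must stay in
  # frame (with room for the blob profile) for every |z_i| <= z_max and pose.
  reach <- max(
    sqrt(rowSums(arm_joints^2)) + arm_length,
    sqrt(core_blobs$x^2 + core_blobs$y^2)
  )
  margin <- (image_size - 1) / 2 - reach
  if (margin < 3 * max(blob_width, core_blobs$width)) {
    stop(
      "arm or core blob can leave the field of view: reach ", round(reach, 2),
      " px leaves margin ", round(margin, 2),
      " px (< 3 blob widths) at image_size ", image_size
    )
  }
  if (!breaks_rotational_symmetry(spec)) {
    stop("core_blobs must break 180-degree rotational symmetry of the scene")
  }
  spec
}

# A noise-free render at phi = 0 must differ from its own 180-degree
# rotation, otherwise pose is only identifiable modulo pi.
breaks_rotational_symmetry <- function(spec, tol = 1e-3) {
  img <- render_blobs(spec, blob_table(spec, c(0, 0), phi = 0))
  rot <- rotate_image_90(rotate_image_90(img))
  max(abs(img - rot)) > tol * max(abs(img))
}

#' Default benchmark molecule
#'
#' 32x32 grid; a rigid core of three blobs (one off-axis marker that breaks
#' 180-degree symmetry) and two five-blob arms anchored at (-3, 0) and
#' (3, 0) with rest directions 135 and 45 degrees. All motion stays in frame
#' for |z| <= pi/2, and blob tails are far enough from the image border that
#' the integrated density is conserved to high precision.
#'
#' @return a `toy_molecule_spec`.
#' @export
default_molecule <- function() {
  toy_molecule_spec(
    image_size = 32,
    core_blobs = data.frame(
      x = c(0, 1.5, -1.0),
      y = c(0, -1.0, 1.5),
      amp = c(1.0, 0.6, 0.8),
      width = c(2.0, 1.2, 1.5)
    ),
    arm_joints = rbind(c(-3, 0), c(3, 0)),
    arm_length = 4.5,
    blobs_per_arm = 5,
    blob_width = 1.5,
    arm_amp = 0.7,
    rest_angles = c(3 * pi / 4, pi / 4),
    z_max = pi / 2
  )
}

# All blob centres/amps/widths of the posed scene as a data.frame.
# Conformation articulates each arm about its joint; pose rotates every
# centre about the image centre. Fully analytic: no resampling anywhere.
blob_table <- function(spec, z, phi = 0) {
  stopifnot(length(z) == 2)
  core <- data.frame(
    x = spec$core_blobs$x,
    y = spec$core_blobs$y,
    amp = spec$core_blobs$amp,
    width = spec$core_blobs$width
  )
  arms <- lapply(1:2, function(i) {
    theta <- spec$rest_angles[i] + z[i]
    frac <- seq_len(spec$blobs_per_arm) / spec$blobs_per_arm
    data.frame(
      x = spec$arm_joints[i, 1] + frac * spec$arm_length * cos(theta),
      y = spec$arm_joints[i, 2] + frac * spec$arm_length * sin(theta),
      amp = spec$arm_amp,
      width = spec$blob_width
    )
  })
  tab <- rbind(core, arms[[1]], arms[[2]])
  if (phi != 0) {
    cphi <- cos(phi)
    sphi <- sin(phi)
    x <- tab$x * cphi - tab$y * sphi
    y <- tab$x * sphi + tab$y * cphi
    tab$x <- x
    tab$y <- y
  }
  tab
}

# Rasterize a blob table onto the pixel grid.
render_blobs <- function(spec, tab) {
  d <- spec$image_size
  ctr <- (d + 1) / 2
  xs <- seq_len(d) - ctr # column coordinates
  ys <- seq_len(d) - ctr # row coordinates
  img <- matrix(0, d, d)
  for (b in seq_len(nrow(tab))) {
    gx <- exp(-(xs - tab$x[b])^2 / (2 * tab$width[b]^2))
    gy <- exp(-(ys - tab$y[b])^2 / (2 * tab$width[b]^2))
    img <- img + tab$amp[b] * (gy %o% gx)
  }
  img
}

#' Render the canonical (pose-free) image of a conformation
#'
#' Places the arm blobs along each articulated arm and sums all Gaussian
#' blobs analytically on the pixel grid. Because every conformation moves
#' rigid blobs without changing their number, amplitude or width, the
#' integrated density of the render is a spec-determined constant,
#' independent of the conformation (volume preservation).
#'
#' @param spec a [toy_molecule_spec()].
#' @param z length-2 conformation vector (radians relative to the rest
#'   angles); must satisfy `|z_i| <= z_max`.
#' @return an `image_size` x `image_size` matrix.
#' @export
render_conformation <- function(spec, z) {
  check_conformation(spec, z)
  render_blobs(spec, blob_table(spec, z, phi = 0))
}

check_conformation <- function(spec, z) {
  if (length(z) != 2 || any(!is.finite(z))) {
    stop("conformation z must be a finite length-2 vector")
  }
  if (any(abs(z) > spec$z_max + 1e-12)) {
    stop(
      "conformation out of range: |z| = (",
      paste(signif(abs(z), 4), collapse = ", "),
      ") exceeds z_max = ", signif(spec$z_max, 4)
    )
  }
  invisible(TRUE)
}

#' Render a posed particle image
#'
#' Applies the in-plane pose rotation analytically: every blob centre is
#' rotated about the image centre before rasterization, so the posed image
#' has no interpolation error. `apply_pose(spec, z, 0)` is identical to
#' [render_conformation()].
#'
#' @inheritParams render_conformation
#' @param phi pose angle, counter-clockwise radians.
#' @return an `image_size` x `image_size` matrix.
#' @export
apply_pose <- function(spec, z, phi) {
  check_conformation(spec, z)
  stopifnot(is.finite(phi))
  render_blobs(spec, blob_table(spec, z, phi = phi))
}

#' Rotate an image array by a multiple of 90 degrees
#'
#' Exact array rotation (no interpolation), counter-clockwise in the same
#' angular convention as [apply_pose()]: `rotate_image_90(apply_pose(s, z, 0))`
#' equals `apply_pose(s, z, pi/2)` whenever all blob centres lie on integer
#' pixel offsets.
#'
#' @param img square matrix.
#' @param k number of 90-degree steps (default 1).
#' @return rotated matrix.
#' @export
rotate_image_90 <- function(img, k = 1) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) {
    img <- t(img[nrow(img):1, , drop = FALSE])
  }
  img
}

#' Generate one noisy particle image
#'
#' Implements the image-formation model: render the conformation, apply the
#' pose, then add i.i.d. Gaussian pixel noise.
#'
#' @inheritParams apply_pose
#' @param noise_sigma std of the additive Gaussian noise (>= 0).
#' @return a list with `pixels` (matrix) and `noise_sigma`, class
#'   `particle_image`. Consumes the current RNG stream deterministically.
#' @export
generate_particle <- function(spec, z, phi, noise_sigma) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  img <- apply_pose(spec, z, phi)
  if (noise_sigma > 0) {
    img <- img + matrix(
      stats::rnorm(length(img), 0, noise_sigma),
      nrow(img), ncol(img)
    )
  }
  structure(list(pixels = img, noise_sigma = noise_sigma),
    class = "particle_image"
  )
}
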