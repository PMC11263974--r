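# Particle-stack bundle: MRCS images + STAR metadata + ground-truth CSV +
# YAML provenance, written and read as one unit.

#' Write a particle stack to disk
#'
#' Produces four mutually consistent files:
#' \itemize{
#'   \item `<prefix>.mrcs` — the images (MRC2014 mode 2; see [write_mrcs()]);
#'   \item `<prefix>.star` — per-particle metadata: `_rlnImageName`
#'     (`index@file`), `_rlnAnglePsi` (pose in degrees, RELION in-plane
#'     convention), and ground-truth fields under the `_cs` prefix
#'     (conformation angles in radians, frame index, pair id, temperature);
#'   \item `<prefix>_truth.csv` — the ground-truth latents as plain CSV, so
#'     downstream scoring never needs a STAR parser;
#'   \item `<prefix>_meta.yaml` — molecule geometry, sampling mode, seed,
#'     noise level, prior parameters, and MD5 checksums of the other three
#'     files.
#' }
#' Output bytes are deterministic given the stack. Pose is stored in
#' degrees on disk and radians in memory; the conversion lives only here
#' and in [read_particle_stack()].
#'
#' @param stack a [particle_stack()].
#' @param prefix path prefix for the four files.
#' @return a `stack_bundle`: list of the four paths plus checksums.
#' @export
write_particle_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "particle_stack"))
  mrcs_path <- paste0(prefix, ".mrcs")
  star_path <- paste0(prefix, ".star")
  csv_path <- paste0(prefix, "_truth.csv")
  meta_path <- paste0(prefix, "_meta.yaml")
  dir.create(dirname(mrcs_path), showWarnings = FALSE, recursive = TRUE)
  write_mrcs(stack$images, mrcs_path)
  n <- n_particles(stack)
  lat <- stack$latents
  star <- data.frame(
    `_rlnImageName` = sprintf("%06d@%s", seq_len(n), basename(mrcs_path)),
    `_rlnAnglePsi` = lat$phi * 180 / pi,
    `_csConfZ1` = lat$z1,
    `_csConfZ2` = lat$z2,
    check.names = FALSE
  )
  if (!is.null(lat$t)) star[["_csFrameIndex"]] <- lat$t
  if (!is.null(lat$pair)) star[["_csPairIndex"]] <- lat$pair
  if (!is.null(lat$tau)) star[["_csTemperature"]] <- lat$tau
  write_star(star, star_path)
  csv_df <- lat
  csv_txt <- vapply(csv_df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(n))
  if (n == 1) csv_txt <- matrix(csv_txt, nrow = 1)
  writeLines(
    c(
      paste(names(csv_df), collapse = ","),
      apply(csv_txt, 1, paste, collapse = ",")
    ),
    csv_path
  )
  spec <- stack$spec
  meta <- list(
    format_version = 1L,
    mode = stack$mode,
    seed = stack$seed,
    noise_sigma = stack$noise_sigma,
    n_particles = n,
    prior_params = stack$prior_params,
    molecule = list(
      image_size = spec$image_size,
      core_blobs = as.list(spec$core_blobs),
      arm_joints = as.vector(t(spec$arm_joints)),
      arm_length = spec$arm_length,
      blobs_per_arm = spec$blobs_per_arm,
      blob_width = spec$blob_width,
      arm_amp = spec$arm_amp,
      rest_angles = spec$rest_angles,
      z_max = spec$z_max
    ),
    checksums = list(
      mrcs = unname(tools::md5sum(mrcs_path)),
      star = unname(tools::md5sum(star_path)),
      truth_csv = unname(tools::md5sum(csv_path))
    )
  )
  yaml::write_yaml(meta, meta_path, precision = 17)
  structure(
    list(
      mrcs_path = mrcs_path, star_path = star_path,
      truth_csv_path = csv_path, meta_path = meta_path,
      checksums = meta$checksums
    ),
    class = "stack_bundle"
  )
}

#' Read a particle stack written by [write_particle_stack()]
#'
#' Validates checksums and mutual particle counts (count mismatch is a
#' hard error); unknown STAR columns are ignored with a warning; a missing
#' truth CSV yields a stack with empty latents and a warning (external
#' stacks can still be scored for reconstruction).
#'
#' @param prefix the path prefix the bundle was written with.
#' @return a [particle_stack()].
#' @export
read_particle_stack <- function(prefix) {
  mrcs_path <- paste0(prefix, ".mrcs")
  star_path <- paste0(prefix, ".star")
  csv_path <- paste0(prefix, "_truth.csv")
  meta_path <- paste0(prefix, "_meta.yaml")
  if (!file.exists(meta_path)) stop("no stack metadata at ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  for (nm in c("mrcs", "star")) {
    path <- c(mrcs = mrcs_path, star = star_path)[[nm]]
    got <- unname(tools::md5sum(path))
    if (!identical(got, meta$checksums[[nm]])) {
      stop("checksum mismatch for ", path, " (file modified or corrupted)")
    }
  }
  m <- meta$molecule
  spec <- toy_molecule_spec(
    image_size = m$image_size,
    core_blobs = as.data.frame(m$core_blobs),
    arm_joints = matrix(unlist(m$arm_joints), 2, 2, byrow = TRUE),
    arm_length = m$arm_length,
    blobs_per_arm = m$blobs_per_arm,
    blob_width = m$blob_width,
    arm_amp = m$arm_amp,
    rest_angles = unlist(m$rest_angles),
    z_max = m$z_max
  )
  mrc <- read_mrcs(mrcs_path)
  star <- read_star(star_path)
  n <- dim(mrc$images)[3]
  if (nrow(star) != n) {
    stop(
      "particle count mismatch: MRCS holds ", n, " sections but STAR has ",
      nrow(star), " rows"
    )
  }
  known <- c(
    "_rlnImageName", "_rlnAnglePsi", "_csConfZ1", "_csConfZ2",
    "_csFrameIndex", "_csPairIndex", "_csTemperature"
  )
  extra <- setdiff(names(star), known)
  if (length(extra) > 0) {
    warning("ignoring unknown STAR fields: ", paste(extra, collapse = ", "))
  }
  if (file.exists(csv_path)) {
    got <- unname(tools::md5sum(csv_path))
    if (!identical(got, meta$checksums$truth_csv)) {
      stop("checksum mismatch for ", csv_path)
    }
    lat <- utils::read.csv(csv_path)
    if (nrow(lat) != n) {
      stop(
        "particle count mismatch: MRCS holds ", n,
        " sections but truth CSV has ", nrow(lat), " rows"
      )
    }
  } else {
    warning("no ground-truth sidecar at ", csv_path, "; latents will be empty")
    lat <- data.frame(
      z1 = rep(NA_real_, n), z2 = rep(NA_real_, n),
      phi = star[["_rlnAnglePsi"]] * pi / 180
    )
  }
  particle_stack(
    mrc$images, lat, spec,
    seed = meta$seed, mode = meta$mode,
    noise_sigma = meta$noise_sigma,
    prior_params = meta$prior_params %||% list()
  )
}
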