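# LatentTable and MetricReport containers: the substrate and output of the
# metrics layer.

#' Build a latent table from a model and a ground-truth stack
#'
#' Pairs learned latents with ground-truth factors for N particles. Learned
#' columns are the conformation posterior means (`learned_z*`) and, when
#' `include_pose` is `TRUE`, the pose angle (`learned_pose`). Factor
#' columns are the true conformation angles and the true pose angle
#' (`factor_phi`, wrapped to `(-pi, pi]`).
#'
#' The learned pose angle is gauge-aligned before tabulation: the global
#' circular offset `atan2(mean sin(phi_hat - phi_true), mean cos(...))` is
#' removed, since a constant rotation of the pose readout is part of the
#' benign equivalence class (like sign and scale for linear latents) but
#' would otherwise corrupt a linear correlation through angle wrap-around.
#'
#' @param model a `trained_model` (or anything [encode()] accepts via
#'   `learned` below).
#' @param stack a [particle_stack()] with ground-truth latents.
#' @param include_pose include the pose angle column in both blocks.
#' @return a `latent_table`: list with `learned` and `factors` matrices
#'   (column-labelled), `n`, and `degenerate` (labels of learned columns
#'   with (near-)zero variance).
#' @export
latent_table <- function(model, stack, include_pose = TRUE) {
  post <- encode(model, stack)
  learned <- post$z_mean
  colnames(learned) <- paste0("learned_z", seq_len(ncol(learned)))
  fac <- cbind(
    factor_z1 = stack$latents$z1,
    factor_z2 = stack$latents$z2
  )
  if (include_pose) {
    phi_true <- stack$latents$phi
    delta <- atan2(
      mean(sin(post$pose_angle - phi_true)),
      mean(cos(post$pose_angle - phi_true))
    )
    learned <- cbind(learned, learned_pose = wrap_angle(post$pose_angle - delta))
    fac <- cbind(fac, factor_phi = wrap_angle(phi_true))
  }
  new_latent_table(learned, fac)
}

new_latent_table <- function(learned, factors) {
  learned <- as.matrix(learned)
  factors <- as.matrix(factors)
  stopifnot(nrow(learned) == nrow(factors))
  if (anyNA(learned) || anyNA(factors)) {
    stop("latent table must not contain NaN/NA")
  }
  # scores themselves enforce their own minimum N; the container allows N >= 1
  sds <- if (nrow(learned) > 1) apply(learned, 2, stats::sd) else rep(0, ncol(learned))
  degenerate <- colnames(learned)[sds < 1e-10] %||% character(0)
  structure(
    list(
      learned = learned, factors = factors, n = nrow(learned),
      degenerate = degenerate
    ),
    class = "latent_table"
  )
}

#' @export
print.latent_table <- function(x, ...) {
  cat(
    "latent_table: N =", x$n, "|", ncol(x$learned), "learned x",
    ncol(x$factors), "factors\n"
  )
  if (length(x$degenerate) > 0) {
    cat("  degenerate learned columns:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Metric report container
#'
#' Named scores with provenance (seed, sample size, configuration echo,
#' warnings). Serialized to JSON by [write_report()].
#'
#' @param scores named numeric vector or list of metric values.
#' @param seed seed the scores were computed under.
#' @param n_samples number of samples scored.
#' @param config configuration echo (list).
#' @param warnings character vector of caveats (e.g. degenerate columns).
#' @return an object of class `metric_report`.
#' @export
metric_report <- function(scores, seed = NA_integer_, n_samples = NA_integer_,
                          config = list(), warnings = character(0)) {
  scores <- as.list(scores)
  stopifnot(length(scores) == 0 || !is.null(names(scores)))
  structure(
    list(
      schema_version = 1L,
      scores = scores,
      seed = seed,
      n_samples = n_samples,
      config = config,
      warnings = as.character(warnings)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (seed", x$seed, ", n =", x$n_samples, ")\n")
  for (nm in names(x$scores)) {
    cat(sprintf("  %-24s %.6g\n", nm, as.numeric(x$scores[[nm]])))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
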