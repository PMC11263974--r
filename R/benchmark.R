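# End-to-end paired benchmarks: simulate -> train baseline and treated
# variant over seeds -> evaluate -> compare on per-metric medians.

#' Benchmark configuration
#'
#' Desk-scale defaults: 2000 particles (i.i.d.) or 2000 frame pairs
#' (temporal), 32x32 images at pixel-noise 0.1, up to 30 epochs. The
#' temporal arm uses data rate 1 with a VAE at `beta = 1`, `gamma = 10` and
#' transition-prior rate 10.
#'
#' @param n_particles particles for the i.i.d. experiment.
#' @param n_pairs frame pairs for the temporal experiment.
#' @param noise_sigma pixel-noise std.
#' @param epochs training epochs.
#' @param K conformation latent dimensions.
#' @param alpha_pose intervention-penalty weight (PoseVAE arm).
#' @param beta,gamma,lap_rate_prior VAE / SlowVAE weights.
#' @param lap_rate,pose_rate temporal data rates.
#' @param spec molecule geometry (default [default_molecule()]).
#' @param eval_n cap on particles used for metric evaluation.
#' @param pose_warm_start physics-informed pose-pathway initialization for
#'   both arms (see [model_config()]).
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_particles = 2000, n_pairs = 2000,
                             noise_sigma = 0.1, epochs = 30, K = 2,
                             alpha_pose = 4, beta = 1, gamma = 10,
                             lap_rate_prior = 10, lap_rate = 1,
                             pose_rate = 1, spec = default_molecule(),
                             eval_n = 4000, pose_warm_start = FALSE) {
  structure(
    list(
      n_particles = n_particles, n_pairs = n_pairs,
      noise_sigma = noise_sigma, epochs = epochs, K = K,
      alpha_pose = alpha_pose, beta = beta, gamma = gamma,
      lap_rate_prior = lap_rate_prior, lap_rate = lap_rate,
      pose_rate = pose_rate, spec = spec, eval_n = eval_n,
      pose_warm_start = isTRUE(pose_warm_start)
    ),
    class = "benchmark_config"
  )
}

config_echo <- function(config) {
  out <- unclass(config)
  out$spec <- list(
    image_size = config$spec$image_size,
    blobs_per_arm = config$spec$blobs_per_arm,
    arm_length = config$spec$arm_length
  )
  out
}

subsample_stack <- function(stack, n_max, seed) {
  n <- n_particles(stack)
  if (n <= n_max) {
    return(stack)
  }
  keep <- with_seed(seed, sort(sample.int(n, n_max)))
  particle_stack(
    stack$images[, , keep, drop = FALSE], stack$latents[keep, , drop = FALSE],
    stack$spec, stack$seed, stack$mode, stack$noise_sigma, stack$prior_params
  )
}

new_comparison_report <- function(experiment, baseline, treated, per_seed,
                                  higher_better, config, seeds) {
  per_seed <- per_seed[order(per_seed$metric, per_seed$variant, per_seed$seed), ]
  rownames(per_seed) <- NULL
  metrics <- unique(per_seed$metric)
  med <- function(v, m) {
    stats::median(per_seed$value[per_seed$variant == v & per_seed$metric == m])
  }
  medians <- data.frame(
    metric = metrics,
    baseline = vapply(metrics, med, numeric(1), v = baseline),
    treated = vapply(metrics, med, numeric(1), v = treated),
    higher_better = unname(higher_better[metrics])
  )
  rownames(medians) <- NULL
  win <- ifelse(medians$higher_better,
    medians$treated > medians$baseline,
    medians$treated < medians$baseline
  )
  structure(
    list(
      experiment = experiment,
      baseline = baseline,
      treated = treated,
      per_seed = per_seed,
      medians = medians,
      win_count = sum(win),
      n_metrics = length(metrics),
      higher_better = higher_better,
      config = config,
      seeds = seeds
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(
    "comparison_report [", x$experiment, "]: ", x$treated, " vs ", x$baseline,
    " over seeds ", paste(x$seeds, collapse = ","), "\n",
    sep = ""
  )
  print(x$medians, row.names = FALSE)
  cat("win_count:", x$win_count, "of", x$n_metrics, "\n")
  invisible(x)
}

evaluate_pose_variant <- function(model, stack, seed) {
  el <- elbo_loss(model, stack)
  ps <- pose_consistency_score(model, stack, seed = seed)
  lt <- latent_table(model, stack, include_pose = TRUE)
  m_all <- mcc(lt$learned, lt$factors)
  m_conf <- mcc(
    lt$learned[, startsWith(colnames(lt$learned), "learned_z"), drop = FALSE],
    lt$factors[, c("factor_z1", "factor_z2")]
  )
  probe <- rotation_invariance_probe(model, stack)
  c(
    recon = el$recon, kl = el$kl, pose_consistency = as.numeric(ps),
    mcc_all = as.numeric(m_all), mcc_conformation = as.numeric(m_conf),
    rotation_displacement = probe$displacement
  )
}

#' Run the pose-disentanglement experiment (VAE vs PoseVAE)
#'
#' Paired design: for each seed, one i.i.d. dataset and one parameter
#' initialization are shared by both variants; the treated arm adds the
#' pose-intervention penalty. Evaluates reconstruction, KL,
#' pose-consistency score, MCC over all latents, MCC over conformation
#' latents, and the rotation-invariance displacement, and counts on how
#' many per-metric medians the PoseVAE beats the VAE (lower is better for
#' losses, higher for MCC).
#'
#' @param config a [benchmark_config()].
#' @param seeds integer vector of experiment seeds (>= 3 recommended).
#' @param verbose print progress.
#' @return a `comparison_report`.
#' @export
run_pose_experiment <- function(config = benchmark_config(), seeds = 1:3,
                                verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"), length(seeds) >= 1)
  rows <- list()
  for (s in seeds) {
    stack <- sample_iid_dataset(
      config$spec, config$n_particles, config$noise_sigma,
      seed = derive_seed(s, 11)
    )
    eval_stack <- subsample_stack(stack, config$eval_n, derive_seed(s, 12))
    for (variant in c("vae", "posevae")) {
      cfg <- model_config(
        K = config$K, beta = config$beta,
        alpha_pose = if (variant == "posevae") config$alpha_pose else 0,
        epochs = config$epochs, seed = derive_seed(s, 22),
        pose_warm_start = config$pose_warm_start
      )
      if (verbose) message("seed ", s, ": training ", variant)
      model <- train(stack, cfg, variant)
      vals <- evaluate_pose_variant(model, eval_stack, derive_seed(s, 33))
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, seed = s, metric = names(vals), value = unname(vals)
      )
    }
  }
  higher <- c(
    recon = FALSE, kl = FALSE, pose_consistency = FALSE,
    mcc_all = TRUE, mcc_conformation = TRUE, rotation_displacement = FALSE
  )
  new_comparison_report(
    "pose", "vae", "posevae", do.call(rbind, rows), higher,
    config_echo(config), seeds
  )
}

evaluate_conformation_panel <- function(model, stack, config, seed) {
  lt <- latent_table(model, stack, include_pose = FALSE)
  conf_cols <- startsWith(colnames(lt$learned), "learned_z")
  learned <- lt$learned[, conf_cols, drop = FALSE]
  fac <- lt$factors[, c("factor_z1", "factor_z2")]
  m <- as.numeric(mcc(learned, fac))
  suite <- supervised_suite(learned, fac, seed = seed)
  sampler <- make_factor_sampler(
    stack$spec, stack$noise_sigma,
    factor_names = c("z1", "z2")
  )
  iv <- interventional_scores(
    sampler, model_batch_encoder(model, "conformation"),
    seed = derive_seed(seed, 7)
  )
  c(MCC = m, suite, iv)
}

#' Run the temporal-disentanglement experiment (VAE vs SlowVAE)
#'
#' Paired design on one temporal dataset (Laplace increments at
#' `lap_rate`) per seed; the treated arm adds the Laplace transition prior
#' (`gamma`, `lap_rate_prior`), the baseline trains the same frame-pair
#' objective without it. Evaluates the seven-metric conformation panel
#' (MCC, MIG, SAP, DCI_D, Modularity, BetaVAE, FactorVAE; higher is better
#' for all) and counts median wins.
#'
#' @inheritParams run_pose_experiment
#' @return a `comparison_report`.
#' @export
run_temporal_experiment <- function(config = benchmark_config(), seeds = 1:3,
                                    verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"), length(seeds) >= 1)
  rows <- list()
  for (s in seeds) {
    stack <- sample_temporal_dataset(
      config$spec,
      temporal_params(config$lap_rate, config$pose_rate, config$n_pairs),
      config$noise_sigma,
      seed = derive_seed(s, 11)
    )
    eval_stack <- subsample_stack(stack, config$eval_n, derive_seed(s, 12))
    for (variant in c("vae", "slowvae")) {
      cfg <- model_config(
        K = config$K, beta = config$beta, gamma = config$gamma,
        lap_rate_prior = config$lap_rate_prior,
        epochs = config$epochs, seed = derive_seed(s, 22),
        pose_warm_start = config$pose_warm_start
      )
      if (verbose) message("seed ", s, ": training ", variant)
      model <- train(stack, cfg, variant)
      vals <- evaluate_conformation_panel(
        model, eval_stack, config, derive_seed(s, 33)
      )
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, seed = s, metric = names(vals), value = unname(vals)
      )
    }
  }
  metrics <- c("MCC", "MIG", "SAP", "DCI_D", "Modularity", "BetaVAE", "FactorVAE")
  higher <- stats::setNames(rep(TRUE, length(metrics)), metrics)
  new_comparison_report(
    "temporal", "vae", "slowvae", do.call(rbind, rows), higher,
    config_echo(config), seeds
  )
}

#' Aggregate per-seed benchmark results
#'
#' Builds the long-format table (variant, seed, metric, value), per-metric
#' medians per variant, and a two-sided exact binomial sign test on the
#' per-seed paired wins of the treated variant over the baseline (ties
#' dropped).
#'
#' @param reports a `comparison_report` or list of them (same experiment).
#' @return list with `long` (data.frame), `medians` (data.frame) and
#'   `sign_tests` (data.frame: metric, wins, losses, p_value).
#' @export
aggregate_seeds <- function(reports) {
  if (inherits(reports, "comparison_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  exps <- unique(vapply(reports, `[[`, character(1), "experiment"))
  if (length(exps) != 1) stop("reports mix experiments: ", paste(exps, collapse = ", "))
  long <- do.call(rbind, lapply(reports, `[[`, "per_seed"))
  long <- long[order(long$metric, long$variant, long$seed), ]
  rownames(long) <- NULL
  baseline <- reports[[1]]$baseline
  treated <- reports[[1]]$treated
  higher <- reports[[1]]$higher_better
  metrics <- unique(long$metric)
  medians <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(
      metric = m,
      baseline = stats::median(long$value[long$metric == m & long$variant == baseline]),
      treated = stats::median(long$value[long$metric == m & long$variant == treated])
    )
  }))
  sign_tests <- do.call(rbind, lapply(metrics, function(m) {
    sub <- long[long$metric == m, ]
    sds <- sort(unique(sub$seed))
    bv <- sub$value[match(paste(baseline, sds), paste(sub$variant, sub$seed))]
    tv <- sub$value[match(paste(treated, sds), paste(sub$variant, sub$seed))]
    better <- if (isTRUE(higher[[m]])) tv > bv else tv < bv
    worse <- if (isTRUE(higher[[m]])) tv < bv else tv > bv
    wins <- sum(better)
    losses <- sum(worse)
    p <- if (wins + losses == 0) {
      1
    } else {
      stats::binom.test(wins, wins + losses, 0.5)$p.value
    }
    data.frame(metric = m, wins = wins, losses = losses, p_value = p)
  }))
  rownames(medians) <- rownames(sign_tests) <- NULL
  list(long = long, medians = medians, sign_tests = sign_tests)
}

#' Write a comparison report to JSON (plus the long CSV)
#'
#' @param report a `comparison_report`.
#' @param path JSON output path; the long-format per-seed table is written
#'   next to it with suffix `_long.csv`.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  utils::write.csv(report$per_seed,
    sub("\\.json$", "_long.csv", path),
    row.names = FALSE
  )
  invisible(path)
}
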