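#' Train a latent-variable model on a particle stack
#'
#' Stochastic-gradient (Adam) training of the split pose/conformation
#' autoencoder. Three variants share one architecture and differ only in
#' the loss:
#' \describe{
#'   \item{`vae`}{reconstruction + `beta` x KL. On a temporal stack the
#'     same frame-pair objective as SlowVAE is used with the transition
#'     penalty switched off, so the `gamma = 0` reduction is exact.}
#'   \item{`posevae`}{adds `alpha_pose` x the pose-intervention loss
#'     ([pose_intervention_loss()]) per batch. With `alpha_pose = 0` the
#'     intervention step is skipped entirely and training is bit-identical
#'     to `vae` under a shared seed.}
#'   \item{`slowvae`}{frame-pair objective: reconstruction of both frames,
#'     KL of frame `t`, plus `gamma` x the Laplace transition penalty
#'     ([slowvae_penalty()]) on frame `t+1`. Requires a temporal stack.}
#' }
#'
#' All stochasticity (initialization, shuffling, reparameterization draws,
#' intervention permutations and noise) is governed by `config$seed`;
#' identical `(stack, config, variant)` give bit-identical models.
#'
#' @param stack a [particle_stack()].
#' @param config a [model_config()].
#' @param variant `"vae"`, `"posevae"` or `"slowvae"`.
#' @param verbose print per-epoch losses.
#' @return a `trained_model` with per-epoch loss history
#'   (`epoch`, `total`, `recon`, `kl`, `pose_loss`, `temporal_pen`).
#' @export
train <- function(stack, config, variant = c("vae", "posevae", "slowvae"),
                  verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(stack, "particle_stack"), inherits(config, "model_config"))
  temporal <- stack$mode == "temporal"
  if (variant == "slowvae" && !temporal) {
    stop("slowvae requires a temporal stack (mode = \"temporal\")")
  }
  if (variant == "posevae" && temporal) {
    stop("posevae training is defined on i.i.d.-style stacks, not temporal pairs")
  }
  d <- stack$spec$image_size
  x_all <- t(stack_matrix(stack)) # n x d^2
  with_seed(config$seed, {
    params <- init_params(d, config)
    state <- adam_init(params)
    history <- vector("list", config$epochs)
    if (temporal) {
      pair_ids <- unique(stack$latents$pair)
      i0 <- match(paste(pair_ids, 0), paste(stack$latents$pair, stack$latents$t))
      i1 <- match(paste(pair_ids, 1), paste(stack$latents$pair, stack$latents$t))
      n_items <- length(pair_ids)
    } else {
      n_items <- nrow(x_all)
    }
    nb <- max(1L, floor(n_items / config$batch_size))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_items)
      acc <- c(total = 0, recon = 0, kl = 0, pose_loss = 0, temporal_pen = 0)
      for (b in seq_len(nb)) {
        take <- ord[seq.int((b - 1L) * config$batch_size + 1L,
          min(b * config$batch_size, n_items)
        )]
        if (temporal) {
          x0 <- x_all[i0[take], , drop = FALSE]
          x1 <- x_all[i1[take], , drop = FALSE]
          nB <- nrow(x0)
          eps0 <- matrix(stats::rnorm(nB * config$K), nB, config$K)
          eps1 <- matrix(stats::rnorm(nB * config$K), nB, config$K)
          cfg_eff <- config
          if (variant == "vae") cfg_eff$gamma <- 0
          res <- slowvae_batch(params, cfg_eff, x0, x1, d, eps0, eps1)
          grads <- res$grads
          acc <- acc + c(res$total, res$recon, res$kl, 0, res$pen)
        } else {
          xb <- x_all[take, , drop = FALSE]
          nB <- nrow(xb)
          eps <- matrix(stats::rnorm(nB * config$K), nB, config$K)
          res <- vae_batch(params, config, xb, d, eps = eps)
          grads <- res$grads
          pose_l <- 0
          if (variant == "posevae" && config$alpha_pose > 0) {
            iv <- intervention_batch(params, config, xb, d,
              add_noise = config$intervention_noise,
              noise_sigma = stack$noise_sigma
            )
            grads <- add_grads(grads, iv$grads, weight = config$alpha_pose)
            pose_l <- iv$loss
          }
          acc <- acc + c(
            res$total + config$alpha_pose * pose_l,
            res$recon, res$kl, pose_l, 0
          )
        }
        upd <- adam_step(params, clip_grads(grads, config$clip_norm), state, config$lr)
        params <- upd$params
        state <- upd$state
      }
      acc <- acc / nb
      history[[epoch]] <- data.frame(
        epoch = epoch, total = acc[1], recon = acc[2], kl = acc[3],
        pose_loss = acc[4], temporal_pen = acc[5]
      )
      if (verbose) {
        message(sprintf(
          "epoch %3d  total %.4f  recon %.4f  kl %.4f  pose %.4f  temp %.4f",
          epoch, acc[1], acc[2], acc[3], acc[4], acc[5]
        ))
      }
    }
    hist_df <- do.call(rbind, history)
    rownames(hist_df) <- NULL
    new_trained_model(params, config, d, hist_df, variant)
  })
}
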