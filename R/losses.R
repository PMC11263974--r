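# Loss functions. Each training loss has an internal *_batch() form that
# returns both the loss components and hand-derived parameter gradients;
# the exported functions evaluate the same quantities without gradients.

# ---- closed forms --------------------------------------------------------

#' KL divergence between a Gaussian and a Laplace distribution
#'
#' Elementwise closed form of `KL( N(mu_q, sd_q^2) || Laplace(mu_p, rate) )`
#' in the rate parameterization (Laplace density
#' `(rate/2) exp(-rate |x - mu_p|)`), expressed with the Gaussian error
#' function:
#' `KL = -1/2 - log(sd_q) - log(2 pi)/2 - log(rate/2)
#'       + rate * [ sd_q sqrt(2/pi) exp(-d^2/(2 sd_q^2)) + d erf(d/(sqrt(2) sd_q)) ]`
#' with `d = mu_q - mu_p`.
#'
#' @param mu_q,sd_q Gaussian mean and std (vectors recycle elementwise).
#' @param mu_p Laplace location.
#' @param rate Laplace rate (> 0).
#' @return elementwise KL values (nats).
#' @export
normal_laplace_kl <- function(mu_q, sd_q, mu_p, rate) {
  stopifnot(all(rate > 0), all(sd_q > 0))
  d <- mu_q - mu_p
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  e_abs <- sd_q * sqrt(2 / pi) * exp(-d^2 / (2 * sd_q^2)) +
    d * erf(d / (sqrt(2) * sd_q))
  -0.5 - log(sd_q) - 0.5 * log(2 * pi) - log(rate / 2) + rate * e_abs
}

# Gradients of normal_laplace_kl w.r.t. mu_q, mu_p and sd_q.
normal_laplace_kl_grad <- function(mu_q, sd_q, mu_p, rate) {
  d <- mu_q - mu_p
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  dmu <- rate * erf(d / (sqrt(2) * sd_q))
  dsd <- -1 / sd_q + rate * sqrt(2 / pi) * exp(-d^2 / (2 * sd_q^2))
  list(dmu_q = dmu, dmu_p = -dmu, dsd_q = dsd)
}

#' Temporal Laplace-prior penalty (SlowVAE)
#'
#' KL divergence between the Gaussian conformation posterior at frame `t+1`
#' and a Laplace transition prior centred on the posterior mean at frame
#' `t`, summed over components and averaged over the batch. Added to the
#' ELBO with weight `gamma` during SlowVAE training.
#'
#' @param q_t1 posterior at `t+1`: a `posterior_factors` object or any list
#'   with `z_mean` and `z_logvar` matrices.
#' @param z_mean_t posterior mean at `t` (matrix of matching shape).
#' @param lap_rate rate of the Laplace transition prior (> 0).
#' @return scalar penalty (nats).
#' @export
slowvae_penalty <- function(q_t1, z_mean_t, lap_rate) {
  if (lap_rate <= 0) stop("lap_rate must be > 0")
  mu1 <- q_t1$z_mean
  if (is.null(dim(mu1))) mu1 <- matrix(mu1, nrow = 1)
  mu0 <- if (is.null(dim(z_mean_t))) matrix(z_mean_t, nrow = 1) else z_mean_t
  sd1 <- exp(0.5 * q_t1$z_logvar)
  if (is.null(dim(sd1))) sd1 <- matrix(sd1, nrow = 1)
  kl <- normal_laplace_kl(mu1, sd1, mu0, lap_rate)
  mean(rowSums(kl))
}

# Standard Gaussian KL against N(0, I), per sample (vector of length n).
gaussian_kl_rows <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

# ---- ELBO ----------------------------------------------------------------

# Core VAE batch: loss components and gradients. `eps` is the reparam draw
# (NULL = use posterior mean, deterministic).
vae_batch <- function(params, config, x, d, eps = NULL, want_grads = TRUE,
                      beta = config$beta) {
  n <- nrow(x)
  enc <- encoder_fwd(params, x, config)
  sigma <- exp(0.5 * enc$logvar)
  z <- if (is.null(eps)) enc$mu else enc$mu + sigma * eps
  dec <- decoder_fwd(params, z)
  rot <- rotate_bilinear_fwd(dec$canon, enc$phi, d)
  err <- rot$out - x
  recon <- sum(err^2) / n
  kl_gauss <- sum(gaussian_kl_rows(enc$mu, enc$logvar)) / n
  posereg <- sum((enc$r - 1)^2) / n
  kl <- kl_gauss + config$pose_reg * posereg
  total <- recon + beta * kl
  out <- list(
    total = total, recon = recon, kl = kl, kl_gauss = kl_gauss,
    posereg = posereg, enc = enc, z = z
  )
  if (!want_grads) {
    return(out)
  }
  dout <- 2 * err / n
  rb <- rotate_bilinear_bwd(rot$cache, dout)
  decb <- decoder_bwd(params, dec, rb$dimages, need_dz = TRUE)
  dmu <- decb$dz + beta * enc$mu / n
  dlv <- beta * 0.5 * (exp(enc$logvar) - 1) / n
  if (!is.null(eps)) {
    dlv <- dlv + decb$dz * eps * sigma * 0.5
  }
  du <- dphi_to_du(enc$u, rb$dphi) +
    beta * config$pose_reg * (2 * (enc$r - 1) / n) * (enc$u / enc$r)
  encb <- encoder_bwd(params, enc, dmu, dlv, du)
  out$grads <- add_grads(encb$grads, decb$grads)
  out
}

#' Evaluate the ELBO loss of a model on a batch of images
#'
#' Deterministic evaluation (posterior mean, no reparameterization draw).
#' The reconstruction term is the per-image summed squared error averaged
#' over the batch; the KL term is the closed-form Gaussian KL of the
#' conformation posterior against `N(0, I)` plus the configured unit-norm
#' pose regularizer; `total = recon + beta * kl`.
#'
#' @param model a `trained_model`.
#' @param x images (any form accepted by [encode()]).
#' @param beta KL weight (defaults to the model's configured `beta`).
#' @return list with `total`, `recon`, `kl`.
#' @export
elbo_loss <- function(model, x, beta = model$config$beta) {
  stopifnot(beta >= 0)
  xm <- as_image_matrix(x, model$image_size)
  res <- vae_batch(model$params, model$config, xm, model$image_size,
    eps = NULL, want_grads = FALSE, beta = beta
  )
  list(total = res$total, recon = res$recon, kl = res$kl)
}

# ---- pose intervention (Algorithm-1 style) -------------------------------

# Internal: intervention loss on a batch, with gradients flowing only
# through the decode and the *second* encode (the first encoding is
# detached by construction: it receives no backward pass).
intervention_batch <- function(params, config, x, d, add_noise, noise_sigma,
                               want_grads = TRUE, perm = NULL) {
  n <- nrow(x)
  if (n < 2) stop("pose intervention needs a batch of at least 2 images")
  enc1 <- encoder_fwd(params, x, config) # detached: never backpropagated
  z <- enc1$mu
  phi <- enc1$phi
  if (is.null(perm)) perm <- sample.int(n)
  phi_p <- phi[perm]
  dec <- decoder_fwd(params, z)
  rot <- rotate_bilinear_fwd(dec$canon, phi_p, d)
  xt <- rot$out
  if (add_noise && noise_sigma > 0) {
    xt <- xt + matrix(stats::rnorm(n * d * d, 0, noise_sigma), n, d * d)
  }
  enc2 <- encoder_fwd(params, xt, config)
  dz_vec <- enc2$mu - z
  dzn <- sqrt(rowSums(dz_vec^2))
  phi_err <- wrap_angle(enc2$phi - phi_p)
  loss_z <- mean(dzn)
  loss_phi <- mean(abs(phi_err))
  out <- list(
    loss = loss_z + loss_phi, loss_z = loss_z, loss_phi = loss_phi,
    perm = perm
  )
  if (!want_grads) {
    return(out)
  }
  safe <- pmax(dzn, 1e-12)
  dmu2 <- dz_vec / safe / n
  dmu2[dzn < 1e-12, ] <- 0
  dphi2 <- sign(phi_err) / n
  du2 <- dphi_to_du(enc2$u, dphi2)
  encb2 <- encoder_bwd(params, enc2, dmu2, matrix(0, n, config$K), du2,
    need_dx = TRUE
  )
  rb <- rotate_bilinear_bwd(rot$cache, encb2$dx)
  decb <- decoder_bwd(params, dec, rb$dimages, need_dz = FALSE)
  out$grads <- add_grads(encb2$grads, decb$grads)
  out
}

#' Pose-intervention loss on a batch of images
#'
#' Implements the intervention procedure used for pose/conformation
#' disentanglement: encode a batch into conformations and poses, treat
#' those latents as given (detached), shuffle the poses across the batch by
#' a uniformly random permutation (so the intervened poses stay inside the
#' pose posterior), decode the shuffled pairs (optionally adding
#' observation noise to mitigate domain shift), re-encode, and average the
#' Euclidean conformation distance plus the geodesic (circular) pose
#' distance between intended and recovered latents.
#'
#' @param model a `trained_model`.
#' @param x images (any form accepted by [encode()]); at least 2.
#' @param add_noise add Gaussian observation noise to the decoded images.
#' @param noise_sigma noise std used when `add_noise` is `TRUE`.
#' @param seed optional seed for the permutation (and noise); `NULL` uses
#'   the current RNG stream.
#' @return scalar loss (latent units + radians), with components
#'   `loss_z`/`loss_phi` as attributes.
#' @export
pose_intervention_loss <- function(model, x, add_noise = TRUE,
                                   noise_sigma = 0.1, seed = NULL) {
  xm <- as_image_matrix(x, model$image_size)
  res <- with_seed(seed, {
    intervention_batch(model$params, model$config, xm, model$image_size,
      add_noise = add_noise, noise_sigma = noise_sigma, want_grads = FALSE
    )
  })
  structure(res$loss, loss_z = res$loss_z, loss_phi = res$loss_phi)
}

# ---- SlowVAE batch -------------------------------------------------------

# Frame-pair batch: reconstruction of both frames, Gaussian KL on frame t,
# Laplace transition penalty on frame t+1's posterior. With gamma = 0 this
# consumes the same RNG and computes the same gradients as the temporal
# baseline VAE, so the reduction is exact.
slowvae_batch <- function(params, config, x0, x1, d, eps0, eps1,
                          want_grads = TRUE) {
  n <- nrow(x0)
  enc0 <- encoder_fwd(params, x0, config)
  enc1 <- encoder_fwd(params, x1, config)
  s0 <- exp(0.5 * enc0$logvar)
  s1 <- exp(0.5 * enc1$logvar)
  z0 <- enc0$mu + s0 * eps0
  z1 <- enc1$mu + s1 * eps1
  dec0 <- decoder_fwd(params, z0)
  dec1 <- decoder_fwd(params, z1)
  rot0 <- rotate_bilinear_fwd(dec0$canon, enc0$phi, d)
  rot1 <- rotate_bilinear_fwd(dec1$canon, enc1$phi, d)
  err0 <- rot0$out - x0
  err1 <- rot1$out - x1
  recon <- (sum(err0^2) + sum(err1^2)) / n
  kl_gauss <- sum(gaussian_kl_rows(enc0$mu, enc0$logvar)) / n
  posereg <- (sum((enc0$r - 1)^2) + sum((enc1$r - 1)^2)) / n
  kl <- kl_gauss + config$pose_reg * posereg
  lam <- config$lap_rate_prior
  pen_mat <- normal_laplace_kl(enc1$mu, s1, enc0$mu, lam)
  pen <- sum(pen_mat) / n
  total <- recon + config$beta * kl + config$gamma * pen
  out <- list(
    total = total, recon = recon, kl = kl, pen = pen,
    kl_gauss = kl_gauss, posereg = posereg
  )
  if (!want_grads) {
    return(out)
  }
  beta <- config$beta
  gamma <- config$gamma
  # frame t
  rb0 <- rotate_bilinear_bwd(rot0$cache, 2 * err0 / n)
  decb0 <- decoder_bwd(params, dec0, rb0$dimages, need_dz = TRUE)
  dmu0 <- decb0$dz + beta * enc0$mu / n
  dlv0 <- beta * 0.5 * (exp(enc0$logvar) - 1) / n + decb0$dz * eps0 * s0 * 0.5
  du0 <- dphi_to_du(enc0$u, rb0$dphi) +
    beta * config$pose_reg * (2 * (enc0$r - 1) / n) * (enc0$u / enc0$r)
  # frame t+1
  rb1 <- rotate_bilinear_bwd(rot1$cache, 2 * err1 / n)
  decb1 <- decoder_bwd(params, dec1, rb1$dimages, need_dz = TRUE)
  dmu1 <- decb1$dz
  dlv1 <- decb1$dz * eps1 * s1 * 0.5
  du1 <- dphi_to_du(enc1$u, rb1$dphi) +
    beta * config$pose_reg * (2 * (enc1$r - 1) / n) * (enc1$u / enc1$r)
  if (gamma > 0) {
    pg <- normal_laplace_kl_grad(enc1$mu, s1, enc0$mu, lam)
    dmu1 <- dmu1 + gamma * pg$dmu_q / n
    dmu0 <- dmu0 + gamma * pg$dmu_p / n
    dlv1 <- dlv1 + gamma * (pg$dsd_q * s1 * 0.5) / n
  }
  encb0 <- encoder_bwd(params, enc0, dmu0, dlv0, du0)
  encb1 <- encoder_bwd(params, enc1, dmu1, dlv1, du1)
  grads <- add_grads(encb0$grads, encb1$grads)
  grads <- add_grads(grads, decb0$grads)
  out$grads <- add_grads(grads, decb1$grads)
  out
}
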