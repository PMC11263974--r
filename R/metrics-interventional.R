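# Interventional disentanglement scores (BetaVAE and FactorVAE style).
# Both need generative access: a factor sampler that can draw image batches
# with one chosen factor held fixed, provided by the simulator.

#' Simulator-backed factor sampler
#'
#' Returns a sampler closure for [interventional_scores()]. Called as
#' `sampler(n, fixed = NULL)` it draws `n` particles from the i.i.d. prior;
#' with `fixed` set to one of `factor_names` that factor is drawn once and
#' held constant across the batch. The closure returns
#' `list(images, factors)` with `images` an `n x d^2` matrix and `factors`
#' an `n x F` matrix in the order of `factor_names`.
#'
#' @param spec a [toy_molecule_spec()].
#' @param noise_sigma pixel-noise std.
#' @param factor_names subset of `c("z1", "z2", "phi")` the sampler exposes.
#' @param z_sd std of the conformation prior.
#' @return a function; its `factor_names` are attached as an attribute.
#' @export
make_factor_sampler <- function(spec, noise_sigma = 0.1,
                                factor_names = c("z1", "z2", "phi"),
                                z_sd = pi / 6) {
  factor_names <- match.arg(factor_names, several.ok = TRUE)
  draw_factor <- function(name, n) {
    if (name == "phi") {
      stats::runif(n, 0, 2 * pi)
    } else {
      rtruncnorm(n, 0, z_sd, -spec$z_max, spec$z_max)
    }
  }
  sampler <- function(n, fixed = NULL, fixed_value = NULL) {
    if (!is.null(fixed) && !(fixed %in% factor_names)) {
      stop("sampler cannot fix factor '", fixed, "'")
    }
    vals <- list(
      z1 = draw_factor("z1", n),
      z2 = draw_factor("z2", n),
      phi = draw_factor("phi", n)
    )
    if (!is.null(fixed)) {
      vals[[fixed]] <- rep(fixed_value %||% draw_factor(fixed, 1), n)
    }
    lat <- data.frame(z1 = vals$z1, z2 = vals$z2, phi = vals$phi)
    images <- render_stack(spec, lat, noise_sigma)
    d <- spec$image_size
    list(
      images = t(matrix(images, nrow = d * d)),
      factors = as.matrix(lat[, factor_names, drop = FALSE])
    )
  }
  attr(sampler, "factor_names") <- factor_names
  sampler
}

#' Encoder adaptors for the interventional scores
#'
#' `model_batch_encoder()` wraps a trained model; `which` selects the
#' conformation posterior means, or those plus the pose angle.
#' `oracle_encoder()` returns the sampler's ground-truth factors (the
#' perfect encoder); `constant_encoder()` ignores its input (the
#' uninformative reference).
#'
#' Each adaptor is called with `list(images, factors)` and returns a
#' latent matrix.
#'
#' @param model a `trained_model`.
#' @param which `"conformation"` or `"all"`.
#' @return a function `batch -> latent matrix`.
#' @export
model_batch_encoder <- function(model, which = c("conformation", "all")) {
  which <- match.arg(which)
  function(batch) {
    post <- encode(model, batch$images)
    if (which == "conformation") {
      post$z_mean
    } else {
      cbind(post$z_mean, post$pose_angle)
    }
  }
}

#' @rdname model_batch_encoder
#' @export
oracle_encoder <- function() {
  function(batch) as.matrix(batch$factors)
}

#' @rdname model_batch_encoder
#' @param K number of constant latent dimensions to emit.
#' @export
constant_encoder <- function(K = 2) {
  function(batch) matrix(0, nrow(as.matrix(batch$factors)), K)
}

#' Interventional disentanglement scores
#'
#' Standard construction: repeatedly fix one ground-truth factor, vary the
#' others, and ask whether the fixed factor can be identified from latent
#' statistics.
#' \describe{
#'   \item{BetaVAE}{per vote, draw `L` image pairs sharing the fixed
#'     factor; the per-dimension mean absolute latent difference is the
#'     feature vector; a nearest-centroid classifier over training votes
#'     predicts the fixed factor on held-out votes.}
#'   \item{FactorVAE}{per vote, draw `L` images with the fixed factor
#'     constant; the latent dimension with the smallest variance (after
#'     normalizing each dimension by its prior std) votes; a majority-vote
#'     table maps dimensions to factors and is scored on held-out votes.}
#' }
#' Both scores lie in `[0, 1]` with chance level `1 / F`.
#'
#' @param factor_sampler sampler from [make_factor_sampler()].
#' @param encoder adaptor from [model_batch_encoder()] (or
#'   [oracle_encoder()] / [constant_encoder()]).
#' @param names which scores to compute.
#' @param n_votes_train,n_votes_eval number of training / evaluation votes.
#' @param L images (or image pairs) per vote.
#' @param seed RNG seed; scores are deterministic given it.
#' @return named numeric vector of scores.
#' @export
interventional_scores <- function(factor_sampler, encoder,
                                  names = c("BetaVAE", "FactorVAE"),
                                  n_votes_train = 150, n_votes_eval = 75,
                                  L = 32, seed = 1) {
  names <- match.arg(names, several.ok = TRUE)
  fns <- attr(factor_sampler, "factor_names")
  stopifnot(!is.null(fns), length(fns) >= 2)
  f <- length(fns)
  with_seed(seed, {
    scores <- c()
    if ("BetaVAE" %in% names) {
      vote_beta <- function() {
        k <- sample.int(f, 1)
        b1 <- factor_sampler(L, fixed = fns[k])
        b2 <- factor_sampler(L, fixed = fns[k], fixed_value = b1$factors[1, k])
        z1 <- encoder(b1)
        z2 <- encoder(b2)
        list(feature = colMeans(abs(z1 - z2)), label = k)
      }
      tr <- replicate(n_votes_train, vote_beta(), simplify = FALSE)
      ev <- replicate(n_votes_eval, vote_beta(), simplify = FALSE)
      feats <- do.call(rbind, lapply(tr, `[[`, "feature"))
      labs <- vapply(tr, `[[`, integer(1), "label")
      centroids <- do.call(rbind, lapply(seq_len(f), function(k) {
        if (any(labs == k)) colMeans(feats[labs == k, , drop = FALSE]) else rep(Inf, ncol(feats))
      }))
      predict_nc <- function(feat) {
        d2 <- rowSums(sweep(centroids, 2, feat)^2)
        which.min(d2)
      }
      correct <- vapply(ev, function(v) predict_nc(v$feature) == v$label, logical(1))
      scores["BetaVAE"] <- mean(correct)
    }
    if ("FactorVAE" %in% names) {
      ref <- factor_sampler(max(256, 4 * L))
      z_ref <- encoder(ref)
      sds <- apply(z_ref, 2, stats::sd)
      active <- sds > 1e-8
      vote_factor <- function() {
        k <- sample.int(f, 1)
        b <- factor_sampler(L, fixed = fns[k])
        z <- encoder(b)
        vars <- apply(z, 2, stats::var)
        vars[active] <- vars[active] / sds[active]^2
        vars[!active] <- Inf
        dim_star <- if (any(active)) which.min(vars) else 1L
        c(dim = dim_star, label = k)
      }
      tr <- t(replicate(n_votes_train, vote_factor()))
      ev <- t(replicate(n_votes_eval, vote_factor()))
      vote_tab <- matrix(0, max(c(tr[, 1], ev[, 1], ncol(z_ref))), f)
      for (r in seq_len(nrow(tr))) {
        vote_tab[tr[r, 1], tr[r, 2]] <- vote_tab[tr[r, 1], tr[r, 2]] + 1
      }
      dim_to_factor <- apply(vote_tab, 1, which.max)
      correct <- dim_to_factor[ev[, 1]] == ev[, 2]
      scores["FactorVAE"] <- mean(correct)
    }
    scores[names]
  })
}
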