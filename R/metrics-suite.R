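# Supervised disentanglement metric suite: MIG, SAP, DCI disentanglement
# and modularity. All scores lie in [0, 1] and are deterministic given
# (data, seed).

# Equal-frequency discretization into `bins` levels.
discretize_ef <- function(x, bins) {
  n <- length(x)
  ceiling(rank(x, ties.method = "first") * bins / n)
}

# Mutual information (nats) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}

discrete_entropy <- function(a) {
  p <- table(a) / length(a)
  -sum(p[p > 0] * log(p[p > 0]))
}

# Matrix of MI between every (latent, factor) pair after equal-frequency
# discretization.
mi_matrix <- function(learned, factors, bins) {
  dl <- apply(learned, 2, discretize_ef, bins = bins)
  df <- apply(factors, 2, discretize_ef, bins = bins)
  k <- ncol(learned)
  f <- ncol(factors)
  m <- matrix(0, k, f)
  for (i in seq_len(k)) {
    for (j in seq_len(f)) {
      m[i, j] <- discrete_mi(dl[, i], df[, j])
    }
  }
  m
}

top_gap <- function(v) {
  s <- sort(v, decreasing = TRUE)
  if (length(s) < 2) s[1] else s[1] - s[2]
}

#' Supervised disentanglement metric suite
#'
#' Computes any subset of:
#' \describe{
#'   \item{MIG}{mutual information gap: per factor, the difference between
#'     the two largest mutual informations with any latent, normalized by
#'     the factor entropy; averaged over factors. MI is estimated after
#'     equal-frequency discretization (`bins` levels).}
#'   \item{SAP}{separated attribute predictability: per factor, the gap
#'     between the two largest single-latent linear R-squared values;
#'     averaged over factors.}
#'   \item{DCI_D}{DCI disentanglement: per-latent importance weights from
#'     per-factor random-forest regressors; one minus the entropy of each
#'     latent's normalized importance profile, weighted by the latent's
#'     share of total importance.}
#'   \item{Modularity}{from the mutual-information matrix: per latent, the
#'     normalized squared deviation of its MI profile from the ideal
#'     one-factor template. Latents whose largest MI does not exceed a
#'     small-sample floor (three times the analytic chance bias
#'     `(bins - 1)^2 / (2N)`) carry no evidence of depending on any factor
#'     and score 0 (flagged in the result's `"warnings"` attribute).}
#' }
#'
#' @param learned `N x K` matrix of learned latents.
#' @param factors `N x F` matrix of ground-truth factors.
#' @param names which scores to compute.
#' @param bins discretization bins for the MI-based scores (equal-frequency).
#' @param seed seed for the random-forest fits (DCI_D).
#' @param num_trees trees per random-forest regressor.
#' @return named numeric vector of scores in `[0, 1]`, with a character
#'   vector of warnings as attribute `"warnings"`.
#' @export
supervised_suite <- function(learned, factors,
                             names = c("MIG", "SAP", "DCI_D", "Modularity"),
                             bins = 20, seed = 1, num_trees = 100) {
  names <- match.arg(names, several.ok = TRUE)
  learned <- as.matrix(learned)
  factors <- as.matrix(factors)
  n <- nrow(learned)
  stopifnot(nrow(factors) == n)
  if (n < 50) stop("supervised_suite needs at least 50 samples")
  if (any(apply(learned, 2, stats::sd) == 0)) {
    stop("constant learned-latent column; suite scores are undefined")
  }
  if (any(apply(factors, 2, stats::sd) == 0)) {
    stop("constant factor column; suite scores are undefined")
  }
  warnings_out <- character(0)
  scores <- c()
  need_mi <- any(c("MIG", "Modularity") %in% names)
  if (need_mi) {
    m <- mi_matrix(learned, factors, bins)
  }
  if ("MIG" %in% names) {
    df <- apply(factors, 2, discretize_ef, bins = bins)
    h <- apply(df, 2, discrete_entropy)
    mig <- mean(apply(m, 2, top_gap) / h)
    scores["MIG"] <- max(0, min(1, mig))
  }
  if ("SAP" %in% names) {
    r2 <- stats::cor(learned, factors)^2
    scores["SAP"] <- max(0, min(1, mean(apply(r2, 2, top_gap))))
  }
  if ("DCI_D" %in% names) {
    imp <- matrix(0, ncol(learned), ncol(factors))
    dat <- as.data.frame(learned)
    colnames(dat) <- paste0("L", seq_len(ncol(learned)))
    for (j in seq_len(ncol(factors))) {
      dat$.y <- factors[, j]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = num_trees, importance = "impurity",
        seed = derive_seed(seed, j), num.threads = 1
      )
      imp[, j] <- pmax(fit$variable.importance, 0)
    }
    tot <- sum(imp)
    if (tot == 0) {
      scores["DCI_D"] <- 0
      warnings_out <- c(warnings_out, "DCI_D: zero total importance")
    } else {
      prof <- imp / pmax(rowSums(imp), 1e-300)
      ent <- -rowSums(ifelse(prof > 0, prof * log(prof), 0))
      d_i <- 1 - ent / log(ncol(factors))
      rho <- rowSums(imp) / tot
      scores["DCI_D"] <- max(0, min(1, sum(rho * d_i)))
    }
  }
  if ("Modularity" %in% names) {
    floor_mi <- 3 * (bins - 1)^2 / (2 * n)
    mod_i <- numeric(ncol(learned))
    for (i in seq_len(ncol(learned))) {
      theta <- max(m[i, ])
      if (theta <= floor_mi) {
        mod_i[i] <- 0
        warnings_out <- c(
          warnings_out,
          paste0("Modularity: latent ", i, " shows no dependence on any factor")
        )
      } else if (ncol(factors) == 1) {
        mod_i[i] <- 1
      } else {
        jstar <- which.max(m[i, ])
        delta <- sum((m[i, -jstar] / theta)^2) / (ncol(factors) - 1)
        mod_i[i] <- 1 - delta
      }
    }
    scores["Modularity"] <- max(0, min(1, mean(mod_i)))
  }
  structure(scores[names], warnings = warnings_out)
}
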