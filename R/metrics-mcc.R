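# Mean correlation coefficient and the linear-sum-assignment machinery.

#' Solve a linear sum assignment (minimization)
#'
#' Hungarian algorithm (shortest augmenting path, O(n^3)) for square or
#' rectangular cost matrices; rectangular inputs are padded internally.
#'
#' @param cost numeric cost matrix (rows assigned to columns).
#' @return integer vector `a` of length `nrow(cost)`: row `i` is assigned to
#'   column `a[i]` (`NA` for rows left unassigned when `nrow > ncol`).
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  a <- matrix(0, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  # shortest-augmenting-path Hungarian; index 1 is a virtual column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  }
  out <- assign_row[seq_len(nr)]
  out[out > nc | out == 0L] <- NA_integer_
  out
}

# All injective maps from seq_len(k) into seq_len(m), as a matrix with one
# map per row. Used by the brute-force matching oracle (k <= 6).
injective_maps <- function(k, m) {
  stopifnot(k <= m, k <= 6)
  grow <- function(prefix, remaining) {
    if (length(prefix) == k) {
      return(matrix(prefix, nrow = 1))
    }
    do.call(rbind, lapply(remaining, function(j) {
      grow(c(prefix, j), setdiff(remaining, j))
    }))
  }
  grow(integer(0), seq_len(m))
}

#' Mean correlation coefficient (MCC)
#'
#' Builds the matrix of absolute correlations between learned latents and
#' ground-truth factors, finds the one-to-one matching that maximizes the
#' mean absolute correlation, and returns that mean. Invariant to
#' permutation, sign flips and per-column rescaling of the latents. With
#' unequal column counts the best matching over `min(K, F)` pairs is
#' scored.
#'
#' @param learned `N x K` matrix of learned latents.
#' @param factors `N x F` matrix of ground-truth factors.
#' @param matching `"assignment"` (Hungarian solver) or `"brute_force"`
#'   (full enumeration, requires `min(K, F) <= 6`; the independent oracle).
#' @param method correlation type: `"pearson"` (default) or `"spearman"`.
#' @return MCC in `[0, 1]`, with the matched `(latent, factor)` pairs as
#'   attribute `"pairs"`.
#' @export
mcc <- function(learned, factors, matching = c("assignment", "brute_force"),
                method = c("pearson", "spearman")) {
  matching <- match.arg(matching)
  method <- match.arg(method)
  learned <- as.matrix(learned)
  factors <- as.matrix(factors)
  stopifnot(nrow(learned) == nrow(factors))
  if (nrow(learned) < 10) stop("MCC needs at least 10 samples")
  check_variance <- function(m, what) {
    sds <- apply(m, 2, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad) > 0) {
      nm <- colnames(m) %||% paste0(what, "_", seq_len(ncol(m)))
      stop("zero-variance column in ", what, ": ", paste(nm[bad], collapse = ", "))
    }
  }
  check_variance(learned, "learned")
  check_variance(factors, "factors")
  cm <- abs(stats::cor(learned, factors, method = method))
  k <- nrow(cm)
  f <- ncol(cm)
  if (matching == "assignment") {
    if (k <= f) {
      assign_col <- solve_assignment(-cm)
      pairs <- cbind(latent = seq_len(k), factor = assign_col)
    } else {
      assign_row <- solve_assignment(-t(cm))
      pairs <- cbind(latent = assign_row, factor = seq_len(f))
    }
  } else {
    small <- min(k, f)
    big <- max(k, f)
    maps <- injective_maps(small, big)
    vals <- apply(maps, 1, function(mp) {
      if (k <= f) {
        mean(cm[cbind(seq_len(k), mp)])
      } else {
        mean(cm[cbind(mp, seq_len(f))])
      }
    })
    best <- maps[which.max(vals), ]
    pairs <- if (k <= f) {
      cbind(latent = seq_len(k), factor = best)
    } else {
      cbind(latent = best, factor = seq_len(f))
    }
  }
  score <- mean(cm[pairs])
  structure(score, pairs = pairs)
}
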