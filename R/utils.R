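# Internal helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor convention puts -pi at the boundary; move it to +pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Wrap angles into [0, 2*pi)
#' @keywords internal
wrap_angle_2pi <- function(x) {
  x - 2 * pi * floor(x / (2 * pi))
}

#' Geodesic (circular) distance between two angles on the circle
#'
#' @param a,b angles in radians, any range.
#' @return distance in radians, in [0, pi].
#' @export
circular_distance <- function(a, b) {
  abs(wrap_angle(a - b))
}

# Evaluate an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. All stochastic entry points route through this so a
# (seed, params) pair is bit-reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of sub-seeds from a master seed, kept below 2^31.
# Distinct (seed, index) pairs map to distinct values with high probability.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269) %% 2147483629L)
}

# Laplace sampler, rate parameterization: density (rate/2) exp(-rate |x - mu|).
rlaplace <- function(n, mu = 0, rate = 1) {
  stopifnot(rate > 0)
  u <- stats::runif(n, -0.5, 0.5)
  mu - sign(u) * log(1 - 2 * abs(u)) / rate
}

# Truncated normal via rejection; fine for the mild truncations used here.
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper)
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Accumulate `values` into a zero vector of length n at (possibly repeated)
# integer positions `idx`. Backward pass of gather-style indexing.
scatter_add <- function(values, idx, n) {
  out <- numeric(n)
  idx <- as.integer(idx)
  o <- order(idx, method = "radix")
  si <- idx[o]
  cs <- cumsum(values[o])
  ends <- c(si[-1] != si[-length(si)], TRUE)
  at <- which(ends)
  out[si[at]] <- diff(c(0, cs[at]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
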