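# Minimal dense-network machinery: Glorot initialization, Adam, and a
# batched differentiable bilinear image rotation. Everything operates on
# plain matrices; gradients are hand-derived and finite-difference tested.

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# params/grads are parallel named lists of numeric arrays.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# Global-norm gradient clipping: rescales the whole gradient so its
# Euclidean norm does not exceed max_norm. Stabilizes the occasional
# ill-conditioned step of small-batch Adam runs.
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pixel-centre coordinates of the flattened D x D grid (column-major, the
# same layout as as.vector(matrix)). x runs along columns, y along rows,
# origin at the image centre.
grid_coords <- function(d) {
  ctr <- (d + 1) / 2
  p <- seq_len(d * d) - 1L
  list(
    x = (p %/% d) + 1 - ctr,
    y = (p %% d) + 1 - ctr
  )
}

#' Differentiable image rotation by bilinear resampling
#'
#' Rotates each image in a batch counter-clockwise by its own angle about
#' the image centre, sampling the source image bilinearly with zero padding
#' outside the frame. The operation is differentiable with respect to both
#' the input pixels and the angles; use [rotate_bilinear_bwd()] with the
#' returned cache for the backward pass. The angular convention matches
#' [apply_pose()] and [rotate_image_90()]: at multiples of 90 degrees the
#' sampling points are exact pixel centres and the result equals the exact
#' array rotation.
#'
#' @param images `n x d^2` matrix, one flattened (column-major) image per row.
#' @param phi length-`n` vector of angles (radians).
#' @param d image side length.
#' @return list with `out` (`n x d^2` matrix) and `cache` for the backward
#'   pass.
#' @export
rotate_bilinear_fwd <- function(images, phi, d) {
  stopifnot(ncol(images) == d * d, length(phi) == nrow(images))
  out <- .cpp_rotate_fwd(images, as.numeric(phi), as.integer(d))
  list(out = out, cache = list(images = images, phi = as.numeric(phi), d = d))
}

#' Backward pass of [rotate_bilinear_fwd()]
#'
#' The sampling geometry is recomputed from the cached inputs; gradients
#' with respect to the angle use the analytic spatial gradient of the
#' bilinear sample (`d(xs)/dphi = ys`, `d(ys)/dphi = -xs`).
#'
#' @param cache cache returned by the forward pass.
#' @param gout gradient of the loss with respect to the rotated output
#'   (`n x d^2`).
#' @return list with `dimages` (`n x d^2`) and `dphi` (length `n`).
#' @export
rotate_bilinear_bwd <- function(cache, gout) {
  .cpp_rotate_bwd(cache$images, cache$phi, gout, as.integer(cache$d))
}
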