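# From score maps to the fused weight map. Each score-map stack is whitened
# channel-wise by ZCA, collapsed to an initial weight map by a windowed
# average of the per-pixel channel l1-norm, and the two candidate maps are
# merged per pixel by comparing weighted local energy (WLE) against the
# weighted sum of the eight-neighborhood modified Laplacian (WSEML).

#' ZCA-whiten a score-map stack channel by channel
#'
#' For each channel `S_i` (an HxW matrix) the HxH covariance
#' `Co = S_i %*% t(S_i)` is decomposed by SVD and the symmetric whitening
#' transform `K = U (Sigma + eta I)^(-1/2) t(U)` is applied:
#' `S_hat_i = K %*% S_i`. `eta` regularizes near-singular covariances.
#'
#' @param S HxWxC numeric array (a score-map stack) or an HxW matrix
#'   (treated as one channel).
#' @param eta small positive ridge added to the singular values.
#' @return array of the same shape as `S`.
#' @export
zca_whiten <- function(S, eta = 1e-5) {
  if (is.matrix(S)) S <- array(S, c(dim(S), 1L))
  stopifnot(length(dim(S)) == 3)
  if (!all(is.finite(S))) stop("`S` contains non-finite values", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  out <- S
  for (i in seq_len(dim(S)[3])) {
    Si <- S[, , i]
    Co <- tcrossprod(Si)
    sv <- svd(Co)
    K <- sv$u %*% ((sv$d + eta)^(-0.5) * t(sv$u))
    out[, , i] <- K %*% Si
  }
  out
}

#' Initial weight map: windowed average of the per-pixel channel l1-norm
#'
#' The per-pixel activity is the l1-norm over channels of the whitened stack,
#' `sum_i |S_hat_i(x, y)|`; the weight map averages it over a
#' `(2k+1) x (2k+1)` window centered at each pixel (replicate-padded at the
#' borders).
#'
#' @param S_hat HxWxC whitened stack (or HxW matrix for one channel).
#' @param k window radius (default 2, a 5x5 window).
#' @return HxW nonnegative matrix.
#' @export
l1_window_average <- function(S_hat, k = 2) {
  if (is.matrix(S_hat)) S_hat <- array(S_hat, c(dim(S_hat), 1L))
  stopifnot(length(dim(S_hat)) == 3)
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  l1 <- apply(abs(S_hat), c(1, 2), sum)
  if (k == 0) return(l1)
  box_sum(l1, k) / (2 * k + 1)^2
}

#' Window weighting matrix with dyadic city-block falloff
#'
#' Entry at offset `(p, q)` from the center is `2^(2r - d)` with
#' `d = |p| + |q|` the four-neighborhood (city-block) distance; normalization
#' divides by the total so the entries sum to one. For `r = 1` the normalized
#' matrix is `(1/16) * [[1,2,1],[2,4,2],[1,2,1]]`.
#'
#' @param r window radius (>= 0).
#' @param normalized divide by the sum (default TRUE).
#' @return `(2r+1) x (2r+1)` matrix with attribute `r`.
#' @export
omega_matrix <- function(r = 1, normalized = TRUE) {
  if (length(r) != 1 || r < 0 || r != round(r)) {
    stop("`r` must be a non-negative integer", call. = FALSE)
  }
  off <- seq(-r, r)
  d <- outer(abs(off), abs(off), `+`)
  om <- 2^(2 * r - d)
  if (normalized) om <- om / sum(om)
  attr(om, "r") <- as.integer(r)
  attr(om, "normalized") <- normalized
  om
}

#' Weighted local energy of a weight map
#'
#' `Phi(u, v) = sum_{p,q} Omega(p + r + 1, q + r + 1) * W(u + p, v + q)^2`
#' with replicate-padded borders. With a normalized kernel this is a weighted
#' local mean of squared weights.
#'
#' @param W HxW nonnegative weight map.
#' @param omega kernel from [omega_matrix()] (must be normalized).
#' @return HxW matrix.
#' @export
wle <- function(W, omega = omega_matrix(1)) {
  stopifnot(is.matrix(W))
  if (!isTRUE(attr(omega, "normalized"))) {
    stop("`omega` must be normalized (entries summing to 1)", call. = FALSE)
  }
  conv_window(W^2, omega, mode = "replicate")
}

#' Eight-neighborhood modified Laplacian
#'
#' Per pixel, the sum of four absolute second differences: horizontal,
#' vertical, and the two diagonals, the diagonals carrying weight 1/2.
#' Borders are replicate-padded, so constant and (interior) linear fields map
#' to zero.
#'
#' @param W HxW matrix, at least 3x3.
#' @return HxW nonnegative matrix.
#' @export
eml <- function(W) {
  check_image(W, "W", min_dim = 3L)
  h <- nrow(W); w <- ncol(W)
  Wp <- pad_matrix(W, 1, 1, 1, 1, mode = "replicate")
  ih <- 1L + seq_len(h); iw <- 1L + seq_len(w)
  ctr <- Wp[ih, iw]
  abs(2 * ctr - Wp[ih - 1L, iw] - Wp[ih + 1L, iw]) +
    abs(2 * ctr - Wp[ih, iw - 1L] - Wp[ih, iw + 1L]) +
    0.5 * abs(2 * ctr - Wp[ih - 1L, iw - 1L] - Wp[ih + 1L, iw + 1L]) +
    0.5 * abs(2 * ctr - Wp[ih - 1L, iw + 1L] - Wp[ih + 1L, iw - 1L])
}

#' Weighted sum of the eight-neighborhood modified Laplacian
#'
#' `Psi(u, v) = sum_{p,q} Omega * EML(u + p, v + q)`: the [eml()] field
#' smoothed by the [omega_matrix()] kernel (replicate borders).
#'
#' @inheritParams wle
#' @return HxW matrix.
#' @export
wseml <- function(W, omega = omega_matrix(1)) {
  conv_window(eml(W), omega, mode = "replicate")
}

#' Fuse two candidate weight maps by the WLE x WSEML selection rule
#'
#' Per pixel, the fused map takes `W1` wherever
#' `Phi1 * Psi1 >= Phi2 * Psi2` (ties go to the first source) and `W2`
#' elsewhere. The binary selection mask is returned alongside the values.
#'
#' @param W1,W2 HxW nonnegative weight maps of identical shape.
#' @param omega kernel from [omega_matrix()].
#' @return object of class `fused_weight_map`: list with `values` (HxW) and
#'   `selection_mask` (HxW, 1 where `W1` was taken).
#' @export
fuse_weight_maps <- function(W1, W2, omega = omega_matrix(1)) {
  stopifnot(is.matrix(W1), is.matrix(W2))
  if (!all(dim(W1) == dim(W2))) {
    stop("`W1` and `W2` must have the same shape", call. = FALSE)
  }
  a1 <- wle(W1, omega) * wseml(W1, omega)
  a2 <- wle(W2, omega) * wseml(W2, omega)
  mask <- (a1 >= a2) * 1
  structure(list(values = mask * W1 + (1 - mask) * W2,
                 selection_mask = mask),
            class = "fused_weight_map")
}
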