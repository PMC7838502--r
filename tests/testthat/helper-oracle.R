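# Independent oracles, kept free of the package's own computational paths.

# Reference solver for the LatLRR program (canonical form):
#   min ||X||_* + ||Y||_* + lam ||Z||_1  s.t.  D X + Y D + Z = D.
# Douglas-Rachford splitting: proximal steps on the separable norms
# alternate with a closed-form projection onto the affine constraint,
# derived through the SVD of D. Algorithmically unrelated to the package's
# inexact-ALM solver (no multipliers, no penalty schedule).
latlrr_reference <- function(D, lam, iters = 5000, gamma = 0.5) {
  h <- nrow(D); w <- ncol(D)
  sv <- svd(D, nu = h, nv = w)
  sh2 <- c(sv$d, rep(0, h))[1:h]^2
  sw2 <- c(sv$d, rep(0, w))[1:w]^2
  denom <- outer(sh2, sw2, `+`) + 1
  proj <- function(X, Y, Z) {
    R <- D %*% X + Y %*% D + Z - D
    A <- crossprod(sv$u, R %*% sv$v) / denom
    Lam <- sv$u %*% A %*% t(sv$v)
    list(X = X - crossprod(D, Lam), Y = Y - Lam %*% t(D), Z = Z - Lam)
  }
  svt1 <- function(M, tau) {
    s <- svd(M); d <- pmax(s$d - tau, 0)
    s$u %*% (d * t(s$v))
  }
  soft <- function(M, tau) sign(M) * pmax(abs(M) - tau, 0)
  zX <- matrix(0, w, w); zY <- matrix(0, h, h); zZ <- matrix(0, h, w)
  yX <- zX; yY <- zY; yZ <- zZ
  for (it in seq_len(iters)) {
    p <- proj(zX, zY, zZ)
    yX <- svt1(2 * p$X - zX, gamma)
    yY <- svt1(2 * p$Y - zY, gamma)
    yZ <- soft(2 * p$Z - zZ, gamma * lam)
    zX <- zX + yX - p$X; zY <- zY + yY - p$Y; zZ <- zZ + yZ - p$Z
  }
  out <- proj(yX, yY, yZ)  # feasible point at the fixed point
  out$objective <- sum(svd(out$X, nu = 0, nv = 0)$d) +
    sum(svd(out$Y, nu = 0, nv = 0)$d) + lam * sum(abs(out$Z))
  out
}

# Loop-based replicate-padded window evaluation: fun receives the
# (2r+1)x(2r+1) neighborhood of each pixel.
bf_window <- function(x, r, fun) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (u in seq_len(h)) {
    for (v in seq_len(w)) {
      win <- matrix(0, 2 * r + 1, 2 * r + 1)
      for (p in -r:r) {
        for (q in -r:r) {
          win[p + r + 1, q + r + 1] <-
            x[min(max(u + p, 1), h), min(max(v + q, 1), w)]
        }
      }
      out[u, v] <- fun(win)
    }
  }
  out
}

bf_wle <- function(W, om) {
  r <- (nrow(om) - 1) / 2
  bf_window(W, r, function(win) sum(om * win^2))
}

bf_eml <- function(W) {
  h <- nrow(W); w <- ncol(W)
  g <- function(u, v) W[min(max(u, 1), h), min(max(v, 1), w)]
  out <- matrix(0, h, w)
  for (u in seq_len(h)) {
    for (v in seq_len(w)) {
      out[u, v] <-
        abs(2 * g(u, v) - g(u - 1, v) - g(u + 1, v)) +
        abs(2 * g(u, v) - g(u, v - 1) - g(u, v + 1)) +
        0.5 * abs(2 * g(u, v) - g(u - 1, v - 1) - g(u + 1, v + 1)) +
        0.5 * abs(2 * g(u, v) - g(u - 1, v + 1) - g(u + 1, v - 1))
    }
  }
  out
}

bf_wseml <- function(W, om) {
  r <- (nrow(om) - 1) / 2
  bf_window(bf_eml(W), r, function(win) sum(om * win))
}

bf_l1_window_average <- function(S, k) {
  l1 <- apply(abs(S), c(1, 2), sum)
  bf_window(l1, k, mean)
}

bf_local_energy <- function(x, r = 1) bf_window(x, r, function(w) sum(w^2))

bf_similarity_q <- function(LC, LM, r = 1) {
  ec <- bf_local_energy(LC, r); em <- bf_local_energy(LM, r)
  cross <- matrix(0, nrow(LC), ncol(LC))
  h <- nrow(LC); w <- ncol(LC)
  for (u in seq_len(h)) {
    for (v in seq_len(w)) {
      s <- 0
      for (p in -r:r) for (q in -r:r) {
        s <- s + LC[min(max(u + p, 1), h), min(max(v + q, 1), w)] *
          LM[min(max(u + p, 1), h), min(max(v + q, 1), w)]
      }
      cross[u, v] <- s
    }
  }
  q <- matrix(1, h, w)
  nz <- ec + em > 0
  q[nz] <- 2 * cross[nz] / (ec + em)[nz]
  q
}

# per-pixel loop evaluation of the weight-map selection rule
bf_fuse_weight_maps <- function(W1, W2, om) {
  a1 <- bf_wle(W1, om) * bf_wseml(W1, om)
  a2 <- bf_wle(W2, om) * bf_wseml(W2, om)
  out <- W2
  mask <- matrix(0, nrow(W1), ncol(W1))
  for (u in seq_len(nrow(W1))) {
    for (v in seq_len(ncol(W1))) {
      if (a1[u, v] >= a2[u, v]) { out[u, v] <- W1[u, v]; mask[u, v] <- 1 }
    }
  }
  list(values = out, mask = mask)
}

# direct Pearson formula for the SCD terms
bf_scd <- function(img1, img2, fused) {
  pearson <- function(d, s) {
    d <- as.vector(d); s <- as.vector(s)
    dm <- d - mean(d); sm <- s - mean(s)
    sum(dm * sm) / sqrt(sum(dm^2) * sum(sm^2))
  }
  pearson(fused - img2, img1) + pearson(fused - img1, img2)
}

# joint-histogram mutual information by explicit counting
bf_qmi <- function(img1, img2, fused, bins = 256) {
  q <- function(x) pmin(pmax(round(x * (bins - 1)), 0), bins - 1)
  ent <- function(tab) {
    p <- tab / sum(tab); p <- p[p > 0]; -sum(p * log2(p))
  }
  mi <- function(a, b) {
    ja <- q(a); jb <- q(b)
    tab <- table(as.vector(ja), as.vector(jb))
    ent(table(as.vector(ja))) + ent(table(as.vector(jb))) - ent(tab)
  }
  h <- function(x) ent(table(as.vector(q(x))))
  2 * (mi(img1, fused) / (h(img1) + h(fused)) +
         mi(img2, fused) / (h(img2) + h(fused)))
}
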