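# Latent low-rank representation: split an observed image matrix D into a
# low-rank self-expressive part D %*% X, a salient projected part, and sparse
# noise Z, by minimizing  ||X||_* + ||Y||_* + lambda * ||Z||_1  subject to the
# exact reconstruction constraint. Solved with the inexact augmented Lagrangian
# multiplier (ALM) scheme: closed-form proximal steps (singular value
# thresholding for the nuclear norms, soft thresholding for the l1 term)
# alternate with multiplier ascent and geometric growth of the penalty.

#' Singular value thresholding (proximal operator of the nuclear norm)
#' @return list with the thresholded matrix and its retained singular values.
#' @keywords internal
svt <- function(M, tau) {
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) {
    return(list(M = matrix(0, nrow(M), ncol(M)), d = numeric(0)))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  list(M = U %*% (d[keep] * t(V)), d = d[keep])
}

#' Soft thresholding (proximal operator of the l1 norm)
#' @keywords internal
soft_threshold <- function(M, tau) {
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Solve the latent low-rank representation program
#'
#' Minimizes `||X||_* + ||Y||_* + lambda * ||Z||_1` subject to the observed
#' matrix `D` being reconstructed exactly from a low-rank term, a saliency
#' term, and sparse noise `Z`. In the canonical form (default) the low-rank
#' term is the right-multiplication `D %*% X` (X is WxW) and the saliency term
#' is the left projection `Y %*% D` (Y is HxH). `mode = "strict"` instead takes
#' the saliency term as a second right-multiplication `D %*% Y`, the form in
#' which both coefficient matrices act identically; it is provided for
#' completeness but is degenerate (X and Y are interchangeable) and is not the
#' default.
#'
#' The inexact ALM iteration introduces auxiliary variables J = X and S = Y
#' with their own multipliers, so each sub-problem is a closed-form proximal
#' update. The penalty `mu` grows geometrically by `rho` up to `mu_max`, and
#' the solver stops when the largest absolute entry of all three constraint
#' residuals falls below `tol`.
#'
#' @param D numeric matrix (H x W), finite, at least 2x2. The image itself is
#'   used as the data matrix; no patch extraction.
#' @param lam positive balance coefficient for the sparse term (default 0.8).
#' @param tol convergence tolerance on the max-abs constraint residuals.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE` rather
#'   than raising an error.
#' @param mode `"canonical"` (saliency = Y %*% D) or `"strict"`
#'   (saliency = D %*% Y).
#' @param mu0,rho,mu_max inexact-ALM penalty schedule.
#' @return an object of class `latlrr_solution`: list with coefficient
#'   matrices `X`, `Y`, sparse part `Z`, `objective_trace`, `residual_trace`,
#'   `objective` (recomputed from the converged variables), `iterations`,
#'   `converged`, and `mode`.
#' @examples
#' D <- outer(sin(1:16 / 3), cos(1:16 / 5))
#' sol <- latlrr_solve(D, lam = 0.8)
#' sol$converged
#' @export
latlrr_solve <- function(D, lam = 0.8, tol = 1e-6, max_iter = 500,
                         mode = c("canonical", "strict"),
                         mu0 = 1e-6, rho = 1.1, mu_max = 1e6) {
  mode <- match.arg(mode)
  check_image(D, "D")
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0) {
    stop("`lam` must be a positive scalar", call. = FALSE)
  }
  if (tol <= 0 || max_iter < 1) {
    stop("`tol` must be positive and `max_iter` at least 1", call. = FALSE)
  }
  h <- nrow(D); w <- ncol(D)

  # Gram inverses are constant across iterations; factor once.
  inv_w <- solve(diag(w) + crossprod(D))    # (I + D'D)^-1, WxW
  inv_h <- solve(diag(h) + tcrossprod(D))   # (I + DD')^-1, HxH

  X <- matrix(0, w, w)
  Y <- if (mode == "canonical") matrix(0, h, h) else matrix(0, w, w)
  Z <- matrix(0, h, w)
  J <- X; S <- Y
  L1 <- matrix(0, h, w)                     # multiplier of the data constraint
  L2 <- X * 0                               # multiplier of X = J
  L3 <- Y * 0                               # multiplier of Y = S
  mu <- mu0

  obj_trace <- numeric(0)
  res_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  saliency_of <- function(Y) if (mode == "canonical") Y %*% D else D %*% Y

  repeat {
    iter <- iter + 1L
    # proximal updates of the auxiliary nuclear-norm variables
    sj <- svt(X + L2 / mu, 1 / mu)
    J <- sj$M
    ss <- svt(Y + L3 / mu, 1 / mu)
    S <- ss$M

    # coefficient updates (ridge-type solves with fixed Gram factors)
    X <- inv_w %*% (crossprod(D, D - saliency_of(Y) - Z) + J +
                      (crossprod(D, L1) - L2) / mu)
    if (mode == "canonical") {
      Y <- ((D - D %*% X - Z) %*% t(D) + S + (L1 %*% t(D) - L3) / mu) %*% inv_h
    } else {
      Y <- inv_w %*% (crossprod(D, D - D %*% X - Z) + S +
                        (crossprod(D, L1) - L3) / mu)
    }

    recon <- D %*% X + saliency_of(Y)
    Z <- soft_threshold(D - recon + L1 / mu, lam / mu)

    R1 <- D - recon - Z
    R2 <- X - J
    R3 <- Y - S
    L1 <- L1 + mu * R1
    L2 <- L2 + mu * R2
    L3 <- L3 + mu * R3
    mu <- min(rho * mu, mu_max)

    # cheap objective surrogate from the already-thresholded variables
    obj_trace[iter] <- sum(sj$d) + sum(ss$d) + lam * sum(abs(Z))
    res <- max(max(abs(R1)), max(abs(R2)), max(abs(R3)))
    res_trace[iter] <- res

    if (res <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  objective <- sum(svd(X, nu = 0, nv = 0)$d) + sum(svd(Y, nu = 0, nv = 0)$d) +
    lam * sum(abs(Z))
  structure(list(X = X, Y = Y, Z = Z,
                 objective = objective,
                 objective_trace = obj_trace,
                 residual_trace = res_trace,
                 iterations = iter,
                 converged = converged,
                 lam = lam, tol = tol, mode = mode),
            class = "latlrr_solution")
}

#' @export
print.latlrr_solution <- function(x, ...) {
  cat(sprintf(
    "LatLRR solution (%s form): %d iterations, %s, objective %.6g\n",
    x$mode, x$iterations,
    if (x$converged) "converged" else "NOT converged", x$objective))
  invisible(x)
}

#' Decompose an image into low-rank, saliency, and noise components
#'
#' Runs [latlrr_solve()] on the image used directly as the data matrix and
#' assembles the three additive components: `low_rank = img %*% X`,
#' `saliency` (the projected term), and `noise = Z`. The three sum back to the
#' input within the solver tolerance. Intensities are expected on the
#' canonical [0, 1] scale; component values are not re-clipped, so saliency
#' and noise entries may be negative.
#'
#' @param img numeric matrix in [0, 1], at least 2x2.
#' @param lam balance coefficient (default 0.8).
#' @param ... further arguments to [latlrr_solve()].
#' @return object of class `decomposition`: list with `low_rank`, `saliency`,
#'   `noise` (all `dim(img)`), and the underlying `solution`.
#' @examples
#' img <- make_gray_pair(phantom_spec(size = 32, seed = 1))$a
#' dec <- decompose_image(img)
#' max(abs(img - (dec$low_rank + dec$saliency + dec$noise)))
#' @export
decompose_image <- function(img, lam = 0.8, ...) {
  check_image(img, "img", unit_range = TRUE)
  sol <- latlrr_solve(img, lam = lam, ...)
  low_rank <- img %*% sol$X
  saliency <- if (sol$mode == "canonical") sol$Y %*% img else img %*% sol$Y
  structure(list(low_rank = low_rank, saliency = saliency, noise = sol$Z,
                 solution = sol),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  d <- dim(x$low_rank)
  cat(sprintf("LatLRR decomposition of a %dx%d image (%s)\n", d[1], d[2],
              if (x$solution$converged) "converged" else "not converged"))
  cat(sprintf("  component energy  low-rank %.4g | saliency %.4g | noise %.4g\n",
              sum(x$low_rank^2), sum(x$saliency^2), sum(x$noise^2)))
  invisible(x)
}
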