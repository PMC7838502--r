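#' Pad a matrix by border replication or reflection
#'
#' Internal helper behind every windowed operator in the package. Replicate
#' padding repeats the border row/column; reflect padding mirrors without
#' repeating the border sample (the convention used by the pyramid filter).
#'
#' @param x numeric matrix.
#' @param top,bottom,left,right non-negative pad widths.
#' @param mode "replicate" or "reflect".
#' @return padded matrix.
#' @keywords internal
pad_matrix <- function(x, top, bottom = top, left = top, right = left,
                       mode = c("replicate", "reflect")) {
  mode <- match.arg(mode)
  h <- nrow(x); w <- ncol(x)
  idx <- function(n, before, after) {
    core <- seq_len(n)
    if (mode == "replicate") {
      c(rep(1L, before), core, rep(n, after))
    } else {
      # mirror without repeating the edge sample; fold indices back into range
      i <- c(rev(seq_len(before)) + 1L, core, n - seq_len(after))
      i[i < 1L] <- 2L - i[i < 1L]
      i[i > n] <- 2L * n - i[i > n]
      pmin(pmax(i, 1L), n)
    }
  }
  x[idx(h, top, bottom), idx(w, left, right), drop = FALSE]
}

#' Dense windowed correlation with border padding
#'
#' Computes `sum_{p,q} kernel[p,q] * x[u+p-r1-1, v+q-r2-1]` at every pixel by
#' shift-and-accumulate, which is exact in floating point (no FFT round-off).
#' Suitable for the small kernels used throughout (3x3 to 7x7).
#'
#' @param x numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @param mode border policy passed to [pad_matrix()].
#' @return matrix of `dim(x)`.
#' @keywords internal
conv_window <- function(x, kernel, mode = "replicate") {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- pad_matrix(x, rh, rh, rw, rw, mode = mode)
  out <- matrix(0, h, w)
  for (p in seq_len(kh)) {
    for (q in seq_len(kw)) {
      kv <- kernel[p, q]
      if (kv != 0) {
        out <- out + kv * xp[(p - 1L) + seq_len(h), (q - 1L) + seq_len(w)]
      }
    }
  }
  out
}

#' Windowed box sum (all-ones kernel of radius r)
#' @keywords internal
box_sum <- function(x, r, mode = "replicate") {
  conv_window(x, matrix(1, 2L * r + 1L, 2L * r + 1L), mode = mode)
}

#' Validate a numeric image matrix
#' @keywords internal
check_image <- function(img, name = "img", min_dim = 2L, unit_range = FALSE) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d", name, min_dim, min_dim),
         call. = FALSE)
  }
  if (unit_range && (min(img) < -1e-9 || max(img) > 1 + 1e-9)) {
    stop(sprintf("`%s` must have intensities in [0, 1]", name), call. = FALSE)
  }
  invisible(img)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic internals never disturb
#' the caller's random stream.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
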