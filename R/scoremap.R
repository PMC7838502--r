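# Per-pixel class-score maps for a low-rank component. Two backends share
# one contract (HxWxC stack, C = 21 by default, deterministic at inference):
#
#  * the FCN family (fcn32s / fcn16s / fcn8s): the VGG16-based fully
#    convolutional segmentation architecture -- 16 convolution layers, 15
#    ReLUs, 5 max-pools and 2 dropout layers before upsampling -- with the
#    stride-32/16/8 skip heads. Weights are external artifacts; seeded random
#    weights are supported for shape-contract checks, with the upsampling
#    stages fixed to bilinear interpolation (the standard initialization of
#    the learned transposed convolutions).
#  * a synthetic backend: a fixed multi-scale bank of derivative-of-Gaussian
#    and Laplacian-of-Gaussian filters (orientation-jittered by a seed), fully
#    deterministic and weight-free, so every downstream stage is testable
#    offline.

fcn_variants <- c("fcn32s", "fcn16s", "fcn8s")

#' Describe a score-map backend
#'
#' @param variant one of `"synthetic"`, `"fcn32s"`, `"fcn16s"`, `"fcn8s"`.
#' @param weights for FCN variants: a path to an `.rds` weight list, a weight
#'   list itself, or the string `"random"` for seeded random weights
#'   (shape-contract testing). Ignored by the synthetic backend.
#' @param seed integer seed (orientation jitter for the synthetic bank;
#'   random weight draw for `weights = "random"`).
#' @param C number of score channels (default 21).
#' @param width_scale multiplies the FCN channel widths; values below 1 give
#'   a thin net for structural tests (the architecture is unchanged).
#' @return list of class `backend_spec`.
#' @export
backend_spec <- function(variant = c("synthetic", fcn_variants),
                         weights = NULL, seed = 1L, C = 21L,
                         width_scale = 1) {
  variant <- match.arg(variant)
  if (C < 1) stop("`C` must be >= 1", call. = FALSE)
  structure(list(variant = variant, weights = weights, seed = as.integer(seed),
                 C = as.integer(C), width_scale = width_scale,
                 preprocessing = list(replicate_channels = 3L,
                                      mean = c(0.485, 0.456, 0.406))),
            class = "backend_spec")
}

#' FCN architecture description
#'
#' Returns the layer table of the VGG16-based fully convolutional network in
#' its three upsampling scenarios. Before upsampling the trunk has 16
#' convolution layers (13 VGG + fc6 + fc7 + the score layer), 15 ReLUs, 5
#' max-pools and 2 dropouts. `fcn32s` upsamples the final stride-32
#' prediction in one step; `fcn16s` fuses the final and pool4 predictions at
#' stride 16; `fcn8s` fuses pool3, pool4 and the final prediction at stride 8.
#'
#' @param variant `"fcn32s"`, `"fcn16s"` or `"fcn8s"`.
#' @param C output channel count (default 21).
#' @param width_scale channel-width multiplier (1 = the published widths).
#' @return list of class `fcn_architecture` with the trunk `layers`
#'   data.frame, the `skips` used by the head, and the output `stride`.
#' @export
fcn_architecture <- function(variant = fcn_variants, C = 21L,
                             width_scale = 1) {
  variant <- match.arg(variant)
  wd <- function(x) max(1L, as.integer(round(x * width_scale)))
  blocks <- list(c(2L, 64L), c(2L, 128L), c(3L, 256L), c(3L, 512L),
                 c(3L, 512L))
  layers <- list()
  add <- function(name, type, out = NA, kernel = NA, pad = NA, stride = 1L) {
    layers[[length(layers) + 1L]] <<- data.frame(
      name = name, type = type, out_channels = out, kernel = kernel,
      pad = pad, stride = stride, stringsAsFactors = FALSE)
  }
  first <- TRUE
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[[b]][1])) {
      nm <- sprintf("conv%d_%d", b, i)
      add(nm, "conv", wd(blocks[[b]][2]), 3L, if (first) 100L else 1L)
      add(sub("conv", "relu", nm), "relu")
      first <- FALSE
    }
    add(sprintf("pool%d", b), "pool", kernel = 2L, stride = 2L)
  }
  add("fc6", "conv", wd(4096L), 7L, 0L); add("relu6", "relu")
  add("drop6", "dropout")
  add("fc7", "conv", wd(4096L), 1L, 0L); add("relu7", "relu")
  add("drop7", "dropout")
  add("score_fr", "conv", as.integer(C), 1L, 0L)
  layers <- do.call(rbind, layers)
  skips <- switch(variant,
                  fcn32s = character(0),
                  fcn16s = "pool4",
                  fcn8s = c("pool4", "pool3"))
  structure(list(variant = variant, C = as.integer(C),
                 width_scale = width_scale, layers = layers, skips = skips,
                 stride = switch(variant, fcn32s = 32L, fcn16s = 16L,
                                 fcn8s = 8L)),
            class = "fcn_architecture")
}

#' @export
print.fcn_architecture <- function(x, ...) {
  tab <- table(x$layers$type)
  cat(sprintf("%s: %d trunk layers (%s), output stride %d, C = %d\n",
              x$variant, nrow(x$layers),
              paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
              x$stride, x$C))
  if (length(x$skips)) cat("  skip connections from:",
                           paste(x$skips, collapse = ", "), "\n")
  invisible(x)
}

# ---- minimal tensor ops (H x W x C arrays) --------------------------------

conv2d <- function(x, w, b, pad = 0L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  if (pad > 0) {
    xp <- array(0, c(h + 2 * pad, wd + 2 * pad, cin))
    xp[pad + seq_len(h), pad + seq_len(wd), ] <- x
    x <- xp; h <- h + 2 * pad; wd <- wd + 2 * pad
  }
  ho <- h - kh + 1L; wo <- wd - kw + 1L
  if (ho < 1 || wo < 1) stop("input too small for this convolution",
                             call. = FALSE)
  acc <- matrix(rep(b, each = ho * wo), ho * wo, cout)
  for (p in seq_len(kh)) {
    for (q in seq_len(kw)) {
      xs <- x[(p - 1L) + seq_len(ho), (q - 1L) + seq_len(wo), , drop = FALSE]
      dim(xs) <- c(ho * wo, cin)
      wk <- w[p, q, , , drop = FALSE]
      dim(wk) <- c(cin, cout)
      acc <- acc + xs %*% wk
    }
  }
  array(acc, c(ho, wo, cout))
}

maxpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  he <- 2L * ceiling(h / 2); we <- 2L * ceiling(w / 2)  # ceil mode
  xp <- array(-Inf, c(he, we, cc))
  xp[seq_len(h), seq_len(w), ] <- x
  io <- seq(1, he, by = 2); jo <- seq(1, we, by = 2)
  pmax(xp[io, jo, , drop = FALSE], xp[io + 1L, jo, , drop = FALSE],
       xp[io, jo + 1L, , drop = FALSE], xp[io + 1L, jo + 1L, , drop = FALSE])
}

# Bilinear upsampling by an integer factor (per channel), the fixed
# initialization of the FCN transposed convolutions.
upsample_bilinear <- function(x, f) {
  interp_mat <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) / f + 0.5 - 0.5 / f
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - ifelse(n_in > 1, 1, 0))
    frac <- src - lo
    A <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      A[i, lo[i]] <- 1 - frac[i]
      A[i, min(lo[i] + 1, n_in)] <- A[i, min(lo[i] + 1, n_in)] + frac[i]
    }
    A
  }
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  Ah <- interp_mat(h, h * f); Aw <- interp_mat(w, w * f)
  out <- array(0, c(h * f, w * f, cc))
  for (k in seq_len(cc)) out[, , k] <- Ah %*% x[, , k] %*% t(Aw)
  out
}

crop_center <- function(x, h, w) {
  dh <- dim(x)[1] - h; dw <- dim(x)[2] - w
  stopifnot(dh >= 0, dw >= 0)
  oi <- dh %/% 2L; oj <- dw %/% 2L
  x[oi + seq_len(h), oj + seq_len(w), , drop = FALSE]
}

#' Seeded random weights for an FCN architecture
#'
#' Gaussian conv weights scaled by fan-in, zero biases. Intended for
#' shape-contract tests only; the upsampling path always uses bilinear
#' interpolation, so no deconvolution weights are drawn.
#'
#' @param arch an [fcn_architecture()].
#' @param seed integer seed.
#' @return named list of `list(w, b)` per conv layer, including the skip
#'   score layers.
#' @export
fcn_random_weights <- function(arch, seed = 1L) {
  with_local_seed(seed, {
    out <- list()
    cin <- 3L
    for (i in seq_len(nrow(arch$layers))) {
      ly <- arch$layers[i, ]
      if (ly$type == "conv") {
        k <- ly$kernel; co <- ly$out_channels
        fan <- k * k * cin
        out[[ly$name]] <- list(
          w = array(rnorm(k * k * cin * co, sd = 1 / sqrt(fan)),
                    c(k, k, cin, co)),
          b = numeric(co))
        cin <- co
      }
    }
    widths <- arch$layers$out_channels
    names(widths) <- arch$layers$name
    pool_in <- c(pool3 = unname(widths["conv3_3"]),
                 pool4 = unname(widths["conv4_3"]))
    for (sk in arch$skips) {
      ci <- pool_in[[sk]]
      out[[paste0("score_", sk)]] <- list(
        w = array(rnorm(ci * arch$C, sd = 1 / sqrt(ci)),
                  c(1L, 1L, ci, arch$C)),
        b = numeric(arch$C))
    }
    out
  })
}

fcn_forward <- function(arch, img, weights) {
  h0 <- nrow(img); w0 <- ncol(img)
  x <- array(rep(img, 3L), c(h0, w0, 3L))
  pre <- c(0.485, 0.456, 0.406)
  for (k in 1:3) x[, , k] <- x[, , k] - pre[k]
  taps <- list()
  for (i in seq_len(nrow(arch$layers))) {
    ly <- arch$layers[i, ]
    x <- switch(ly$type,
                conv = conv2d(x, weights[[ly$name]]$w, weights[[ly$name]]$b,
                              pad = ly$pad),
                relu = pmax(x, 0),
                pool = maxpool2(x),
                dropout = x)  # inference: dropout is the identity
    if (ly$type == "pool") taps[[ly$name]] <- x
  }
  score <- x
  # skip head: progressively upsample by 2 and add scored pool taps
  for (sk in arch$skips) {
    score <- upsample_bilinear(score, 2L)
    wsk <- weights[[paste0("score_", sk)]]
    tap <- conv2d(taps[[sk]], wsk$w, wsk$b, pad = 0L)
    hh <- min(dim(score)[1], dim(tap)[1])
    ww <- min(dim(score)[2], dim(tap)[2])
    score <- crop_center(score, hh, ww) + crop_center(tap, hh, ww)
  }
  final_up <- arch$stride
  score <- upsample_bilinear(score, final_up)
  crop_center(score, h0, w0)
}

# ---- synthetic filter-bank backend ----------------------------------------

gauss_deriv_bank <- function(C, seed) {
  scales <- c(1, 2, 4)
  jitter <- if (is.null(seed)) rep(0, C) else {
    with_local_seed(seed, runif(C, -pi / 16, pi / 16))
  }
  kernels <- vector("list", C)
  ci <- 1L
  per_scale <- ceiling(C / length(scales))
  for (sg in scales) {
    r <- ceiling(3 * sg)
    xs <- seq(-r, r)
    g <- exp(-xs^2 / (2 * sg^2))
    G <- outer(g, g); G <- G / sum(G)
    X <- outer(xs, rep(1, length(xs))); Yc <- t(X)
    gx <- -X / sg^2 * G
    gy <- -Yc / sg^2 * G
    log_k <- ((X^2 + Yc^2) / sg^4 - 2 / sg^2) * G
    for (j in seq_len(per_scale)) {
      if (ci > C) break
      kind <- (j - 1L) %% 7L
      th <- (j - 1L) * pi / 4 + jitter[ci]
      kernels[[ci]] <- switch(
        as.character(kind %% 3L),
        "0" = cos(th) * gx + sin(th) * gy,          # oriented first derivative
        "1" = log_k * (1 + 0.25 * sin(th)),         # scaled LoG
        "2" = cos(th) * (gx - gy) + sin(th) * (gx + gy))
      # enforce exact zero mean so flat images map to exactly zero response
      kernels[[ci]] <- kernels[[ci]] - mean(kernels[[ci]])
      ci <- ci + 1L
    }
  }
  kernels
}

synthetic_score_maps <- function(img, spec) {
  bank <- gauss_deriv_bank(spec$C, spec$seed)
  out <- array(0, c(nrow(img), ncol(img), spec$C))
  for (i in seq_len(spec$C)) {
    out[, , i] <- conv_window(img, bank[[i]], mode = "replicate")
  }
  out
}

#' Compute per-pixel class-score maps for an image
#'
#' Runs the configured backend on a [0, 1] grayscale image and returns the
#' HxWxC score-map stack. Inference is deterministic: dropout is disabled in
#' the FCN path and the synthetic bank is a pure function of its seed.
#'
#' @param img numeric matrix in [0, 1].
#' @param backend a [backend_spec()] (default: synthetic, C = 21).
#' @return HxWxC numeric array with attribute `variant`.
#' @examples
#' s <- score_maps(make_gray_pair(phantom_spec(size = 32))$a)
#' dim(s)
#' @export
score_maps <- function(img, backend = backend_spec()) {
  check_image(img, "img", unit_range = TRUE)
  stopifnot(inherits(backend, "backend_spec"))
  if (backend$variant == "synthetic") {
    out <- synthetic_score_maps(img, backend)
  } else {
    arch <- fcn_architecture(backend$variant, C = backend$C,
                             width_scale = backend$width_scale)
    w <- backend$weights
    if (is.null(w)) {
      stop(sprintf(
        "backend '%s' needs trained weights: set `weights` to an .rds path, a weight list, or \"random\"",
        backend$variant), call. = FALSE)
    }
    if (identical(w, "random")) {
      w <- fcn_random_weights(arch, backend$seed)
    } else if (is.character(w)) {
      if (!file.exists(w)) {
        stop(sprintf("weight file not found: %s", w), call. = FALSE)
      }
      w <- readRDS(w)
    }
    out <- fcn_forward(arch, img, w)
  }
  attr(out, "variant") <- backend$variant
  out
}
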