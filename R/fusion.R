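# End-to-end fusion of a co-registered image pair:
#   part 1  LatLRR decomposition of both sources;
#   part 2  score maps -> ZCA + windowed l1 weight maps -> WLE/WSEML fused
#           weight map -> pyramid fusion of the low-rank components;
#   part 3  sum of the saliency components;
#   part 4  combination (and clipping) of the fused low-rank and saliency
#           parts into the final image.
# The grayscale + RGB path converts the color image to YUV, fuses the luma
# against the grayscale source, and passes the chroma through untouched.

#' Configuration of the fusion pipeline
#'
#' Defaults reproduce the reference parameterization: `lam = 0.8` (LatLRR
#' balance), `tau = 0.8` (pyramid similarity threshold), `C = 21` score
#' channels, `k = 2` (5x5 l1 window), `r = 1` (3x3 WLE/WSEML kernel).
#'
#' @param lam LatLRR balance coefficient.
#' @param tau pyramid similarity threshold in (0, 1].
#' @param C score-map channel count.
#' @param k l1-average window radius.
#' @param r WLE/WSEML kernel radius.
#' @param eta ZCA whitening ridge.
#' @param backend a [backend_spec()]; its `C` is synchronized with `C`.
#' @param pyramid list with `levels` ("auto" or integer), `max_levels`,
#'   `window`.
#' @param clip output policy: `"clip"` truncates the combined image to
#'   [0, 1]; `"rescale"` affinely maps its range onto [0, 1].
#' @param latlrr list of solver settings forwarded to [latlrr_solve()].
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(lam = 0.8, tau = 0.8, C = 21L, k = 2L, r = 1L,
                          eta = 1e-5, backend = backend_spec(C = C),
                          pyramid = list(levels = "auto", max_levels = 8L,
                                         window = 3L),
                          clip = c("clip", "rescale"),
                          latlrr = list(tol = 1e-6, max_iter = 500,
                                        mode = "canonical")) {
  clip <- match.arg(clip)
  backend$C <- as.integer(C)
  structure(list(lam = lam, tau = tau, C = as.integer(C), k = as.integer(k),
                 r = as.integer(r), eta = eta, backend = backend,
                 pyramid = pyramid, clip = clip, latlrr = latlrr),
            class = "fusion_config")
}

#' Fuse two saliency components by summation
#'
#' Plain elementwise sum, the energy-preserving rule for the LatLRR saliency
#' parts. No rescaling is applied.
#'
#' @param ls1,ls2 saliency components of identical shape.
#' @return matrix `ls1 + ls2`.
#' @export
fuse_saliency <- function(ls1, ls2) {
  if (!all(dim(ls1) == dim(ls2))) stop("shape mismatch", call. = FALSE)
  ls1 + ls2
}

apply_output_policy <- function(x, policy) {
  if (policy == "rescale") {
    rng <- range(x)
    if (rng[2] > rng[1]) return(list(img = (x - rng[1]) / (rng[2] - rng[1]),
                                     clipped_fraction = 0))
    return(list(img = pmin(pmax(x, 0), 1), clipped_fraction = 0))
  }
  frac <- mean(x < 0 | x > 1)
  if (frac > 0) {
    message(sprintf("output clipping: %.2f%% of pixels outside [0, 1]",
                    100 * frac))
  }
  list(img = pmin(pmax(x, 0), 1), clipped_fraction = frac)
}

#' Fuse a co-registered pair of grayscale images
#'
#' Runs the full pipeline and returns the fused image together with every
#' intermediate, so any downstream stage can be re-run in isolation. The
#' computation is deterministic for a fixed configuration (the score-map
#' backend seed included).
#'
#' @param img1,img2 numeric matrices in [0, 1], identical shape.
#' @param cfg a [fusion_config()].
#' @return object of class `fusion_result`: list with `fused`,
#'   `fused_low_rank`, `fused_saliency`, decompositions `dec1`/`dec2`,
#'   weight maps `w1`/`w2`, fused weight map `fw` (with `selection_mask`),
#'   `clipped_fraction`, the `config`, and the executed `stage_trace`.
#' @examples
#' p <- make_gray_pair(phantom_spec(size = 32, seed = 5))
#' res <- fuse_pair(p$a, p$b, fusion_config(latlrr = list(max_iter = 200)))
#' range(res$fused)
#' @export
fuse_pair <- function(img1, img2, cfg = fusion_config()) {
  check_image(img1, "img1", unit_range = TRUE)
  check_image(img2, "img2", unit_range = TRUE)
  if (!all(dim(img1) == dim(img2))) {
    stop("`img1` and `img2` must have the same shape", call. = FALSE)
  }
  stopifnot(inherits(cfg, "fusion_config"))
  trace <- character(0)
  note <- function(s) trace <<- c(trace, s)

  la <- cfg$latlrr
  solver_args <- list(lam = cfg$lam)
  for (nm in c("tol", "max_iter", "mode")) {
    if (!is.null(la[[nm]])) solver_args[[nm]] <- la[[nm]]
  }
  note("decompose")
  dec1 <- do.call(decompose_image, c(list(img1), solver_args))
  dec2 <- do.call(decompose_image, c(list(img2), solver_args))

  note("score_maps")
  # low-rank components can stray marginally outside [0,1]; the score-map
  # backends expect unit-range input, so clamp for scoring only
  s1 <- score_maps(pmin(pmax(dec1$low_rank, 0), 1), cfg$backend)
  s2 <- score_maps(pmin(pmax(dec2$low_rank, 0), 1), cfg$backend)

  note("zca_l1_weight_maps")
  w1 <- l1_window_average(zca_whiten(s1, cfg$eta), cfg$k)
  w2 <- l1_window_average(zca_whiten(s2, cfg$eta), cfg$k)

  note("wle_wseml_fusion")
  om <- omega_matrix(cfg$r)
  fw <- fuse_weight_maps(w1, w2, om)

  note("pyramid_fuse_low_rank")
  pf <- pyramid_fuse(dec1$low_rank, dec2$low_rank, fw$values,
                     tau = cfg$tau, levels = cfg$pyramid$levels,
                     window = cfg$pyramid$window,
                     max_levels = cfg$pyramid$max_levels)

  note("sum_saliency")
  f_ls <- fuse_saliency(dec1$saliency, dec2$saliency)

  note("combine")
  out <- apply_output_policy(pf$fused + f_ls, cfg$clip)

  structure(list(fused = out$img,
                 fused_low_rank = pf$fused,
                 fused_saliency = f_ls,
                 dec1 = dec1, dec2 = dec2,
                 w1 = w1, w2 = w2, fw = fw,
                 clipped_fraction = out$clipped_fraction,
                 config = cfg, stage_trace = trace),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused)
  cat(sprintf("fusion result %dx%d | stages: %s | clipped %.2f%%\n",
              d[1], d[2], paste(x$stage_trace, collapse = " -> "),
              100 * x$clipped_fraction))
  invisible(x)
}

# BT.601 analog YUV: Y in [0,1]; U, V zero-centered chroma differences.
# U and V rows are built from the luma row (U = 0.436 (B - Y) / (1 - wb),
# V = 0.615 (R - Y) / (1 - wr)) so achromatic inputs map to exactly zero
# chroma; the inverse is the exact matrix inverse.
yuv_forward_matrix <- local({
  wr <- 0.299; wg <- 0.587; wb <- 0.114
  y <- c(wr, wg, wb)
  rbind(y,
        0.436 / (1 - wb) * (c(0, 0, 1) - y),
        0.615 / (1 - wr) * (c(1, 0, 0) - y))
})
yuv_inverse_matrix <- solve(yuv_forward_matrix)

#' RGB to YUV (BT.601 analog) and back
#'
#' The forward matrix maps R, G, B in [0, 1] to luma Y in [0, 1] and
#' zero-centered chroma U, V; the inverse is the exact matrix inverse, so a
#' round trip reproduces the input to floating-point precision.
#'
#' @param rgb HxWx3 array in [0, 1] (`rgb_to_yuv`).
#' @param yuv HxWx3 array of Y, U, V planes (`yuv_to_rgb`).
#' @return HxWx3 array. `yuv_to_rgb` output is not clipped.
#' @export
rgb_to_yuv <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  apply_color_matrix(rgb, yuv_forward_matrix)
}

#' @rdname rgb_to_yuv
#' @export
yuv_to_rgb <- function(yuv) {
  stopifnot(length(dim(yuv)) == 3, dim(yuv)[3] == 3)
  apply_color_matrix(yuv, yuv_inverse_matrix)
}

apply_color_matrix <- function(x, M) {
  d <- dim(x)
  flat <- matrix(x, d[1] * d[2], 3)
  array(flat %*% t(M), d)
}

#' Fuse a grayscale image with an RGB image through the YUV path
#'
#' Converts the RGB (functional) image to YUV, fuses its luma channel with
#' the grayscale (structural) image via [fuse_pair()], recombines the fused
#' luma with the original chroma, and inverse-transforms. Chroma passes
#' through untouched before the final clip.
#'
#' @param gray numeric matrix in [0, 1].
#' @param rgb HxWx3 array in [0, 1], co-registered with `gray`.
#' @param cfg a [fusion_config()].
#' @return object of class `color_fusion_result`: list with the clipped
#'   `fused_rgb`, the pre-clip `fused_rgb_raw`, the luma `fusion`
#'   ([fuse_pair()] result), and the input chroma planes `u`, `v`.
#' @export
fuse_color <- function(gray, rgb, cfg = fusion_config()) {
  check_image(gray, "gray", unit_range = TRUE)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("`rgb` must be an HxWx3 array", call. = FALSE)
  }
  if (!all(dim(rgb)[1:2] == dim(gray))) stop("shape mismatch", call. = FALSE)
  yuv <- rgb_to_yuv(rgb)
  y <- pmin(pmax(yuv[, , 1], 0), 1)
  res <- fuse_pair(gray, y, cfg)
  out_yuv <- yuv
  out_yuv[, , 1] <- res$fused
  raw <- yuv_to_rgb(out_yuv)
  structure(list(fused_rgb = pmin(pmax(raw, 0), 1),
                 fused_rgb_raw = raw,
                 fusion = res, u = yuv[, , 2], v = yuv[, , 3]),
            class = "color_fusion_result")
}
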