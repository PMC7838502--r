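# The five standard objective fusion-quality scores, computed on
# (source 1, source 2, fused) triples of [0,1] images. Histogram-based
# metrics quantize to 8-bit levels first; all degenerate cases (flat images,
# zero variance) return defined values with a warning so batch evaluation
# never aborts.

quantize8 <- function(img, bins = 256L) {
  pmin(pmax(round(img * (bins - 1L)), 0L), bins - 1L)
}

entropy_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of an image histogram
#'
#' Base-2 entropy of the `bins`-level intensity histogram (0 log 0 = 0).
#' Measures the information content of a fused image; lies in
#' [0, log2(bins)].
#'
#' @param img numeric matrix in [0, 1].
#' @param bins histogram resolution (default 256).
#' @return scalar entropy in bits.
#' @export
image_entropy <- function(img, bins = 256L) {
  check_image(img, "img", min_dim = 1L, unit_range = TRUE)
  q <- quantize8(img, bins)
  entropy_counts(tabulate(q + 1L, nbins = bins))
}

joint_hist <- function(a, b, bins = 256L) {
  qa <- quantize8(a, bins); qb <- quantize8(b, bins)
  idx <- qa + bins * qb + 1L
  matrix(tabulate(idx, nbins = bins * bins), bins, bins)
}

mutual_information <- function(a, b, bins = 256L) {
  jh <- joint_hist(a, b, bins)
  entropy_counts(rowSums(jh)) + entropy_counts(colSums(jh)) -
    entropy_counts(jh)
}

#' Normalized mutual information quality of a fused image
#'
#' `Q_MI = 2 * [ MI(Img1, F) / (H(Img1) + H(F)) + MI(Img2, F) / (H(Img2) +
#' H(F)) ]` from joint 8-bit histograms. Equals 2 when the fused image is an
#' exact copy of both (non-constant) sources. A zero-entropy denominator
#' contributes 0 with a warning.
#'
#' @param img1,img2,fused numeric matrices in [0, 1], identical shape.
#' @param bins histogram resolution.
#' @return scalar in [0, 2] up to histogram round-off.
#' @export
metric_qmi <- function(img1, img2, fused, bins = 256L) {
  stopifnot(all(dim(img1) == dim(fused)), all(dim(img2) == dim(fused)))
  hf <- image_entropy(fused, bins)
  term <- function(src) {
    den <- image_entropy(src, bins) + hf
    if (den <= 0) {
      warning("zero-entropy image pair; Q_MI term set to 0", call. = FALSE)
      return(0)
    }
    mutual_information(src, fused, bins) / den
  }
  2 * (term(img1) + term(img2))
}

sobel_xy <- function(img) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = conv_window(img, sx, mode = "replicate"),
       gy = conv_window(img, t(sx), mode = "replicate"))
}

#' Gradient-based edge preservation metric Q^AB/F
#'
#' Measures how well edge strength and orientation of each source survive in
#' the fused image. Sobel gradients give per-pixel strength `g` and angle
#' `alpha`; relative preservation values are mapped through the standard
#' logistic models `Q_g = Gamma_g / (1 + exp(kappa_g * (G - sigma_g)))` and
#' likewise for orientation, multiplied, and averaged with weights equal to
#' the source edge strengths. Lies in [0, 1]; a copy of the (identical)
#' sources scores the logistic ceiling `Q_g(1) * Q_alpha(1)`.
#'
#' @param img1,img2,fused numeric matrices in [0, 1], identical shape, at
#'   least 3x3.
#' @param gamma_g,kappa_g,sigma_g strength-preservation logistic constants.
#' @param gamma_a,kappa_a,sigma_a orientation-preservation constants.
#' @param L exponent of the edge-strength weights.
#' @return scalar in [0, 1]; 0 with a warning when all inputs are flat.
#' @export
metric_qabf <- function(img1, img2, fused,
                        gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                        gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
                        L = 1) {
  stopifnot(all(dim(img1) == dim(fused)), all(dim(img2) == dim(fused)))
  check_image(fused, "fused", min_dim = 3L)
  gf <- sobel_xy(fused)
  g_f <- sqrt(gf$gx^2 + gf$gy^2)
  a_f <- atan2(gf$gy, gf$gx)
  qxf <- function(src) {
    gs <- sobel_xy(src)
    g_s <- sqrt(gs$gx^2 + gs$gy^2)
    a_s <- atan2(gs$gy, gs$gx)
    # relative strength preservation: ratio of the weaker to the stronger,
    # defined as 1 when both strengths agree (including both zero)
    G <- ifelse(g_s > g_f, ifelse(g_s > 0, g_f / pmax(g_s, 1e-300), 1),
                ifelse(g_f > g_s, ifelse(g_f > 0, g_s / pmax(g_f, 1e-300), 1),
                       1))
    da <- abs(a_s - a_f)
    da <- pmin(da, 2 * pi - da)      # wrap
    da <- ifelse(da > pi / 2, pi - da, da)  # gradient sign is immaterial
    A <- 1 - da / (pi / 2)
    Qg <- gamma_g / (1 + exp(kappa_g * (G - sigma_g)))
    Qa <- gamma_a / (1 + exp(kappa_a * (A - sigma_a)))
    list(q = Qg * Qa, w = g_s^L)
  }
  q1 <- qxf(img1); q2 <- qxf(img2)
  wsum <- sum(q1$w) + sum(q2$w)
  # treat numerically-zero total edge strength (flat inputs up to Sobel
  # cancellation round-off) as "no edges"
  if (wsum <= length(g_f) * 1e-12) {
    warning("all-flat inputs: no edges to preserve, Q^AB/F = 0",
            call. = FALSE)
    return(0)
  }
  (sum(q1$q * q1$w) + sum(q2$q * q2$w)) / wsum
}

#' Sum of the correlations of differences (SCD)
#'
#' `SCD = r(F - Img2, Img1) + r(F - Img1, Img2)` with Pearson correlation
#' `r`. Each difference image is compared with the source it should contain;
#' `F = Img1 + Img2` gives exactly 2. A zero-variance argument contributes 0
#' with a warning.
#'
#' @param img1,img2,fused numeric matrices of identical shape.
#' @return scalar in [-2, 2].
#' @export
metric_scd <- function(img1, img2, fused) {
  stopifnot(all(dim(img1) == dim(fused)), all(dim(img2) == dim(fused)))
  term <- function(d, s) {
    if (stats::sd(d) == 0 || stats::sd(s) == 0) {
      warning("zero-variance image in SCD; term set to 0", call. = FALSE)
      return(0)
    }
    stats::cor(as.vector(d), as.vector(s))
  }
  term(fused - img2, img1) + term(fused - img1, img2)
}

# Per-scale Gaussian window used by the VIFF sub-band filtering.
viff_gauss <- function(n, sd) {
  xs <- seq(-(n - 1) / 2, (n - 1) / 2)
  g <- exp(-xs^2 / (2 * sd^2))
  K <- outer(g, g)
  K / sum(K)
}

# Visual information of one block, with distortion (vid: through the local
# linear channel fused = g * source + noise) and without (vind).
viff_block_info <- function(s, f, sigma_nsq) {
  vs <- stats::var(s)
  # blocks with (numerically) zero variance carry no visual information;
  # without the threshold the channel gain cv/vs can overflow on denormal
  # variances
  if (!is.finite(vs) || vs <= 1e-10) return(c(vid = 0, vind = 0))
  cv <- stats::cov(s, f)
  g <- cv / vs
  sv <- max(stats::var(f) - g * cv, 0)
  c(vid = log2(1 + g^2 * vs / (sv + sigma_nsq)),
    vind = log2(1 + vs / sigma_nsq))
}

#' Visual information fidelity for fusion (VIFF)
#'
#' Multi-scale information-ratio metric modeling human vision: at each of
#' `scales` sub-bands the images are Gaussian-filtered and subsampled, cut
#' into blocks, and each block is modeled as a local linear (GSM-style)
#' channel `fused = g * source + noise` with additive visual noise variance
#' `sigma_nsq` (on the 8-bit scale). Per block the visual information with
#' distortion (source -> fused) and without it is accumulated; per sub-band,
#' the source carrying more information is retained per block and the
#' sub-band score is the ratio of the two totals; sub-band scores are
#' averaged with normalized weights `weights`. A distortion-free copy of the
#' sources scores exactly 1.
#'
#' @param img1,img2,fused numeric matrices in [0, 1], at least 32x32.
#' @param scales number of sub-bands (default 4).
#' @param block block side length (default 8).
#' @param sigma_nsq visual noise variance on the 0-255 intensity scale.
#' @param weights per-sub-band weights (normalized internally).
#' @return nonnegative scalar; 1 for perfect fidelity.
#' @export
metric_viff <- function(img1, img2, fused, scales = 4L, block = 8L,
                        sigma_nsq = 2, weights = c(0.45, 0.3, 0.15, 0.1)) {
  stopifnot(all(dim(img1) == dim(fused)), all(dim(img2) == dim(fused)))
  if (nrow(fused) < 32 || ncol(fused) < 32) {
    stop("VIFF needs images of at least 32x32", call. = FALSE)
  }
  if (length(weights) != scales) {
    stop("`weights` must have one entry per scale", call. = FALSE)
  }
  weights <- weights / sum(weights)
  a <- img1 * 255; b <- img2 * 255; f <- fused * 255
  score <- 0
  for (sc in seq_len(scales)) {
    if (sc > 1) {
      n <- 2^(scales - sc + 1) + 1
      K <- viff_gauss(n, n / 5)
      smooth_half <- function(x) {
        xs <- conv_window(x, K, mode = "replicate")
        xs[seq(1, nrow(xs), by = 2), seq(1, ncol(xs), by = 2), drop = FALSE]
      }
      a <- smooth_half(a); b <- smooth_half(b); f <- smooth_half(f)
    }
    if (min(dim(f)) < block) break
    bi <- seq(1, nrow(f) - block + 1, by = block)
    bj <- seq(1, ncol(f) - block + 1, by = block)
    vid_tot <- 0; vind_tot <- 0
    for (i in bi) {
      for (j in bj) {
        ri <- i + seq_len(block) - 1L; rj <- j + seq_len(block) - 1L
        fb <- as.vector(f[ri, rj])
        r1 <- viff_block_info(as.vector(a[ri, rj]), fb, sigma_nsq)
        r2 <- viff_block_info(as.vector(b[ri, rj]), fb, sigma_nsq)
        # keep the source whose block carries more visual information
        r <- if (r1["vind"] >= r2["vind"]) r1 else r2
        vid_tot <- vid_tot + r["vid"]
        vind_tot <- vind_tot + r["vind"]
      }
    }
    sb <- if (vind_tot > 0) vid_tot / vind_tot else {
      warning("flat sub-band in VIFF; ratio defined as 1", call. = FALSE)
      1
    }
    score <- score + weights[sc] * sb
  }
  unname(score)
}

#' All five fusion-quality metrics at once
#'
#' @param img1,img2,fused numeric matrices in [0, 1], identical shape.
#' @param bins histogram resolution for EN and Q_MI.
#' @return object of class `metric_report`: list with `en`, `q_mi`, `q_abf`,
#'   `scd`, `viff` and the `parameters` used.
#' @examples
#' p <- make_gray_pair(phantom_spec(size = 64, seed = 2))
#' rep <- fusion_metrics(p$a, p$b, (p$a + p$b) / 2)
#' @export
fusion_metrics <- function(img1, img2, fused, bins = 256L) {
  structure(list(en = image_entropy(fused, bins),
                 q_mi = metric_qmi(img1, img2, fused, bins),
                 q_abf = metric_qabf(img1, img2, fused),
                 scd = metric_scd(img1, img2, fused),
                 viff = metric_viff(img1, img2, fused),
                 parameters = list(bins = bins, viff_scales = 4L,
                                   viff_block = 8L, viff_sigma_nsq = 2)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("EN %.4f | Q_MI %.4f | Q^AB/F %.4f | SCD %.4f | VIFF %.4f\n",
              x$en, x$q_mi, x$q_abf, x$scd, x$viff))
  invisible(x)
}
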