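# Burt-Adelson Gaussian/Laplacian pyramids and the three-branch level fusion
# rule. The fused weight map is decomposed into a Gaussian pyramid G{S}; each
# low-rank component into a Laplacian pyramid L{C}, L{M}. At every level a
# local similarity Q decides between a G{S}-weighted combination (similar
# bands) and a winner-take-all pick by local energy (dissimilar bands).

pyr_kernel_1d <- c(1, 4, 6, 4, 1) / 16

pyr_blur <- function(x) {
  k <- pyr_kernel_1d
  x <- conv_window(x, matrix(k, 5, 1), mode = "reflect")
  conv_window(x, matrix(k, 1, 5), mode = "reflect")
}

pyr_reduce <- function(x) {
  b <- pyr_blur(x)
  b[seq(1, nrow(b), by = 2), seq(1, ncol(b), by = 2), drop = FALSE]
}

# Expand to an explicit target size (handles odd sizes from ceil-halving):
# zero-stuff onto the target grid, blur with a doubled kernel.
pyr_expand <- function(x, target_dim) {
  h <- target_dim[1]; w <- target_dim[2]
  up <- matrix(0, h, w)
  up[seq(1, h, by = 2), seq(1, w, by = 2)] <- x
  4 * pyr_blur(up)
}

#' Number of pyramid decomposition levels for an image size
#'
#' `l = floor(log2(min(H, W)))`, optionally capped by `max_levels` so the
#' coarsest level stays desk-sized (a 256x256 image gives l = 8).
#'
#' @param H,W image dimensions (both >= 2).
#' @param max_levels optional cap (default 8; `Inf` disables).
#' @return integer level count (level 1 is full resolution).
#' @export
num_levels <- function(H, W, max_levels = 8) {
  if (H < 2 || W < 2) stop("image must be at least 2x2", call. = FALSE)
  min(floor(log2(min(H, W))), max_levels)
}

new_pyramid <- function(kind, levels) {
  structure(list(kind = kind, levels = levels, l = length(levels)),
            class = "pyramid")
}

#' @export
print.pyramid <- function(x, ...) {
  sizes <- vapply(x$levels, function(z) paste(dim(z), collapse = "x"), "")
  cat(sprintf("%s pyramid, %d levels: %s\n", x$kind, x$l,
              paste(sizes, collapse = " > ")))
  invisible(x)
}

#' Gaussian pyramid
#'
#' Standard construction with the 5-tap binomial kernel `[1,4,6,4,1]/16`
#' (reflect boundary) and ceil-halving, so odd sizes are supported.
#'
#' @param img numeric matrix.
#' @param l level count (defaults to [num_levels()]).
#' @return object of class `pyramid` with `kind = "gaussian"`; level 1 is the
#'   input, level `l` the coarsest.
#' @export
gaussian_pyramid <- function(img, l = num_levels(nrow(img), ncol(img))) {
  check_image(img, "img")
  lmax <- num_levels(nrow(img), ncol(img), max_levels = Inf)
  if (l < 1 || l > lmax) {
    stop(sprintf("`l` must be in 1..%d for this image", lmax), call. = FALSE)
  }
  levels <- vector("list", l)
  levels[[1]] <- img
  for (i in seq_len(l - 1L)) levels[[i + 1L]] <- pyr_reduce(levels[[i]])
  new_pyramid("gaussian", levels)
}

#' Laplacian pyramid
#'
#' Band-pass residuals `G_i - expand(G_{i+1})` for levels 1..l-1 plus the
#' coarsest Gaussian level at position l. The construction is exactly
#' invertible: [reconstruct_pyramid()] reproduces the source to floating
#' point round-off.
#'
#' @inheritParams gaussian_pyramid
#' @return object of class `pyramid` with `kind = "laplacian"`.
#' @export
laplacian_pyramid <- function(img, l = num_levels(nrow(img), ncol(img))) {
  g <- gaussian_pyramid(img, l)
  levels <- vector("list", l)
  if (l > 1) {
    for (i in seq_len(l - 1L)) {
      levels[[i]] <- g$levels[[i]] -
        pyr_expand(g$levels[[i + 1L]], dim(g$levels[[i]]))
    }
  }
  levels[[l]] <- g$levels[[l]]
  new_pyramid("laplacian", levels)
}

#' Reconstruct an image from a Laplacian pyramid
#'
#' Iterative expand-and-add from the coarsest level to the finest.
#'
#' @param pyr a `pyramid` of kind `"laplacian"`.
#' @return numeric matrix with the dimensions of level 1.
#' @export
reconstruct_pyramid <- function(pyr) {
  stopifnot(inherits(pyr, "pyramid"), pyr$kind == "laplacian")
  acc <- pyr$levels[[pyr$l]]
  if (pyr$l > 1) {
    for (i in rev(seq_len(pyr$l - 1L))) {
      acc <- pyr$levels[[i]] + pyr_expand(acc, dim(pyr$levels[[i]]))
    }
  }
  acc
}

#' Local energy of a pyramid level
#'
#' Windowed sum of squares over a square neighborhood (default 3x3),
#' replicate-padded.
#'
#' @param x numeric matrix (one pyramid level).
#' @param window odd window side length (default 3).
#' @return nonnegative matrix of `dim(x)`.
#' @export
local_energy <- function(x, window = 3) {
  r <- (window - 1L) %/% 2L
  box_sum(x^2, r)
}

#' Local similarity between two band-pass levels
#'
#' `Q = 2 * windowed_sum(LC * LM) / (E_C + E_M)`, a normalized correlation in
#' [-1, 1] where the energies are positive. Where both energies vanish the
#' two null signals are identical, so `Q` is defined as 1.
#'
#' @param LC,LM matching pyramid levels.
#' @param window odd window side (default 3).
#' @return matrix of `dim(LC)` with values in [-1, 1].
#' @export
similarity_q <- function(LC, LM, window = 3) {
  if (!all(dim(LC) == dim(LM))) stop("shape mismatch", call. = FALSE)
  r <- (window - 1L) %/% 2L
  ec <- box_sum(LC^2, r)
  em <- box_sum(LM^2, r)
  cross <- box_sum(LC * LM, r)
  den <- ec + em
  q <- matrix(1, nrow(LC), ncol(LC))
  nz <- den > 0
  q[nz] <- 2 * cross[nz] / den[nz]
  q
}

#' Fuse one pyramid level under the three-branch rule
#'
#' Where the bands agree (`Q >= tau`) the fused coefficient is the convex
#' combination `GS * LC + (1 - GS) * LM` steered by the Gaussian level of the
#' fused weight map; where they disagree (`Q < tau`) the band with the larger
#' local energy wins outright (`LC` if `E_C >= E_M`, else `LM`).
#'
#' @param LC,LM matching Laplacian levels of the two low-rank components.
#' @param GS Gaussian level of the fused weight map, expected in [0, 1].
#' @param tau similarity threshold in (0, 1] (default 0.8).
#' @param window local window side for Q and the energies.
#' @return fused level, a matrix of `dim(LC)`.
#' @export
fuse_level <- function(LC, LM, GS, tau = 0.8, window = 3) {
  if (!all(dim(LC) == dim(LM)) || !all(dim(LC) == dim(GS))) {
    stop("`LC`, `LM`, `GS` must share a shape", call. = FALSE)
  }
  if (tau <= 0 || tau > 1) stop("`tau` must be in (0, 1]", call. = FALSE)
  r <- (window - 1L) %/% 2L
  ec <- box_sum(LC^2, r)
  em <- box_sum(LM^2, r)
  q <- similarity_q(LC, LM, window)
  weighted <- GS * LC + (1 - GS) * LM
  select <- ifelse(ec >= em, LC, LM)
  ifelse(q >= tau, weighted, select)
}

# Rescale a weight-map Gaussian level to [0,1] so it acts as a convex weight;
# a constant level carries no preference and maps to 1/2.
normalize_gs <- function(g) {
  rng <- range(g)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(abs(rng), 1)) {
    return(matrix(0.5, nrow(g), ncol(g)))
  }
  (g - rng[1]) / (rng[2] - rng[1])
}

#' Fuse two low-rank components through the pyramid rule set
#'
#' Decomposes both components into Laplacian pyramids and the fused weight
#' map into a Gaussian pyramid, applies [fuse_level()] at every level (each
#' weight-map level rescaled to [0, 1] first), and reconstructs.
#'
#' @param lr1,lr2 low-rank components (matrices of identical shape).
#' @param fw fused weight map (same shape).
#' @param tau similarity threshold.
#' @param levels `"auto"` or an integer level count.
#' @param window local window side.
#' @param max_levels cap used when `levels = "auto"`.
#' @return list with the fused low-rank image `fused` and the fused
#'   `pyramid`.
#' @export
pyramid_fuse <- function(lr1, lr2, fw, tau = 0.8, levels = "auto",
                         window = 3, max_levels = 8) {
  if (!all(dim(lr1) == dim(lr2)) || !all(dim(lr1) == dim(fw))) {
    stop("inputs must share a shape", call. = FALSE)
  }
  l <- if (identical(levels, "auto")) {
    num_levels(nrow(lr1), ncol(lr1), max_levels)
  } else as.integer(levels)
  pc <- laplacian_pyramid(lr1, l)
  pm <- laplacian_pyramid(lr2, l)
  gs <- gaussian_pyramid(fw, l)
  fused_levels <- vector("list", l)
  for (i in seq_len(l)) {
    fused_levels[[i]] <- fuse_level(pc$levels[[i]], pm$levels[[i]],
                                    normalize_gs(gs$levels[[i]]),
                                    tau = tau, window = window)
  }
  fp <- new_pyramid("laplacian", fused_levels)
  list(fused = reconstruct_pyramid(fp), pyramid = fp)
}
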