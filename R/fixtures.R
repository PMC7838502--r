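# Synthetic co-registered phantom pairs. Both modalities are rendered from
# the same ellipse geometry, so registration holds by construction; the
# modality contrast maps emulate the complementary appearance of CT/MR-style
# pairs (dense structures bright vs. graded soft-tissue contrast plus fine
# texture). Everything is a pure function of the spec, so fixtures are
# reproducible anywhere without downloads.

#' Specification of a synthetic co-registered phantom pair
#'
#' @param size side length in pixels (square images).
#' @param seed integer seed controlling geometry, texture, and noise.
#' @param n_structures number of elliptical structures.
#' @param preset modality contrast preset: `"ct-mr"` (dense structures bright
#'   in A, graded contrast plus texture in B), `"t1-t2"` (two graded soft
#'   contrasts with inverted weighting), `"mr-pet"` (structural A, smooth
#'   blob-like functional B; used for the color path).
#' @param texture_amp amplitude of the fine sinusoidal texture on the
#'   soft-contrast modality.
#' @param noise_sd standard deviation of additive Gaussian noise (0 disables).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256, seed = 7, n_structures = 6,
                         preset = c("ct-mr", "t1-t2", "mr-pet"),
                         texture_amp = 0.06, noise_sd = 0) {
  preset <- match.arg(preset)
  if (size < 2) stop("`size` must be at least 2", call. = FALSE)
  if (n_structures < 0) stop("`n_structures` must be >= 0", call. = FALSE)
  structure(list(size = size, seed = seed, n_structures = n_structures,
                 preset = preset, texture_amp = texture_amp,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

# Render the soft masks of the shared ellipse geometry: a list of HxW fields
# in [0,1], one per structure, plus a head outline mask.
render_geometry <- function(spec) {
  n <- spec$size
  u <- matrix(seq(-1, 1, length.out = n), n, n)
  v <- t(u)
  head <- pmax(0, 1 - (u^2 / 0.85^2 + v^2 / 0.92^2))^0.5
  masks <- list()
  if (spec$n_structures > 0) {
    with_local_seed(spec$seed, {
      for (i in seq_len(spec$n_structures)) {
        cx <- runif(1, -0.45, 0.45); cy <- runif(1, -0.45, 0.45)
        a <- runif(1, 0.08, 0.35);  b <- runif(1, 0.08, 0.35)
        th <- runif(1, 0, pi)
        ur <- (u - cx) * cos(th) + (v - cy) * sin(th)
        vr <- -(u - cx) * sin(th) + (v - cy) * cos(th)
        q <- ur^2 / a^2 + vr^2 / b^2
        # smooth-edged ellipse: soft indicator with a narrow transition band
        masks[[i]] <- 1 / (1 + exp((q - 1) * 25))
      }
    })
  }
  list(head = head, masks = masks, u = u, v = v)
}

#' Generate a co-registered grayscale modality pair
#'
#' Renders the shared geometry of [phantom_spec()] under two modality
#' contrast maps. For the `"ct-mr"` preset, modality A lights up the densest
#' structures on a flat background (CT-like) while modality B shows graded
#' contrast on every structure plus a fine sinusoidal texture (MR-like), so
#' the two images correlate positively but far from perfectly.
#'
#' @param spec a [phantom_spec()].
#' @return list with matrices `a` and `b`, both in [0, 1] and `size x size`.
#' @examples
#' p <- make_gray_pair(phantom_spec(size = 64, seed = 3))
#' cor(as.vector(p$a), as.vector(p$b))
#' @export
make_gray_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- render_geometry(spec)
  n <- spec$size
  k <- length(g$masks)
  a <- 0.05 * g$head
  b <- 0.25 * g$head
  if (k > 0) {
    dens <- with_local_seed(spec$seed + 1L, runif(k, 0.1, 1))
    for (i in seq_len(k)) {
      if (spec$preset == "ct-mr") {
        # A: only dense structures respond, strongly; B: graded response
        a <- a + (dens[i] > 0.55) * 0.85 * g$masks[[i]]
        b <- b + (0.15 + 0.55 * (1 - dens[i])) * g$masks[[i]]
      } else if (spec$preset == "t1-t2") {
        a <- a + (0.2 + 0.6 * dens[i]) * g$masks[[i]]
        b <- b + (0.2 + 0.6 * (1 - dens[i])) * g$masks[[i]]
      } else { # mr-pet: A structural, B handled separately in make_color_pair
        a <- a + (0.2 + 0.5 * dens[i]) * g$masks[[i]]
        b <- b + 0.5 * dens[i] * g$masks[[i]]
      }
    }
  }
  if (spec$texture_amp > 0 && n >= 4) {
    ph <- with_local_seed(spec$seed + 2L, runif(3, 0, 2 * pi))
    fx <- matrix(seq_len(n), n, n); fy <- t(fx)
    tex <- sin(2 * pi * fx / 7 + ph[1]) * sin(2 * pi * fy / 9 + ph[2]) +
      0.5 * sin(2 * pi * (fx + fy) / 5 + ph[3])
    b <- b + spec$texture_amp * tex * g$head
  }
  if (spec$noise_sd > 0) {
    nz <- with_local_seed(spec$seed + 3L,
                          list(a = matrix(rnorm(n * n, sd = spec$noise_sd), n),
                               b = matrix(rnorm(n * n, sd = spec$noise_sd), n)))
    a <- a + nz$a; b <- b + nz$b
  }
  list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1))
}

#' Generate a grayscale + RGB phantom pair for the color fusion path
#'
#' The grayscale image is the structural phantom of [make_gray_pair()]; the
#' RGB image is a pseudo-functional map built from smooth colored blobs over
#' the same geometry (PET/SPECT-like). With `achromatic = TRUE` the blobs are
#' gray (R = G = B), which is useful for checking that the luma channel alone
#' carries the fused content.
#'
#' @param spec a [phantom_spec()] (preset `"mr-pet"` is the natural choice).
#' @param achromatic render the functional image without chroma.
#' @return list with matrix `gray` and `size x size x 3` array `rgb`, both in
#'   [0, 1], plus the logical blob `mask` (chroma is neutral outside it).
#' @export
make_color_pair <- function(spec, achromatic = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- render_geometry(spec)
  n <- spec$size
  pair <- make_gray_pair(spec)
  act <- pair$b                      # activity field over the shared geometry
  mask <- act > 0.3
  rgb <- array(0, c(n, n, 3))
  if (achromatic) {
    for (c3 in 1:3) rgb[, , c3] <- act
  } else {
    # hot-metal style colormap confined to the active mask; neutral gray floor
    floor_g <- 0.08 * g$head
    rgb[, , 1] <- floor_g + mask * pmin(2 * act, 1)
    rgb[, , 2] <- floor_g + mask * pmin(pmax(2 * act - 0.7, 0), 1)
    rgb[, , 3] <- floor_g + mask * pmin(pmax(2 * act - 1.4, 0), 1)
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  list(gray = pair$a, rgb = rgb, mask = mask)
}
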