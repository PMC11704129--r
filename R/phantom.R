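#' Phantom z-stack parameters
#'
#' Describes a synthetic confocal volume with known ground truth: a bright
#' ellipsoidal membrane band enclosing a cytoplasmic interior, dark
#' ellipsoidal cavities inside it, and (optionally) a dark invagination
#' channel breaching the top of the band, so that the luminal opening seen
#' in real longitudinal sections is reproduced. The rasterized geometry is
#' degraded by Gaussian blur, additive Gaussian noise (after the blur,
#' clipped to \[0, 1\]) and intensity quantization.
#'
#' The default geometry emulates a deconvolved spinning-disk acquisition at
#' 0.16 x 0.16 x 0.3 um voxels: a 96 x 96 x 16 stack (about 15 x 15 um
#' laterally), a cell of ~11 um diameter with a 0.8 um membrane band, an
#' invagination channel ~1 um wide, and sub-pixel residual blur
#' (deconvolution leaves nearly piecewise-constant intensities). The two
#' default cavities mirror the structures seen in real sections: an
#' axially elongated section of the luminal invagination, present in every
#' slice, and a bleb-like cytoplasmic void spanning most of the stack.
#' Intensities are ordered background < cavity < cytoplasm < membrane, as
#' required for the two filtration directions to isolate the membrane and
#' the cavities respectively.
#'
#' @param shape `c(H, W, n_slices)`.
#' @param center `c(row, col)` of the cell axis in pixels.
#' @param membrane_radii `c(row, col, z)` outer semi-axes of the membrane
#'   ellipsoid, in pixels (row, col) and slices (z).
#' @param z_center Axial centre of the ellipsoids, in slice units.
#' @param band_thickness Membrane band thickness in pixels.
#' @param membrane_intensity,cytoplasm_intensity,background_intensity
#'   Intensities in \[0, 1\].
#' @param invagination `NULL`, or `list(width =, depth =)` in pixels: a dark
#'   channel of that width through the top of the band, reaching `depth`
#'   pixels below the band's outer top.
#' @param cavities List of `list(center = c(row, col, z), radii = c(row,
#'   col, z), intensity =)` ellipsoids.
#' @param blur_sigma Gaussian blur in pixels (0 = none).
#' @param noise_sigma Additive Gaussian noise (intensity units, after blur;
#'   0 = none).
#' @param quantize Number of intensity levels (256 emulates an 8-bit
#'   camera; 0 disables quantization).
#' @param seed Integer seed controlling the noise stream.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(shape = c(96L, 96L, 16L),
                           center = c(48.5, 48.5),
                           membrane_radii = c(35, 35, 40),
                           z_center = 8.5,
                           band_thickness = 5,
                           membrane_intensity = 0.95,
                           cytoplasm_intensity = 0.65,
                           background_intensity = 0.05,
                           invagination = list(width = 6, depth = 13),
                           cavities = list(
                             list(center = c(58, 34, 8.5), radii = c(7, 7, 20),
                                  intensity = 0.10),
                             list(center = c(56, 63, 8.5), radii = c(6, 6, 7),
                                  intensity = 0.10)),
                           blur_sigma = 0.25,
                           noise_sigma = 0,
                           quantize = 256L,
                           seed = 1L) {
  p <- list(shape = as.integer(shape), center = center,
            membrane_radii = membrane_radii, z_center = z_center,
            band_thickness = band_thickness,
            membrane_intensity = membrane_intensity,
            cytoplasm_intensity = cytoplasm_intensity,
            background_intensity = background_intensity,
            invagination = invagination, cavities = cavities,
            blur_sigma = blur_sigma, noise_sigma = noise_sigma,
            quantize = quantize, seed = as.integer(seed))
  cav_int <- vapply(p$cavities, `[[`, numeric(1), "intensity")
  ints <- c(p$background_intensity, cav_int,
            p$cytoplasm_intensity, p$membrane_intensity)
  ok <- p$cytoplasm_intensity < p$membrane_intensity &&
    (!length(cav_int) || (all(cav_int > p$background_intensity) &&
                          all(cav_int <= p$cytoplasm_intensity))) &&
    p$background_intensity < p$cytoplasm_intensity
  if (!ok)
    stop("intensities must satisfy background < cavity <= cytoplasm < membrane")
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")
  if (any(p$membrane_radii <= 0) || p$band_thickness <= 0)
    stop("radii and band thickness must be positive")
  structure(p, class = "phantom_params")
}

# cross-section mask of an axis-aligned ellipsoid at slice z
ellipsoid_section <- function(H, W, center_rc, radii_rcz, zc, z) {
  f2 <- 1 - ((z - zc) / radii_rcz[3])^2
  if (f2 <= 0) return(matrix(FALSE, H, W))
  dr <- outer(seq_len(H) - center_rc[1], rep(1, W))
  dc <- outer(rep(1, H), seq_len(W) - center_rc[2])
  (dr / radii_rcz[1])^2 + (dc / radii_rcz[2])^2 < f2
}

#' Generate a phantom z-stack with ground truth
#'
#' Rasterizes per-slice cross-sections of the 3D phantom geometry described
#' by [phantom_params()], then applies Gaussian blur, additive Gaussian
#' noise (clipped to \[0, 1\]) and quantization. Deterministic for a fixed
#' seed.
#'
#' @param params A [phantom_params()].
#' @return List with `stack` (list of [intensity_image()], raw intensities),
#'   `truth` (per-slice `membrane_masks`, `cavity_masks` (a list per slice),
#'   `cavity_count` vector, and `expected_components` for the 3D
#'   reconstruction), and the echoed `params`.
#' @export
generate_phantom_stack <- function(params = phantom_params()) {
  H <- params$shape[1]; W <- params$shape[2]; nz <- params$shape[3]
  ctr <- params$center
  outer_r <- params$membrane_radii
  inner_r <- params$membrane_radii - params$band_thickness
  if (any(inner_r <= 0)) stop("band thickness exceeds the membrane radii")
  if (ctr[1] + outer_r[1] > H + 0.5 || ctr[1] - outer_r[1] < 0.5 ||
      ctr[2] + outer_r[2] > W + 0.5 || ctr[2] - outer_r[2] < 0.5)
    stop("membrane ellipsoid exceeds the image bounds")
  chan <- NULL
  if (!is.null(params$invagination)) {
    inv <- params$invagination
    cols <- abs(outer(rep(1, H), seq_len(W)) - ctr[2]) <= inv$width / 2
    rows <- outer(seq_len(H), rep(1, W)) <= ctr[1] - outer_r[1] + inv$depth
    chan <- cols & rows
  }
  set.seed(params$seed)
  stack <- vector("list", nz)
  membrane_masks <- vector("list", nz)
  cavity_masks <- vector("list", nz)
  for (z in seq_len(nz)) {
    out_m <- ellipsoid_section(H, W, ctr, outer_r, params$z_center, z)
    in_m <- ellipsoid_section(H, W, ctr, inner_r, params$z_center, z)
    u <- matrix(params$background_intensity, H, W)
    u[out_m] <- params$membrane_intensity
    u[in_m] <- params$cytoplasm_intensity
    cms <- list()
    for (cv in params$cavities) {
      cm <- ellipsoid_section(H, W, cv$center[1:2], cv$radii, cv$center[3], z)
      cm <- cm & in_m
      if (any(cm)) {
        u[cm] <- cv$intensity
        cms[[length(cms) + 1L]] <- cm
      }
    }
    if (!is.null(chan)) u[chan] <- params$background_intensity
    if (params$blur_sigma > 0) {
      u <- as.matrix(EBImage::gblur(u, sigma = params$blur_sigma,
                                    boundary = "replicate"))
    }
    if (params$noise_sigma > 0)
      u <- u + stats::rnorm(length(u), sd = params$noise_sigma)
    u <- pmin(pmax(u, 0), 1)
    if (params$quantize > 0)
      u <- round(u * (params$quantize - 1)) / (params$quantize - 1)
    dim(u) <- c(H, W)
    stack[[z]] <- intensity_image(u, normalize = FALSE)
    membrane_masks[[z]] <- out_m & !(if (is.null(chan)) FALSE else chan)
    cavity_masks[[z]] <- cms
  }
  truth <- list(membrane_masks = membrane_masks,
                cavity_masks = cavity_masks,
                cavity_count = vapply(cavity_masks, length, integer(1)),
                expected_components = 2L + sum(vapply(
                  params$cavities, function(cv) {
                    sum(vapply(seq_len(nz), function(z)
                      abs(z - cv$center[3]) < cv$radii[3], logical(1))) >= 2L
                  }, logical(1))))
  list(stack = stack, truth = truth, params = params)
}

#' Deterministic toy images with documented topology
#'
#' Small fixtures used in examples and tests:
#' \describe{
#'   \item{`ring3`}{3 x 3 image, centre 0.9 on a 0.1 ring: exactly one
#'     sublevel H1 pair (birth 0.1, death 0.9).}
#'   \item{`disk`}{21 x 21 bright disk of radius 6 (0.9) on 0.1.}
#'   \item{`saddle_dumbbell`}{Two bright plateaus (0.75 and 0.57) joined by
#'     a 0.3 bar on a 0.05 background: the sublevel diagram has an elder
#'     class spanning both hills and a class born at the saddle value 0.3.}
#'   \item{`nested_cavities`}{A closed bright ring enclosing mid-intensity
#'     cytoplasm with two dark disks of different depth: cavity detection
#'     yields one representative around the whole interior nested with a
#'     tight disk, exercising the nested-cycle splitting.}
#'   \item{`const`}{Constant 0.5 image (empty diagrams).}
#' }
#'
#' @param kind Fixture name.
#' @return An [intensity_image()] (not re-normalized).
#' @export
generate_toy_image <- function(kind) {
  kinds <- c("ring3", "disk", "saddle_dumbbell", "nested_cavities", "const")
  if (!kind %in% kinds)
    stop("unknown fixture '", kind, "'; available: ", paste(kinds, collapse = ", "))
  u <- switch(kind,
    ring3 = {
      m <- matrix(0.1, 3, 3); m[2, 2] <- 0.9; m
    },
    disk = {
      m <- matrix(0.1, 21, 21)
      d <- outer((1:21 - 11)^2, (1:21 - 11)^2, "+")
      m[d <= 36] <- 0.9; m
    },
    saddle_dumbbell = {
      m <- matrix(0.05, 24, 40)
      d1 <- outer((1:24 - 12)^2, (1:40 - 10)^2, "+")
      d2 <- outer((1:24 - 12)^2, (1:40 - 30)^2, "+")
      m[11:13, 10:30] <- 0.3
      m[d1 <= 25] <- 0.75
      m[d2 <= 25] <- 0.57
      m
    },
    nested_cavities = {
      m <- matrix(0.05, 48, 48)
      d <- sqrt(outer((1:48 - 24)^2, (1:48 - 24)^2, "+"))
      m[d < 21] <- 0.9
      m[d < 16] <- 0.8
      dA <- outer((1:48 - 24)^2, (1:48 - 17)^2, "+")
      dB <- outer((1:48 - 24)^2, (1:48 - 31)^2, "+")
      m[dA <= 16] <- 0.1
      m[dB <= 16] <- 0.2
      m
    },
    const = matrix(0.5, 8, 8))
  intensity_image(u, normalize = FALSE)
}
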