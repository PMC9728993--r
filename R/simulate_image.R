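#' Simulate a radially biased nuclear image with mask and DAPI
#'
#' Generates the single-slice input of the erosion-shell analysis: a
#' circular (optionally elliptical) nucleus mask, a flat DAPI channel inside
#' the mask, and a probe channel whose intensity follows `(r / R)^radial_bias`
#' plus Gaussian noise (zero outside the mask). A positive `radial_bias`
#' biases the probe towards the nuclear periphery, zero gives a flat signal,
#' and a negative exponent would require `r > 0` so central bias is obtained
#' with `invert = TRUE`, which uses `(1 - r / R)^|radial_bias|`.
#'
#' @param image_size image side length in pixels (square image).
#' @param nucleus_radius nucleus radius in pixels; must fit inside the image.
#' @param radial_bias exponent of the radial intensity profile (>= 0).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0);
#'   noisy intensities are clamped at 0.
#' @param seed integer seed; global RNG state restored afterwards.
#' @param axis_ratio ellipse minor/major axis ratio in (0, 1]; 1 (default)
#'   gives a circle.
#' @param invert if `TRUE`, bias towards the centre instead of the periphery.
#' @return list with numeric matrices `probe`, `dapi` and binary matrix
#'   `mask`, all `image_size x image_size`.
#' @examples
#' img <- simulate_radial_image(64, 25, radial_bias = 2, seed = 1)
#' sum(img$mask)
#' @export
simulate_radial_image <- function(image_size, nucleus_radius,
                                  radial_bias = 0, noise_sd = 0, seed = NULL,
                                  axis_ratio = 1, invert = FALSE) {
  assert_scalar_number(image_size, "image_size", 4)
  assert_scalar_number(nucleus_radius, "nucleus_radius", 1)
  assert_scalar_number(radial_bias, "radial_bias", 0)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(axis_ratio, "axis_ratio", 0, 1, strict_lower = TRUE)
  if (2 * nucleus_radius + 2 > image_size) {
    stop("nucleus does not fit inside the image", call. = FALSE)
  }
  centre <- (image_size + 1) / 2
  ix <- matrix(seq_len(image_size), image_size, image_size)
  iy <- t(ix)
  # normalised elliptical radius in [0, 1] at the nuclear boundary
  r <- sqrt(((ix - centre) / nucleus_radius)^2 +
            ((iy - centre) / (nucleus_radius * axis_ratio))^2)
  mask <- matrix(as.integer(r <= 1), image_size, image_size)
  base <- if (invert) (1 - pmin(r, 1))^radial_bias else pmin(r, 1)^radial_bias
  probe <- base * mask
  dapi <- 1 * mask
  if (noise_sd > 0) {
    noise <- with_local_seed(seed,
      matrix(stats::rnorm(image_size^2, sd = noise_sd),
             image_size, image_size))
    probe <- pmax(probe + noise * mask, 0)
  }
  list(probe = probe, dapi = dapi, mask = mask)
}

#' Write a simulated nucleus image set as single-plane TIFFs
#'
#' Intensity channels are rescaled to \[0, 1\] and written as 16-bit
#' grayscale TIFFs; the mask is written as an 8-bit binary TIFF.
#'
#' @param img list with `probe`, `dapi`, `mask` (as produced by
#'   [simulate_radial_image()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_image_set <- function(img, dir, prefix = "nucleus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probe = file.path(dir, paste0(prefix, "_probe.tif")),
             dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
             mask = file.path(dir, paste0(prefix, "_mask.tif")))
  scale01 <- function(m) if (max(m) > 0) m / max(m) else m
  EBImage::writeImage(EBImage::Image(scale01(img$probe)), paths["probe"],
                      type = "tiff", bits.per.sample = 16)
  EBImage::writeImage(EBImage::Image(scale01(img$dapi)), paths["dapi"],
                      type = "tiff", bits.per.sample = 16)
  EBImage::writeImage(EBImage::Image(img$mask), paths["mask"],
                      type = "tiff", bits.per.sample = 8)
  invisible(paths)
}

#' Read a single-plane grayscale TIFF as a matrix
#'
#' @param path TIFF path.
#' @param binarise if `TRUE`, threshold at > 0 to recover a binary mask.
#' @return numeric (or integer when binarised) matrix.
#' @export
read_image_matrix <- function(path, binarise = FALSE) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (binarise) m <- matrix(as.integer(m > 0), nrow(m), ncol(m))
  m
}
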