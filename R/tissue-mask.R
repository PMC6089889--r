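#' Parameters of the automated tissue detector
#'
#' @param gaussian_sigma Standard deviation (pixels) of the Gaussian
#'   smoothing applied before thresholding.
#' @param morph_radius Radius (pixels) of the disc structuring element used
#'   by the dilation-then-erosion (morphological closing) step.
#' @return Object of class `tissue_mask_params`.
#' @export
tissue_mask_params <- function(gaussian_sigma = 2, morph_radius = 10) {
  stopifnot(gaussian_sigma > 0, morph_radius >= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 morph_radius = as.integer(morph_radius)),
            class = "tissue_mask_params")
}

#' Detect tissue pixels in a spot image
#'
#' Pipeline: Gaussian filtering of the luminance image to remove noise, Otsu
#' thresholding separating (dark) tissue from (light) background, then
#' dilation followed by erosion with a disc structuring element, which fills
#' small holes such as gland lumens and restores the tissue border.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`, or a grayscale matrix.
#' @param params A [tissue_mask_params()].
#' @return Logical H x W matrix (`TRUE` = tissue). For a constant-intensity
#'   image the Otsu threshold is undefined; an empty mask is returned with a
#'   warning.
#' @export
detect_tissue <- function(image, params = tissue_mask_params()) {
  gray <- to_gray(image)
  blurred <- EBImage::gblur(gray, sigma = params$gaussian_sigma)
  if (diff(range(blurred)) < 1e-8) {
    warn("constant-intensity image: Otsu threshold undefined, empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(clamp01(blurred)))
  tissue <- blurred < thr  # H&E tissue is darker than the white background
  brush <- EBImage::makeBrush(2L * params$morph_radius + 1L, shape = "disc")
  closed <- EBImage::erode(EBImage::dilate(tissue * 1, brush), brush)
  matrix(as.logical(closed > 0.5), nrow(gray), ncol(gray))
}

#' Write a binary tissue mask as an 8-bit PNG (0 background, 255 tissue)
#' @param mask Logical matrix from [detect_tissue()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tissue_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
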