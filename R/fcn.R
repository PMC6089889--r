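#' Convert a trained patch classifier into a pixel-level annotator
#'
#' The global average pooling layer (which sees a `k x k` feature map at the
#' training input size, 7 x 7 for 224-px inputs) is replaced by a local
#' `k x k` average pooling layer with stride 1, the classification layer by
#' an equivalent 1 x 1 convolution with four output channels, softmax is
#' applied at every spatial location, and a factor-32 nearest-neighbour
#' upsampling restores the input dimensions.
#'
#' @param model A `patch_classifier`.
#' @return Object of class `pixel_annotator`.
#' @export
convert_to_fcn <- function(model) {
  stopifnot(inherits(model, "patch_classifier"))
  d <- gn_config(model$ptr)
  if (d$feature_hw < 1)
    abort("model input size yields an empty pre-pooling feature map")
  w <- gn_get_weights(model$ptr)
  structure(list(model = model, pool_hw = d$feature_hw,
                 Wfc = w$Wfc, bfc = as.numeric(w$bfc),
                 input_mean = as.numeric(w$input_mean),
                 halo_cells = fcn_halo_cells(),
                 model_id = model$model_id),
            class = "pixel_annotator")
}

# radius of influence of the convolutional stack in output cells: the stack's
# receptive field is 315 px (initial stride-2 3x3 conv + thirteen 3x3
# depthwise convolutions, strides doubling the jump at blocks 2, 4, 6, 12),
# so one output cell sees at most ceiling(157 / 32) = 5 cells on each side
fcn_halo_cells <- function() {
  r <- 1; j <- 1
  bump <- function(k, s) { r <<- r + (k - 1) * j; j <<- j * s }
  bump(3, 2)
  strides <- c(1, 2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 2, 1)
  for (s in strides) bump(3, s)
  as.integer(ceiling(((r - 1) / 2) / 32))
}

# stride-1 valid-window average pooling of a (h, w, C) cell map
local_avg_pool <- function(f, k) {
  h <- dim(f)[1]; w <- dim(f)[2]; C <- dim(f)[3]
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  out <- array(0, dim(f))
  # integral-image per channel; windows are clipped at the map border and
  # averaged over their in-bounds part (the centre window of a k x k map is
  # then exactly the global average)
  for (ch in seq_len(C)) {
    s <- rbind(0, apply(f[, , ch, drop = FALSE][, , 1], 2, cumsum))
    s <- cbind(0, t(apply(s, 1, cumsum)))
    r1 <- pmax(seq_len(h) - half_lo, 1L); r2 <- pmin(seq_len(h) + half_hi, h)
    c1 <- pmax(seq_len(w) - half_lo, 1L); c2 <- pmin(seq_len(w) + half_hi, w)
    cnt <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
    out[, , ch] <- (s[r2 + 1L, c2 + 1L, drop = FALSE] -
                    s[r1, c2 + 1L, drop = FALSE] -
                    s[r2 + 1L, c1, drop = FALSE] +
                    s[r1, c1, drop = FALSE]) / cnt
  }
  out
}

cell_softmax <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}

# pooling + 1x1 classification + softmax on a stitched cell feature map
classify_cells <- function(ann, feats) {
  pooled <- local_avg_pool(feats, ann$pool_hw)
  d <- dim(pooled)
  logits <- matrix(pooled, ncol = d[3]) %*% ann$Wfc
  logits <- sweep(logits, 2, ann$bfc, `+`)
  cell_softmax(array(logits, dim = c(d[1], d[2], ncol(ann$Wfc))))
}

#' Pre-upsampling class probabilities on the 32-px cell grid of an image
#'
#' The image is embedded in a neutral (dataset-mean colour) margin wide
#' enough to cover the network's receptive field, and the convolutional
#' stack is evaluated tile-wise: every tile is extracted with a halo of
#' `halo_cells` cells of real context, so the stitched feature map — and
#' hence the returned probabilities — is identical for any tiling,
#' including the single-tile (untiled) case.
#'
#' @param annotator A [convert_to_fcn()] result.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param tile_cells Cells per tile side (32 cells = 1024 px); `Inf` runs a
#'   single tile.
#' @return `ceiling(H/32) x ceiling(W/32) x 4` probability array.
#' @export
fcn_cell_probs <- function(annotator, image, tile_cells = 32L) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  ch <- ceiling(h / 32); cw <- ceiling(w / 32)
  halo <- annotator$halo_cells
  ph <- (ch + 2 * halo) * 32L; pw <- (cw + 2 * halo) * 32L
  padded <- array(0, dim = c(ph, pw, 3))
  for (k in 1:3) padded[, , k] <- annotator$input_mean[k]
  r0 <- halo * 32L; c0 <- halo * 32L
  padded[r0 + seq_len(h), c0 + seq_len(w), ] <- image
  if (!is.finite(tile_cells)) tile_cells <- max(ch, cw)
  tile_cells <- max(1L, min(as.integer(tile_cells), max(ch, cw)))
  feats <- NULL
  for (a0 in seq(0L, ch - 1L, by = tile_cells)) {
    a1 <- min(a0 + tile_cells, ch)
    for (b0 in seq(0L, cw - 1L, by = tile_cells)) {
      b1 <- min(b0 + tile_cells, cw)
      rows <- (a0 * 32L + 1L):((a1 + 2L * halo) * 32L)
      cols <- (b0 * 32L + 1L):((b1 + 2L * halo) * 32L)
      f <- gn_features(annotator$model$ptr,
                       padded[rows, cols, , drop = FALSE])
      if (is.null(feats))
        feats <- array(0, dim = c(ch, cw, dim(f)[3]))
      feats[(a0 + 1L):a1, (b0 + 1L):b1, ] <-
        f[halo + seq_len(a1 - a0), halo + seq_len(b1 - b0), , 1]
    }
  }
  classify_cells(annotator, feats)
}

#' Annotator probabilities for a bare patch (no context margin)
#'
#' Runs the converted network on exactly one patch with its own padding, so
#' the centre cell of the returned grid — whose pooling window covers the
#' whole pre-pooling feature map — reproduces [predict_patch()] on the same
#' tensor exactly.
#'
#' @param annotator A `pixel_annotator`.
#' @param patch `S x S x 3` array, `S` a multiple of 32.
#' @return `S/32 x S/32 x 4` probability array.
#' @export
fcn_patch_probs <- function(annotator, patch) {
  assert_rgb(patch)
  f <- gn_features(annotator$model$ptr, patch)
  classify_cells(annotator, array(f[, , , 1], dim = dim(f)[1:3]))
}

#' Whole-spot pixel-level probability map
#'
#' Computes cell-grid probabilities with [fcn_cell_probs()], restores the
#' image resolution by factor-32 nearest-neighbour upsampling (which
#' preserves the per-pixel probability simplex exactly) and zeroes all
#' channels outside the tissue mask.
#'
#' @param annotator A `pixel_annotator`.
#' @param image H x W x 3 spot image in `[0, 1]`.
#' @param tissue Logical H x W tissue mask (e.g. from [detect_tissue()]).
#' @param scale Resolution factor applied to the image before inference so
#'   that textures appear at the scale the classifier was trained on; use
#'   [training_scale()] of the patch geometry (`resize_to / patch_size`,
#'   e.g. 250/750 for the full protocol). `1` runs at native resolution.
#' @param tile_cells Tiling granularity, see [fcn_cell_probs()].
#' @param spot_id Identifier stored in the map.
#' @return A `probability_map`; its `border_px` attribute flags the band
#'   (half the training input size) where the receptive field extends past
#'   the image.
#' @export
probability_map <- function(annotator, image, tissue, scale = 1,
                            tile_cells = 32L, spot_id = NA_character_) {
  stopifnot(inherits(annotator, "pixel_annotator"))
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!all(dim(tissue) == c(h, w)))
    abort("tissue mask and image shapes differ")
  if (!any(tissue)) {
    warn("empty tissue mask: all-zero probability map")
    out <- new_probability_map(array(0, dim = c(h, w, 4)), tissue,
                               spot_id, annotator$model_id)
    attr(out, "border_px") <- annotator$model$config$input_size %/% 2L
    return(out)
  }
  if (scale != 1) {
    img_s <- as.array(EBImage::resize(
      EBImage::Image(image, colormode = "Color"),
      w = max(32L, round(h * scale)), h = max(32L, round(w * scale))))
  } else img_s <- image
  cells <- fcn_cell_probs(annotator, img_s, tile_cells)
  # nearest-neighbour map back to native pixels (effective stride 32 / scale)
  hs <- dim(img_s)[1]; ws <- dim(img_s)[2]
  ri <- pmin((pmax(round(seq_len(h) * hs / h), 1L) - 1L) %/% 32L + 1L,
             dim(cells)[1])
  ci <- pmin((pmax(round(seq_len(w) * ws / w), 1L) - 1L) %/% 32L + 1L,
             dim(cells)[2])
  p <- array(0, dim = c(h, w, 4))
  for (k in 1:4) {
    up <- cells[, , k][ri, ci, drop = FALSE]
    up[!tissue] <- 0
    p[, , k] <- up
  }
  out <- new_probability_map(p, tissue, spot_id, annotator$model_id)
  attr(out, "border_px") <- annotator$model$config$input_size %/% 2L
  out
}
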