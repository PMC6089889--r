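#' Select confidently and correctly classified patches
#'
#' Keeps patches whose predicted class equals the true label with predicted
#' probability strictly greater than `threshold` (a probability of exactly
#' `threshold` is excluded).
#'
#' @param patches Patch tibble with `label` and `pixels` columns.
#' @param model A `patch_classifier`.
#' @param geometry Matching [patch_geometry()].
#' @param threshold Confidence cut-off (default 0.8).
#' @return Subset of `patches` with added `class` and `confidence` columns.
#' @export
select_confident <- function(patches, model, geometry = patch_geometry(),
                             threshold = 0.8) {
  if (nrow(patches) == 0) return(patches)
  pred <- predict_patches(model, patches, geometry)
  keep <- as.character(pred$class) == as.character(patches$label) &
    pred$confidence > threshold
  out <- patches[keep, , drop = FALSE]
  out$class <- pred$class[keep]
  out$confidence <- pred$confidence[keep]
  out
}

#' Class activation map of a patch
#'
#' Projects the output-layer weights of `target_class` onto the feature
#' maps of the last convolutional layer: the raw map is the weighted sum of
#' feature channels, negative values are clipped to zero, the map is scaled
#' so its maximum is 1 (an entirely non-positive raw map yields all zeros),
#' and bilinear upsampling restores the patch resolution.
#'
#' @param model A `patch_classifier` (global average pooling before the
#'   classification layer, as built by [build_network()]).
#' @param patch `S x S x 3` array matching the network input size.
#' @param target_class One of `"Benign", "G3", "G4", "G5"`.
#' @return Object of class `activation_map`: list with `heatmap` (`S x S`
#'   matrix in `[0, 1]`), `target_class`, `confidence` (model probability
#'   of that class).
#' @export
class_activation_map <- function(model, patch, target_class) {
  stopifnot(inherits(model, "patch_classifier"))
  k <- match(target_class, GLEASON_CLASSES)
  if (is.na(k)) abort("unknown target class")
  assert_rgb(patch)
  f <- gn_features(model$ptr, patch)              # fH x fW x C x 1
  w <- gn_get_weights(model$ptr)$Wfc[, k]         # C
  fh <- dim(f)[1]; fw <- dim(f)[2]; C <- dim(f)[3]
  raw <- matrix(matrix(f[, , , 1], ncol = C) %*% w, fh, fw)
  raw[raw < 0] <- 0
  if (max(raw) > 0) raw <- raw / max(raw)
  hm <- as.matrix(EBImage::resize(EBImage::Image(raw), w = dim(patch)[1],
                                  h = dim(patch)[2]))
  hm <- pmin(pmax(hm, 0), 1)
  conf <- predict_patch(model, patch)[1, k]
  structure(list(heatmap = hm, target_class = target_class,
                 confidence = unname(conf)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> class %s, confidence %.3f, %d x %d\n",
              x$target_class, x$confidence, nrow(x$heatmap),
              ncol(x$heatmap)))
  invisible(x)
}

#' Triptych visualization of a class activation map
#'
#' Mirrors the usual CAM presentation: the original patch, the heatmap
#' overlay, and the patch masked to high-activation regions.
#'
#' @param object An `activation_map`.
#' @param patch The patch the map was computed from.
#' @param mask_threshold Activation level defining the masked panel.
#' @param ... Unused.
#' @return A ggplot object with three panels.
#' @export
autoplot.activation_map <- function(object, patch, mask_threshold = 0.5,
                                    ...) {
  h <- nrow(object$heatmap); w <- ncol(object$heatmap)
  rgb_hex <- function(img) grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  hm <- object$heatmap
  overlay <- patch
  overlay[, , 1] <- clamp01(patch[, , 1] * (1 - hm) + hm)
  overlay[, , 2] <- patch[, , 2] * (1 - hm)
  overlay[, , 3] <- patch[, , 3] * (1 - hm)
  masked <- patch
  for (ch in 1:3) masked[, , ch][hm < mask_threshold] <- 1
  df <- tibble::tibble(
    row = rep(rep(seq_len(h), times = w), 3),
    col = rep(rep(seq_len(w), each = h), 3),
    panel = rep(c("patch", "overlay", "masked"), each = h * w),
    fill = c(rgb_hex(patch), rgb_hex(overlay), rgb_hex(masked)))
  df$panel <- factor(df$panel, levels = c("patch", "overlay", "masked"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = I(.data$fill))) +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("CAM %s (p = %.2f)", object$target_class,
                                  object$confidence))
}
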