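#' Patch sampling and augmentation geometry
#'
#' Defaults follow the full-resolution protocol: 750 x 750 patches sampled
#' on a 375-px grid, labelled by their central 250 x 250 window, resized to
#' 250 x 250 and randomly cropped to 224 x 224 for the network. The
#' `"half"` profile halves every length (spot 1550 px) for desk-scale runs.
#'
#' @param profile `"full"` or `"half"`; individual fields can be overridden.
#' @param patch_size,step,label_window,resize_to,crop_size Pixel sizes.
#' @return Object of class `patch_geometry`.
#' @export
patch_geometry <- function(profile = c("full", "half"),
                           patch_size = NULL, step = NULL,
                           label_window = NULL, resize_to = NULL,
                           crop_size = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "full")
    list(patch_size = 750L, step = 375L, label_window = 250L,
         resize_to = 250L, crop_size = 224L)
  else
    list(patch_size = 375L, step = 188L, label_window = 125L,
         resize_to = 125L, crop_size = 112L)
  g <- list(patch_size = patch_size %||% def$patch_size,
            step = step %||% def$step,
            label_window = label_window %||% def$label_window,
            resize_to = resize_to %||% def$resize_to,
            crop_size = crop_size %||% def$crop_size)
  g <- lapply(g, as.integer)
  if (g$label_window > g$patch_size)
    abort("label_window must not exceed patch_size")
  if (g$step < 1) abort("step must be >= 1")
  if (g$crop_size > g$resize_to)
    abort("crop_size must not exceed resize_to")
  structure(c(g, list(profile = profile)), class = "patch_geometry")
}

#' Extract labelled training patches from an annotated spot
#'
#' Candidate top-left corners form the grid `{0, step, 2 step, ...}` (0-based
#' pixel coordinates), clipped so each patch lies fully inside the spot. A
#' candidate is kept iff the set of non-zero mask labels inside its central
#' `label_window` window has cardinality exactly one; that label becomes the
#' patch label. Windows with no annotation, or annotations from more than
#' one class, are discarded.
#'
#' @param spot A `tma_spot` (needs `mask`; `image` required when
#'   `pixels != "none"`).
#' @param geometry A [patch_geometry()].
#' @param pixels `"none"` returns the manifest only; `"uint8"` attaches the
#'   patch pixels resized to `resize_to` as compact raw arrays; `"array"`
#'   attaches full-resolution numeric arrays.
#' @return Tibble with columns `spot_id`, `row`, `col` (0-based top-left),
#'   `label`, and (optionally) `pixels` (list column).
#' @export
extract_patches <- function(spot, geometry = patch_geometry(),
                            pixels = c("none", "uint8", "array")) {
  pixels <- match.arg(pixels)
  mask <- spot$mask
  ps <- geometry$patch_size
  h <- nrow(mask); w <- ncol(mask)
  if (h < ps || w < ps) {
    warn("spot smaller than patch_size: no patches")
    return(empty_patch_tibble(pixels))
  }
  starts_r <- seq(0L, h - ps, by = geometry$step)
  starts_c <- seq(0L, w - ps, by = geometry$step)
  off <- (ps - geometry$label_window) %/% 2L
  lw <- geometry$label_window
  grid <- expand.grid(row = starts_r, col = starts_c)
  lab <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r0 <- grid$row[i] + off; c0 <- grid$col[i] + off
    win <- mask[(r0 + 1L):(r0 + lw), (c0 + 1L):(c0 + lw)]
    present <- unique(win[win > 0L])
    lab[i] <- if (length(present) == 1L) GLEASON_CLASSES[present]
              else NA_character_
  }
  keep <- !is.na(lab)
  out <- tibble::tibble(spot_id = spot$spot_id %||% NA_character_,
                        row = as.integer(grid$row[keep]),
                        col = as.integer(grid$col[keep]),
                        label = factor(lab[keep], levels = GLEASON_CLASSES))
  if (pixels != "none") {
    if (is.null(spot$image)) abort("spot has no image pixels")
    out$pixels <- purrr::map2(out$row, out$col, function(r, c) {
      px <- spot$image[(r + 1L):(r + ps), (c + 1L):(c + ps), , drop = FALSE]
      if (pixels == "array") return(px)
      rs <- geometry$resize_to
      small <- EBImage::resize(EBImage::Image(px, colormode = "Color"),
                               w = rs, h = rs)
      a <- as.array(small)
      array(as.raw(pmin(pmax(round(a * 255), 0), 255)), dim = dim(a))
    })
  }
  out
}

#' Resolution factor between stored patches and the native spot image
#'
#' Patches of `patch_size` native pixels are resized to `resize_to` before
#' entering the network, so whole-spot inference must shrink the spot by
#' this factor for textures to appear at the training scale.
#'
#' @param geometry A [patch_geometry()].
#' @return `resize_to / patch_size` (1/3 for the full protocol).
#' @export
training_scale <- function(geometry) {
  geometry$resize_to / geometry$patch_size
}

empty_patch_tibble <- function(pixels = "none") {
  out <- tibble::tibble(spot_id = character(), row = integer(),
                        col = integer(),
                        label = factor(character(),
                                       levels = GLEASON_CLASSES))
  if (pixels != "none") out$pixels <- list()
  out
}

#' Extract patches from every spot of a cohort
#'
#' @inheritParams extract_patches
#' @param cohort A `tma_cohort`.
#' @return Row-bound patch tibble over all spots.
#' @export
extract_cohort_patches <- function(cohort, geometry = patch_geometry(),
                                   pixels = c("none", "uint8", "array")) {
  pixels <- match.arg(pixels)
  purrr::map_dfr(cohort$spots, extract_patches, geometry = geometry,
                 pixels = pixels)
}

# decode a stored uint8 patch back to a [0,1] numeric array
decode_patch <- function(px) {
  if (is.raw(px)) {
    a <- array(as.integer(px) / 255, dim = dim(px))
    a
  } else px
}

# 3x3 colour transform implementing brightness/contrast/saturation scaling
# and a small hue rotation about the gray axis
jitter_matrix <- function(brightness, contrast, saturation, hue_turns) {
  lum <- c(0.299, 0.587, 0.114)
  sat <- saturation * diag(3) +
    (1 - saturation) * matrix(lum, 3, 3, byrow = TRUE)
  th <- 2 * pi * hue_turns
  u <- c(1, 1, 1) / sqrt(3)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  rot <- cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
  # contrast pivots around mid-gray: y = b * (contrast * x + 0.5 (1 - contrast))
  list(m = (brightness * contrast) * (rot %*% sat),
       offset = 0.5 * (1 - contrast) * brightness)
}

#' Randomly augment one training patch
#'
#' Augmentation order: resize (already applied when patches are stored), a
#' random `crop_size` crop, rotation by a multiple of 90 degrees, horizontal
#' and vertical flips with probability 1/2 each, and mild colour jitter
#' (brightness/contrast/saturation scales in `[0.9, 1.1]`, hue rotation
#' within ±0.02 turns). With `random = FALSE` the deterministic fallback is
#' the centre crop of the resized patch, unrotated, unjittered.
#'
#' @param px `resize_to` square RGB array in `[0,1]`, or the raw-byte
#'   encoding produced by [extract_patches()].
#' @param geometry A [patch_geometry()].
#' @param random Draw random augmentation parameters from the R RNG.
#' @return `crop_size` x `crop_size` x 3 array.
#' @export
augment_patch <- function(px, geometry = patch_geometry(), random = TRUE) {
  raw_in <- is.raw(px)
  rs <- dim(px)[1]
  cs <- geometry$crop_size
  if (rs < cs) abort("patch smaller than crop size")
  if (!random) {
    r0 <- (rs - cs) %/% 2L + 1L
    c0 <- (rs - cs) %/% 2L + 1L
    out <- px[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L), , drop = FALSE]
    return(if (raw_in) decode_patch(out) else out)
  }
  r0 <- sample.int(rs - cs + 1L, 1L)
  c0 <- sample.int(rs - cs + 1L, 1L)
  k <- sample(0:3, 1L)
  fh <- runif(1) < 0.5
  fv <- runif(1) < 0.5
  # compose crop + rotation + flips into one subscript operation
  ri <- r0:(r0 + cs - 1L); ci <- c0:(c0 + cs - 1L)
  rev_r <- k %in% c(1L, 2L); rev_c <- k %in% c(2L, 3L)
  swap <- k %% 2L == 1L
  if (xor(rev_r, if (swap) fh else fv)) ri <- rev(ri)
  if (xor(rev_c, if (swap) fv else fh)) ci <- rev(ci)
  out <- if (swap) aperm(px[ri, ci, , drop = FALSE], c(2, 1, 3))
         else px[ri, ci, , drop = FALSE]
  out <- decode_patch(out)
  jm <- jitter_matrix(runif(1, 0.9, 1.1), runif(1, 0.9, 1.1),
                      runif(1, 0.9, 1.1), runif(1, -0.02, 0.02))
  flat <- matrix(out, ncol = 3L) %*% t(jm$m) + jm$offset
  array(clamp01(flat), dim = dim(out))
}

#' Class-balanced mini-batch sampler
#'
#' Every batch holds exactly `batch_size / 4` patches per class, sampled
#' uniformly with replacement within class.
#'
#' @param patches Patch tibble (needs the `label` column).
#' @param batch_size Divisible by 4 (the paper protocol uses 32).
#' @param n_batches Number of batches to draw.
#' @return List of `n_batches` integer index vectors into `patches`.
#' @export
balanced_batches <- function(patches, batch_size = 32L, n_batches = 1L) {
  if (batch_size %% 4L != 0L) abort("batch_size must be divisible by 4")
  idx_by_class <- split(seq_len(nrow(patches)), patches$label)
  missing <- GLEASON_CLASSES[!GLEASON_CLASSES %in%
                               names(Filter(length, idx_by_class))]
  if (length(missing) > 0)
    abort(sprintf("no patches for class: %s",
                  paste(missing, collapse = ", ")))
  per <- batch_size %/% 4L
  lapply(seq_len(n_batches), function(i) {
    unlist(lapply(GLEASON_CLASSES, function(cl) {
      pool <- idx_by_class[[cl]]
      pool[sample.int(length(pool), per, replace = TRUE)]
    }), use.names = FALSE)
  })
}

#' Write a patch manifest CSV (`spot_id,row,col,label`)
#' @param patches Patch tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_manifest <- function(patches, path) {
  write.csv(patches[, c("spot_id", "row", "col", "label")], path,
            row.names = FALSE)
  invisible(path)
}
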