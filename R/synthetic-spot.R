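#' Per-pattern texture parameters for the synthetic TMA-spot generator
#'
#' The generator renders the architectural criteria that distinguish Gleason
#' patterns rather than photorealistic H&E: benign tissue as sparse large
#' glands with a thin epithelial rim and wide lumen; Gleason 3 as small,
#' well-separated glands; Gleason 4 as fused gland chains plus cribriform
#' ("sieve") discs; Gleason 5 as dense nuclear sheets without lumen
#' formation. All length parameters are in pixels at the working resolution.
#'
#' @param scale Multiplier applied to every length parameter (use `0.5` for
#'   the half-geometry profile where a spot is 1550 px instead of 3100 px).
#' @return Named list with one parameter list per pattern
#'   (`benign`, `g3`, `g4`, `g5`).
#' @export
texture_params <- function(scale = 1) {
  s <- function(x) pmax(1, round(x * scale))
  list(
    benign = list(radius = s(56), radius_sd = 6 * scale, ring = s(5),
                  coverage = 0.20, min_gap = s(30)),
    g3 = list(radius = s(18), radius_sd = 2.5 * scale, ring_frac = 0.45,
              coverage = 0.30, min_gap = s(10)),
    g4 = list(radius = s(20), radius_sd = 3 * scale, ring_frac = 0.55,
              coverage = 0.40, chain_len = c(3L, 7L),
              crib_radius = s(52), crib_frac = 0.35,
              crib_holes = c(5L, 9L), crib_hole_radius = s(8)),
    g5 = list(dot_radius = s(3), coverage = 0.35)
  )
}

#' Stain palette used by the synthetic renderer
#'
#' Approximate H&E colours in `[0, 1]` RGB: near-white background and gland
#' lumens, pink stroma, purple epithelium, dark basophilic nuclei.
#' @return Named list of RGB triples.
#' @export
stain_colors <- function() {
  list(background = c(0.96, 0.96, 0.97),
       stroma     = c(0.91, 0.76, 0.83),
       epithelium = c(0.58, 0.38, 0.64),
       nucleus    = c(0.27, 0.16, 0.42),
       lumen      = c(0.97, 0.96, 0.97))
}

#' Configuration of one synthetic TMA spot
#'
#' @param spot_size_px Side of the square raster in pixels (3100 at the full
#'   geometry; tests use smaller spots).
#' @param regions Data frame with columns `pattern` (one of `"Benign"`,
#'   `"G3"`, `"G4"`, `"G5"`) and `area_fraction` (target fraction of the
#'   circular tissue disc). Fractions must be non-negative and sum to at
#'   most 1; remaining tissue stays unannotated (mask code 0).
#' @param texture Output of [texture_params()].
#' @param colors Output of [stain_colors()].
#' @param noise_sd Pixel-wise Gaussian colour noise.
#' @param seed Optional integer seed making the spot reproducible.
#' @return Object of class `spot_config`.
#' @export
spot_config <- function(spot_size_px = 3100,
                        regions = tibble::tibble(pattern = "G3",
                                                 area_fraction = 0.6),
                        texture = texture_params(spot_size_px / 3100),
                        colors = stain_colors(),
                        noise_sd = 0.015,
                        seed = NULL) {
  regions <- tibble::as_tibble(regions)
  if (!all(c("pattern", "area_fraction") %in% names(regions)))
    abort("`regions` needs columns `pattern` and `area_fraction`")
  if (!all(regions$pattern %in% GLEASON_CLASSES))
    abort("unknown pattern label in `regions`")
  if (any(regions$area_fraction < 0))
    abort("area fractions must be non-negative")
  if (sum(regions$area_fraction) > 1 + 1e-9)
    abort("area fractions sum to more than 1")
  if (spot_size_px < 64) abort("spot_size_px is too small")
  structure(list(spot_size_px = as.integer(spot_size_px), regions = regions,
                 texture = texture, colors = colors, noise_sd = noise_sd,
                 seed = seed),
            class = "spot_config")
}

# relative (dr, dc) offsets of a filled disk of integer radius
disk_offsets <- function(radius) {
  radius <- max(0L, as.integer(round(radius)))
  g <- seq.int(-radius, radius)
  dr <- rep(g, times = length(g))
  dc <- rep(g, each = length(g))
  keep <- dr * dr + dc * dc <= radius^2
  cbind(dr[keep], dc[keep])
}

# linear pixel indices of disks stamped at integer centers (n x 2), clipped
stamp_indices <- function(h, w, centers, offsets) {
  if (nrow(centers) == 0) return(integer(0))
  n <- nrow(centers); k <- nrow(offsets)
  r <- rep.int(centers[, 1], rep.int(k, n)) + rep.int(offsets[, 1], n)
  c <- rep.int(centers[, 2], rep.int(k, n)) + rep.int(offsets[, 2], n)
  keep <- r >= 1 & r <= h & c >= 1 & c <= w
  r[keep] + (c[keep] - 1L) * h
}

# uniform sample of n points inside an annular sector of the tissue disc;
# angles follow the mask convention theta = atan2(row - cx, col - cx)
sample_sector <- function(n, cx, R, a0, a1, margin = 0) {
  rad <- (R - margin) * sqrt(runif(n))
  ang <- runif(n, a0, a1)
  cbind(round(cx + rad * sin(ang)), round(cx + rad * cos(ang)))
}

# thin points so that no two are closer than min_gap (greedy)
thin_points <- function(pts, min_gap) {
  if (nrow(pts) <= 1) return(pts)
  keep <- logical(nrow(pts))
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(pts))) {
    if (nrow(kept) == 0 ||
        min((kept[, 1] - pts[i, 1])^2 + (kept[, 2] - pts[i, 2])^2) >=
          min_gap^2) {
      keep[i] <- TRUE
      kept <- rbind(kept, pts[i, , drop = FALSE])
    }
  }
  pts[keep, , drop = FALSE]
}

# stamp glands given per-gland radii: epithelial ring then lumen
draw_glands <- function(chan, centers, radii, ring_px, cols, lumen = TRUE) {
  h <- nrow(chan[[1]]); w <- ncol(chan[[1]])
  for (rr in unique(radii)) {
    ctr <- centers[radii == rr, , drop = FALSE]
    ring <- max(1L, as.integer(round(ring_px(rr))))
    outer_idx <- stamp_indices(h, w, ctr, disk_offsets(rr))
    for (ch in 1:3) chan[[ch]][outer_idx] <- cols$epithelium[ch]
    if (lumen && rr - ring >= 1) {
      lum_idx <- stamp_indices(h, w, ctr, disk_offsets(rr - ring))
      for (ch in 1:3) chan[[ch]][lum_idx] <- cols$lumen[ch]
    }
  }
  chan
}

draw_pattern <- function(chan, pattern, cx, R, a0, a1, tp, cols) {
  sector_area <- (a1 - a0) / 2 * R^2
  if (pattern == "Benign") {
    p <- tp$benign
    n <- max(1, round(p$coverage * sector_area / (pi * p$radius^2)))
    ctr <- thin_points(sample_sector(3 * n, cx, R, a0, a1, p$radius),
                       2 * p$radius + p$min_gap)
    ctr <- ctr[seq_len(min(n, nrow(ctr))), , drop = FALSE]
    radii <- pmax(4, round(rnorm(nrow(ctr), p$radius, p$radius_sd)))
    chan <- draw_glands(chan, ctr, radii, function(r) p$ring, cols)
  } else if (pattern == "G3") {
    p <- tp$g3
    n <- max(1, round(p$coverage * sector_area / (pi * p$radius^2)))
    ctr <- thin_points(sample_sector(4 * n, cx, R, a0, a1, p$radius),
                       2 * p$radius + p$min_gap)
    ctr <- ctr[seq_len(min(n, nrow(ctr))), , drop = FALSE]
    radii <- pmax(3, round(rnorm(nrow(ctr), p$radius, p$radius_sd)))
    chan <- draw_glands(chan, ctr, radii,
                        function(r) max(2, round(p$ring_frac * r)), cols)
  } else if (pattern == "G4") {
    p <- tp$g4
    crib_area <- p$crib_frac * p$coverage * sector_area
    n_crib <- max(1, round(crib_area / (pi * p$crib_radius^2)))
    chain_area <- (1 - p$crib_frac) * p$coverage * sector_area
    mean_len <- mean(p$chain_len)
    n_chain <- max(1, round(chain_area / (mean_len * pi * p$radius^2)))
    # fused gland chains: random-walk strings of overlapping glands
    starts <- sample_sector(n_chain, cx, R, a0, a1, p$radius)
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(starts))) {
      len <- sample(seq(p$chain_len[1], p$chain_len[2]), 1)
      pos <- starts[i, ]
      ang <- runif(1, 0, 2 * pi)
      pts <- matrix(0, len, 2)
      for (j in seq_len(len)) {
        pts[j, ] <- pos
        ang <- ang + rnorm(1, 0, 0.6)
        pos <- pos + round(1.35 * p$radius * c(cos(ang), sin(ang)))
      }
      centers <- rbind(centers, pts)
    }
    radii <- pmax(3, round(rnorm(nrow(centers), p$radius, p$radius_sd)))
    # epithelium of all chain glands first, then lumens: fused appearance
    h <- nrow(chan[[1]]); w <- ncol(chan[[1]])
    all_idx <- unlist(lapply(unique(radii), function(rr)
      stamp_indices(h, w, centers[radii == rr, , drop = FALSE],
                    disk_offsets(rr))))
    for (ch in 1:3) chan[[ch]][all_idx] <- cols$epithelium[ch]
    lum_idx <- unlist(lapply(unique(radii), function(rr)
      stamp_indices(h, w, centers[radii == rr, , drop = FALSE],
                    disk_offsets(max(1, round(0.35 * rr))))))
    for (ch in 1:3) chan[[ch]][lum_idx] <- cols$lumen[ch]
    # cribriform discs: one epithelial sheet pierced by small round lumens
    crib_ctr <- sample_sector(n_crib, cx, R, a0, a1, p$crib_radius)
    disc_idx <- stamp_indices(h, w, crib_ctr, disk_offsets(p$crib_radius))
    for (ch in 1:3) chan[[ch]][disc_idx] <- cols$epithelium[ch]
    hole_off <- disk_offsets(p$crib_hole_radius)
    for (i in seq_len(nrow(crib_ctr))) {
      nh <- sample(seq(p$crib_holes[1], p$crib_holes[2]), 1)
      ha <- runif(nh, 0, 2 * pi)
      hr <- 0.65 * p$crib_radius * sqrt(runif(nh))
      holes <- cbind(round(crib_ctr[i, 1] + hr * cos(ha)),
                     round(crib_ctr[i, 2] + hr * sin(ha)))
      hidx <- stamp_indices(h, w, holes, hole_off)
      for (ch in 1:3) chan[[ch]][hidx] <- cols$lumen[ch]
    }
  } else if (pattern == "G5") {
    p <- tp$g5
    n <- max(1, round(p$coverage * sector_area / (pi * p$dot_radius^2)))
    ctr <- sample_sector(n, cx, R, a0, a1)
    h <- nrow(chan[[1]]); w <- ncol(chan[[1]])
    idx <- stamp_indices(h, w, ctr, disk_offsets(p$dot_radius))
    for (ch in 1:3) chan[[ch]][idx] <- cols$nucleus[ch]
  }
  chan
}

#' Render one synthetic TMA spot with its ground-truth annotation mask
#'
#' Draws a circular tissue disc on a light background, splits it into
#' angular sectors realizing the requested region area fractions, labels the
#' mask accordingly and renders the pattern-specific gland texture inside
#' each region. The mask uses the encoding 0 = unannotated/background,
#' 1 = Benign, 2 = Gleason 3, 3 = Gleason 4, 4 = Gleason 5.
#'
#' @param config A [spot_config()].
#' @return Object of class `tma_spot`: list with `image` (H x W x 3 array in
#'   `[0, 1]`), `mask` (H x W integer matrix), `regions` (the realized region
#'   table) and `spot_id`.
#' @export
generate_spot <- function(config) {
  stopifnot(inherits(config, "spot_config"))
  run <- function() generate_spot_impl(config)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

generate_spot_impl <- function(config) {
  H <- config$spot_size_px
  cols <- config$colors
  cx <- (H + 1) / 2
  R <- 0.47 * H
  d2 <- outer((seq_len(H) - cx)^2, (seq_len(H) - cx)^2, "+")
  tissue <- d2 <= R^2

  # angular sectors, one per region, in a random orientation
  fr <- config$regions$area_fraction
  theta <- atan2(rep(seq_len(H) - cx, times = H),
                 rep(seq_len(H) - cx, each = H))
  dim(theta) <- c(H, H)
  start <- runif(1, 0, 2 * pi)
  ang <- (theta - start) %% (2 * pi)
  bounds <- 2 * pi * cumsum(c(0, fr))

  mask <- matrix(0L, H, H)
  chan <- lapply(1:3, function(ch)
    matrix(cols$background[ch], H, H))
  for (ch in 1:3) chan[[ch]][tissue] <- cols$stroma[ch]

  for (k in seq_len(nrow(config$regions))) {
    pat <- config$regions$pattern[k]
    sector <- tissue & ang >= bounds[k] & ang < bounds[k + 1]
    mask[sector] <- match(pat, GLEASON_CLASSES)  # 1..4
    chan <- draw_pattern(chan, pat, cx, R, start + bounds[k],
                         start + bounds[k + 1], config$texture, cols)
  }
  # gland strokes may spill a little past the disc; repaint the outside
  for (ch in 1:3) chan[[ch]][!tissue] <- cols$background[ch]
  img <- array(0, dim = c(H, H, 3))
  for (ch in 1:3)
    img[, , ch] <- clamp01(chan[[ch]] + rnorm(H * H, 0, config$noise_sd))
  structure(list(image = img, mask = mask,
                 regions = config$regions, spot_id = NA_character_),
            class = "tma_spot")
}

#' Build a one-hot (optionally label-smoothed) probability-map fixture
#'
#' Converts a ground-truth annotation mask into a per-pixel 4-class
#' probability map: at every annotated tissue pixel the channel of the mask
#' label gets probability `1 - smoothing` and the remainder is spread
#' uniformly over the other three channels. Pixels with mask code 0 are
#' treated as non-tissue and get all-zero channels. These fixtures exercise
#' the scoring stack without a trained network.
#'
#' @param mask Integer matrix using the standard `{0..4}` encoding.
#' @param smoothing Fraction in `[0, 1)` moved off the labelled channel.
#' @param spot_id Optional identifier stored in the map.
#' @return A `probability_map` object.
#' @export
one_hot_probability_map <- function(mask, smoothing = 0, spot_id = NA_character_) {
  if (smoothing < 0 || smoothing >= 1)
    abort("`smoothing` must be in [0, 1)")
  if (!all(mask %in% 0:4)) abort("mask uses labels outside {0..4}")
  h <- nrow(mask); w <- ncol(mask)
  tissue <- mask > 0
  p <- array(0, dim = c(h, w, 4))
  off <- smoothing / 3
  for (k in 1:4) {
    pk <- matrix(0, h, w)
    pk[tissue] <- off
    pk[mask == k] <- 1 - smoothing
    p[, , k] <- pk
  }
  new_probability_map(p, tissue, spot_id = spot_id, model_id = "one-hot")
}
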