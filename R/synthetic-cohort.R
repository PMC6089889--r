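#' Hazard model of the synthetic survival generator
#'
#' Survival times are exponential with a hazard that multiplies by `ratio`
#' per risk tier (low / intermediate / high, derived from the composite
#' score) or per unit of composite score, with independent uniform censoring
#' on `[0, censor_horizon]`.
#'
#' @param base_hazard Events per month in the lowest tier.
#' @param ratio Hazard ratio per tier (or per score unit).
#' @param per Either `"tier"` (default) or `"score"`.
#' @param censor_horizon Months; censoring times are uniform on this range.
#' @return Object of class `hazard_params`.
#' @export
hazard_params <- function(base_hazard = 0.006, ratio = 3, per = c("tier", "score"),
                          censor_horizon = 120) {
  per <- match.arg(per)
  stopifnot(base_hazard > 0, ratio > 0, censor_horizon > 0)
  structure(list(base_hazard = base_hazard, ratio = ratio, per = per,
                 censor_horizon = censor_horizon),
            class = "hazard_params")
}

# region recipes realizing each composite score; fractions of the tissue disc
# are kept well clear of the 0.25 scoring threshold
score_region_spec <- function(score) {
  spec <- switch(as.character(score),
    "0"  = list(c("Benign", 0.85)),
    "6"  = list(c("G3", 0.55), c("Benign", 0.35)),
    "7"  = list(c("G3", 0.45), c("G4", 0.35), c("Benign", 0.15)),
    "8"  = list(c("G4", 0.55), c("Benign", 0.35)),
    "9"  = list(c("G4", 0.45), c("G5", 0.35), c("Benign", 0.15)),
    "10" = list(c("G5", 0.55), c("Benign", 0.35)),
    abort(sprintf("no region recipe for score %s", score)))
  tibble::tibble(pattern = vapply(spec, `[`, "", 1),
                 area_fraction = as.numeric(vapply(spec, `[`, "", 2)))
}

#' Generate a synthetic TMA cohort with linked survival records
#'
#' Draws a composite Gleason score per spot from `score_mix`, renders a spot
#' whose annotated region areas realize that score under the c = 0.25
#' weighted-threshold scoring rule, and simulates a disease-specific
#' survival record whose hazard increases with the risk tier.
#'
#' @param n_spots Number of spots (>= 1).
#' @param score_mix Named probability vector over
#'   `c("Benign","6","7","8","9","10")`; must sum to 1. The default loosely
#'   imitates a score-balanced test cohort.
#' @param spot_size_px Spot raster size (see [spot_config()]).
#' @param texture Texture parameters; defaults scale with `spot_size_px`.
#' @param hazard A [hazard_params()].
#' @param keep_images If `FALSE`, drop the RGB rasters and keep only masks
#'   (sufficient for scoring fixtures; saves memory for large cohorts).
#' @param seed Optional integer seed; the cohort is then fully reproducible.
#' @return Object of class `tma_cohort`: list of `spots` and a `clinical`
#'   tibble with columns `spot_id`, `true_score` (0 = benign), `time_months`,
#'   `event`.
#' @export
generate_cohort <- function(n_spots,
                            score_mix = c(Benign = 0.12, `6` = 0.18,
                                          `7` = 0.30, `8` = 0.18,
                                          `9` = 0.16, `10` = 0.06),
                            spot_size_px = 3100,
                            texture = texture_params(spot_size_px / 3100),
                            hazard = hazard_params(),
                            keep_images = TRUE,
                            seed = NULL) {
  if (n_spots < 1) abort("`n_spots` must be at least 1")
  if (abs(sum(score_mix) - 1) > 1e-8) abort("`score_mix` must sum to 1")
  lev <- c("Benign", "6", "7", "8", "9", "10")
  if (!all(names(score_mix) %in% lev)) abort("unknown score in `score_mix`")
  run <- function() {
    drawn <- sample(names(score_mix), n_spots, replace = TRUE,
                    prob = score_mix)
    scores <- as.integer(ifelse(drawn == "Benign", "0", drawn))
    build_cohort(scores, lapply(scores, score_region_spec), spot_size_px,
                 texture, hazard, keep_images, seed)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate a clinical table without rendering spot images
#'
#' Draws composite scores from `score_mix` and survival records from the
#' [hazard_params()] model (exponential event times, hazard multiplied per
#' risk tier or score unit, independent uniform censoring). Useful for
#' survival-analysis simulation studies where images are not needed.
#'
#' @inheritParams generate_cohort
#' @return Tibble with `spot_id`, `true_score`, `time_months`, `event`.
#' @export
simulate_clinical <- function(n_spots,
                              score_mix = c(Benign = 0.12, `6` = 0.18,
                                            `7` = 0.30, `8` = 0.18,
                                            `9` = 0.16, `10` = 0.06),
                              hazard = hazard_params(),
                              seed = NULL) {
  if (n_spots < 1) abort("`n_spots` must be at least 1")
  if (abs(sum(score_mix) - 1) > 1e-8) abort("`score_mix` must sum to 1")
  run <- function() {
    drawn <- sample(names(score_mix), n_spots, replace = TRUE,
                    prob = score_mix)
    scores <- as.integer(ifelse(drawn == "Benign", "0", drawn))
    simulate_survival(scores, hazard)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# survival records for a vector of composite scores
simulate_survival <- function(scores, hazard) {
  n <- length(scores)
  tier <- match(risk_group(scores), c("low", "intermediate", "high")) - 1L
  rate <- switch(hazard$per,
                 tier = hazard$base_hazard * hazard$ratio^tier,
                 score = hazard$base_hazard *
                   hazard$ratio^pmax(scores - 6, 0))
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 0, hazard$censor_horizon)
  tibble::tibble(
    spot_id = sprintf("spot_%04d", seq_len(n)),
    true_score = scores,
    time_months = pmax(round(pmin(t_event, t_cens), 1), 0.1),
    event = as.integer(t_event <= t_cens))
}

# shared cohort assembly: render spots from region recipes, verify that each
# realizes its score under the scoring rule, and simulate survival records
build_cohort <- function(scores, specs, spot_size_px, texture, hazard,
                         keep_images, seed) {
  n_spots <- length(scores)
  ids <- sprintf("spot_%04d", seq_len(n_spots))
  spots <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    cfg <- spot_config(spot_size_px = spot_size_px, regions = specs[[i]],
                       texture = texture,
                       seed = if (is.null(seed)) NULL
                              else derive_seed(seed, i))
    sp <- generate_spot(cfg)
    sp$spot_id <- ids[i]
    realized <- mask_score(sp$mask)
    if (realized != scores[i])
      abort(sprintf("spot %s realized score %d != drawn %d",
                    ids[i], realized, scores[i]))
    if (!keep_images) sp$image <- NULL
    spots[[i]] <- sp
  }
  names(spots) <- ids
  clinical <- simulate_survival(scores, hazard)
  clinical$spot_id <- ids
  structure(list(spots = spots, clinical = clinical), class = "tma_cohort")
}

#' Generate a region-pure cohort for classifier training
#'
#' Each spot carries a single annotated region of one pattern (plus
#' unannotated surrounding tissue), emulating patch sampling from within
#' pathologist-delineated regions: every extracted patch then shows one
#' texture. Composite scores are the single-pattern ones (Benign = 0,
#' G3 = 6, G4 = 8, G5 = 10).
#'
#' @param n_spots Number of spots.
#' @param pattern_mix Named probability vector over the four patterns.
#' @param coverage Area fraction of the tissue disc covered by the region.
#' @inheritParams generate_cohort
#' @return A `tma_cohort`.
#' @export
generate_pattern_cohort <- function(n_spots,
                                    pattern_mix = c(Benign = 0.25, G3 = 0.25,
                                                    G4 = 0.25, G5 = 0.25),
                                    coverage = 0.85,
                                    spot_size_px = 3100,
                                    texture = texture_params(spot_size_px / 3100),
                                    hazard = hazard_params(),
                                    keep_images = TRUE,
                                    seed = NULL) {
  if (n_spots < 1) abort("`n_spots` must be at least 1")
  if (abs(sum(pattern_mix) - 1) > 1e-8) abort("`pattern_mix` must sum to 1")
  if (!all(names(pattern_mix) %in% GLEASON_CLASSES))
    abort("unknown pattern in `pattern_mix`")
  run <- function() {
    # deterministic composition (largest-remainder rounding of the expected
    # counts) guarantees every requested pattern is represented, which the
    # classifier's balanced batches require; only the order is random
    expected <- n_spots * pattern_mix / sum(pattern_mix)
    counts <- floor(expected)
    short <- n_spots - sum(counts)
    if (short > 0) {
      ord <- order(expected - counts, decreasing = TRUE)
      counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1L
    }
    pat <- sample(rep(names(pattern_mix), counts))
    scores <- c(Benign = 0L, G3 = 6L, G4 = 8L, G5 = 10L)[pat]
    specs <- lapply(pat, function(p)
      tibble::tibble(pattern = p, area_fraction = coverage))
    build_cohort(unname(scores), specs, spot_size_px, texture, hazard,
                 keep_images, seed)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# composite score implied by a ground-truth mask under the default
# weighted-threshold rule (0 = benign)
mask_score <- function(mask, threshold = 0.25) {
  areas <- vapply(1:4, function(k) sum(mask == k), 0)
  if (sum(areas) == 0) return(0L)
  asg <- assign_score(areas / sum(areas), scoring_config(threshold))
  if (is.na(asg$composite)) 0L else as.integer(asg$composite)
}

#' Write a cohort to disk in interchange formats
#'
#' Spot images as 8-bit RGB PNG, masks as single-channel 8-bit PNG with the
#' `{0..4}` code in the pixel value, and the clinical table as CSV with
#' header `spot_id,true_score,time_months,event`.
#'
#' @param cohort A `tma_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tma_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in cohort$spots) {
    if (!is.null(sp$image))
      png::writePNG(sp$image, file.path(dir, paste0(sp$spot_id, ".png")))
    png::writePNG(sp$mask / 255,
                  file.path(dir, paste0(sp$spot_id, "_mask.png")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `*_mask.png`, optional `*.png` images and
#'   `clinical.csv`.
#' @return A `tma_cohort`.
#' @export
read_cohort <- function(dir) {
  clinical <- tibble::as_tibble(read.csv(file.path(dir, "clinical.csv")))
  spots <- lapply(clinical$spot_id, function(id) {
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    img_path <- file.path(dir, paste0(id, ".png"))
    mask_png <- png::readPNG(mask_path)
    mask <- matrix(as.integer(round(mask_png * 255)), nrow = nrow(mask_png))
    sp <- list(image = if (file.exists(img_path)) png::readPNG(img_path),
               mask = mask, regions = NULL, spot_id = id)
    class(sp) <- "tma_spot"
    sp
  })
  names(spots) <- clinical$spot_id
  structure(list(spots = spots, clinical = clinical), class = "tma_cohort")
}
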