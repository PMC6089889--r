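#' Configuration of the weighted-threshold Gleason scoring rule
#'
#' @param threshold The cut-off `c` on the per-class weighted score; with
#'   four output classes `c = 0.25` guarantees that at least one class keeps
#'   a non-zero final score (up to the degenerate all-equal tie, see
#'   `tie_rule`).
#' @param tie_rule What to do when the strict inequality `w > c` zeroes
#'   every class (only possible when all four weights are exactly equal to
#'   `c`): `"argmax"` keeps the largest-weight class regardless of the
#'   threshold (ties broken towards the less aggressive pattern);
#'   `"strict"` applies the printed rule literally and returns a benign
#'   call.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(threshold = 0.25, tie_rule = c("argmax", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (threshold < 0 || threshold >= 1)
    abort("`threshold` must be in [0, 1)")
  structure(list(threshold = threshold, tie_rule = tie_rule),
            class = "scoring_config")
}

#' Per-class weighted scores of a probability map
#'
#' For class `k` with per-pixel probabilities `o[i,j,k]`, the weighted score
#' is `w_k = sum_ij o[i,j,k] / sum_ijk o[i,j,k]`, with both sums running
#' over tissue pixels. The result lies on the 4-simplex.
#'
#' @param map A `probability_map` with at least one tissue pixel.
#' @return Named numeric vector `(Benign, G3, G4, G5)` summing to 1.
#' @export
class_weights <- function(map) {
  stopifnot(inherits(map, "probability_map"))
  if (!any(map$tissue)) abort("probability map has no tissue pixels")
  w <- vapply(1:4, function(k) sum(map$p[, , k][map$tissue]), 0)
  total <- sum(w)
  if (total <= 0) abort("probability mass is zero over tissue")
  setNames(w / total, GLEASON_CLASSES)
}

#' Assign primary/secondary patterns and the composite Gleason score
#'
#' Final per-class scores are `w_final_k = I(w_k > c) * w_k` (strict
#' inequality). Candidate cancer patterns are Gleason 3/4/5 with a non-zero
#' final score; the primary pattern is the one with the largest final score
#' and the secondary the second largest (defaulting to the primary when it
#' is the only one). The spot is called benign iff no cancer pattern
#' survives the threshold. Exact ties between cancer patterns are broken
#' towards the lower (less aggressive) pattern.
#'
#' @param w Weight vector on the 4-simplex, ordered
#'   `(Benign, G3, G4, G5)` (see [class_weights()]).
#' @param config A [scoring_config()].
#' @return Object of class `gleason_assignment`: list with `weights`,
#'   `final_scores`, `primary`, `secondary` (pattern numbers 3-5 or `NA`),
#'   `composite` (6-10 or `NA`), `benign` flag.
#' @export
assign_score <- function(w, config = scoring_config()) {
  if (length(w) != 4 || any(is.na(w)))
    abort("`w` must be 4 finite weights (Benign, G3, G4, G5)")
  w <- setNames(as.numeric(w), GLEASON_CLASSES)
  w_final <- ifelse(w > config$threshold, w, 0)
  if (all(w_final == 0) && config$tie_rule == "argmax") {
    # degenerate all-equal tie: the printed strict rule would zero every
    # class and contradict its stated guarantee; keep the argmax class
    k <- which.max(w)  # which.max breaks ties towards the first (lower) class
    w_final[k] <- w[k]
  }
  cancer <- w_final[2:4]
  names(cancer) <- c("3", "4", "5")
  nz <- cancer[cancer > 0]
  if (length(nz) == 0) {
    out <- list(weights = w, final_scores = w_final,
                primary = NA_integer_, secondary = NA_integer_,
                composite = NA_integer_, benign = TRUE)
  } else {
    ord <- order(-nz, as.integer(names(nz)))  # ties: lower pattern first
    primary <- as.integer(names(nz)[ord[1]])
    secondary <- if (length(nz) >= 2) as.integer(names(nz)[ord[2]])
                 else primary
    out <- list(weights = w, final_scores = w_final,
                primary = primary, secondary = secondary,
                composite = primary + secondary, benign = FALSE)
  }
  structure(out, class = "gleason_assignment")
}

#' @export
print.gleason_assignment <- function(x, ...) {
  if (x$benign) cat("<gleason_assignment> Benign\n")
  else cat(sprintf("<gleason_assignment> %d + %d = %d\n",
                   x$primary, x$secondary, x$composite))
  cat("  weights:", paste(sprintf("%s %.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Gleason assignment into one row
#' @param x A `gleason_assignment`.
#' @param ... Unused.
#' @return One-row tibble: `primary`, `secondary`, `score` (0 = benign) and
#'   the four weights.
#' @export
tidy.gleason_assignment <- function(x, ...) {
  tibble::tibble(primary = x$primary, secondary = x$secondary,
                 score = if (x$benign) 0L else x$composite,
                 w_benign = x$weights[1], w_g3 = x$weights[2],
                 w_g4 = x$weights[3], w_g5 = x$weights[4])
}

#' Score a cohort of probability maps
#'
#' Applies [class_weights()] and [assign_score()] to every map and returns
#' one row per spot, ordered by `spot_id`. Benign calls are encoded as
#' score 0 in the machine-readable table.
#'
#' @param maps List of `probability_map` objects with distinct `spot_id`s.
#' @param config A [scoring_config()].
#' @return Tibble with columns `spot_id`, `primary`, `secondary`, `score`.
#' @export
score_cohort <- function(maps, config = scoring_config()) {
  if (length(maps) == 0)
    return(tibble::tibble(spot_id = character(), primary = integer(),
                          secondary = integer(), score = integer()))
  ids <- vapply(maps, function(m) m$spot_id, "")
  if (anyDuplicated(ids)) abort("duplicate spot ids in `maps`")
  out <- purrr::map_dfr(maps, function(m) {
    asg <- assign_score(class_weights(m), config)
    tibble::tibble(spot_id = m$spot_id,
                   primary = asg$primary, secondary = asg$secondary,
                   score = if (asg$benign) 0L else as.integer(asg$composite))
  })
  dplyr::arrange(out, .data$spot_id)
}
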