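#' Contingency (confusion) matrix over an ordered class set
#'
#' `O[i, j]` counts items labelled class `i` by the first rater (ground
#' truth) and class `j` by the second. The row-normalized matrix divides
#' each row by its total (empty rows stay zero), so diagonal entries of the
#' normalized matrix are per-class recalls.
#'
#' @param labels_a,labels_b Equal-length label vectors (values must belong
#'   to `classes`).
#' @param classes Ordered class labels.
#' @return List with `counts` and `normalized` matrices.
#' @export
confusion_matrix <- function(labels_a, labels_b, classes = gleason_classes()) {
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b))
    abort("label vectors differ in length")
  bad <- setdiff(unique(c(labels_a, labels_b)), as.character(classes))
  if (length(bad) > 0)
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  fa <- factor(labels_a, levels = classes)
  fb <- factor(labels_b, levels = classes)
  O <- unclass(table(fa, fb))
  dimnames(O) <- list(truth = classes, rated = classes)
  rs <- rowSums(O)
  norm <- O / ifelse(rs == 0, 1, rs)
  list(counts = O, normalized = norm)
}

#' Quadratic weighted Cohen's kappa
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with weights
#' `w[i, j] = (i - j)^2 / (N - 1)^2` over ordered rating ranks `1..N`,
#' observed counts `O` and expected counts
#' `E[i, j] = rowsum_i * colsum_j / total` (no correlation between raters).
#' Perfect agreement gives 1, chance-level agreement 0.
#'
#' @param O Square non-negative count matrix over ordered categories.
#' @return Scalar kappa (<= 1), or an error for degenerate marginals where
#'   the expected disagreement is zero.
#' @export
quadratic_kappa <- function(O) {
  O <- as.matrix(O)
  if (nrow(O) != ncol(O) || nrow(O) < 2)
    abort("`O` must be a square matrix over at least 2 categories")
  if (any(O < 0)) abort("counts must be non-negative")
  n <- nrow(O)
  i <- matrix(seq_len(n), n, n)
  w <- (i - t(i))^2 / (n - 1)^2
  total <- sum(O)
  if (total == 0) abort("empty contingency matrix")
  E <- outer(rowSums(O), colSums(O)) / total
  denom <- sum(w * E)
  if (denom == 0)
    abort("degenerate marginals: expected disagreement is zero, kappa undefined")
  1 - sum(w * O) / denom
}

#' Macro-average recall
#'
#' Unweighted mean of per-class recalls `O[k, k] / rowsum_k`; classes absent
#' from the truth (empty rows) are excluded from the average.
#'
#' @param O Square count matrix (truth in rows).
#' @return Scalar in `[0, 1]`.
#' @export
macro_recall <- function(O) {
  O <- as.matrix(O)
  rs <- rowSums(O)
  if (all(rs == 0)) abort("no labelled examples in any class")
  mean(diag(O)[rs > 0] / rs[rs > 0])
}

#' Restrict to items annotated by both raters
#'
#' Keeps the ids with a non-missing annotation from both raters so that
#' model-versus-rater and inter-rater agreement are quantified on the same
#' examples, and aligns the model predictions to them.
#'
#' @param rater_a,rater_b Data frames with columns `id` and `label`
#'   (`NA` = not annotated).
#' @param predictions Data frame with columns `id` and `label`.
#' @return Tibble with columns `id`, `rater_a`, `rater_b`, `prediction`.
#' @export
common_subset <- function(rater_a, rater_b, predictions) {
  a <- dplyr::filter(tibble::as_tibble(rater_a), !is.na(.data$label))
  b <- dplyr::filter(tibble::as_tibble(rater_b), !is.na(.data$label))
  out <- dplyr::inner_join(
    dplyr::rename(a, rater_a = "label"),
    dplyr::rename(b, rater_b = "label"), by = "id")
  out <- dplyr::left_join(
    out, dplyr::rename(tibble::as_tibble(predictions), prediction = "label"),
    by = "id")
  if (nrow(out) == 0) warn("no items annotated by both raters")
  out
}

#' Per-class precision against the consensus of two raters
#'
#' A prediction of class `k` counts as correct when `k` coincides with at
#' least one of the two raters' labels. Classes never predicted are absent
#' from the result.
#'
#' @param predictions,rater_a,rater_b Aligned label vectors.
#' @param classes Class labels.
#' @return Tibble with columns `class`, `n_predicted`, `precision`.
#' @export
consensus_precision <- function(predictions, rater_a, rater_b,
                                classes = gleason_classes()) {
  predictions <- as.character(predictions)
  ok <- predictions == as.character(rater_a) |
        predictions == as.character(rater_b)
  purrr::map_dfr(classes, function(k) {
    sel <- predictions == k
    if (!any(sel)) return(NULL)
    tibble::tibble(class = k, n_predicted = sum(sel),
                   precision = mean(ok[sel]))
  })
}

#' Agreement summary between two annotators
#'
#' Bundles the contingency matrix, quadratic weighted kappa and macro
#' recall for a pair of label vectors over an ordered class set. For
#' spot-level scores use the ordered classes
#' `c("Benign", "6", "7", "8", "9", "10")` (ranks 1-6).
#'
#' @param labels_a,labels_b Label vectors (truth first).
#' @param classes Ordered class labels.
#' @return Object of class `rater_agreement`.
#' @export
rater_agreement <- function(labels_a, labels_b,
                            classes = gleason_classes()) {
  cm <- confusion_matrix(labels_a, labels_b, classes)
  structure(list(counts = cm$counts, normalized = cm$normalized,
                 classes = as.character(classes),
                 kappa = quadratic_kappa(cm$counts),
                 macro_recall = macro_recall(cm$counts),
                 n = sum(cm$counts)),
            class = "rater_agreement")
}

#' @export
print.rater_agreement <- function(x, ...) {
  cat(sprintf("<rater_agreement> n = %d, quadratic kappa = %.3f, macro recall = %.3f\n",
              x$n, x$kappa, x$macro_recall))
  print(x$counts)
  invisible(x)
}

#' Tidy the cells of an agreement contingency matrix
#' @param x A `rater_agreement`.
#' @param ... Unused.
#' @return Tibble with `truth`, `rated`, `n`, `recall` (row-normalized).
#' @export
tidy.rater_agreement <- function(x, ...) {
  tibble::tibble(truth = rep(x$classes, times = length(x$classes)),
                 rated = rep(x$classes, each = length(x$classes)),
                 n = as.vector(x$counts),
                 recall = as.vector(x$normalized))
}

#' One-row agreement summary
#' @param x A `rater_agreement`.
#' @param ... Unused.
#' @return Tibble with `n`, `kappa`, `macro_recall`.
#' @export
glance.rater_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, kappa = x$kappa, macro_recall = x$macro_recall)
}

#' Heatmap of the row-normalized confusion matrix
#' @param object A `rater_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rater_agreement <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = object$classes)
  df$rated <- factor(df$rated, levels = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(.data$rated, .data$truth,
                                   fill = .data$recall)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "rated", y = "truth", fill = "recall")
}
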