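#' @rdname probability_map
#' @usage NULL
#' @export
new_probability_map <- function(p, tissue, spot_id = NA_character_,
                                model_id = NA_character_) {
  stopifnot(length(dim(p)) == 3, dim(p)[3] == 4,
            all(dim(p)[1:2] == dim(tissue)))
  structure(list(p = p, tissue = tissue, spot_id = spot_id,
                 model_id = model_id),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d, %d tissue px, spot %s, model %s\n",
              dim(x$p)[1], dim(x$p)[2], sum(x$tissue),
              x$spot_id, x$model_id))
  invisible(x)
}

#' Tidy a probability map into a long tibble
#'
#' @param x A `probability_map`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `class`, `probability`
#'   (tissue pixels only).
#' @export
tidy.probability_map <- function(x, ...) {
  idx <- which(x$tissue, arr.ind = TRUE)
  purrr::map_dfr(seq_along(GLEASON_CLASSES), function(k)
    tibble::tibble(row = idx[, 1], col = idx[, 2],
                   class = GLEASON_CLASSES[k],
                   probability = x$p[, , k][x$tissue]))
}

#' Plot the four class channels of a probability map
#'
#' @param object A `probability_map`.
#' @param downsample Integer stride applied before plotting.
#' @param ... Unused.
#' @return A ggplot object with one facet per class.
#' @export
autoplot.probability_map <- function(object, downsample = 4, ...) {
  h <- dim(object$p)[1]; w <- dim(object$p)[2]
  ri <- seq(1, h, by = downsample); ci <- seq(1, w, by = downsample)
  df <- purrr::map_dfr(seq_along(GLEASON_CLASSES), function(k) {
    m <- object$p[ri, ci, k]
    tibble::tibble(row = rep(ri, times = length(ci)),
                   col = rep(ci, each = length(ri)),
                   class = GLEASON_CLASSES[k],
                   probability = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "p")
}
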