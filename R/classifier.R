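#' Architecture configuration of the depthwise-separable patch classifier
#'
#' The network is the depthwise-separable architecture selected for this
#' pipeline: an initial 3 x 3 convolution with `ceiling(32 * alpha)`
#' channels (stride 2), thirteen depthwise-separable blocks (3 x 3
#' per-channel convolution, stride 2 at blocks 2, 4, 6 and 12, each followed
#' by a 1 x 1 pointwise convolution that grows the width up to
#' `ceiling(1024 * alpha)`), batch normalization and ReLU after every
#' convolution, then global average pooling, dropout and a softmax output
#' over the four Gleason classes. With `input_size = 224` the pre-pooling
#' feature map is 7 x 7.
#'
#' @param alpha Width multiplier (paper setting: 0.5, i.e. 16 to 512
#'   channels; 1 gives the full 32 to 1024 network). Non-integer channel
#'   counts are rounded up with a warning.
#' @param input_size Square input size in pixels; must be a multiple of 32.
#' @param n_classes Number of output classes (4 for this pipeline).
#' @param dropout_rate Dropout fraction before the output layer.
#' @return Object of class `network_config`.
#' @export
network_config <- function(alpha = 0.5, input_size = 224L, n_classes = 4L,
                           dropout_rate = 0.2) {
  stopifnot(alpha > 0, input_size %% 32 == 0, n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  base <- c(32, 64, 128, 128, 256, 256, 512, 512, 512, 512, 512, 512,
            1024, 1024)
  if (any(abs(alpha * base - round(alpha * base)) > 1e-9))
    warn("alpha yields non-integer channel counts; rounding up")
  structure(list(alpha = alpha, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate),
            class = "network_config")
}

#' Instantiate a randomly initialized patch classifier
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization (and dropout).
#' @return Object of class `patch_classifier`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  ptr <- gn_create(config$alpha, config$input_size, config$n_classes,
                   config$dropout_rate, seed)
  structure(list(ptr = ptr, config = config, seed = as.integer(seed),
                 model_id = sprintf("dsconv-a%s-in%d", config$alpha,
                                    config$input_size),
                 trained = FALSE, input_mean = c(0, 0, 0)),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  d <- gn_config(x$ptr)
  cat(sprintf(
    "<patch_classifier> alpha %.3g, input %d, %d classes, %s params\n",
    d$alpha, d$input_size, d$n_classes, format(d$n_params, big.mark = ",")))
  cat(sprintf("  channels %d..%d, pre-pooling map %dx%d, %s\n",
              d$channels[1], d$channels[length(d$channels)],
              d$feature_hw, d$feature_hw,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Architecture summary of a classifier
#'
#' @param model A `patch_classifier` (or `pixel_annotator`).
#' @return Named list: `alpha`, `input_size`, `channels` (initial convolution
#'   followed by the 13 block widths), `block_strides`, `n_params`,
#'   `feature_hw` (side of the pre-pooling feature map).
#' @export
network_summary <- function(model) {
  gn_config(model$ptr)
}

#' Training configuration (two regimes)
#'
#' `"scratch"` trains from random initialization with Adam at learning rate
#' 0.001; `"finetune"` uses SGD at 0.0001 with Nesterov momentum 0.9 (the
#' regime used when starting from pretrained weights, which can be injected
#' via [set_model_weights()]). Categorical cross-entropy is minimized with
#' balanced mini-batches of size 32 by default.
#'
#' @param mode `"scratch"` or `"finetune"`.
#' @param iterations Number of mini-batch updates (paper protocol: 50000).
#' @param batch_size Mini-batch size, divisible by 4.
#' @param learning_rate Override of the regime default.
#' @param momentum Nesterov momentum (finetune regime).
#' @param eval_every Evaluate held-out metrics every this many iterations.
#' @param seed Integer seed for batch sampling and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(mode = c("scratch", "finetune"),
                         iterations = 50000L, batch_size = 32L,
                         learning_rate = NULL, momentum = 0.9,
                         eval_every = 500L, seed = 1L) {
  mode <- match.arg(mode)
  lr <- learning_rate %||% if (mode == "scratch") 1e-3 else 1e-4
  stopifnot(lr > 0, iterations >= 1)
  structure(list(mode = mode, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), learning_rate = lr,
                 momentum = momentum, eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# assemble an (S, S, 3, n) batch array of augmented patches; the gather and
# colour transform run in compiled code, parameters come from the R RNG
assemble_batch <- function(patches, idx, geometry, random = TRUE) {
  cs <- geometry$crop_size
  px <- patches$pixels[idx]
  rs <- dim(px[[1]])[1]
  n <- length(idx)
  if (random) {
    r0 <- sample.int(rs - cs + 1L, n, replace = TRUE)
    c0 <- sample.int(rs - cs + 1L, n, replace = TRUE)
    k <- sample(0:3, n, replace = TRUE)
    fh <- runif(n) < 0.5
    fv <- runif(n) < 0.5
    swap <- k %% 2L == 1L
    rev_r <- xor(k %in% c(1L, 2L), ifelse(swap, fh, fv))
    rev_c <- xor(k %in% c(2L, 3L), ifelse(swap, fv, fh))
    jit <- t(vapply(seq_len(n), function(i) {
      jm <- jitter_matrix(runif(1, 0.9, 1.1), runif(1, 0.9, 1.1),
                          runif(1, 0.9, 1.1), runif(1, -0.02, 0.02))
      c(t(jm$m), jm$offset)
    }, numeric(10)))
  } else {
    r0 <- rep((rs - cs) %/% 2L + 1L, n)
    c0 <- r0
    swap <- rev_r <- rev_c <- rep(FALSE, n)
    jit <- cbind(matrix(rep(c(diag(3)), each = n), n), 0)
  }
  params <- cbind(r0, c0, swap, rev_r, rev_c, jit)
  gn_assemble_batch(px, rs, cs, params)
}

#' Train the patch classifier on labelled patches
#'
#' Streams class-balanced mini-batches, augments every sample, and minimizes
#' the categorical cross-entropy. Inputs are scaled to `[0, 1]` and centred
#' by the per-channel mean of the training patches. A non-finite loss aborts
#' with a diagnostic. When `holdout` is given, macro-average recall on it is
#' recorded every `eval_every` iterations.
#'
#' @param model A `patch_classifier` (modified in place and returned).
#' @param patches Patch tibble with `label` and `pixels` columns
#'   (see [extract_patches()] with `pixels = "uint8"`).
#' @param config A [train_config()].
#' @param geometry The [patch_geometry()] the patches were produced with.
#' @param holdout Optional patch tibble for interval evaluation.
#' @return The model, with a `history` tibble attached
#'   (`iteration`, `loss`, `holdout_macro_recall`).
#' @export
train_classifier <- function(model, patches, config = train_config(),
                             geometry = patch_geometry(), holdout = NULL) {
  stopifnot(inherits(model, "patch_classifier"))
  if (!"pixels" %in% names(patches))
    abort("patches must carry pixels (extract with pixels = 'uint8')")
  if (geometry$crop_size != model$config$input_size)
    abort("geometry crop_size must equal the network input size")
  gn_set_optimizer(model$ptr,
                   if (config$mode == "scratch") "adam" else "sgdn",
                   config$learning_rate, config$momentum)
  withr::with_seed(config$seed, {
    # per-channel dataset mean over (deterministic) centre crops
    mean_idx <- head(seq_len(nrow(patches)), 64L)
    msum <- c(0, 0, 0)
    for (i in mean_idx) {
      px <- augment_patch(patches$pixels[[i]], geometry, random = FALSE)
      msum <- msum + apply(px, 3, mean)
    }
    model$input_mean <- msum / length(mean_idx)
    gn_set_input_mean(model$ptr, model$input_mean)

    hist_it <- integer(0); hist_loss <- numeric(0); hist_rec <- numeric(0)
    batches <- balanced_batches(patches, config$batch_size,
                                config$iterations)
    for (it in seq_len(config$iterations)) {
      idx <- batches[[it]]
      x <- assemble_batch(patches, idx, geometry, random = TRUE)
      y <- as.integer(patches$label[idx])
      loss <- gn_train_step(model$ptr, x, y)
      if (it %% config$eval_every == 0 || it == config$iterations) {
        rec <- NA_real_
        if (!is.null(holdout) && nrow(holdout) > 0) {
          pred <- predict_patches(model, holdout, geometry)
          O <- confusion_matrix(holdout$label, pred$class,
                                GLEASON_CLASSES)$counts
          rec <- macro_recall(O)
        }
        hist_it <- c(hist_it, it)
        hist_loss <- c(hist_loss, loss)
        hist_rec <- c(hist_rec, rec)
      }
    }
    model$history <- tibble::tibble(iteration = hist_it, loss = hist_loss,
                                    holdout_macro_recall = hist_rec)
  })
  model$trained <- TRUE
  model
}

#' Predict class probabilities for patch tensors
#'
#' @param model A `patch_classifier`.
#' @param x One `S x S x 3` array or an `S x S x 3 x N` batch, `S` being the
#'   network input size, values in `[0, 1]`.
#' @return N x 4 matrix of probabilities with columns
#'   `Benign, G3, G4, G5`; each row sums to 1.
#' @export
predict_patch <- function(model, x) {
  d <- dim(x)
  s <- model$config$input_size
  if (is.null(d) || !(length(d) %in% c(3, 4)) || d[1] != s || d[2] != s)
    abort(sprintf("input must be %d x %d x 3 (x N)", s, s))
  p <- gn_predict(model$ptr, x)
  colnames(p) <- GLEASON_CLASSES
  p
}

#' Predict labels for a patch tibble (deterministic centre crops)
#'
#' @param model A `patch_classifier`.
#' @param patches Patch tibble with a `pixels` column.
#' @param geometry Matching [patch_geometry()].
#' @param batch_size Prediction batch size.
#' @return Tibble: input columns plus `class` (factor) and `confidence`
#'   (probability of the predicted class).
#' @export
predict_patches <- function(model, patches, geometry = patch_geometry(),
                            batch_size = 64L) {
  n <- nrow(patches)
  cls <- character(n); conf <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- assemble_batch(patches, idx, geometry, random = FALSE)
    p <- predict_patch(model, x)
    k <- max.col(p, ties.method = "first")
    cls[idx] <- GLEASON_CLASSES[k]
    conf[idx] <- p[cbind(seq_along(idx), k)]
  }
  out <- patches[, setdiff(names(patches), "pixels")]
  out$class <- factor(cls, levels = GLEASON_CLASSES)
  out$confidence <- conf
  out
}

#' Read or replace the full weight set of a classifier
#'
#' Weights are a named list of numeric arrays (convolution kernels,
#' batch-norm parameters and running statistics, classifier weights and the
#' input channel means), usable for checkpointing or for injecting
#' externally pretrained parameters before fine-tuning.
#'
#' @param model A `patch_classifier`.
#' @return Named list of arrays.
#' @export
model_weights <- function(model) gn_get_weights(model$ptr)

#' @rdname model_weights
#' @param weights Named list as returned by [model_weights()].
#' @export
set_model_weights <- function(model, weights) {
  gn_set_weights(model$ptr, weights)
  model$input_mean <- as.numeric(weights$input_mean %||% model$input_mean)
  model
}

#' Save / load a model checkpoint
#'
#' Writes the weights in R's native serialization plus a JSON architecture
#' descriptor (`architecture.json`) so a checkpoint is self-describing.
#'
#' @param model A `patch_classifier`.
#' @param dir Checkpoint directory.
#' @return `dir` (save) or the restored `patch_classifier` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model_weights(model), file.path(dir, "weights.rds"))
  desc <- c(network_summary(model),
            list(model_id = model$model_id, trained = model$trained,
                 seed = model$seed,
                 dropout = model$config$dropout_rate))
  jsonlite::write_json(desc, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "architecture.json"))
  cfg <- network_config(alpha = desc$alpha, input_size = desc$input_size,
                        n_classes = desc$n_classes,
                        dropout_rate = desc$dropout)
  model <- build_network(cfg, seed = desc$seed %||% 1L)
  model <- set_model_weights(model, readRDS(file.path(dir, "weights.rds")))
  model$trained <- isTRUE(desc$trained)
  model$model_id <- desc$model_id %||% model$model_id
  model
}

#' Tidy the training history of a fitted classifier
#' @param x A trained `patch_classifier`.
#' @param ... Unused.
#' @return The history tibble (`iteration`, `loss`, `holdout_macro_recall`).
#' @export
tidy.patch_classifier <- function(x, ...) {
  x$history %||% tibble::tibble(iteration = integer(), loss = numeric(),
                                holdout_macro_recall = numeric())
}

#' One-row model summary
#' @param x A `patch_classifier`.
#' @param ... Unused.
#' @return Tibble with `alpha`, `input_size`, `n_params`, `trained`,
#'   `final_loss`.
#' @export
glance.patch_classifier <- function(x, ...) {
  d <- gn_config(x$ptr)
  h <- x$history
  tibble::tibble(alpha = d$alpha, input_size = d$input_size,
                 n_params = d$n_params, trained = x$trained,
                 final_loss = if (!is.null(h) && nrow(h)) h$loss[nrow(h)]
                              else NA_real_)
}
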