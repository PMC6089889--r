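# shared fixtures; expensive artifacts are built lazily and cached for the
# whole test session

half_geom <- function() {
  patch_geometry("half", resize_to = 107L, crop_size = 96L)
}

# patch tibble with synthetic class-specific striped textures; linearly
# separable, used for fast optimizer/determinism checks
fake_patch_set <- function(n_per_class = 12L, rs = 72L, seed = 400L) {
  withr::with_seed(seed, {
    mk <- function(cls) {
      x <- array(0.85 + rnorm(rs * rs * 3, 0, 0.03), dim = c(rs, rs, 3))
      idx <- seq_len(rs)
      if (cls == 1) x[, (idx %/% (rs %/% 3)) %% 2 == 0, 1] <- 0.3
      if (cls == 2) x[, (idx %/% 4) %% 2 == 0, 1] <- 0.3
      if (cls == 3) x[(idx %/% 8) %% 2 == 0, , 2] <- 0.3
      if (cls == 4) {
        g <- outer(idx, idx, function(a, b) ((a %/% 6) + (b %/% 6)) %% 2)
        ch <- x[, , 3]; ch[g == 0] <- 0.3; x[, , 3] <- ch
      }
      pmin(pmax(x, 0), 1)
    }
    lab <- rep(gleason_classes(), each = n_per_class)
    tibble::tibble(
      spot_id = "fake", row = 0L, col = 0L,
      label = factor(lab, levels = gleason_classes()),
      pixels = lapply(rep(1:4, each = n_per_class), mk))
  })
}

.fixture_cache <- new.env(parent = emptyenv())

# small trained classifier on region-pure synthetic spots (about 500
# iterations); shared by the CAM and inference tests
desk_model_fixture <- function() {
  if (!is.null(.fixture_cache$desk)) return(.fixture_cache$desk)
  geom <- half_geom()
  train_co <- generate_pattern_cohort(12, spot_size_px = 1550, seed = 501)
  hold_co <- generate_pattern_cohort(4, spot_size_px = 1550, seed = 502)
  patches <- extract_cohort_patches(train_co, geom, pixels = "uint8")
  holdout <- extract_cohort_patches(hold_co, geom, pixels = "uint8")
  rm(train_co, hold_co); gc(verbose = FALSE)
  model <- build_network(network_config(alpha = 0.25, input_size = 96L),
                         seed = 511)
  model <- train_classifier(
    model, patches,
    train_config("scratch", iterations = 800L, eval_every = 800L,
                 seed = 521),
    geom, holdout = holdout)
  .fixture_cache$desk <- list(model = model, geom = geom,
                              patches = patches, holdout = holdout)
  .fixture_cache$desk
}

# independent brute-force evaluation of the quadratic weighted kappa
# formula: explicit double loops, no shared code with the implementation
kappa_brute_force <- function(O) {
  n <- nrow(O)
  num <- 0; den <- 0
  total <- sum(O)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w <- (i - j)^2 / (n - 1)^2
      e <- sum(O[i, ]) * sum(O[, j]) / total
      num <- num + w * O[i, j]
      den <- den + w * e
    }
  }
  1 - num / den
}
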