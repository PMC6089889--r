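test_that("confidence pre-selection applies a strict threshold", {
  g <- patch_geometry("half", patch_size = 72L, step = 72L,
                      label_window = 24L, resize_to = 72L, crop_size = 64L)
  patches <- fake_patch_set(3, rs = 72L)
  model <- build_network(network_config(alpha = 0.25, input_size = 64),
                         seed = 61)
  w <- model_weights(model)
  w$Wfc[] <- 0; w$bfc[] <- 0  # uniform head: every prediction is 0.25
  model <- set_model_weights(model, w)

  # uniform probabilities tie-break to Benign: only Benign patches are
  # "correct", and a threshold of exactly their confidence excludes them
  sel_strict <- select_confident(patches, model, g, threshold = 0.25)
  expect_equal(nrow(sel_strict), 0)
  sel_below <- select_confident(patches, model, g, threshold = 0.2)
  expect_true(all(sel_below$label == "Benign"))
  expect_true(all(sel_below$confidence > 0.2))

  # all-misclassified set is empty at any threshold
  wrong <- patches[patches$label != "Benign", ]
  expect_equal(nrow(select_confident(wrong, model, g, threshold = 0)), 0)
})

test_that("activation maps are the clipped, scaled weight projection", {
  model <- build_network(network_config(alpha = 0.25, input_size = 64),
                         seed = 62)
  x <- withr::with_seed(63, array(runif(64 * 64 * 3), dim = c(64, 64, 3)))
  f <- gleasonet:::gn_features(model$ptr, x)  # 2 x 2 x C x 1

  # single active channel with positive weight: map proportional to it
  w <- model_weights(model)
  w$Wfc[] <- 0
  w$Wfc[5, 3] <- 2  # channel 5 drives class G4
  model <- set_model_weights(model, w)
  am <- class_activation_map(model, x, "G4")
  ref <- f[, , 5, 1]
  ref[ref < 0] <- 0
  if (max(ref) > 0) ref <- ref / max(ref)
  ref_up <- as.matrix(EBImage::resize(EBImage::Image(ref), w = 64, h = 64))
  expect_equal(am$heatmap, pmin(pmax(ref_up, 0), 1), tolerance = 1e-6)
  expect_true(all(am$heatmap >= 0 & am$heatmap <= 1))

  # negated weight clips everything to zero
  w$Wfc[5, 3] <- -2
  model <- set_model_weights(model, w)
  am_neg <- class_activation_map(model, x, "G4")
  expect_true(all(am_neg$heatmap == 0))

  expect_error(class_activation_map(model, x, "G6"), "unknown")
})

test_that("trained CAMs focus on epithelium rather than stroma", {
  fx <- desk_model_fixture()
  conf <- select_confident(fx$holdout, fx$model, fx$geom, threshold = 0.8)
  expect_gt(nrow(conf), 0)
  expect_gt(mean(conf$confidence), 0.8)  # forced by the filter

  cancer <- conf[conf$label %in% c("G3", "G4", "G5"), ]
  checked <- 0; focused <- 0
  for (i in head(seq_len(nrow(cancer)), 9)) {
    px <- augment_patch(cancer$pixels[[i]], fx$geom, random = FALSE)
    am <- class_activation_map(fx$model, px,
                               as.character(cancer$label[i]))
    gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    fg <- gray < 0.75   # epithelium / nuclei
    bg <- gray >= 0.75  # stroma, lumen, background
    if (sum(fg) < 50 || sum(bg) < 50) next
    checked <- checked + 1
    focused <- focused + (mean(am$heatmap[fg]) > mean(am$heatmap[bg]))
  }
  expect_gt(checked, 0)
  expect_gte(focused / checked, 0.5)
})
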