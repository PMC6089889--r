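make_spot <- function(mask, image = NULL) {
  structure(list(image = image, mask = mask, spot_id = "s1"),
            class = "tma_spot")
}

test_that("the sampling grid and central-window rule match the protocol", {
  # fully G3-annotated spot at the paper geometry: (floor(2350/375)+1)^2
  grid_n <- (floor((3100 - 750) / 375) + 1)^2
  p <- extract_patches(make_spot(matrix(2L, 3100, 3100)),
                       patch_geometry("full"))
  expect_equal(nrow(p), grid_n)
  expect_equal(grid_n, 49)
  expect_true(all(p$label == "G3"))
  expect_true(all(p$row %% 375 == 0) && all(p$col %% 375 == 0))

  # mixed central window -> discarded; annotation outside window ignored
  g <- patch_geometry("full", patch_size = 100L, step = 100L,
                      label_window = 50L)
  mask <- matrix(0L, 200, 200)
  mask[1:100, 1:100] <- 2L
  mask[1:100, 101:200] <- 3L
  mask[101:200, 1:25] <- 4L  # G5 in the outer band only, window empty
  p <- extract_patches(make_spot(mask), g)
  expect_equal(nrow(p), 2)
  expect_setequal(as.character(p$label), c("G3", "G4"))

  # window straddling two labels is dropped
  mask2 <- matrix(0L, 100, 100)
  mask2[, 1:50] <- 2L
  mask2[, 51:100] <- 3L
  expect_equal(nrow(extract_patches(make_spot(mask2), g)), 0)

  # unannotated spot -> no patches; undersized spot -> warning + empty
  expect_equal(nrow(extract_patches(make_spot(matrix(0L, 200, 200)), g)), 0)
  expect_warning(p0 <- extract_patches(make_spot(matrix(2L, 50, 50)), g),
                 "smaller")
  expect_equal(nrow(p0), 0)
})

test_that("emitted patches pass the central-window audit on real spots", {
  sp <- generate_spot(spot_config(
    1550, tibble::tibble(pattern = c("G3", "G4", "Benign"),
                         area_fraction = c(0.4, 0.3, 0.2)),
    texture = texture_params(0.5), seed = 12))
  sp$spot_id <- "audit"
  g <- half_geom()
  p1 <- extract_patches(sp, g)
  off <- (g$patch_size - g$label_window) %/% 2
  for (i in seq_len(nrow(p1))) {
    win <- sp$mask[(p1$row[i] + off + 1):(p1$row[i] + off + g$label_window),
                   (p1$col[i] + off + 1):(p1$col[i] + off + g$label_window)]
    lab <- unique(win[win > 0])
    expect_length(lab, 1)
    expect_equal(gleason_classes()[lab], as.character(p1$label[i]))
  }
  # deterministic: same inputs give the same list in the same order
  expect_identical(p1, extract_patches(sp, g))
})

test_that("augmentation is seeded, shape-stable and has a centre-crop fallback", {
  g <- half_geom()
  px <- array(runif(107 * 107 * 3), dim = c(107, 107, 3))
  a1 <- withr::with_seed(3, augment_patch(px, g))
  a2 <- withr::with_seed(3, augment_patch(px, g))
  expect_identical(a1, a2)
  expect_equal(dim(a1), c(96, 96, 3))
  expect_true(all(a1 >= 0 & a1 <= 1))

  ctr <- augment_patch(px, g, random = FALSE)
  o <- (107 - 96) %/% 2 + 1
  expect_equal(ctr, px[o:(o + 95), o:(o + 95), ])
})

test_that("balanced batches hold exactly batch_size/4 per class", {
  patches <- fake_patch_set(5)
  withr::with_seed(2, {
    b <- balanced_batches(patches, 32L, 3L)
    for (idx in b) {
      expect_length(idx, 32)
      expect_true(all(table(patches$label[idx]) == 8))
    }
    # a single patch per class is repeated by sampling with replacement
    single <- patches[!duplicated(patches$label), ]
    idx <- balanced_batches(single, 32L, 1L)[[1]]
    expect_true(all(table(single$label[idx]) == 8))
    # law of large numbers: marginal frequency 0.25 +/- 0.01
    many <- unlist(balanced_batches(patches, 32L, 2000L))
    freq <- table(patches$label[many]) / length(many)
    expect_true(all(abs(freq - 0.25) <= 0.01))
  })
  expect_error(balanced_batches(patches, 30L), "divisible")
  expect_error(balanced_batches(patches[patches$label != "G5", ], 32L),
               "G5")
})
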