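test_that("generated spots honour the requested regions and encoding", {
  cfg <- spot_config(512, tibble::tibble(pattern = "G3", area_fraction = 0.3),
                     texture = texture_params(512 / 3100), seed = 5)
  sp <- generate_spot(cfg)
  expect_true(all(unique(as.vector(sp$mask)) %in% c(0L, 2L)))

  # realized area fraction of the tissue disc within 0.3 +/- 0.1
  cx <- (512 + 1) / 2
  disc <- outer((1:512 - cx)^2, (1:512 - cx)^2, "+") <= (0.47 * 512)^2
  expect_equal(sum(sp$mask == 2) / sum(disc), 0.3, tolerance = 0.1 / 0.3)

  # bit-identical under the same seed
  sp2 <- generate_spot(cfg)
  expect_identical(sp$image, sp2$image)
  expect_identical(sp$mask, sp2$mask)

  expect_error(
    spot_config(512, tibble::tibble(pattern = c("G3", "G4"),
                                    area_fraction = c(0.7, 0.6))),
    "sum")
})

test_that("one-hot probability maps implement label smoothing exactly", {
  mask <- matrix(0L, 8, 8)
  mask[2:5, 2:5] <- 3L  # G4
  mask[6, 6] <- 1L      # Benign
  pm0 <- one_hot_probability_map(mask, 0)
  expect_equal(pm0$p[3, 3, ], c(0, 0, 1, 0))
  pm <- one_hot_probability_map(mask, 0.3)
  expect_equal(pm$p[3, 3, ], c(0.1, 0.1, 0.7, 0.1))
  expect_equal(pm$p[6, 6, ], c(0.7, 0.1, 0.1, 0.1))
  sums <- apply(pm$p, c(1, 2), sum)
  expect_true(all(abs(sums[mask > 0] - 1) < 1e-9))
  expect_true(all(sums[mask == 0] == 0))
  expect_error(one_hot_probability_map(mask, 1), "smoothing")
})

test_that("cohorts are reproducible with valid clinical linkage", {
  expect_error(generate_cohort(0), "at least 1")
  co <- generate_cohort(6, spot_size_px = 256, seed = 7, keep_images = FALSE)
  expect_s3_class(co$clinical, "tbl_df")
  expect_setequal(co$clinical$spot_id, names(co$spots))
  expect_true(all(co$clinical$time_months > 0))
  expect_true(all(co$clinical$event %in% 0:1))
  co2 <- generate_cohort(6, spot_size_px = 256, seed = 7,
                         keep_images = FALSE)
  expect_identical(lapply(co$spots, `[[`, "mask"),
                   lapply(co2$spots, `[[`, "mask"))
  expect_identical(co$clinical, co2$clinical)

  # every drawn score is realized by its mask under the scoring rule
  realized <- vapply(co$spots,
                     function(s) gleasonet:::mask_score(s$mask), 0L)
  expect_equal(unname(realized), co$clinical$true_score)
})

test_that("pattern cohorts represent every requested class", {
  co <- generate_pattern_cohort(6, spot_size_px = 256, seed = 3,
                                keep_images = FALSE)
  pat <- vapply(co$spots, function(s) {
    codes <- setdiff(unique(as.vector(s$mask)), 0L)
    expect_length(codes, 1L)
    codes
  }, 0L)
  expect_setequal(pat, 1:4)
  expect_true(all(co$clinical$true_score %in% c(0L, 6L, 8L, 10L)))
})

test_that("the four patterns have separable texture statistics", {
  # 20 single-texture patches per class; features: lumen count, mean lumen
  # area, dark (epithelial/nuclear) fraction
  feats <- purrr::map_dfr(gleason_classes(), function(pat) {
    co <- generate_pattern_cohort(
      1, pattern_mix = setNames(1, pat), spot_size_px = 700,
      seed = 31 + match(pat, gleason_classes()))
    sp <- co$spots[[1]]
    cx <- 350
    withr::with_seed(77, {
      purrr::map_dfr(1:20, function(i) {
        r0 <- sample(180:360, 1); c0 <- sample(180:360, 1)
        px <- sp$image[r0:(r0 + 127), c0:(c0 + 127), ]
        gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
        lum <- EBImage::bwlabel(gray > 0.9)
        sizes <- table(lum[lum > 0])
        sizes <- sizes[sizes >= 4]
        tibble::tibble(pattern = pat, n_lumen = length(sizes),
                       lumen_area = if (length(sizes)) mean(sizes) else 0,
                       dark_frac = mean(gray < 0.55))
      })
    })
  })
  welch_t <- function(x, y) {
    abs(mean(x) - mean(y)) /
      sqrt(var(x) / length(x) + var(y) / length(y) + 1e-12)
  }
  pairs <- utils::combn(gleason_classes(), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- feats[feats$pattern == pairs[1, k], ]
    b <- feats[feats$pattern == pairs[2, k], ]
    tmax <- max(welch_t(a$n_lumen, b$n_lumen),
                welch_t(a$lumen_area, b$lumen_area),
                welch_t(a$dark_frac, b$dark_frac))
    expect_gt(tmax, 4)
  }
})

test_that("survival generator orders hazards by risk tier", {
  # strong hazard ordering: low-vs-high logrank significant in >= 9/10 seeds
  hits <- sum(vapply(1:10, function(s) {
    cl <- simulate_clinical(200, hazard = hazard_params(ratio = 3),
                            seed = 900 + s)
    rep <- stratification_report(
      tibble::tibble(spot_id = cl$spot_id, score = cl$true_score), cl)
    p <- rep$tests$p_adjusted[rep$tests$group_a == "low" &
                                rep$tests$group_b == "high"]
    isTRUE(p < 0.05)
  }, TRUE))
  expect_gte(hits, 9)

  # degenerate benign-only mix is still a valid cohort (possibly no events)
  cl <- simulate_clinical(20, score_mix = c(Benign = 1), seed = 2)
  expect_true(all(cl$true_score == 0))
  expect_true(all(cl$time_months > 0))
})

test_that("cohorts round-trip through the PNG/CSV interchange format", {
  co <- generate_cohort(3, spot_size_px = 256, seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  back <- read_cohort(dir)
  expect_equal(back$clinical$true_score, co$clinical$true_score)
  expect_identical(back$spots[[1]]$mask, co$spots[[1]]$mask)
  expect_equal(back$spots[[1]]$image, co$spots[[1]]$image,
               tolerance = 1 / 254)
})
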