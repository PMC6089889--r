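test_that("the converted annotator reproduces patch predictions exactly", {
  model <- build_network(network_config(alpha = 0.25, input_size = 96),
                         seed = 11)
  ann <- convert_to_fcn(model)
  withr::with_seed(12, {
    errs <- vapply(1:10, function(i) {
      x <- array(runif(96 * 96 * 3), dim = c(96, 96, 3))
      grid <- fcn_patch_probs(ann, x)
      ctr <- (dim(grid)[1] - 1L) %/% 2L + 1L
      max(abs(grid[ctr, ctr, ] - predict_patch(model, x)))
    }, 0)
  })
  expect_lt(max(errs), 1e-4)
  # four channels, simplex at every location
  x <- array(runif(160 * 128 * 3), dim = c(160, 128, 3))
  cells <- fcn_cell_probs(ann, x, tile_cells = Inf)
  expect_equal(dim(cells), c(5, 4, 4))
  expect_equal(apply(cells, c(1, 2), sum),
               matrix(1, 5, 4), tolerance = 1e-5)
})

test_that("halo tiling is seamless", {
  model <- build_network(network_config(alpha = 0.25, input_size = 96),
                         seed = 13)
  ann <- convert_to_fcn(model)
  img <- withr::with_seed(14,
    array(runif(512 * 512 * 3), dim = c(512, 512, 3)))
  untiled <- fcn_cell_probs(ann, img, tile_cells = Inf)
  tiled <- fcn_cell_probs(ann, img, tile_cells = 5L)
  expect_lt(max(abs(untiled - tiled)), 1e-4)
})

test_that("shifting the input by 32 px shifts the cell grid by one", {
  model <- build_network(network_config(alpha = 0.25, input_size = 96),
                         seed = 15)
  ann <- convert_to_fcn(model)
  n <- 1024  # 32 cells: leaves an interior beyond halo + pooling reach
  base <- array(0.9, dim = c(n, n, 3))
  img1 <- base; img1[, 417:512, 1] <- 0.2
  img2 <- base; img2[, 449:544, 1] <- 0.2
  c1 <- fcn_cell_probs(ann, img1, tile_cells = Inf)
  c2 <- fcn_cell_probs(ann, img2, tile_cells = Inf)
  inner <- 10:22
  expect_equal(c1[inner, 10:20, ], c2[inner, 11:21, ], tolerance = 1e-5)
})

test_that("probability maps conserve the simplex and respect the mask", {
  model <- build_network(network_config(alpha = 0.25, input_size = 96),
                         seed = 16)
  ann <- convert_to_fcn(model)
  sp <- generate_spot(spot_config(384, texture = texture_params(384 / 3100),
                                  seed = 17))
  tissue <- sp$mask > 0
  pm <- probability_map(ann, sp$image, tissue, spot_id = "s")
  expect_equal(dim(pm$p)[1:2], dim(sp$mask))
  sums <- apply(pm$p, c(1, 2), sum)
  expect_true(all(abs(sums[tissue] - 1) < 1e-5))
  expect_true(all(sums[!tissue] == 0))
  expect_equal(attr(pm, "border_px"), 48)

  # empty tissue mask -> zero map with a warning
  expect_warning(
    pm0 <- probability_map(ann, sp$image, matrix(FALSE, 384, 384)),
    "empty")
  expect_true(all(pm0$p == 0))
})

test_that("a desk-scale model annotates tissue pixels accurately", {
  fx <- desk_model_fixture()
  ann <- convert_to_fcn(fx$model)
  co <- generate_cohort(2, spot_size_px = 1550, seed = 531)
  accs <- vapply(co$spots, function(sp) {
    tissue <- detect_tissue(sp$image, tissue_mask_params(2, 5))
    pm <- probability_map(ann, sp$image, tissue,
                          scale = training_scale(fx$geom),
                          spot_id = sp$spot_id)
    am <- apply(pm$p, c(1, 2), which.max)
    sel <- sp$mask > 0 & tissue
    mean(am[sel] == sp$mask[sel])
  }, 0)
  expect_gt(mean(accs), 0.8)
})
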