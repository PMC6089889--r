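test_that("confusion matrices count and normalize per truth row", {
  cm <- confusion_matrix(c("G3", "G4"), c("G3", "G4"))
  expect_equal(diag(cm$counts), c(Benign = 0, G3 = 1, G4 = 1, G5 = 0))

  cm2 <- confusion_matrix(c("G3", "G3", "G4"), c("G3", "G4", "G4"),
                          c("G3", "G4"))
  expect_equal(unname(cm2$counts), rbind(c(1, 1), c(0, 1)))
  expect_equal(unname(cm2$normalized), rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(sum(cm2$counts), 3)

  expect_error(confusion_matrix("G3", "G6", c("G3", "G4")), "G6")
})

test_that("quadratic kappa matches a brute-force evaluation of the formula", {
  # perfect agreement and independence anchors
  expect_equal(quadratic_kappa(diag(c(3, 1, 4, 1))), 1)
  O_ind <- outer(c(2, 5, 3, 7), c(4, 1, 6, 2))
  expect_equal(quadratic_kappa(O_ind), 0, tolerance = 1e-12)

  withr::with_seed(33, {
    for (i in 1:100) {
      O <- matrix(rpois(16, 4), 4, 4)
      if (sum(O) == 0) next
      k <- tryCatch(quadratic_kappa(O), error = function(e) NA)
      kb <- tryCatch(kappa_brute_force(O), error = function(e) NA)
      if (is.na(k) || is.na(kb)) next
      expect_lt(abs(k - kb), 1e-12)
      # symmetry and scaling invariance
      expect_lt(abs(quadratic_kappa(t(O)) - k), 1e-12)
      expect_lt(abs(quadratic_kappa(3 * O) - k), 1e-12)
    }
  })
  # degenerate marginals: everything in one category
  O_deg <- matrix(0, 3, 3); O_deg[2, 2] <- 5
  expect_error(quadratic_kappa(O_deg), "degenerate")
})

test_that("macro recall averages over classes present in the truth", {
  expect_equal(macro_recall(diag(c(2, 3, 4))), 1)
  expect_equal(macro_recall(rbind(c(9, 1), c(5, 5))), 0.7)
  # absent class excluded from the mean
  O <- rbind(c(8, 2, 0), c(0, 0, 0), c(1, 0, 9))
  expect_equal(macro_recall(O), mean(c(0.8, 0.9)))
  expect_error(macro_recall(matrix(0, 2, 2)), "class")
})

test_that("the common-subset rule keeps doubly annotated items", {
  a <- tibble::tibble(id = 1:5, label = c("G3", "G4", NA, "G5", "G3"))
  b <- tibble::tibble(id = c(1:2, 4:6), label = c("G3", NA, "G4", "G5",
                                                  "G3"))
  p <- tibble::tibble(id = 1:6, label = "G3")
  cs <- common_subset(a, b, p)
  expect_equal(cs$id, c(1, 4, 5))

  expect_warning(
    empty <- common_subset(tibble::tibble(id = 1, label = "G3"),
                           tibble::tibble(id = 2, label = "G3"), p),
    "both raters")
  expect_equal(nrow(empty), 0)

  same <- common_subset(a[1:2, ], a[1:2, ], p)
  expect_equal(nrow(same), 2)
})

test_that("consensus precision accepts either rater's label", {
  pr <- consensus_precision(c("G5", "Benign", "G3"),
                            c("G4", "G3", "G3"),
                            c("G5", "G4", "G4"))
  expect_equal(pr$precision[pr$class == "G5"], 1)      # one rater matches
  expect_equal(pr$precision[pr$class == "Benign"], 0)  # neither matches
  expect_equal(pr$precision[pr$class == "G3"], 1)
  expect_false("G4" %in% pr$class)                     # never predicted

  all_ok <- consensus_precision(c("G3", "G4"), c("G3", "G4"), c("G3", "G3"))
  expect_true(all(all_ok$precision == 1))
})

test_that("the spot-level agreement pipeline gives kappa 1 on itself", {
  co <- generate_cohort(8, spot_size_px = 256, seed = 41,
                        keep_images = FALSE)
  maps <- lapply(co$spots, function(s)
    one_hot_probability_map(s$mask, 0, s$spot_id))
  sc <- score_cohort(maps)
  lev <- c("Benign", "6", "7", "8", "9", "10")
  lab <- function(s) ifelse(s == 0, "Benign", as.character(s))
  agr <- rater_agreement(lab(co$clinical$true_score), lab(sc$score), lev)
  expect_equal(agr$kappa, 1)
  expect_equal(glance(agr)$macro_recall, 1)
  expect_equal(sum(tidy(agr)$n), nrow(sc))
})
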