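test_that("risk groups follow the Gleason cut-points", {
  expect_equal(as.character(risk_group(c(0, 6, 7, 8, 9, 10))),
               c("low", "low", "intermediate", "high", "high", "high"))
  expect_equal(as.character(risk_group("Benign")), "low")
})

test_that("the product-limit estimator matches hand arithmetic", {
  # times 1 (event), 2 (censored), 3 (event): S = 2/3 on [1, 3), 0 at 3
  km <- kaplan_meier(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$ci_lower <= km$survival + 1e-12 &
                    km$survival <= km$ci_upper + 1e-12))

  # no events: flat at 1
  flat <- kaplan_meier(data.frame(time = c(2, 4, 9), event = c(0, 0, 0)))
  expect_true(all(flat$survival == 1))

  # duplicating every record leaves the curve unchanged
  rec <- data.frame(time = c(2, 3, 5, 7), event = c(1, 0, 1, 1))
  k1 <- kaplan_meier(rec)
  k2 <- kaplan_meier(rbind(rec, rec))
  expect_equal(k2$survival, k1$survival)

  # without censoring the estimate is the empirical survival function
  tt <- c(1, 2, 4, 6, 9)
  k3 <- kaplan_meier(data.frame(time = tt, event = 1))
  expect_equal(k3$survival, 1 - seq_along(tt) / length(tt))
})

test_that("the logrank statistic matches a hand O-E computation", {
  a <- data.frame(time = c(1, 3), event = c(1, 1))
  b <- data.frame(time = c(2, 4), event = c(1, 0))
  # by hand: O_A = 2; E_A = 1/2 + 1/3 + 1/2 = 4/3;
  # V = 1/4 + 2/9 + 1/4 = 13/18; chi-square = (2 - 4/3)^2 / (13/18)
  expect_equal(logrank_test(a, b)$statistic,
               (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-10)

  # identical groups: statistic 0, p-value 1
  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  expect_error(
    logrank_test(data.frame(time = 1, event = 0),
                 data.frame(time = 2, event = 0)),
    "no events")
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(8, {
    p <- runif(20)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone in the ranked order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  })
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("stratification reports join, test and flag empty comparisons", {
  cl <- simulate_clinical(120, hazard = hazard_params(ratio = 3),
                          seed = 71)
  scores <- tibble::tibble(spot_id = cl$spot_id, score = cl$true_score)
  rep <- stratification_report(scores, cl)
  expect_equal(nrow(rep$records), 120)
  expect_equal(sum(rep$group_counts), 120)
  expect_equal(nrow(rep$tests), 3)
  expect_true(all(rep$tests$available))
  expect_true(all(rep$tests$p_adjusted >= rep$tests$p_value - 1e-15,
                  na.rm = TRUE))

  # an empty group is reported as unavailable, not an error
  cl2 <- cl[risk_group(cl$true_score) != "high", ]
  rep2 <- stratification_report(
    tibble::tibble(spot_id = cl2$spot_id, score = cl2$true_score), cl2)
  expect_false(all(rep2$tests$available))
  expect_true(any(rep2$tests$available))
})
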