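#' Risk group of a composite Gleason score
#'
#' Low risk: Gleason score <= 6 (benign spots, encoded 0 or `"Benign"`, are
#' grouped with low risk); intermediate: score 7; high: score >= 8.
#'
#' @param score Numeric scores (0 = benign) or character with `"Benign"`.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
risk_group <- function(score) {
  if (is.character(score))
    score <- ifelse(score == "Benign", 0, suppressWarnings(as.numeric(score)))
  if (any(is.na(score))) abort("scores contain missing values")
  g <- ifelse(score <= 6, "low", ifelse(score == 7, "intermediate", "high"))
  factor(g, levels = c("low", "intermediate", "high"))
}

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with Greenwood variance and log-transformed 95%
#' confidence bands (censored subjects at a tied time are counted as still
#' at risk at that time).
#'
#' @param records Data frame with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored).
#' @return Tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `ci_lower`, `ci_upper`.
#' @export
kaplan_meier <- function(records) {
  records <- as.data.frame(records)
  stopifnot(nrow(records) >= 1, all(records$time > 0),
            all(records$event %in% 0:1))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log")
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv,
                        ci_lower = ifelse(is.na(fit$lower), 0, fit$lower),
                        ci_upper = ifelse(is.na(fit$upper), 1, fit$upper))
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-sample logrank test
#'
#' Standard two-sided logrank chi-square statistic with one degree of
#' freedom; the p-value is the upper chi-square tail.
#'
#' @param records_a,records_b Data frames with `time` and `event` columns.
#' @return One-row tibble: `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(records_a, records_b) {
  if (nrow(records_a) == 0 || nrow(records_b) == 0)
    abort("both groups must be non-empty")
  df <- rbind(
    data.frame(time = records_a$time, event = records_a$event, g = "a"),
    data.frame(time = records_b$time, event = records_b$event, g = "b"))
  if (sum(df$event) == 0)
    abort("no events in either group: logrank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  tibble::tibble(statistic = unname(sd$chisq),
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n_a = nrow(records_a), n_b = nrow(records_b))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Survival stratification report for scored spots
#'
#' Joins score assignments to clinical records, splits the cohort into the
#' three Gleason risk groups, computes a Kaplan-Meier curve per group and
#' all pairwise two-tailed logrank tests with Benjamini-Hochberg correction
#' across the three comparisons. Comparisons involving an empty group (or
#' with no events) are reported as unavailable.
#'
#' @param scores Tibble with `spot_id` and `score` (0 = benign), e.g. from
#'   [score_cohort()].
#' @param clinical Tibble with `spot_id`, `time_months`, `event`.
#' @return Object of class `stratification_report`: list with `records`
#'   (joined rows with `group`), `curves` (per-group `km_curve` rows),
#'   `tests` (pairwise tibble with raw and BH-adjusted p-values),
#'   `group_counts`.
#' @export
stratification_report <- function(scores, clinical) {
  scores <- tibble::as_tibble(scores)[, c("spot_id", "score")]
  clinical <- tibble::as_tibble(clinical)[, c("spot_id", "time_months",
                                              "event")]
  rec <- dplyr::inner_join(scores, clinical, by = "spot_id")
  if (nrow(rec) == 0) abort("no spots join between scores and clinical")
  rec$group <- risk_group(rec$score)
  rec <- dplyr::rename(rec, time = "time_months")
  curves <- purrr::map_dfr(levels(rec$group), function(g) {
    sub <- rec[rec$group == g, ]
    if (nrow(sub) == 0) return(NULL)
    dplyr::mutate(kaplan_meier(sub), group = g, .before = 1)
  })
  pairs <- list(c("low", "intermediate"), c("low", "high"),
                c("intermediate", "high"))
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- rec[rec$group == pr[1], ]; b <- rec[rec$group == pr[2], ]
    res <- tryCatch(logrank_test(a, b), error = function(e) NULL)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = if (is.null(res)) NA_real_ else res$statistic,
                   p_value = if (is.null(res)) NA_real_ else res$p_value,
                   available = !is.null(res))
  })
  ok <- !is.na(tests$p_value)
  tests$p_adjusted <- NA_real_
  if (any(ok)) tests$p_adjusted[ok] <- bh_adjust(tests$p_value[ok])
  structure(list(records = rec, curves = curves, tests = tests,
                 group_counts = table(rec$group)),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("<stratification_report> %d spots (low %d / intermediate %d / high %d)\n",
              nrow(x$records), x$group_counts["low"],
              x$group_counts["intermediate"], x$group_counts["high"]))
  print(as.data.frame(x$tests))
  invisible(x)
}

#' Tidy the pairwise logrank tests of a stratification report
#' @param x A `stratification_report`.
#' @param ... Unused.
#' @return The `tests` tibble.
#' @export
tidy.stratification_report <- function(x, ...) x$tests

#' Kaplan-Meier plot of the three risk groups
#'
#' Step curves with shaded 95% confidence bands and BH-adjusted pairwise
#' logrank p-values in the subtitle.
#'
#' @param object A `stratification_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stratification_report <- function(object, ...) {
  cv <- dplyr::group_modify(
    dplyr::group_by(object$curves, .data$group),
    ~dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1, ci_lower = 1, ci_upper = 1),
      .x[, c("time", "survival", "ci_lower", "ci_upper")]))
  lab <- paste(sprintf("%s vs %s: p = %.3g", object$tests$group_a,
                       object$tests$group_b, object$tests$p_adjusted),
               collapse = "; ")
  ggplot2::ggplot(cv, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "disease-specific survival",
                  subtitle = lab)
}
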