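# Longitudinal cohort statistics: logMAR conversion, timepoint t-tests,
# multiple regression of 12-month visual acuity on baseline markers.

#' Convert raw visual acuity records to logMAR
#'
#' Decimal Snellen acuity v maps to -log10(v); the qualitative categories
#' "counting fingers" and "hand movement" map to the established constants
#' 1.98 and 2.28 logMAR. Unrecognized categories raise an error naming the
#' offending value - there is no silent default.
#'
#' @param raw Numeric vector of decimal acuities, or character vector mixing
#'   decimal values and the categories (case-insensitive; "CF"/"HM"
#'   abbreviations accepted).
#' @return Numeric vector of logMAR values.
#' @examples
#' va_to_logmar(c("counting fingers", "1.0", "hand movement"))
#' @export
va_to_logmar <- function(raw) {
  if (is.numeric(raw)) {
    .check(all(raw > 0), "decimal acuity must be positive")
    return(-log10(raw))
  }
  key <- tolower(trimws(raw))
  out <- numeric(length(raw))
  cf <- key %in% c("counting fingers", "cf")
  hm <- key %in% c("hand movement", "hm")
  out[cf] <- 1.98
  out[hm] <- 2.28
  rest <- !(cf | hm)
  if (any(rest)) {
    v <- suppressWarnings(as.numeric(key[rest]))
    bad <- is.na(v) | v <= 0
    .check(!any(bad), "unrecognized visual acuity record(s): %s",
           paste(unique(raw[rest][bad]), collapse = ", "))
    out[rest] <- -log10(v)
  }
  out
}

#' Independent-samples t-tests between timepoints
#'
#' Two-sided independent-samples t-test for each marker and each month pair,
#' with no multiplicity correction (a Bonferroni flag is available but
#' defaults off). Welch's unequal-variance form is the default; the pooled
#' form is available via `var_equal = TRUE`.
#'
#' @param cohort Cohort table as returned by [simulate_cohort()]: columns
#'   `eye_id`, `month`, marker columns.
#' @param markers Marker columns to test (default [cohort_markers()]
#'   intersected with the table).
#' @param pairs List of month pairs (default (0,3), (0,12), (3,12)).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param bonferroni Apply Bonferroni correction across all tests.
#' @return A `data.frame` (class `ttest_results`): marker, month pair,
#'   group means/SDs/sizes, `t`, `p`, `significant`.
#' @export
timepoint_ttests <- function(cohort, markers = NULL,
                             pairs = list(c(0, 3), c(0, 12), c(3, 12)),
                             alpha = 0.05, var_equal = FALSE,
                             bonferroni = FALSE) {
  if (is.null(markers)) markers <- intersect(cohort_markers(), names(cohort))
  .check(length(markers) >= 1, "no marker columns to test")
  out <- list()
  for (mk in markers) for (pr in pairs) {
    g1 <- cohort[[mk]][cohort$month == pr[1]]
    g2 <- cohort[[mk]][cohort$month == pr[2]]
    .check(length(g1) >= 2 && length(g2) >= 2,
           "need >= 2 observations per group (%s, months %s-%s)",
           mk, pr[1], pr[2])
    if (stats::sd(g1) == 0 && stats::sd(g2) == 0) {
      tt <- list(statistic = 0, p.value = 1)  # degenerate: constant groups
    } else {
      tt <- stats::t.test(g1, g2, var.equal = var_equal)
    }
    out[[length(out) + 1]] <- data.frame(
      marker = mk, month1 = pr[1], month2 = pr[2],
      mean1 = mean(g1), mean2 = mean(g2),
      sd1 = stats::sd(g1), sd2 = stats::sd(g2),
      n1 = length(g1), n2 = length(g2),
      t = unname(tt$statistic), p = unname(tt$p.value),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (bonferroni) res$p <- pmin(res$p * nrow(res), 1)
  res$significant <- res$p < alpha
  class(res) <- c("ttest_results", "data.frame")
  res
}

#' Multiple regression of 12-month visual acuity on baseline markers
#'
#' Ordinary least squares of month-12 logMAR VA on the 11 baseline (month-0)
#' markers with intercept. The CRT predictor enters per millimetre so its
#' coefficient is on a scale commensurate with the volumetric markers.
#'
#' @param cohort Cohort table with columns `eye_id`, `month`, `va_logmar`
#'   and the marker columns.
#' @param markers Predictor columns (default [cohort_markers()]).
#' @return An object of class `regression_result`: `coefficients`
#'   (data.frame term/b/se/t/p including the intercept row), `adj_r_squared`,
#'   `r_squared`, `f_statistic`, `n`, and the underlying `lm` fit.
#' @export
fit_va_regression <- function(cohort, markers = cohort_markers()) {
  .check(all(markers %in% names(cohort)), "missing marker column(s): %s",
         paste(setdiff(markers, names(cohort)), collapse = ", "))
  base <- cohort[cohort$month == 0, c("eye_id", markers)]
  out12 <- cohort[cohort$month == 12, c("eye_id", "va_logmar")]
  d <- merge(base, out12, by = "eye_id")
  d <- d[stats::complete.cases(d), ]
  .check(nrow(d) >= length(markers) + 2,
         "need at least %d complete-case rows, have %d", length(markers) + 2, nrow(d))
  X <- d[, markers, drop = FALSE]
  if ("CRT" %in% markers) X$CRT <- X$CRT / 1000  # per mm
  fit <- stats::lm(d$va_logmar ~ ., data = X)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- sub("^\\(Intercept\\)$", "intercept", rownames(co))
  structure(list(
    coefficients = data.frame(term = terms, b = co[, 1], se = co[, 2],
                              t = co[, 3], p = co[, 4], row.names = NULL,
                              stringsAsFactors = FALSE),
    adj_r_squared = sm$adj.r.squared,
    r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic[1]),
    n = nrow(d), fit = fit),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS of 12-month VA on baseline markers (n = %d)\n", x$n))
  print(transform(x$coefficients, b = round(b, 3), se = round(se, 3),
                  t = round(t, 2), p = round(p, 4)))
  cat(sprintf("adj. R^2 = %.3f,  F = %.2f\n", x$adj_r_squared, x$f_statistic))
  invisible(x)
}

#' Summary table of marker means, SDs and pairwise p-values
#'
#' Mirrors the layout of a longitudinal biomarker table: one column per
#' marker; rows are the means and SDs at months 0, 3 and 12 followed by the
#' pairwise t-test p-values (0-3, 0-12, 3-12). Fixed row order:
#' `mean_0, mean_3, mean_12, sd_0, sd_3, sd_12, p_0_3, p_0_12, p_3_12`.
#'
#' @inheritParams timepoint_ttests
#' @return A `data.frame` with the 9 rows above and one column per marker.
#' @export
summary_table <- function(cohort, markers = NULL, alpha = 0.05,
                          var_equal = FALSE) {
  if (is.null(markers)) markers <- intersect(cohort_markers(), names(cohort))
  tt <- timepoint_ttests(cohort, markers, alpha = alpha, var_equal = var_equal)
  rows <- c("mean_0", "mean_3", "mean_12", "sd_0", "sd_3", "sd_12",
            "p_0_3", "p_0_12", "p_3_12")
  out <- matrix(NA_real_, length(rows), length(markers),
                dimnames = list(rows, markers))
  for (mk in markers) {
    for (m in c(0, 3, 12)) {
      v <- cohort[[mk]][cohort$month == m]
      out[paste0("mean_", m), mk] <- mean(v)
      out[paste0("sd_", m), mk] <- stats::sd(v)
    }
    sub <- tt[tt$marker == mk, ]
    out["p_0_3", mk] <- sub$p[sub$month1 == 0 & sub$month2 == 3]
    out["p_0_12", mk] <- sub$p[sub$month1 == 0 & sub$month2 == 12]
    out["p_3_12", mk] <- sub$p[sub$month1 == 3 & sub$month2 == 12]
  }
  as.data.frame(out)
}

#' Write a summary table to CSV
#'
#' @param x A `summary_table()` result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(cbind(statistic = rownames(x), x), path, row.names = FALSE)
  invisible(path)
}
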