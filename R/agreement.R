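#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' mean squares of the subjects-by-raters ANOVA:
#' \deqn{\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with `k = 2` raters (reference and test). Absolute agreement penalizes
#' systematic offsets, which is the property wanted for method comparison.
#'
#' @param reference,test Paired measurements (equal length, n >= 2, finite).
#' @return The ICC estimate; `NA` when the total variance is zero.
#' @export
#' @examples
#' icc(1:10, 1:10)        # 1
#' icc(1:10, 1:10 + 5)    # < cor(1:10, 1:10 + 5)
icc <- function(reference, test) {
  n <- length(reference)
  if (length(test) != n) abort("`reference` and `test` must be paired")
  if (n < 2L) abort("ICC needs at least 2 paired observations")
  if (!all(is.finite(reference)) || !all(is.finite(test))) {
    abort("ICC inputs must be finite")
  }
  k <- 2L
  d <- data.frame(
    y = c(reference, test),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  if (stats::var(d$y) == 0) return(NA_real_)
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1L]][["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Median and SD of paired differences, with Bland-Altman pairs
#'
#' Differences are `test - reference`; the median is reported because
#' ischemic-volume differences are typically non-Gaussian.
#'
#' @param reference,test Paired measurements.
#' @return A one-row tibble: `n`, `median_diff`, `sd_diff`.
#' @seealso [bland_altman()] for the per-case pairs.
#' @export
difference_stats <- function(reference, test) {
  if (length(reference) != length(test)) abort("inputs must be paired")
  d <- test - reference
  tibble::tibble(
    n = length(d),
    median_diff = stats::median(d),
    sd_diff = stats::sd(d)
  )
}

#' Bland-Altman pairs
#'
#' @param reference,test Paired measurements.
#' @return A tibble with `mean` (`(test + reference) / 2`) and `difference`
#'   (`test - reference`).
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test)) abort("inputs must be paired")
  tibble::tibble(mean = (test + reference) / 2, difference = test - reference)
}

#' Cohort-level agreement between reference and reduced samplings
#'
#' For each metric, subsampling factor and scan-quality stratum, pairs the
#' factor-1 (reference) values with the reduced-sampling values case by case
#' and reports ICC(2,1), the median and SD of the differences, and `n`.
#' Mismatch-ratio rows are restricted to cases whose core volume exceeds
#' 3 mL at both the reference and the test sampling. Stratification uses the
#' reference-sampling quality class. Strata with fewer than 2 cases are
#' skipped with a warning.
#'
#' @param results A long tibble with columns `case_id`, `factor`,
#'   `quality_class` (at the reference sampling), `ratio_evaluable` and the
#'   metric columns.
#' @param metrics Metric column names to analyze.
#' @param by_quality Stratify by reference quality class (default); if
#'   `FALSE` a single `"all"` stratum is used.
#' @return A tibble: `stratum`, `metric`, `factor`, `n`, `icc`,
#'   `median_diff`, `sd_diff`.
#' @export
cohort_agreement <- function(results,
                             metrics = c("core_ml", "hypoperfusion_ml",
                                         "mismatch_ml", "mismatch_ratio"),
                             by_quality = TRUE) {
  ref <- dplyr::filter(results, .data$factor == 1L)
  strata <- if (by_quality) unique(ref$quality_class) else "all"
  test_factors <- sort(setdiff(unique(results$factor), 1L))
  out <- list()
  for (st in strata) {
    ids <- if (by_quality) ref$case_id[ref$quality_class == st] else ref$case_id
    for (metric in metrics) {
      for (f in test_factors) {
        r <- ref[match(ids, ref$case_id), ]
        t_ <- dplyr::filter(results, .data$factor == f, .data$case_id %in% ids)
        t_ <- t_[match(ids, t_$case_id), ]
        keep <- is.finite(r[[metric]]) & is.finite(t_[[metric]])
        if (metric == "mismatch_ratio") {
          keep <- keep & r$ratio_evaluable & t_$ratio_evaluable
        }
        if (sum(keep) < 2L) {
          warn(sprintf("stratum '%s', metric '%s', factor %d: fewer than 2 cases, skipped",
                       st, metric, f))
          next
        }
        x <- r[[metric]][keep]
        y <- t_[[metric]][keep]
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(stratum = st, metric = metric, factor = f,
                         icc = icc(x, y)),
          difference_stats(x, y)
        )
      }
    }
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::relocate(dplyr::bind_rows(out), "stratum", "metric", "factor", "n")
}
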