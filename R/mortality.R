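# Mortality measures: relative monthly mortality (TMrel), strong-heat-
# related mortality (SHRM) and its reference ratio, plus an effect-recovery
# estimator used to validate the stage on synthetic data.

#' Relative monthly mortality
#'
#' A month's all-cause deaths as a percentage of the reference-period mean
#' for the same month: `TMrel = 100 * TMx / TMavg`.
#'
#' @param tmx Total deaths in the month under analysis.
#' @param tmavg Mean monthly deaths over the reference years (> 0).
#' @return TMrel in percent.
#' @examples
#' tm_rel(1100, 1000)  # 110
#' @export
tm_rel <- function(tmx, tmavg) {
  if (any(tmavg <= 0)) {
    stop_bioheat("'tmavg' must be > 0", class = "bioheat_input_error")
  }
  100 * tmx / tmavg
}

#' Strong-heat-related mortality
#'
#' Model-attributed monthly deaths due to strong heat:
#' `SHRM = 2.595 * PopRate * (SHS + VSHS)`, where `PopRate` is the city
#' population per 100,000 inhabitants and `SHS`/`VSHS` count the month's
#' days with strong and very strong heat stress. The 2.595 coefficient is
#' an adopted empirical constant; outputs are labelled model-attributed
#' deaths per month.
#'
#' @param pop_rate Population / 100,000.
#' @param shs_days,vshs_days Counts of strong / very strong heat-stress
#'   days in the month (>= 0).
#' @return Expected deaths attributable to strong heat.
#' @examples
#' shrm(8, 3, 2)  # 103.8
#' @export
shrm <- function(pop_rate, shs_days, vshs_days) {
  if (any(pop_rate < 0 | shs_days < 0 | vshs_days < 0)) {
    stop_bioheat("inputs must be >= 0", class = "bioheat_input_error")
  }
  2.595 * pop_rate * (shs_days + vshs_days)
}

#' SHRM relative to a reference period
#'
#' `SHRMrel = 100 * SHRM / mean reference SHRM`, in percent.
#'
#' @param shrm_value SHRM for the month under analysis.
#' @param reference_mean_shrm Mean SHRM over the reference years (> 0).
#' @return Percent of the reference mean.
#' @export
shrm_rel <- function(shrm_value, reference_mean_shrm) {
  if (any(reference_mean_shrm <= 0)) {
    stop_bioheat("'reference_mean_shrm' must be > 0",
                 class = "bioheat_input_error")
  }
  100 * shrm_value / reference_mean_shrm
}

#' Estimate the heat effect on daily mortality
#'
#' Ratio-of-means relative risk: mean daily deaths on strong-heat days
#' (SHS or VSHS) divided by mean daily deaths on all other days, with a
#' stratified percentile bootstrap interval (days resampled with
#' replacement within each stratum, so no resample loses a stratum).
#' Grouping of the non-stress stratum is irrelevant: any relabeling among
#' the non-heat categories leaves the estimate unchanged.
#'
#' @param daily_deaths Daily death counts.
#' @param daily_categories One thermal-stress category per day.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level of the percentile interval.
#' @param seed Optional integer seed for the bootstrap.
#' @return List: `rr` (point estimate), `ci` (length-2 vector),
#'   `n_stress`, `n_other`.
#' @export
estimate_heat_effect <- function(daily_deaths, daily_categories,
                                 n_boot = 1000L, conf = 0.95, seed = NULL) {
  if (length(daily_deaths) != length(daily_categories)) {
    stop_bioheat("'daily_deaths' and 'daily_categories' must align",
                 class = "bioheat_input_error")
  }
  stress <- as.character(daily_categories) %in% c("SHS", "VSHS")
  x <- daily_deaths[stress]
  y <- daily_deaths[!stress]
  if (length(x) == 0 || length(y) == 0) {
    stop_bioheat("need at least one strong-heat day and one other day",
                 class = "bioheat_input_error")
  }
  rr <- mean(x) / mean(y)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  boot <- vapply(seq_len(n_boot), function(i) {
    xb <- x[sample.int(length(x), replace = TRUE)]
    yb <- y[sample.int(length(y), replace = TRUE)]
    mean(xb) / mean(yb)
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf) / 2
  list(
    rr = rr,
    ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
    n_stress = length(x), n_other = length(y)
  )
}
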