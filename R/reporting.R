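# Reporting-scale transforms, multiple-testing correction, and power for
# binary outcomes.

#' Convert a log-odds estimate to an odds ratio with CI
#'
#' Exponentiates the estimate and any finite confidence bounds.
#' Non-finite Fieller set types (`"exclusive"`, `"whole_line"`,
#' `"half_line"`) are propagated as flags, with the excluded-interval
#' bounds exponentiated where finite.
#'
#' @param est an `mr_estimate` on the log-odds scale
#' @return list with `or`, `ci_low`, `ci_high`, `ci_type`, `pvalue`,
#'   `method`, `n_snps`
#' @export
to_odds_ratio <- function(est) {
  list(or = exp(est$estimate),
       ci_low = exp(est$ci_low), ci_high = exp(est$ci_high),
       ci_type = est$ci_type, pvalue = est$pvalue,
       method = est$method, n_snps = est$n_snps)
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise level by the number of comparisons, taken as
#' the number of outcome traits times the number of exposures.
#'
#' @param alpha family-wise level in (0,1)
#' @param n_traits number of outcome traits considered
#' @param n_exposures number of exposures
#' @return corrected per-test threshold
#' @export
bonferroni_threshold <- function(alpha, n_traits, n_exposures) {
  stopifnot(alpha > 0, alpha < 1, n_traits >= 1, n_exposures >= 1)
  alpha / (n_traits * n_exposures)
}

#' Construct a power-calculation configuration
#'
#' Describes a binary-outcome (case-control) MR design: total sample size,
#' case fraction, variance in the exposure explained by the instruments,
#' test level and target power.
#'
#' @param n_total total sample size (cases + controls)
#' @param n_cases number of cases (used to derive the case fraction;
#'   alternatively give `case_fraction` directly)
#' @param case_fraction proportion of cases K in (0,1)
#' @param r2 variance in the exposure explained by the instruments, (0,1)
#' @param alpha two-sided level; default 0.05
#' @param target_power default 0.8
#' @return list of class `mr_power_config`
#' @export
power_config <- function(n_total, n_cases = NULL, case_fraction = NULL,
                         r2, alpha = 0.05, target_power = 0.8) {
  if (is.null(case_fraction)) {
    stopifnot(!is.null(n_cases))
    case_fraction <- n_cases / n_total
  }
  stopifnot(n_total > 0, case_fraction > 0, case_fraction < 1,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  out <- list(n_total = n_total, case_fraction = case_fraction, r2 = r2,
              alpha = alpha, target_power = target_power)
  class(out) <- "mr_power_config"
  out
}

# non-centrality scale sqrt(N R2 K (1-K)) shared by power and detectable OR
.power_scale <- function(cfg) {
  sqrt(cfg$n_total * cfg$r2 * cfg$case_fraction * (1 - cfg$case_fraction))
}

#' Power to detect an odds ratio in a binary-outcome MR design
#'
#' Normal-approximation power for a two-sided Wald test of the log odds
#' ratio per SD of the exposure:
#' `power = Phi(|ln OR| sqrt(N R2 K(1-K)) - z_{1-alpha/2})`,
#' with K the case fraction (the negligible opposite-tail term is
#' omitted).
#'
#' @param cfg an `mr_power_config`
#' @param odds_ratio alternative OR per SD of exposure (> 0)
#' @return power in (0,1); vectorized over `odds_ratio`
#' @export
power_binary <- function(cfg, odds_ratio) {
  stopifnot(all(odds_ratio > 0))
  stats::pnorm(abs(log(odds_ratio)) * .power_scale(cfg) -
               stats::qnorm(1 - cfg$alpha / 2))
}

#' Minimal detectable odds ratio at the target power
#'
#' Inverts [power_binary()] at `cfg$target_power`:
#' `OR = exp((z_power + z_{1-alpha/2}) / sqrt(N R2 K(1-K)))`.
#'
#' @param cfg an `mr_power_config`
#' @return smallest OR > 1 detectable with the target power
#' @export
detectable_or <- function(cfg) {
  exp((stats::qnorm(cfg$target_power) + stats::qnorm(1 - cfg$alpha / 2)) /
      .power_scale(cfg))
}

#' Format a results table on the odds-ratio reporting scale
#'
#' Takes the per-method output of [estimate_all()] and adds OR columns
#' (exponentiated estimate and CI, 2 decimals by default) and the
#' Bonferroni verdict at a supplied corrected threshold.  Intercept rows
#' are reported on the original (log-odds) scale since the Egger intercept
#' is an average pleiotropic effect, not a causal OR.
#'
#' @param results data.frame from [estimate_all()]
#' @param bonferroni corrected threshold (e.g. from
#'   [bonferroni_threshold()]); NULL to omit the verdict
#' @param digits rounding for OR and CI; default 2
#' @return the input with columns `or`, `or_ci_low`, `or_ci_high` and
#'   optionally `bonferroni_significant`
#' @export
format_or_table <- function(results, bonferroni = NULL, digits = 2) {
  is_or <- results$method != "egger_intercept"
  results$or <- ifelse(is_or, round(exp(results$estimate), digits), NA)
  results$or_ci_low <- ifelse(is_or & results$ci_type == "finite",
                              round(exp(results$ci_low), digits), NA)
  results$or_ci_high <- ifelse(is_or & results$ci_type == "finite",
                               round(exp(results$ci_high), digits), NA)
  if (!is.null(bonferroni))
    results$bonferroni_significant <- results$pvalue < bonferroni
  results
}
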