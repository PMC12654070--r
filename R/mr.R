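#' Wald-ratio causal estimate for a single instrument
#'
#' With one instrument, the causal effect of a 1-SD higher exposure on the
#' outcome log-odds is estimated by the ratio of the per-allele
#' associations, `beta_mr = by / bx`. The default standard error is the
#' first-order delta approximation `se_y / |bx|`; the second-order form
#' `sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)` additionally propagates
#' exposure-side uncertainty and is never smaller than the first-order
#' value.
#'
#' @param bx,se_x Exposure-side per-allele effect (SD units) and its SE.
#' @param by,se_y Outcome-side per-allele effect (log-odds) and its SE.
#' @param se_method `"first_order"` (default) or `"second_order"`.
#' @return Tibble with `beta_mr`, `se_mr`, `se_method` (vectorized).
#' @export
#' @examples
#' wald_ratio(0.5, 0.05, 0.25, 0.1)
wald_ratio <- function(bx, se_x, by, se_y,
                       se_method = c("first_order", "second_order")) {
  se_method <- match.arg(se_method)
  if (any(is.na(bx)) || any(bx == 0)) {
    abort("exposure effect bx must be nonzero (undefined Wald ratio)")
  }
  if (any(se_y <= 0, na.rm = TRUE)) {
    abort("outcome standard errors must be positive")
  }
  beta_mr <- by / bx
  se_mr <- if (se_method == "first_order") {
    se_y / abs(bx)
  } else {
    sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  }
  tibble(beta_mr = beta_mr, se_mr = se_mr, se_method = se_method)
}

#' Odds ratio, confidence interval, and p-value from a log-odds estimate
#'
#' Exponentiates a Wald-ratio estimate for interpretability: the odds
#' ratio per 1-SD higher genetically predicted exposure, with a
#' normal-theory CI `exp(beta_mr +/- z * se_mr)` and a two-sided normal
#' p-value.
#'
#' @param beta_mr Log-odds estimate(s).
#' @param se_mr Standard error(s), positive.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `or`, `ci_low`, `ci_high`, `pval`.
#' @export
to_odds_ratio <- function(beta_mr, se_mr, level = 0.95) {
  if (any(se_mr <= 0, na.rm = TRUE)) {
    abort("se_mr must be positive")
  }
  z <- qnorm((1 + level) / 2)
  tibble(
    or = exp(beta_mr),
    ci_low = exp(beta_mr - z * se_mr),
    ci_high = exp(beta_mr + z * se_mr),
    pval = 2 * pnorm(-abs(beta_mr / se_mr))
  )
}

#' Multiplicity-control configuration
#'
#' Bonferroni control within an outcome family: the significance threshold
#' is `alpha / n_tests` (with 83 metabolites per outcome and alpha 0.05,
#' `6.02e-4`). Findings below it are `significant`; findings below `alpha`
#' but not the Bonferroni bar are `suggestive` (exploratory); the rest are
#' `null`.
#'
#' @param n_tests Number of tests in the family (metabolites actually
#'   tested for the outcome).
#' @param alpha Family-wise alpha (default 0.05), also the suggestive
#'   threshold.
#' @return A list of class `multiplicity_config` with `n_tests`, `alpha`,
#'   `bonferroni_threshold` (= `alpha / n_tests` exactly) and
#'   `suggestive_threshold`.
#' @export
#' @examples
#' multiplicity_config(83)$bonferroni_threshold  # 0.05 / 83
multiplicity_config <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) abort("n_tests must be at least 1")
  structure(
    list(n_tests = n_tests, alpha = alpha,
         bonferroni_threshold = alpha / n_tests,
         suggestive_threshold = alpha),
    class = "multiplicity_config"
  )
}

#' @export
print.multiplicity_config <- function(x, ...) {
  cat(sprintf("<multiplicity_config> %d tests, alpha %.3g, Bonferroni %.3g\n",
              x$n_tests, x$alpha, x$bonferroni_threshold))
  invisible(x)
}

#' Classify p-values into significance tiers
#'
#' @param pval Two-sided p-value(s) in (0, 1].
#' @param cfg A [multiplicity_config()].
#' @return Character vector: `"significant"`, `"suggestive"`, or
#'   `"null"`.
#' @export
classify_significance <- function(pval, cfg) {
  stopifnot(inherits(cfg, "multiplicity_config"))
  dplyr::case_when(
    pval < cfg$bonferroni_threshold ~ "significant",
    pval < cfg$suggestive_threshold ~ "suggestive",
    TRUE ~ "null"
  )
}

#' Internal-consistency diagnostics for a reported OR and CI
#'
#' A normal-theory CI is symmetric on the log scale, so a reported
#' (ci_low, ci_high) pair implies: OR = geometric mean `sqrt(lo * hi)`,
#' SE = `(log(hi) - log(lo)) / (2 z)`, and a two-sided p-value from the
#' implied z. Useful for checking published tables that print OR and CI to
#' two decimals: the check passes when the implied OR matches the printed
#' one within `tol` (default 0.005, i.e. two-decimal rounding).
#'
#' @param or_printed Reported odds ratio(s).
#' @param ci_low,ci_high Reported 95% CI bounds, `0 < ci_low < ci_high`.
#' @param level Confidence level the bounds correspond to (default 0.95).
#' @param tol Pass tolerance on `|implied OR - printed OR|`.
#' @return Tibble with `implied_or`, `implied_se`, `implied_p`, `pass`.
#' @export
#' @examples
#' ci_consistency(2.19, 1.45, 3.31)
ci_consistency <- function(or_printed, ci_low, ci_high, level = 0.95,
                           tol = 0.005) {
  if (any(!(ci_low > 0 & ci_low < ci_high))) {
    abort("require 0 < ci_low < ci_high")
  }
  z <- qnorm((1 + level) / 2)
  implied_or <- sqrt(ci_low * ci_high)
  implied_se <- (log(ci_high) - log(ci_low)) / (2 * z)
  implied_p <- 2 * pnorm(-abs(log(implied_or)) / implied_se)
  tibble(
    or_printed = or_printed,
    implied_or = implied_or,
    implied_se = implied_se,
    implied_p = implied_p,
    pass = abs(implied_or - or_printed) <= tol + 1e-12
  )
}

#' Wald-ratio estimates for a table of harmonized pairs
#'
#' Runs the single-instrument estimator over every non-excluded harmonized
#' pair and tiers the results with Bonferroni control sized by the number
#' of tests actually performed.
#'
#' @param pairs Output of [harmonize_all()].
#' @param outcome_id Label for the outcome column of the result.
#' @param se_method Passed to [wald_ratio()].
#' @param alpha Family-wise alpha for [multiplicity_config()].
#' @param level Confidence level for [to_odds_ratio()].
#' @return Tibble with one `MRResult` row per tested pair: identifiers,
#'   `beta_mr`, `se_mr`, `or`, `ci_low`, `ci_high`, `pval`, `tier`,
#'   `method = "wald_ratio"`, `n_snv = 1`.
#' @export
mr_wald <- function(pairs, outcome_id = "outcome",
                    se_method = c("first_order", "second_order"),
                    alpha = 0.05, level = 0.95) {
  se_method <- match.arg(se_method)
  if (!"proxy_rsid" %in% names(pairs)) pairs$proxy_rsid <- NA_character_
  if (!"proxy_r2" %in% names(pairs)) pairs$proxy_r2 <- NA_real_
  if (!"metabolite_id" %in% names(pairs)) pairs$metabolite_id <- pairs$rsid
  tested <- filter(pairs, .data$action != "excluded")
  if (nrow(tested) == 0) {
    return(tibble(metabolite = character(), outcome = character(),
                  rsid = character(), beta_mr = numeric(), se_mr = numeric(),
                  or = numeric(), ci_low = numeric(), ci_high = numeric(),
                  pval = numeric(), tier = character(), method = character(),
                  n_snv = integer()))
  }
  wr <- wald_ratio(tested$exposure_beta, tested$exposure_se,
                   tested$outcome_beta, tested$outcome_se, se_method)
  orci <- to_odds_ratio(wr$beta_mr, wr$se_mr, level)
  cfg <- multiplicity_config(nrow(tested), alpha)
  tibble(
    metabolite = tested$metabolite_id,
    outcome = outcome_id,
    rsid = tested$rsid,
    beta_mr = wr$beta_mr,
    se_mr = wr$se_mr,
    or = orci$or,
    ci_low = orci$ci_low,
    ci_high = orci$ci_high,
    pval = orci$pval,
    tier = classify_significance(orci$pval, cfg),
    method = "wald_ratio",
    se_method = se_method,
    n_snv = 1L,
    n_tests = cfg$n_tests,
    proxy_rsid = tested$proxy_rsid,
    proxy_r2 = tested$proxy_r2
  )
}
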