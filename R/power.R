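#' Post hoc power for a single-instrument MR test on a binary outcome
#'
#' Closed-form approximation for the power of the two-sided Wald-ratio
#' test at level `alpha` against a true odds ratio `or_target` per 1-SD
#' exposure, for an outcome GWAS of `n_total` individuals with case
#' fraction `K = n_cases / n_total` and an instrument explaining `r2` of
#' the exposure variance. The non-centrality is
#' `|ln(or_target)| * sqrt(n_total * r2 * K * (1 - K))` — the case-control
#' ratio enters through `K (1 - K)` — and
#' `power = Phi(ncp - z_{1-alpha/2})`, optionally adding the mirror tail
#' `Phi(-ncp - z_{1-alpha/2})` (negligible away from the null, exact at
#' it).
#'
#' @param n_total Outcome GWAS size (cases + controls).
#' @param n_cases Number of cases, `0 < n_cases < n_total`.
#' @param r2 Instrument variance explained, in \[0, 1).
#' @param or_target True odds ratio under the alternative (the screen
#'   reports 0.90, 1.20, 1.50).
#' @param alpha Two-sided test level (default 0.05).
#' @param mirror_tail Include the opposite-direction rejection tail
#'   (default `FALSE`; at the null the single-tail value is `alpha / 2`).
#' @return Numeric vector of power values (vectorized over all arguments).
#' @export
#' @examples
#' posthoc_power(795167, 1585, 0.004381, 1.5)
posthoc_power <- function(n_total, n_cases, r2, or_target, alpha = 0.05,
                          mirror_tail = FALSE) {
  K <- n_cases / n_total
  degenerate <- K <= 0 | K >= 1 | (r2 == 0 & or_target != 1)
  if (any(degenerate)) {
    warn("degenerate power scenario (K in {0,1} or r2 = 0): reporting alpha/2")
  }
  z <- qnorm(1 - alpha / 2)
  ncp <- abs(log(or_target)) * sqrt(pmax(n_total * r2 * K * (1 - K), 0))
  ncp[degenerate] <- 0
  p <- pnorm(ncp - z)
  if (mirror_tail) p <- p + pnorm(-ncp - z)
  p
}

#' Power table over outcomes, metabolites, and target odds ratios
#'
#' Expands the full grid outcome x metabolite x target OR and evaluates
#' [posthoc_power()] row-wise.
#'
#' @param outcomes Tibble with `outcome_id`, `n_total`, `n_cases`.
#' @param r2_per_metabolite Tibble with `metabolite_id`, `r2`.
#' @param or_targets Target odds ratios (default `c(0.90, 1.20, 1.50)`).
#' @param alpha Test level (default 0.05).
#' @return Tibble with one row per combination: `outcome_id`,
#'   `metabolite_id`, `n_total`, `n_cases`, `r2`, `or_target`, `power`.
#' @export
power_table <- function(outcomes, r2_per_metabolite,
                        or_targets = c(0.90, 1.20, 1.50), alpha = 0.05) {
  grid <- crossing(
    select(as_tibble(outcomes), "outcome_id", "n_total", "n_cases"),
    select(as_tibble(r2_per_metabolite), "metabolite_id", "r2"),
    or_target = or_targets
  )
  grid$power <- posthoc_power(grid$n_total, grid$n_cases, grid$r2,
                              grid$or_target, alpha)
  arrange(grid, .data$outcome_id, .data$metabolite_id, .data$or_target)
}
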