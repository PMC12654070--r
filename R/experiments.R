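# ---- validation experiments on synthetic data -----------------------------

#' Conditional log-OR benchmark by direct logistic regression
#'
#' The estimand of a Wald ratio on a logistic-scale outcome is the
#' conditional log-OR of disease per 1-SD exposure, which can differ
#' slightly from the generating `theta` under non-collapsibility. This
#' oracle computes the benchmark directly: it simulates one large cohort
#' under the ground-truth model and fits `glm(D ~ X, binomial)`, entirely
#' independent of the summary-statistic pipeline.
#'
#' @param truth A [sim_truth()] row.
#' @param n_oracle Cohort size for the oracle regression (default 1e6).
#' @param seed Seed for the oracle cohort.
#' @return The fitted log-OR per 1-SD exposure (scalar).
#' @export
conditional_logor_oracle <- function(truth, n_oracle = 1e6, seed = 1L) {
  truth <- as.list(truth[1, , drop = FALSE])
  set.seed(seed)
  v <- 2 * truth$maf * (1 - truth$maf)
  s <- sqrt(truth$beta_gx^2 * v + 1)
  K <- truth$n_cases / truth$n_out
  alpha <- .solve_alpha(K, truth$maf, truth$theta, truth$beta_gx, 1, s,
                        truth$pleiotropy_delta)
  g <- rbinom(n_oracle, 2, truth$maf)
  x <- (truth$beta_gx * g + rnorm(n_oracle)) / s
  d <- rbinom(n_oracle, 1,
              plogis(alpha + truth$theta * x + truth$pleiotropy_delta * g))
  unname(coef(glm(d ~ x, family = binomial()))[2])
}

#' Replicate the single-pair Wald-ratio analysis
#'
#' Repeatedly simulates an exposure/outcome pair under one ground truth,
#' runs the Wald-ratio estimator, and returns the per-replicate results.
#' This is the workhorse behind parameter-recovery, CI-coverage, and
#' type-I-error checks.
#'
#' @param truth A [sim_truth()] row (its `seed` field is ignored; each
#'   replicate uses a seed derived from `seed`).
#' @param replicates Number of replicates.
#' @param seed Master seed.
#' @param se_method Passed to [wald_ratio()].
#' @param level CI level (default 0.95).
#' @return Tibble with one row per replicate: `beta_mr`, `se_mr`,
#'   `ci_low`, `ci_high` (log-odds scale), `pval`.
#' @export
mr_replicates <- function(truth, replicates = 500, seed = 1L,
                          se_method = "first_order", level = 0.95) {
  truth <- as.list(truth[1, , drop = FALSE])
  z <- qnorm((1 + level) / 2)
  out <- map_dfr(seq_len(replicates), function(r) {
    set.seed(.child_seed(seed, r))
    ex <- .sim_exposure_stats(truth$maf, truth$beta_gx, truth$n_exp)
    ou <- .sim_outcome_stats(truth$maf, truth$theta, truth$beta_gx,
                             truth$pleiotropy_delta, truth$n_out,
                             truth$n_cases)
    if (!is.finite(ou$se) || ex$beta == 0) {
      return(tibble(beta_mr = NA_real_, se_mr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, pval = 1))
    }
    wr <- wald_ratio(ex$beta, ex$se, ou$beta, ou$se, se_method)
    tibble(beta_mr = wr$beta_mr, se_mr = wr$se_mr,
           ci_low = wr$beta_mr - z * wr$se_mr,
           ci_high = wr$beta_mr + z * wr$se_mr,
           pval = 2 * pnorm(-abs(wr$beta_mr / wr$se_mr)))
  })
  out
}

#' Parameter-recovery and calibration report
#'
#' For each ground-truth row: replicates the full estimator, compares the
#' mean Wald estimate with the conditional-log-OR oracle benchmark, and
#' reports bias, RMSE, CI coverage of the benchmark, and the rejection
#' rate at `alpha` (type-I error when `theta = 0`).
#'
#' @param truths A [sim_truth()] tibble (one row per scenario).
#' @param replicates Replicates per scenario (at least 200 recommended).
#' @param seed Master seed.
#' @param alpha Test level for the rejection-rate column.
#' @param n_oracle Oracle cohort size (see [conditional_logor_oracle()]).
#' @return Tibble with one row per scenario: `theta`, `benchmark`,
#'   `mean_beta_mr`, `bias`, `rmse`, `coverage`, `rejection_rate`,
#'   `n_replicates`.
#' @export
recovery_experiment <- function(truths, replicates = 500, seed = 1L,
                                alpha = 0.05, n_oracle = 1e6) {
  map_dfr(seq_len(nrow(truths)), function(i) {
    truth <- truths[i, ]
    bench <- if (truth$theta == 0 && truth$pleiotropy_delta == 0) {
      0
    } else {
      conditional_logor_oracle(truth, n_oracle, seed = .child_seed(seed, 10000 + i))
    }
    reps <- mr_replicates(truth, replicates, seed = .child_seed(seed, i))
    ok <- !is.na(reps$beta_mr)
    tibble(
      metabolite_id = truth$metabolite_id, outcome_id = truth$outcome_id,
      theta = truth$theta, benchmark = bench,
      mean_beta_mr = mean(reps$beta_mr[ok]),
      bias = mean(reps$beta_mr[ok]) - bench,
      rmse = sqrt(mean((reps$beta_mr[ok] - bench)^2)),
      coverage = mean(reps$ci_low[ok] <= bench & bench <= reps$ci_high[ok]),
      rejection_rate = mean(reps$pval < alpha),
      n_replicates = sum(ok)
    )
  })
}

#' Family-wise error of the Bonferroni screen under the global null
#'
#' Simulates a screen of `n_metabolites` null metabolites (`theta = 0`)
#' against one outcome, `replicates` times, and reports the fraction of
#' replicates in which any Wald-ratio p-value falls below
#' `alpha / n_metabolites` — the family-wise error rate the Bonferroni
#' rule is meant to hold at `alpha`.
#'
#' @param n_metabolites Family size (default 83).
#' @param replicates Number of replicated screens (default 500).
#' @param n_exp,n_out,n_cases Cohort sizes per metabolite pair.
#' @param maf_range Per-metabolite minor-allele frequencies are drawn
#'   uniformly from this range once and reused across replicates.
#' @param f_range Target instrument-strength range (log-uniform, drawn
#'   once).
#' @param alpha Family-wise level.
#' @param seed Master seed.
#' @return Tibble with `fwer`, `mean_min_p`, `n_replicates`,
#'   `n_metabolites`, `bonferroni_threshold`.
#' @export
fwer_experiment <- function(n_metabolites = 83, replicates = 500,
                            n_exp = 8299, n_out = 50000, n_cases = 100,
                            maf_range = c(0.05, 0.5), f_range = c(50, 4000),
                            alpha = 0.05, seed = 1L) {
  set.seed(seed)
  maf <- runif(n_metabolites, maf_range[1], maf_range[2])
  f_target <- exp(runif(n_metabolites, log(f_range[1]), log(f_range[2])))
  r2 <- f_target / (f_target + n_exp - 2)
  beta_gx <- sqrt(r2 / (2 * maf * (1 - maf)))
  thr <- alpha / n_metabolites

  any_reject <- logical(replicates)
  min_p <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(.child_seed(seed, r))
    p <- vapply(seq_len(n_metabolites), function(i) {
      ex <- .sim_exposure_stats(maf[i], beta_gx[i], n_exp)
      ou <- .sim_outcome_stats(maf[i], 0, beta_gx[i], 0, n_out, n_cases)
      if (!is.finite(ou$se) || ex$beta == 0) return(1)
      wr <- wald_ratio(ex$beta, ex$se, ou$beta, ou$se)
      2 * pnorm(-abs(wr$beta_mr / wr$se_mr))
    }, numeric(1))
    any_reject[r] <- any(p < thr)
    min_p[r] <- min(p)
  }
  tibble(fwer = mean(any_reject), mean_min_p = mean(min_p),
         n_replicates = replicates, n_metabolites = n_metabolites,
         bonferroni_threshold = thr)
}

# vectorized Newton-Raphson logistic fit across R replicate 2x3 tables;
# counts and cases are 3 x R matrices
.fit_logistic3_vec <- function(counts, cases) {
  R <- ncol(counts)
  g <- c(0, 1, 2)
  tot_k <- colSums(cases)
  tot_n <- colSums(counts)
  degenerate <- tot_k == 0 | tot_k == tot_n
  a <- qlogis(pmin(pmax(tot_k / tot_n, 1e-12), 1 - 1e-12))
  b <- rep(0, R)
  for (iter in 1:40) {
    eta0 <- a; eta1 <- a + b; eta2 <- a + 2 * b
    mu <- rbind(plogis(eta0), plogis(eta1), plogis(eta2))
    w <- counts * mu * (1 - mu)
    u <- cases - counts * mu
    s0 <- colSums(u)
    s1 <- colSums(u * g)
    i00 <- colSums(w)
    i01 <- colSums(w * g)
    i11 <- colSums(w * g * g)
    det <- i00 * i11 - i01^2
    ok <- is.finite(det) & det > 1e-12 & !degenerate
    da <- ifelse(ok, (i11 * s0 - i01 * s1) / det, 0)
    db <- ifelse(ok, (-i01 * s0 + i00 * s1) / det, 0)
    a <- a + da
    b <- pmin(pmax(b + db, -20), 20)
    if (max(abs(da), abs(db)) < 1e-10) break
  }
  mu <- rbind(plogis(a), plogis(a + b), plogis(a + 2 * b))
  w <- counts * mu * (1 - mu)
  i00 <- colSums(w); i01 <- colSums(w * g); i11 <- colSums(w * g * g)
  det <- i00 * i11 - i01^2
  se <- ifelse(is.finite(det) & det > 1e-12, sqrt(i00 / det), Inf)
  se[degenerate | abs(b) >= 15] <- Inf
  list(beta = b, se = se)
}

#' Monte-Carlo power oracle for the single-instrument test
#'
#' Estimates the rejection rate of the two-sided Wald-ratio test by
#' simulation under the same data-generating model as [simulate_pair()]:
#' the exposure is affected by the instrument with variance explained
#' `r2`, the disease arises from the exposure via a logistic model with a
#' per-1-SD odds ratio `or_target`, and the outcome GWAS is an
#' independent cohort of `n_total` individuals with `n_cases` expected
#' cases. Outcome genotypes are simulated as Hardy-Weinberg cell counts
#' with exact per-cell disease probabilities (distributionally identical
#' to per-individual simulation) and fitted by logistic regression; with
#' the first-order Wald SE the MR z-statistic equals the outcome-side
#' z-statistic, so rejection does not involve the exposure draw.
#'
#' @param n_total,n_cases Outcome cohort size and expected case count.
#' @param r2 Instrument variance explained.
#' @param or_target True odds ratio per 1-SD exposure.
#' @param maf Instrument minor-allele frequency (default 0.3).
#' @param n_reps Monte-Carlo replicates (default 10,000).
#' @param alpha Two-sided test level.
#' @param seed Seed.
#' @return Scalar Monte-Carlo rejection rate.
#' @export
simulate_power <- function(n_total, n_cases, r2, or_target, maf = 0.3,
                           n_reps = 10000, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  K <- n_cases / n_total
  v <- 2 * maf * (1 - maf)
  beta_gx <- sqrt(r2 / v)
  s <- sqrt(beta_gx^2 * v + 1)
  theta <- log(or_target)
  alpha0 <- .solve_alpha(K, maf, theta, beta_gx, 1, s, 0)
  p_g <- .cell_probs(alpha0, theta, beta_gx, 1, s, 0)
  counts <- rmultinom(n_reps, n_total, .hwe_probs(maf))
  cases <- matrix(rbinom(3 * n_reps, as.vector(counts), rep(p_g, n_reps)),
                  nrow = 3)
  fit <- .fit_logistic3_vec(counts, cases)
  z_crit <- qnorm(1 - alpha / 2)
  mean(abs(fit$beta / fit$se) > z_crit, na.rm = TRUE)
}

#' Compare closed-form power with the Monte-Carlo oracle over a grid
#'
#' @param grid Tibble with `n_total`, `n_cases`, `r2`, `or_target` (and
#'   optionally `maf`).
#' @param n_reps Monte-Carlo replicates per grid point.
#' @param alpha Test level.
#' @param seed Master seed.
#' @param mirror_tail Include the opposite-direction rejection tail in the
#'   closed form (default `TRUE`: the Monte-Carlo test is two-sided, so
#'   near the null its rejection rate contains both tails).
#' @return `grid` with `power_formula`, `power_mc`, and `abs_gap`.
#' @export
power_grid_check <- function(grid, n_reps = 10000, alpha = 0.05, seed = 1L,
                             mirror_tail = TRUE) {
  grid <- as_tibble(grid)
  if (!"maf" %in% names(grid)) grid$maf <- 0.3
  grid$power_formula <- posthoc_power(grid$n_total, grid$n_cases, grid$r2,
                                      grid$or_target, alpha,
                                      mirror_tail = mirror_tail)
  grid$power_mc <- map_dbl(seq_len(nrow(grid)), function(i) {
    simulate_power(grid$n_total[i], grid$n_cases[i], grid$r2[i],
                   grid$or_target[i], grid$maf[i], n_reps, alpha,
                   seed = .child_seed(seed, i))
  })
  grid$abs_gap <- abs(grid$power_formula - grid$power_mc)
  grid
}
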