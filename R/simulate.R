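# ---- low-level simulation kernels -----------------------------------------

.hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# Gauss-Hermite nodes transformed for expectations over a standard normal
.gh_cache <- new.env(parent = emptyenv())
.gh_nodes <- function(k = 40) {
  key <- as.character(k)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(k)
    .gh_cache[[key]] <- list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .gh_cache[[key]]
}

# P(D = 1 | G = g) marginalized over the non-genetic exposure component.
# X_raw = b_eff * G + resid_sd * eps with eps ~ N(0,1); the disease model is
# logit P = alpha + theta * X_raw / s + delta * G where s is the population
# SD of the exposure (so theta is per 1-SD).
.cell_probs <- function(alpha, theta, b_eff, resid_sd, s, delta) {
  if (theta == 0) {
    return(plogis(alpha + delta * (0:2)))
  }
  gh <- .gh_nodes()
  vapply(0:2, function(g) {
    sum(gh$w * plogis(alpha + theta * (b_eff * g + resid_sd * gh$x) / s +
                        delta * g))
  }, numeric(1))
}

# intercept such that the population case fraction equals K
.solve_alpha <- function(K, maf, theta, b_eff, resid_sd, s, delta) {
  if (theta == 0 && delta == 0) {
    return(qlogis(K))
  }
  hwe <- .hwe_probs(maf)
  f <- function(a) sum(hwe * .cell_probs(a, theta, b_eff, resid_sd, s, delta)) - K
  uniroot(f, lower = qlogis(K) - 30, upper = qlogis(K) + 30, tol = 1e-12)$root
}

# Logistic regression of case status on allele count fitted on the 2x3
# genotype table by Newton-Raphson; identical to the individual-level MLE.
.fit_logistic3 <- function(n_g, k_g) {
  use <- n_g > 0
  if (sum(k_g) == 0 || sum(k_g) == sum(n_g) || sum(use) < 2) {
    return(list(beta = 0, se = Inf, pval = 1, converged = FALSE))
  }
  g <- (0:2)[use]
  n_g <- n_g[use]
  k_g <- k_g[use]
  a <- qlogis(sum(k_g) / sum(n_g))
  b <- 0
  for (iter in 1:40) {
    mu <- plogis(a + b * g)
    w <- n_g * mu * (1 - mu)
    u <- k_g - n_g * mu
    s0 <- sum(u); s1 <- sum(u * g)
    i00 <- sum(w); i01 <- sum(w * g); i11 <- sum(w * g * g)
    det <- i00 * i11 - i01^2
    if (!is.finite(det) || det <= 1e-12) break
    da <- (i11 * s0 - i01 * s1) / det
    db <- (-i01 * s0 + i00 * s1) / det
    a <- a + da
    b <- b + db
    if (abs(da) < 1e-10 && abs(db) < 1e-10) break
    if (abs(b) > 20) break
  }
  mu <- plogis(a + b * g)
  w <- n_g * mu * (1 - mu)
  i00 <- sum(w); i01 <- sum(w * g); i11 <- sum(w * g * g)
  det <- i00 * i11 - i01^2
  if (!is.finite(det) || det <= 1e-12 || abs(b) > 15) {
    return(list(beta = b, se = Inf, pval = 1, converged = FALSE))
  }
  se <- sqrt(i00 / det)
  list(beta = b, se = se, pval = max(2 * pnorm(-abs(b / se)), 1e-300),
       converged = TRUE)
}

# Exposure-side GWAS for one variant: simulate an individual-level cohort,
# standardize the trait to unit variance, regress on allele count.
.sim_exposure_stats <- function(maf, beta_gx, n) {
  g <- rbinom(n, 2, maf)
  x <- beta_gx * g + rnorm(n)
  x <- (x - mean(x)) / sd(x)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx == 0) {
    return(list(beta = 0, se = Inf, pval = 1, eaf = mean(g) / 2, r2_hat = 0))
  }
  beta <- sum(gc * x) / sxx
  rss <- sum(x^2) - beta^2 * sxx   # x is centered and unit-variance
  se <- sqrt(rss / (n - 2) / sxx)
  # floor the p-value so extreme associations do not underflow to an
  # (invalid) exact zero in the emitted records
  p <- max(2 * pnorm(-abs(beta / se)), 1e-300)
  list(beta = beta, se = se, pval = p,
       eaf = mean(g) / 2, r2_hat = beta^2 * sxx / (n - 1))
}

# Outcome-side GWAS for one variant in an independent cohort. Genotypes are
# drawn as Hardy-Weinberg multinomial cell counts and case status as binomial
# counts within each cell, using the exact per-cell disease probability; this
# is distributionally identical to simulating individuals one by one because
# genotype is the only regressor (disease status is conditionally iid within
# a cell) and the cell-level logistic fit is the individual-level MLE.
# `ld_r` < 1 simulates an LD proxy of the causal sentinel: the proxy's
# allelic correlation with the sentinel attenuates the genetic effect and
# inflates the residual exposure spread.
.sim_outcome_stats <- function(maf, theta, beta_gx, delta, n, n_cases,
                               ld_r = 1) {
  K <- n_cases / n
  v <- 2 * maf * (1 - maf)
  s <- sqrt(beta_gx^2 * v + 1)
  b_eff <- beta_gx * ld_r
  resid_sd <- sqrt(beta_gx^2 * v * (1 - ld_r^2) + 1)
  alpha <- .solve_alpha(K, maf, theta, b_eff, resid_sd, s, delta)
  p_g <- .cell_probs(alpha, theta, b_eff, resid_sd, s, delta)
  counts <- as.integer(rmultinom(1, n, .hwe_probs(maf)))
  cases <- rbinom(3, counts, p_g)
  fit <- .fit_logistic3(counts, cases)
  list(beta = fit$beta, se = fit$se, pval = fit$pval,
       eaf = (counts[2] + 2 * counts[3]) / (2 * n),
       n_cases_obs = sum(cases), converged = fit$converged)
}

# deterministic per-metabolite child seed (kept below 2^31)
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647L)
}

# ---- ground-truth containers ----------------------------------------------

#' Ground truth for one synthetic metabolite-outcome scenario
#'
#' Bundles the parameters that fully determine one synthetic exposure /
#' outcome GWAS pair: minor-allele frequency, genotype-to-exposure effect
#' (SD units), causal log-OR `theta` of the exposure on disease, a direct
#' genotype-to-outcome log-OR `pleiotropy_delta` (0 in the clean
#' scenario), cohort sizes, and the seed. The two cohorts are
#' non-overlapping by construction.
#'
#' @param metabolite_id,rsid,outcome_id Identifiers.
#' @param maf Minor-allele frequency in (0, 0.5\].
#' @param beta_gx Per-allele genotype-to-exposure effect, SD units.
#' @param theta Causal log-OR of a 1-SD exposure increase on disease.
#' @param n_exp Exposure cohort size (default 8299).
#' @param n_out,n_cases Outcome cohort size and expected case count
#'   (defaults 50,000 and 100, a rare-disease case fraction of 0.002).
#' @param pleiotropy_delta Direct genotype-to-outcome log-OR.
#' @param seed Integer seed; fully determines [simulate_pair()] output.
#' @param chrom,pos,effect_allele,other_allele Variant coordinates and
#'   alleles used in the emitted records.
#' @return One-row tibble of class `sim_truth`.
#' @export
sim_truth <- function(metabolite_id = "met_001", rsid = "rs10001",
                      outcome_id = "CLL", maf = 0.3, beta_gx = 0.25,
                      theta = 0, n_exp = 8299, n_out = 50000, n_cases = 100,
                      pleiotropy_delta = 0, seed = 1L, chrom = "1",
                      pos = 1e6, effect_allele = "A", other_allele = "G") {
  if (maf <= 0 || maf > 0.5) abort("maf must lie in (0, 0.5]")
  out <- tibble(
    metabolite_id = metabolite_id, rsid = rsid, outcome_id = outcome_id,
    maf = maf, beta_gx = beta_gx, theta = theta, n_exp = n_exp,
    n_out = n_out, n_cases = n_cases, pleiotropy_delta = pleiotropy_delta,
    seed = as.integer(seed), chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele
  )
  class(out) <- c("sim_truth", class(out))
  out
}

#' Simulate one exposure/outcome summary-statistic pair
#'
#' Generates the two GWAS association records the Wald-ratio estimator
#' consumes, from independent cohorts. Exposure side: genotypes
#' `G ~ Binomial(2, maf)` in Hardy-Weinberg proportions,
#' `X = beta_gx * G + eps` standardized to unit variance, per-variant
#' linear regression. Outcome side: an independent cohort in which disease
#' arises via `logit P(D=1) = alpha + theta * X + pleiotropy_delta * G`,
#' with `alpha` solved so the expected case count equals `n_cases`, and a
#' per-variant logistic regression of case status on allele count.
#'
#' @param truth A [sim_truth()] row.
#' @return List with elements `exposure` and `outcome`, each a one-row
#'   tibble in the canonical summary-statistic layout.
#' @export
#' @examples
#' simulate_pair(sim_truth(theta = 0.5, seed = 42))
simulate_pair <- function(truth) {
  truth <- as.list(truth[1, , drop = FALSE])
  if (truth$n_cases <= 0 || truth$n_cases >= truth$n_out) {
    abort("n_cases must lie strictly between 0 and n_out")
  }
  set.seed(truth$seed)
  ex <- .sim_exposure_stats(truth$maf, truth$beta_gx, truth$n_exp)
  ou <- .sim_outcome_stats(truth$maf, truth$theta, truth$beta_gx,
                           truth$pleiotropy_delta, truth$n_out, truth$n_cases)
  rec <- function(stats, trait_id, n, n_cases) {
    tibble(
      rsid = truth$rsid, chrom = truth$chrom, pos = truth$pos,
      effect_allele = truth$effect_allele, other_allele = truth$other_allele,
      eaf = stats$eaf, beta = stats$beta, se = stats$se, pval = stats$pval,
      n = n, n_cases = n_cases, trait_id = trait_id
    )
  }
  list(
    exposure = rec(ex, truth$metabolite_id, truth$n_exp, NA_real_),
    outcome = rec(ou, truth$outcome_id, truth$n_out,
                  as.numeric(ou$n_cases_obs))
  )
}

#' The four leukemia outcome GWAS sizes
#'
#' Case and control counts of the outcome meta-analyses the screen
#' targets: AML 731/793,587; CML 474/793,588; ALL 313/706,277; CLL
#' 1585/793,582.
#'
#' @return Tibble with `outcome_id`, `n_cases`, `n_controls`, `n_total`,
#'   `case_fraction`.
#' @export
leukemia_outcomes <- function() {
  tibble(
    outcome_id = c("AML", "CML", "ALL", "CLL"),
    n_cases = c(731, 474, 313, 1585),
    n_controls = c(793587, 793588, 706277, 793582)
  ) |>
    mutate(n_total = .data$n_cases + .data$n_controls,
           case_fraction = .data$n_cases / .data$n_total)
}

#' Configuration for a full synthetic screen
#'
#' Defines the default study conditions the generator emulates: 83
#' metabolites instrumented in an exposure GWAS of 8299 individuals;
#' four leukemia outcome cohorts with the subtype case fractions
#' preserved but cohorts scaled to `outcome_n_total` (default 50,000;
#' `NULL` keeps full outcome sizes); instrument strength drawn log-uniform
#' over a first-stage F range of 50-4000; a handful of planted true
#' effects with strong instruments and the rest null; palindromic and
#' proxy-requiring sentinels injected at configurable fractions; optional
#' flagged-domain annotation contamination (0 in the clean default).
#'
#' @param n_metabolites Number of metabolites (default 83).
#' @param n_exp Exposure GWAS size (default 8299).
#' @param outcome_n_total Scaled outcome cohort size, or `NULL` for full
#'   size.
#' @param f_range Target first-stage F range (log-uniform draw).
#' @param maf_range Minor-allele frequency range (uniform draw).
#' @param frac_palindromic Fraction of sentinels given A/T or C/G alleles.
#' @param frac_missing_outcome Fraction of sentinels absent from the
#'   outcome files (exercising LD-proxy substitution).
#' @param planted Tibble (`metabolite_index`, `outcome_id`, `theta`) of
#'   true causal effects; default three large effects on CLL, AML, CML.
#' @param planted_r2 Variance explained of planted-effect instruments
#'   (default 0.25, near the top of the F range, so the scaled-down screen
#'   has near-complete power).
#' @param annotation_rates Named per-domain probabilities that a sentinel
#'   receives a genome-wide significant flagged-domain annotation.
#' @param benign_annotation_rate Probability of a benign metabolite-domain
#'   annotation.
#' @param presentation_probs Probabilities that an outcome record is
#'   emitted as-is, allele-swapped, strand-flipped, or both (the emitted
#'   numbers are transformed consistently, so every presentation encodes
#'   the same association).
#' @param seed Master seed; per-metabolite child seeds are derived by
#'   fixed arithmetic on the metabolite index.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_metabolites = 83, n_exp = 8299,
                            outcome_n_total = 50000,
                            f_range = c(50, 4000), maf_range = c(0.05, 0.5),
                            frac_palindromic = 0.1,
                            frac_missing_outcome = 0.1,
                            planted = NULL, planted_r2 = 0.25,
                            annotation_rates = c(neoplastic = 0, immune = 0,
                                                 hematologic = 0,
                                                 cardiometabolic = 0),
                            benign_annotation_rate = 0.3,
                            presentation_probs = c(none = 0.7, swap = 0.1,
                                                   strand = 0.1, both = 0.1),
                            seed = 1L) {
  if (is.null(planted)) {
    planted <- tibble(
      metabolite_index = c(1L, 2L, 3L),
      outcome_id = c("CLL", "AML", "CML"),
      theta = c(1.0, 1.2, -1.2)
    )
    planted <- filter(planted, .data$metabolite_index <= n_metabolites)
  }
  stopifnot(frac_palindromic >= 0, frac_palindromic <= 1,
            frac_missing_outcome >= 0, frac_missing_outcome <= 1)
  structure(
    list(n_metabolites = n_metabolites, n_exp = n_exp,
         outcome_n_total = outcome_n_total, f_range = f_range,
         maf_range = maf_range, frac_palindromic = frac_palindromic,
         frac_missing_outcome = frac_missing_outcome, planted = planted,
         planted_r2 = planted_r2, annotation_rates = annotation_rates,
         benign_annotation_rate = benign_annotation_rate,
         presentation_probs = presentation_probs, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

.nonpalindromic_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

# consistent re-presentation of one aligned outcome record: the printed
# labels change but beta/eaf are transformed in step, so the record always
# encodes the same physical association
.present_record <- function(rec, presentation) {
  if (presentation %in% c("swap", "both")) {
    tmp <- rec$effect_allele
    rec$effect_allele <- rec$other_allele
    rec$other_allele <- tmp
    rec$beta <- -rec$beta
    rec$eaf <- 1 - rec$eaf
  }
  if (presentation %in% c("strand", "both")) {
    rec$effect_allele <- unname(.rc[rec$effect_allele])
    rec$other_allele <- unname(.rc[rec$other_allele])
  }
  rec
}

#' Simulate a full synthetic screen bundle
#'
#' Emits everything [run_pipeline()] consumes, with known ground truth:
#' an exposure summary-statistic table (sentinels plus extra independent
#' signals per metabolite), one outcome table per leukemia subtype with
#' the configured case fractions, an LD table covering the
#' proxy-requiring sentinels (best proxy plus decoys), a variant-to-trait
#' annotation table, a metabolite-to-gene-to-drug table, and a truth
#' registry. The same seed and configuration reproduce the bundle
#' exactly.
#'
#' @param cfg A [scenario_config()].
#' @return List of class `sim_bundle` with elements `exposure`,
#'   `outcomes` (named list of tibbles), `ld`, `annotations`, `drugs`,
#'   `truth`, `planted`, `outcome_info`, `config`.
#' @export
simulate_screen <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  m <- cfg$n_metabolites

  info <- leukemia_outcomes()
  if (!is.null(cfg$outcome_n_total)) {
    info <- info |>
      mutate(n_cases = round(.data$case_fraction * cfg$outcome_n_total),
             n_total = cfg$outcome_n_total,
             n_controls = .data$n_total - .data$n_cases)
  }

  ids <- sprintf("met_%03d", seq_len(m))
  rsids <- sprintf("rs%05d", 10000 + seq_len(m))
  genes <- sprintf("GENE%03d", seq_len(m))
  if (m >= 1) genes[1] <- "SULT2A1"

  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  f_target <- exp(runif(m, log(cfg$f_range[1]), log(cfg$f_range[2])))
  r2 <- f_target / (f_target + cfg$n_exp - 2)
  planted_idx <- cfg$planted$metabolite_index
  maf[planted_idx] <- 0.3
  r2[planted_idx] <- cfg$planted_r2
  beta_gx <- sqrt(r2 / (2 * maf * (1 - maf)))

  palindromic <- runif(m) < cfg$frac_palindromic
  alleles <- t(vapply(seq_len(m), function(i) {
    if (palindromic[i]) {
      if (runif(1) < 0.5) c("A", "T") else c("C", "G")
    } else {
      .nonpalindromic_pairs[sample.int(8, 1), ]
    }
  }, character(2)))
  chrom <- as.character(sample(c(1:5, 7:10, 12:22), m, replace = TRUE))
  pos <- round(runif(m, 1e6, 2e8))
  missing_outcome <- runif(m) < cfg$frac_missing_outcome
  n_extra <- stats::rpois(m, 0.7)

  # proxy layout for sentinels absent from the outcome files
  proxy_plan <- map(seq_len(m), function(i) {
    if (!missing_outcome[i]) return(NULL)
    n_prox <- 1 + (runif(1) < 0.5)
    r2_ld <- sort(runif(n_prox, 0.82, 0.99), decreasing = TRUE)
    pa <- t(vapply(seq_len(n_prox), function(j) {
      .nonpalindromic_pairs[sample.int(8, 1), ]
    }, character(2)))
    tibble(
      proxy_rsid = sprintf("rs9%04d%d", i, seq_len(n_prox)),
      r2 = r2_ld,
      p_ea = pa[, 1], p_oa = pa[, 2]
    )
  })

  drop_domains <- names(cfg$annotation_rates)
  domain_traits <- list(
    neoplastic = c("chronic lymphocytic leukemia", "prostate carcinoma",
                   "breast carcinoma"),
    immune = c("rheumatoid arthritis", "systemic lupus erythematosus"),
    hematologic = c("platelet count", "monocyte count"),
    cardiometabolic = c("LDL cholesterol", "type 2 diabetes",
                        "body mass index")
  )

  exposure_rows <- list()
  outcome_rows <- setNames(vector("list", nrow(info)), info$outcome_id)
  ld_rows <- list()
  ann_rows <- list()
  truth_rows <- list()

  for (i in seq_len(m)) {
    set.seed(.child_seed(cfg$seed, i))

    # exposure side: sentinel plus weaker independent signals
    ex <- .sim_exposure_stats(maf[i], beta_gx[i], cfg$n_exp)
    exposure_rows[[length(exposure_rows) + 1]] <- tibble(
      rsid = rsids[i], chrom = chrom[i], pos = pos[i],
      effect_allele = alleles[i, 1], other_allele = alleles[i, 2],
      eaf = ex$eaf, beta = ex$beta, se = ex$se, pval = ex$pval,
      n = cfg$n_exp, n_cases = NA_real_, trait_id = ids[i], gene = genes[i]
    )
    extras <- NULL
    if (n_extra[i] > 0) {
      for (j in seq_len(n_extra[i])) {
        maf_j <- runif(1, cfg$maf_range[1], cfg$maf_range[2])
        r2_j <- r2[i] * runif(1, 0.2, 0.8)
        b_j <- sqrt(r2_j / (2 * maf_j * (1 - maf_j)))
        exj <- .sim_exposure_stats(maf_j, b_j, cfg$n_exp)
        pair <- .nonpalindromic_pairs[sample.int(8, 1), ]
        extras <- bind_rows(extras, tibble(
          rsid = sprintf("rs8%04d%d", i, j), maf = maf_j, beta_gx = b_j,
          ea = pair[1], oa = pair[2], pos = pos[i] + j * 1e6
        ))
        exposure_rows[[length(exposure_rows) + 1]] <- tibble(
          rsid = extras$rsid[j], chrom = chrom[i], pos = extras$pos[j],
          effect_allele = pair[1], other_allele = pair[2],
          eaf = exj$eaf, beta = exj$beta, se = exj$se, pval = exj$pval,
          n = cfg$n_exp, n_cases = NA_real_, trait_id = ids[i],
          gene = genes[i]
        )
      }
    }

    pp <- proxy_plan[[i]]
    if (!is.null(pp)) {
      for (j in seq_len(nrow(pp))) {
        ld_rows[[length(ld_rows) + 1]] <- tibble(
          rsid_a = rsids[i], rsid_b = pp$proxy_rsid[j], r2 = pp$r2[j],
          allele_map = paste0(alleles[i, 1], "=", pp$p_ea[j], ",",
                              alleles[i, 2], "=", pp$p_oa[j])
        )
      }
      # a sub-threshold decoy that must never be selected
      ld_rows[[length(ld_rows) + 1]] <- tibble(
        rsid_a = rsids[i], rsid_b = sprintf("rs7%04d0", i), r2 = 0.5,
        allele_map = "A=A,G=G"
      )
    }

    # outcome side: one record per subtype, at the sentinel or its proxies
    for (o in seq_len(nrow(info))) {
      oid <- info$outcome_id[o]
      hit <- filter(cfg$planted, .data$metabolite_index == i,
                    .data$outcome_id == oid)
      theta_io <- if (nrow(hit) > 0) hit$theta[1] else 0
      emit <- function(rsid_o, ea, oa, maf_o, b_o, ld_r, pos_o) {
        ou <- .sim_outcome_stats(maf_o, theta_io, b_o, 0,
                                 info$n_total[o], info$n_cases[o], ld_r)
        rec <- tibble(
          rsid = rsid_o, chrom = chrom[i], pos = pos_o,
          effect_allele = ea, other_allele = oa,
          eaf = ou$eaf, beta = ou$beta, se = ou$se, pval = ou$pval,
          n = info$n_total[o], n_cases = as.numeric(ou$n_cases_obs),
          trait_id = oid
        )
        pres <- sample(names(cfg$presentation_probs), 1,
                       prob = cfg$presentation_probs)
        .present_record(rec, pres)
      }
      if (!missing_outcome[i]) {
        outcome_rows[[oid]][[length(outcome_rows[[oid]]) + 1]] <-
          emit(rsids[i], alleles[i, 1], alleles[i, 2], maf[i], beta_gx[i],
               1, pos[i])
      } else {
        for (j in seq_len(nrow(pp))) {
          outcome_rows[[oid]][[length(outcome_rows[[oid]]) + 1]] <-
            emit(pp$proxy_rsid[j], pp$p_ea[j], pp$p_oa[j], maf[i],
                 beta_gx[i], sqrt(pp$r2[j]), pos[i])
        }
      }
      # the outcome GWAS also covers the metabolite's secondary signals
      if (!is.null(extras)) {
        for (j in seq_len(nrow(extras))) {
          outcome_rows[[oid]][[length(outcome_rows[[oid]]) + 1]] <-
            emit(extras$rsid[j], extras$ea[j], extras$oa[j], extras$maf[j],
                 extras$beta_gx[j], 1, extras$pos[j])
        }
      }
    }

    # annotations for the rsid the screen will actually inspect
    screened_rsid <- if (missing_outcome[i]) pp$proxy_rsid[1] else rsids[i]
    if (runif(1) < cfg$benign_annotation_rate) {
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        rsid = screened_rsid,
        trait = paste0("plasma metabolite level (", ids[i], ")"),
        domain = "metabolite", pval = 1e-12
      )
    }
    for (d in drop_domains) {
      if (runif(1) < cfg$annotation_rates[[d]]) {
        ann_rows[[length(ann_rows) + 1]] <- tibble(
          rsid = screened_rsid,
          trait = sample(domain_traits[[d]], 1),
          domain = d, pval = 10^runif(1, -12, -8.5)
        )
      }
    }

    mo_i <- missing_outcome[i]
    truth_rows[[i]] <- tibble(
      metabolite_id = ids[i], rsid = rsids[i], gene = genes[i],
      maf = maf[i], beta_gx = beta_gx[i], r2_true = r2[i],
      f_target = f_statistic(r2[i], cfg$n_exp),
      palindromic = palindromic[i], missing_outcome = mo_i,
      proxy_rsid = if (mo_i) pp$proxy_rsid[1] else NA_character_,
      proxy_r2 = if (mo_i) pp$r2[1] else NA_real_
    )
  }

  exposure <- validate_summary_stats(bind_rows(exposure_rows),
                                     trait_kind = "exposure_quantitative")
  outcomes <- map(outcome_rows, function(rows) {
    validate_summary_stats(bind_rows(rows), trait_kind = "outcome_binary")
  })
  ld <- if (length(ld_rows) > 0) bind_rows(ld_rows) else
    tibble(rsid_a = character(), rsid_b = character(), r2 = numeric(),
           allele_map = character())
  annotations <- if (length(ann_rows) > 0) bind_rows(ann_rows) else
    tibble(rsid = character(), trait = character(), domain = character(),
           pval = numeric())

  drugs <- default_drug_table(tibble(metabolite_id = ids, gene = genes))

  structure(
    list(exposure = exposure, outcomes = outcomes, ld = ld,
         annotations = annotations, drugs = drugs,
         truth = bind_rows(truth_rows), planted = cfg$planted,
         outcome_info = info, config = cfg),
    class = "sim_bundle"
  )
}

#' Drug-annotation table for a set of metabolite effector genes
#'
#' Builds the metabolite-gene-drug join table the pipeline's annotation
#' step consumes. Genes present in the packaged effector-gene drug
#' reference (currently SULT2A1, whose eight clinical substrates are
#' shipped in `extdata/sult2a1_drug_annotations.tsv`) receive their
#' curated rows; other genes receive none (they pass through the join
#' unannotated).
#'
#' @param gene_map Tibble with `metabolite_id` and `gene`.
#' @return Tibble with columns `metabolite`, `effector_gene`,
#'   `protein_type`, `drugbank_id`, `drug_name`, `relation`, `antagonist`,
#'   `agonist`, `substrate`, `inhibitor`, `inducer`.
#' @export
default_drug_table <- function(gene_map) {
  ref <- readr::read_tsv(
    system.file("extdata", "sult2a1_drug_annotations.tsv",
                package = "sentinelmr"),
    col_types = readr::cols(
      effector_gene = readr::col_character(),
      protein_type = readr::col_character(),
      drugbank_id = readr::col_character(),
      drug_name = readr::col_character(),
      relation = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE
  )
  gene_map |>
    inner_join(ref, by = c(gene = "effector_gene")) |>
    transmute(metabolite = .data$metabolite_id, effector_gene = .data$gene,
              protein_type = .data$protein_type,
              drugbank_id = .data$drugbank_id, drug_name = .data$drug_name,
              relation = .data$relation, antagonist = .data$antagonist,
              agonist = .data$agonist, substrate = .data$substrate,
              inhibitor = .data$inhibitor, inducer = .data$inducer)
}

#' Write a synthetic bundle to disk as canonical TSV files
#'
#' @param bundle A `sim_bundle` from [simulate_screen()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(as_tibble(x), file.path(dir, name), progress = FALSE)
  }
  w(select(bundle$exposure, -any_of(c("valid", "exclusion_reason"))),
    "exposure.tsv")
  for (oid in names(bundle$outcomes)) {
    w(select(bundle$outcomes[[oid]], -any_of(c("valid", "exclusion_reason"))),
      paste0("outcome_", oid, ".tsv"))
  }
  w(bundle$ld, "ld.tsv")
  w(bundle$annotations, "annotations.tsv")
  w(bundle$drugs, "drugs.tsv")
  w(bundle$truth, "truth_registry.tsv")
  invisible(dir)
}
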