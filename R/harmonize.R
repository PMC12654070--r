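.rc <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a, b) .rc[[a]] == b

# Core single-pair harmonization kernel. All alleles must already be
# validated single A/C/G/T characters (callers route non-ACGT to exclusion).
# Returns list(action, reason, beta, eaf, ea, oa) where beta/eaf are the
# outcome values aligned to the exposure's effect allele.
.harmonize1 <- function(ea_x, oa_x, ea_y, oa_y, beta_y, eaf_y, eaf_x, window) {
  excl <- function(reason) list(action = "excluded", reason = reason,
                                beta = NA_real_, eaf = NA_real_,
                                ea = ea_y, oa = oa_y)
  ok <- function(a) !is.na(a) && a %in% names(.rc)
  if (!ok(ea_x) || !ok(oa_x) || !ok(ea_y) || !ok(oa_y) ||
      ea_x == oa_x || ea_y == oa_y) {
    return(excl("non_acgt"))
  }

  if (.is_palindromic(ea_x, oa_x)) {
    # palindromic exposure pair: outcome pair must be the same unordered set
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
      return(excl("allele_mismatch"))
    }
    inside <- function(f) !is.na(f) && f >= window[1] && f <= window[2]
    if (is.na(eaf_y) || is.na(eaf_x) || inside(eaf_y) || inside(eaf_x)) {
      return(excl("palindromic_ambiguous"))
    }
    # align labels first (swap if printed effect allele is the exposure's
    # other allele), then let minor/major concordance decide the strand
    swapped <- ea_y != ea_x
    b <- if (swapped) -beta_y else beta_y
    f <- if (swapped) 1 - eaf_y else eaf_y
    concordant <- (eaf_x < 0.5) == (f < 0.5)
    if (concordant) {
      action <- if (swapped) "swap_flip" else "none"
    } else {
      # frequencies indicate the printed labels sit on the opposite strand
      b <- -b
      f <- 1 - f
      action <- if (swapped) "strand_flip" else "strand_flip_and_swap"
    }
    return(list(action = action, reason = NA_character_, beta = b, eaf = f,
                ea = ea_x, oa = oa_x))
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    return(list(action = "none", reason = NA_character_, beta = beta_y,
                eaf = eaf_y, ea = ea_x, oa = oa_x))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(list(action = "swap_flip", reason = NA_character_, beta = -beta_y,
                eaf = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y,
                ea = ea_x, oa = oa_x))
  }
  if (.rc[[ea_y]] == ea_x && .rc[[oa_y]] == oa_x) {
    return(list(action = "strand_flip", reason = NA_character_, beta = beta_y,
                eaf = eaf_y, ea = ea_x, oa = oa_x))
  }
  if (.rc[[ea_y]] == oa_x && .rc[[oa_y]] == ea_x) {
    return(list(action = "strand_flip_and_swap", reason = NA_character_,
                beta = -beta_y,
                eaf = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y,
                ea = ea_x, oa = oa_x))
  }
  excl("allele_mismatch")
}

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. For
#' non-palindromic variants the allele labels decide everything: a direct
#' match needs no action; swapped alleles negate the outcome beta and
#' complement its frequency (`swap_flip`); a reverse-complement match
#' relabels the strand (`strand_flip`), possibly combined with a swap
#' (`strand_flip_and_swap`); irreconcilable alleles are excluded
#' (`allele_mismatch`). Palindromic variants (A/T or C/G) carry no strand
#' information in their labels, so allele-frequency concordance decides:
#' when both frequencies fall outside the ambiguity window the pair is
#' aligned so minor/major status agrees (negating beta when the
#' frequencies indicate opposite labels); when either frequency is inside
#' the window, or the outcome frequency is missing, the pair is excluded
#' (`palindromic_ambiguous`). Non-A/C/G/T alleles are excluded
#' (`non_acgt`), never raised as errors.
#'
#' A beta sign change and an eaf complement are always applied together;
#' harmonizing an already-harmonized pair is the identity (action
#' `"none"`).
#'
#' @param exposure,outcome One-row data frames (or named lists) with
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf` (and optionally
#'   `rsid`, `pval`, `n`, `n_cases`).
#' @param ambiguity_window Frequency interval within which a palindromic
#'   variant is considered unresolvable; default `c(0.42, 0.58)`.
#' @return One-row tibble: `rsid`, `action`, `exclusion_reason`, exposure
#'   fields (`exposure_` prefix), aligned outcome fields (`outcome_`
#'   prefix), and the window bounds used.
#' @export
#' @examples
#' exp <- list(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'             beta = 0.5, se = 0.05, eaf = 0.2)
#' out <- list(rsid = "rs1", effect_allele = "G", other_allele = "A",
#'             beta = 0.2, se = 0.1, eaf = 0.8)
#' harmonize_pair(exp, out)  # swap_flip: outcome beta -0.2, eaf 0.2
harmonize_pair <- function(exposure, outcome, ambiguity_window = c(0.42, 0.58)) {
  g <- function(rec, field) {
    v <- rec[[field]]
    if (is.null(v) || length(v) == 0) NA else v[[1]]
  }
  h <- .harmonize1(
    g(exposure, "effect_allele"), g(exposure, "other_allele"),
    g(outcome, "effect_allele"), g(outcome, "other_allele"),
    as.numeric(g(outcome, "beta")), as.numeric(g(outcome, "eaf")),
    as.numeric(g(exposure, "eaf")), ambiguity_window
  )
  tibble(
    rsid = as.character(g(exposure, "rsid")),
    outcome_rsid = as.character(g(outcome, "rsid")),
    action = h$action,
    exclusion_reason = h$reason,
    effect_allele = h$ea,
    other_allele = h$oa,
    exposure_beta = as.numeric(g(exposure, "beta")),
    exposure_se = as.numeric(g(exposure, "se")),
    exposure_eaf = as.numeric(g(exposure, "eaf")),
    exposure_pval = as.numeric(g(exposure, "pval")),
    exposure_n = as.numeric(g(exposure, "n")),
    outcome_beta = h$beta,
    outcome_se = if (h$action == "excluded") NA_real_ else as.numeric(g(outcome, "se")),
    outcome_eaf = h$eaf,
    outcome_pval = as.numeric(g(outcome, "pval")),
    outcome_n = as.numeric(g(outcome, "n")),
    outcome_n_cases = as.numeric(g(outcome, "n_cases")),
    eaf_window_low = ambiguity_window[1],
    eaf_window_high = ambiguity_window[2]
  )
}

#' Harmonize every active sentinel against an outcome table
#'
#' Produces one [harmonize_pair()] row per active sentinel, routing each
#' sentinel to its own outcome record or — when a proxy was assigned — to
#' the proxy's record with the proxy's alleles first translated back to
#' the sentinel's alleles via the LD allele correspondence. Sentinels
#' whose (proxy) rsid is absent from the outcome table are excluded as
#' `allele_mismatch`-free `no_outcome_match` rows upstream; here they are
#' skipped. The result conserves inputs: harmonized + excluded = active
#' sentinels.
#'
#' @param sentinels Sentinel tibble (active rows are harmonized; proxy
#'   columns are honored).
#' @param outcomes Outcome `summary_stats` tibble for a single trait.
#' @param ambiguity_window See [harmonize_pair()].
#' @return Tibble of harmonized pairs with a `metabolite_id` column; the
#'   per-action / per-reason audit is available via
#'   [harmonization_audit()].
#' @export
harmonize_all <- function(sentinels, outcomes, ambiguity_window = c(0.42, 0.58)) {
  active <- filter(sentinels, .data$status == "active")
  rows <- map(seq_len(nrow(active)), function(i) {
    s <- active[i, ]
    target_rsid <- if (!is.na(s$proxy_rsid)) s$proxy_rsid else s$rsid
    out <- filter(outcomes, .data$rsid == target_rsid)
    if (nrow(out) == 0) {
      return(NULL)
    }
    out <- out[1, ]
    if (!is.na(s$proxy_rsid) && !is.na(s$proxy_allele_map)) {
      # translate proxy alleles into sentinel allele space before aligning;
      # the correspondence is extended to reverse complements so a proxy
      # record reported on the opposite strand still translates (and the
      # strand flip is then resolved by the ordinary harmonization rules)
      to_sentinel <- .invert_allele_map(.parse_allele_map(s$proxy_allele_map))
      ext <- setNames(unname(.rc[unname(to_sentinel)]),
                      unname(.rc[names(to_sentinel)]))
      to_sentinel <- c(to_sentinel, ext[setdiff(names(ext), names(to_sentinel))])
      tr <- function(a) {
        if (!is.na(a) && a %in% names(to_sentinel)) to_sentinel[[a]] else a
      }
      out$effect_allele <- tr(out$effect_allele)
      out$other_allele <- tr(out$other_allele)
    }
    hp <- harmonize_pair(s, out, ambiguity_window)
    hp$metabolite_id <- s$metabolite_id
    hp$proxy_rsid <- s$proxy_rsid
    hp$proxy_r2 <- s$proxy_r2
    hp
  })
  pairs <- bind_rows(rows)
  if (nrow(pairs) > 0) {
    pairs <- select(pairs, "metabolite_id", everything())
  } else {
    pairs <- tibble(
      metabolite_id = character(), rsid = character(),
      outcome_rsid = character(), action = character(),
      exclusion_reason = character(), effect_allele = character(),
      other_allele = character(), exposure_beta = numeric(),
      exposure_se = numeric(), exposure_eaf = numeric(),
      exposure_pval = numeric(), exposure_n = numeric(),
      outcome_beta = numeric(), outcome_se = numeric(),
      outcome_eaf = numeric(), outcome_pval = numeric(),
      outcome_n = numeric(), outcome_n_cases = numeric(),
      eaf_window_low = numeric(), eaf_window_high = numeric(),
      proxy_rsid = character(), proxy_r2 = numeric()
    )
  }
  pairs
}

#' Audit summary of a harmonization run
#'
#' @param pairs Output of [harmonize_all()].
#' @return Tibble of counts per action and exclusion reason.
#' @export
harmonization_audit <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(tibble(action = character(), exclusion_reason = character(),
                  n = integer()))
  }
  count(pairs, .data$action, .data$exclusion_reason, name = "n")
}
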