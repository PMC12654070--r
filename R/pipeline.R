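#' Pipeline configuration
#'
#' Collects every threshold and path the end-to-end screen uses. All
#' thresholds default to the screen's standard values: genome-wide
#' significance `5e-8` for instruments and the pleiotropy screen, LD-proxy
#' bound `r2 > 0.8`, palindromic ambiguity window \[0.42, 0.58\],
#' family-wise alpha 0.05 with Bonferroni sizing recomputed from the
#' number of tests actually performed per outcome.
#'
#' @param paths Optional named list of input paths (`exposure`, `outcomes`
#'   named list/vector, `ld`, `annotations`, `drugs`, `out_dir`).
#' @param gw_sig Genome-wide significance threshold.
#' @param proxy_r2_min Strict LD r-squared lower bound for proxies.
#' @param ambiguity_window Palindromic ambiguity interval.
#' @param alpha Family-wise alpha (also the suggestive threshold).
#' @param se_method Wald-ratio SE method.
#' @param power_or Target odds ratios for the power table.
#' @param exclusion_regions Region tibble; default
#'   [default_exclusion_regions()].
#' @param flagged_domains Annotation domains that trigger the pleiotropy
#'   drop.
#' @param seed Seed recorded in the run manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, gw_sig = 5e-8, proxy_r2_min = 0.8,
                            ambiguity_window = c(0.42, 0.58), alpha = 0.05,
                            se_method = "first_order",
                            power_or = c(0.90, 1.20, 1.50),
                            exclusion_regions = default_exclusion_regions(),
                            flagged_domains = .flagged_domains,
                            seed = 1L) {
  stopifnot(gw_sig > 0, gw_sig < 1, proxy_r2_min >= 0, proxy_r2_min < 1,
            length(ambiguity_window) == 2,
            ambiguity_window[1] <= ambiguity_window[2],
            alpha > 0, alpha < 1)
  structure(
    list(paths = paths, gw_sig = gw_sig, proxy_r2_min = proxy_r2_min,
         ambiguity_window = ambiguity_window, alpha = alpha,
         se_method = se_method, power_or = power_or,
         exclusion_regions = exclusion_regions,
         flagged_domains = flagged_domains, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(raw$exclusion_regions)) {
    raw$exclusion_regions <- bind_rows(lapply(raw$exclusion_regions, as_tibble))
  }
  if (!is.null(raw$ambiguity_window)) {
    raw$ambiguity_window <- as.numeric(raw$ambiguity_window)
  }
  do.call(pipeline_config, raw)
}

.audit_row <- function(stage, outcome, n_in, n_kept, detail = NA_character_) {
  tibble(stage = stage, outcome = outcome, n_in = n_in, n_kept = n_kept,
         n_dropped = n_in - n_kept, detail = detail)
}

#' Run the full single-sentinel MR screen
#'
#' Executes the stages in order — read/validate, sentinel selection,
#' region exclusion, outcome matching with LD-proxy substitution,
#' pleiotropy drop-list screen, harmonization, Wald-ratio estimation with
#' Bonferroni tiering, post hoc power, drug-annotation join — logging a
#' conserved count at every stage. Each outcome is analyzed fully
#' independently. A stage that leaves zero instruments produces an empty
#' result table plus an explanatory audit, never an error.
#'
#' @param exposure Exposure candidate table (canonical layout; a `gene`
#'   column is honored) or `NULL` to read from `cfg$paths`.
#' @param outcomes Named list of outcome `summary_stats` tibbles, one per
#'   outcome trait, or `NULL` to read from `cfg$paths`.
#' @param ld LD table (may be `NULL`).
#' @param annotations Variant-to-trait annotation table (may be `NULL`).
#' @param drugs Drug-annotation table (may be `NULL`).
#' @param cfg A [pipeline_config()].
#' @return Object of class `mr_screen`: list with `results` (all
#'   outcomes), `sentinels` (per-outcome instrument status), `pairs`
#'   (harmonized pairs), `audit`, `instrument_strength`, `power`,
#'   `drug_annotations`, `validation`, `config`, `manifest`. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
run_pipeline <- function(exposure = NULL, outcomes = NULL, ld = NULL,
                         annotations = NULL, drugs = NULL,
                         cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  p <- cfg$paths
  if (is.null(exposure)) {
    exposure <- read_summary_stats(p$exposure, trait_kind = "exposure_quantitative")
  }
  if (is.null(outcomes)) {
    outcomes <- lapply(p$outcomes, read_summary_stats,
                       trait_kind = "outcome_binary")
    names(outcomes) <- names(p$outcomes)
  }
  if (is.null(ld) && !is.null(p$ld)) {
    ld <- readr::read_tsv(p$ld, col_types = "ccdc", progress = FALSE)
  }
  if (is.null(annotations) && !is.null(p$annotations)) {
    annotations <- readr::read_tsv(p$annotations, col_types = "cccd",
                                   progress = FALSE)
  }
  if (is.null(drugs) && !is.null(p$drugs)) {
    drugs <- readr::read_tsv(p$drugs, progress = FALSE,
                             col_types = readr::cols())
  }

  audit <- list()
  # stage 1: validation
  if (!"valid" %in% names(exposure)) {
    exposure <- validate_summary_stats(exposure,
                                       trait_kind = "exposure_quantitative")
  }
  vrep_exp <- validation_report(exposure)
  audit[[length(audit) + 1]] <-
    .audit_row("validate_exposure", NA_character_, vrep_exp$n_input,
               vrep_exp$n_valid)
  vreps_out <- list()
  for (oid in names(outcomes)) {
    if (!"valid" %in% names(outcomes[[oid]])) {
      outcomes[[oid]] <- validate_summary_stats(outcomes[[oid]],
                                                trait_kind = "outcome_binary")
    }
    vreps_out[[oid]] <- validation_report(outcomes[[oid]])
    audit[[length(audit) + 1]] <-
      .audit_row("validate_outcome", oid, vreps_out[[oid]]$n_input,
                 vreps_out[[oid]]$n_valid)
  }

  # stage 2: sentinel selection (shared across outcomes)
  sentinels0 <- select_sentinels(exposure, p_threshold = cfg$gw_sig)
  n_met <- nrow(sentinels0)
  audit[[length(audit) + 1]] <-
    .audit_row("select_sentinels", NA_character_, n_met,
               sum(sentinels0$status == "active"),
               detail = paste0("uninstrumented=",
                               sum(sentinels0$status == "uninstrumented")))

  # stage 3: region exclusions
  sentinels0 <- apply_region_exclusions(sentinels0, cfg$exclusion_regions)
  audit[[length(audit) + 1]] <-
    .audit_row("region_exclusion", NA_character_,
               sum(sentinels0$status %in% c("active", "dropped_region")),
               sum(sentinels0$status == "active"))

  results <- list()
  sentinel_tbls <- list()
  pair_tbls <- list()
  power_tbls <- list()
  outcome_sizes <- list()

  for (oid in names(outcomes)) {
    otab <- filter(outcomes[[oid]], .data$valid)
    sen <- sentinels0

    # stage 4: outcome matching / proxy substitution
    n_active_in <- sum(sen$status == "active")
    sen <- find_proxies(sen, otab$rsid, ld, r2_min = cfg$proxy_r2_min)
    audit[[length(audit) + 1]] <-
      .audit_row("outcome_match", oid, n_active_in,
                 sum(sen$status == "active"),
                 detail = paste0("proxied=", sum(!is.na(sen$proxy_rsid) &
                                                   sen$status == "active")))

    # stage 5: pleiotropy drop list
    n_active_in <- sum(sen$status == "active")
    if (!is.null(annotations) && nrow(annotations) > 0) {
      sen <- screen_pleiotropy(sen, annotations, outcome_trait = oid,
                               gw_threshold = cfg$gw_sig,
                               flagged_domains = cfg$flagged_domains)
    } else {
      sen$retained_annotations <- NA_character_
    }
    audit[[length(audit) + 1]] <-
      .audit_row("pleiotropy_screen", oid, n_active_in,
                 sum(sen$status == "active"),
                 detail = paste0(
                   "dropped_pleiotropy=", sum(sen$status == "dropped_pleiotropy"),
                   ";dropped_outcome_gwas=", sum(sen$status == "dropped_outcome_gwas")))

    # stage 6: harmonization
    n_active_in <- sum(sen$status == "active")
    pairs <- harmonize_all(sen, otab, cfg$ambiguity_window)
    n_harmonized <- sum(pairs$action != "excluded")
    audit[[length(audit) + 1]] <-
      .audit_row("harmonize", oid, n_active_in, n_harmonized,
                 detail = paste(
                   harmonization_audit(pairs) |>
                     filter(.data$action == "excluded") |>
                     mutate(lab = paste0(.data$exclusion_reason, "=", .data$n)) |>
                     pull(.data$lab),
                   collapse = ";"))

    # stage 7: Wald ratio + tiering
    res <- mr_wald(pairs, outcome_id = oid, se_method = cfg$se_method,
                   alpha = cfg$alpha)
    res <- left_join(res,
                     select(sen, metabolite = "metabolite_id", "gene",
                            "r2", "f_stat"),
                     by = "metabolite")
    audit[[length(audit) + 1]] <-
      .audit_row("wald_ratio", oid, n_harmonized, nrow(res),
                 detail = paste0("n_tests=", nrow(res)))

    # stage 8: power
    n_total_o <- suppressWarnings(max(otab$n, na.rm = TRUE))
    n_cases_o <- suppressWarnings(max(otab$n_cases, na.rm = TRUE))
    if (is.finite(n_total_o) && is.finite(n_cases_o) && nrow(res) > 0) {
      power_tbls[[oid]] <- power_table(
        tibble(outcome_id = oid, n_total = n_total_o, n_cases = n_cases_o),
        res |> transmute(metabolite_id = .data$metabolite, r2 = .data$r2),
        or_targets = cfg$power_or, alpha = cfg$alpha
      )
    }

    results[[oid]] <- res
    sen$outcome_id <- oid
    sentinel_tbls[[oid]] <- sen
    if (nrow(pairs) > 0) pairs$outcome_id <- oid
    pair_tbls[[oid]] <- pairs
  }

  all_results <- bind_rows(results)

  # stage 9: drug-annotation join on significant/suggestive hits
  drug_annotated <- if (!is.null(drugs) && nrow(all_results) > 0) {
    drug_join(all_results, drugs)
  } else {
    NULL
  }

  structure(
    list(
      results = all_results,
      sentinels = bind_rows(sentinel_tbls),
      pairs = bind_rows(pair_tbls),
      audit = bind_rows(audit),
      instrument_strength = sentinels0 |>
        filter(.data$status != "uninstrumented") |>
        select("metabolite_id", "rsid", "gene", "r2", "f_stat", "weak_flag",
               "n", "status"),
      power = bind_rows(power_tbls),
      drug_annotations = drug_annotated,
      validation = c(list(exposure = vrep_exp), vreps_out),
      config = cfg,
      manifest = list(
        seed = cfg$seed,
        n_metabolites = n_met,
        outcomes = names(outcomes),
        timestamp_free = TRUE,
        config_hash = rlang::hash(cfg)
      )
    ),
    class = "mr_screen"
  )
}

#' Join significant and suggestive hits to drug annotations
#'
#' Each significant or suggestive metabolite is joined to the drug rows of
#' its effector gene, preserving the role flags (antagonist, agonist,
#' substrate, inhibitor, inducer). Metabolites with no drug entries pass
#' through unannotated (one row, `NA` drug fields). Re-joining an already
#' annotated table is the identity.
#'
#' @param results MR result tibble with `metabolite`, `gene`, `tier`.
#' @param drugs Drug table keyed by `effector_gene` (see
#'   [default_drug_table()]).
#' @return Tibble of hits with drug columns appended.
#' @export
drug_join <- function(results, drugs) {
  if ("drugbank_id" %in% names(results)) {
    return(results)  # already annotated; joining again adds nothing
  }
  hits <- filter(results, .data$tier %in% c("significant", "suggestive"))
  if (nrow(hits) == 0) {
    return(mutate(hits, drugbank_id = character(0), drug_name = character(0),
                  relation = character(0)))
  }
  drugs <- as_tibble(drugs)
  left_join(hits,
            select(drugs, -any_of(c("metabolite", "protein_type"))),
            by = c(gene = "effector_gene"),
            relationship = "many-to-many")
}

#' Consistency checks for published single-sentinel estimates
#'
#' Re-derives each reported odds ratio and p-value from its reported
#' confidence interval via [ci_consistency()] (a normal-theory CI is
#' symmetric on the log scale, so the bounds imply the OR, its SE, and the
#' p-value) and checks agreement at two-decimal rounding tolerance. The
#' packaged fixture carries the headline metabolite-leukemia associations
#' this screen design reported.
#'
#' @param path Fixture path; defaults to the packaged
#'   `extdata/reported_associations.tsv`.
#' @param tol Pass tolerance on the implied vs printed OR.
#' @return Tibble with the fixture columns plus `implied_or`,
#'   `implied_se`, `implied_p`, `pass`.
#' @export
check_reported_estimates <- function(path = NULL, tol = 0.005) {
  if (is.null(path)) {
    path <- system.file("extdata", "reported_associations.tsv",
                        package = "sentinelmr")
  }
  fix <- readr::read_tsv(path, col_types = "ccddddd", progress = FALSE)
  diag <- ci_consistency(fix$or, fix$ci_low, fix$ci_high, tol = tol)
  bind_cols(fix, select(diag, -"or_printed"))
}

# ---- methods on the screen object -----------------------------------------

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("<mr_screen> %d metabolites x %d outcomes, %d tests\n",
              x$manifest$n_metabolites, length(x$manifest$outcomes),
              nrow(x$results)))
  tiers <- count(x$results, .data$tier)
  for (i in seq_len(nrow(tiers))) {
    cat(sprintf("  %-12s %d\n", tiers$tier[i], tiers$n[i]))
  }
  invisible(x)
}

#' Tidy the per-test results of an MR screen
#'
#' @param x An `mr_screen` object.
#' @param ... Unused.
#' @return The results tibble (one row per metabolite-outcome test).
#' @method tidy mr_screen
#' @export
tidy.mr_screen <- function(x, ...) x$results

#' One-row summary of an MR screen
#'
#' @param x An `mr_screen` object.
#' @param ... Unused.
#' @return Tibble with metabolite, test, and tier counts.
#' @method glance mr_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble(
    n_metabolites = x$manifest$n_metabolites,
    n_outcomes = length(x$manifest$outcomes),
    n_tests = nrow(x$results),
    n_significant = sum(x$results$tier == "significant"),
    n_suggestive = sum(x$results$tier == "suggestive"),
    min_f = suppressWarnings(min(x$instrument_strength$f_stat, na.rm = TRUE)),
    max_f = suppressWarnings(max(x$instrument_strength$f_stat, na.rm = TRUE))
  )
}

#' Write the result tables of a screen to a directory
#'
#' @param x An `mr_screen` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(x, dir) {
  stopifnot(inherits(x, "mr_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(x$results) > 0) {
    write_results(x$results, file.path(dir, "mr_results.tsv"))
  }
  readr::write_tsv(x$audit, file.path(dir, "audit.tsv"), progress = FALSE)
  readr::write_tsv(x$instrument_strength,
                   file.path(dir, "instrument_strength.tsv"), progress = FALSE)
  if (!is.null(x$power) && nrow(x$power) > 0) {
    readr::write_tsv(x$power, file.path(dir, "power.tsv"), progress = FALSE)
  }
  if (!is.null(x$drug_annotations) && nrow(x$drug_annotations) > 0) {
    readr::write_tsv(x$drug_annotations, file.path(dir, "drug_annotations.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
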