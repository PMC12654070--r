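#' Read variant-level GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file into the canonical
#' variant-level layout used throughout the package: one row per variant
#' with columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `n_cases` and `trait_id`. Source files
#' rarely use these names, so a `dialect` mapping translates source column
#' names onto the canonical ones explicitly — never by guessing.
#'
#' Rows that fail content validation (non-A/C/G/T alleles, out-of-range
#' values, duplicates, missing required fields) are flagged, not dropped:
#' the returned table carries a logical `valid` column and a character
#' `exclusion_reason`, and row order is preserved.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Named character vector mapping canonical names to source
#'   column names, e.g. `c(rsid = "SNP", beta = "Effect")`. Canonical names
#'   not listed are assumed to appear verbatim in the header. `NULL` means
#'   the file already uses canonical names.
#' @param trait_kind Either `"exposure_quantitative"` (SD-scaled
#'   quantitative trait; effect-allele frequency is required per row) or
#'   `"outcome_binary"` (log-odds scale; `eaf` may be missing, which only
#'   bars palindromic resolution downstream).
#' @param trait_id Optional trait identifier applied to every row when the
#'   file does not carry a `trait_id` column.
#' @param provenance Free-text source label stored as an attribute.
#'
#' @return A tibble of class `summary_stats` with the canonical columns
#'   plus `valid` and `exclusion_reason`, and attributes `trait_kind` and
#'   `provenance`.
#' @seealso [validate_summary_stats()], [validation_report()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
#'   "rs1\tA\tG\t0.21\t0.31\t0.03\t1e-20\t8299"
#' ), tf)
#' read_summary_stats(tf, trait_id = "met_001")
read_summary_stats <- function(path,
                               dialect = NULL,
                               trait_kind = c("exposure_quantitative", "outcome_binary"),
                               trait_id = NULL,
                               provenance = NULL) {
  trait_kind <- match.arg(trait_kind)
  if (!file.exists(path)) {
    abort(paste0("cannot read summary-statistics file: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  # resolve dialect: canonical name -> source header
  map <- setNames(.canonical_cols, .canonical_cols)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), .canonical_cols)
    if (length(bad) > 0) {
      abort(paste0("dialect maps unknown canonical column(s): ",
                   paste(bad, collapse = ", ")))
    }
    map[names(dialect)] <- unname(dialect)
  }
  need <- .required_cols
  if (trait_kind == "exposure_quantitative") need <- c(need, "eaf", "n")
  missing_src <- need[!map[need] %in% names(raw)]
  if (length(missing_src) > 0) {
    abort(paste0("summary-statistics file lacks required column(s): ",
                 paste(missing_src, collapse = ", "),
                 " (expected source header(s): ",
                 paste(map[missing_src], collapse = ", "), ")"))
  }

  pick <- function(canon) {
    src <- map[[canon]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tbl <- tibble(
    rsid = pick("rsid"),
    chrom = pick("chrom"),
    pos = num(pick("pos")),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    eaf = num(pick("eaf")),
    beta = num(pick("beta")),
    se = num(pick("se")),
    pval = num(pick("pval")),
    n = num(pick("n")),
    n_cases = num(pick("n_cases")),
    trait_id = if (!is.null(trait_id)) as.character(trait_id) else pick("trait_id")
  )
  out <- validate_summary_stats(tbl, trait_kind = trait_kind)
  attr(out, "provenance") <- provenance
  out
}

#' Validate a summary-statistics table
#'
#' Applies the row-level content rules and attaches `valid` /
#' `exclusion_reason` flags. Validation reports rather than throws: problem
#' rows stay in the table with a single primary reason code each, drawn
#' from `missing_field`, `non_acgt`, `bad_range`, `duplicate` (checked in
#' that order of precedence). Re-validating a validated table changes
#' nothing (idempotence).
#'
#' Rules: required fields complete; both alleles single characters in
#' A/C/G/T and distinct (indels and multi-character alleles are flagged
#' `non_acgt`, the "non-canonical variant" filter); `eaf` in \[0, 1\];
#' `se > 0`; `pval` in (0, 1\]; `n > 0` where present; `(rsid, trait_id)`
#' unique (later occurrences flagged). For exposure tables `eaf` is
#' required; for binary outcomes a missing `eaf` is permitted here and only
#' prevents palindromic resolution during harmonization.
#'
#' @param tbl A data frame with the canonical columns (missing canonical
#'   columns are added as `NA`).
#' @inheritParams read_summary_stats
#' @return A `summary_stats` tibble with `valid` and `exclusion_reason`.
#' @export
validate_summary_stats <- function(tbl,
                                   trait_kind = c("exposure_quantitative", "outcome_binary")) {
  trait_kind <- match.arg(trait_kind)
  tbl <- as_tibble(tbl)
  for (col in .canonical_cols) {
    if (!col %in% names(tbl)) {
      tbl[[col]] <- if (col %in% c("rsid", "chrom", "effect_allele", "other_allele", "trait_id")) {
        NA_character_
      } else {
        NA_real_
      }
    }
  }
  tbl$valid <- NULL
  tbl$exclusion_reason <- NULL

  req <- .required_cols
  if (trait_kind == "exposure_quantitative") req <- c(req, "eaf", "n")
  missing_field <- Reduce(`|`, lapply(req, function(col) {
    x <- tbl[[col]]
    is.na(x) | (is.character(x) & !is.na(x) & x == "")
  }))

  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  non_acgt <- !(ok_allele(tbl$effect_allele) & ok_allele(tbl$other_allele) &
                  tbl$effect_allele != tbl$other_allele)

  bad_range <- (!is.na(tbl$eaf) & (tbl$eaf < 0 | tbl$eaf > 1)) |
    (!is.na(tbl$se) & tbl$se <= 0) |
    (!is.na(tbl$pval) & (tbl$pval <= 0 | tbl$pval > 1)) |
    (!is.na(tbl$n) & tbl$n <= 0) |
    (!is.na(tbl$pos) & tbl$pos < 1)

  key <- paste(tbl$rsid, tbl$trait_id, sep = "\r")
  duplicate <- duplicated(key) & !is.na(tbl$rsid)

  reason <- rep(NA_character_, nrow(tbl))
  reason[duplicate] <- "duplicate"
  reason[bad_range] <- "bad_range"
  reason[non_acgt] <- "non_acgt"
  reason[missing_field] <- "missing_field"

  tbl$valid <- is.na(reason)
  tbl$exclusion_reason <- reason
  class(tbl) <- c("summary_stats", class(tbl))
  attr(tbl, "trait_kind") <- trait_kind
  tbl
}

#' Summarize validation flags as an accounting report
#'
#' Collapses the row-level flags of a validated table into a report that
#' satisfies the accounting identity `n_input = n_valid + nrow(exclusions)`
#' exactly, with one primary reason code per excluded row.
#'
#' @param tbl A `summary_stats` tibble (output of
#'   [validate_summary_stats()] or [read_summary_stats()]).
#' @return An object of class `validation_report`: a list with `n_input`,
#'   `n_valid`, and `exclusions` (tibble of `rsid`, `trait_id`, `reason`).
#'   [tidy()] returns the exclusions, [glance()] the counts.
#' @export
validation_report <- function(tbl) {
  if (!"valid" %in% names(tbl)) {
    tbl <- validate_summary_stats(tbl)
  }
  exclusions <- tbl |>
    filter(!.data$valid) |>
    transmute(rsid = .data$rsid, trait_id = .data$trait_id,
              reason = .data$exclusion_reason)
  structure(
    list(n_input = nrow(tbl), n_valid = sum(tbl$valid), exclusions = exclusions),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d rows: %d valid, %d excluded\n",
              x$n_input, x$n_valid, nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    print(count(x$exclusions, .data$reason))
  }
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$exclusions

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_valid = x$n_valid,
         n_excluded = nrow(x$exclusions))
}

# canonical result columns written to disk
.result_cols <- c(
  "metabolite", "outcome", "rsid", "gene", "beta", "se", "or", "ci_low",
  "ci_high", "pval", "tier", "n_snv", "r2", "f_stat", "proxy_rsid", "proxy_r2"
)

#' Write and read Wald-ratio screen results
#'
#' `write_results()` writes one tab-separated row per metabolite-outcome
#' test, with `n_snv = 1` for every row (single-sentinel design). Numeric
#' columns round-trip through `read_results()` to at least 12 significant
#' digits.
#'
#' @param results Non-empty data frame of MR results; columns beyond the
#'   canonical ones are preserved after the canonical block.
#' @param path Output (or input) file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("refusing to write an empty results table")
  }
  results <- as_tibble(results)
  if (!"beta" %in% names(results) && "beta_mr" %in% names(results)) {
    results <- rename(results, beta = "beta_mr")
  }
  if (!"se" %in% names(results) && "se_mr" %in% names(results)) {
    results <- rename(results, se = "se_mr")
  }
  if (!"n_snv" %in% names(results)) results$n_snv <- 1L
  for (col in .result_cols) {
    if (!col %in% names(results)) {
      results[[col]] <- if (col %in% c("metabolite", "outcome", "rsid", "gene",
                                       "tier", "proxy_rsid")) NA_character_ else NA_real_
    }
  }
  results <- select(results, all_of(.result_cols), everything())
  out <- tryCatch(
    readr::write_tsv(results, path, progress = FALSE),
    error = function(e) abort(paste0("cannot write results to ", path, ": ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    metabolite = readr::col_character(),
    outcome = readr::col_character(),
    rsid = readr::col_character(),
    gene = readr::col_character(),
    tier = readr::col_character(),
    proxy_rsid = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
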