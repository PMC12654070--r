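#' Variance explained by a single variant
#'
#' For an SD-scaled quantitative trait, the variance explained by one
#' biallelic variant is `R^2 = 2 * eaf * (1 - eaf) * beta^2`, i.e. the
#' per-allele effect squared times the Hardy-Weinberg genotype variance.
#' Values are clamped to \[0, 1).
#'
#' @param beta Per-allele effect in SD units of the exposure.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @return Numeric vector of R-squared values.
#' @export
#' @examples
#' variance_explained(1, 0.5)    # 0.5
#' variance_explained(0.3, 0.1)  # 0.0162
variance_explained <- function(beta, eaf) {
  if (any(is.na(eaf)) || any(eaf <= 0 | eaf >= 1)) {
    abort("eaf must lie strictly inside (0, 1); monomorphic variants have no R^2")
  }
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  pmin(pmax(r2, 0), 1 - .Machine$double.eps)
}

#' First-stage F statistic
#'
#' Instrument strength for `k` instruments explaining `r2` of the exposure
#' variance in a GWAS of `n` individuals:
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))`. With `k = 1` this reduces
#' to `R^2 (n - 2) / (1 - R^2)`. F is reported alongside estimates and
#' flagged (not filtered) when at or below the conventional weak-instrument
#' bar of 10.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Exposure GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments (default 1, the single-sentinel setting).
#' @return Numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(0.1, 1001)  # 111
f_statistic <- function(r2, n, k = 1) {
  if (any(is.na(r2)) || any(r2 < 0 | r2 >= 1)) {
    abort("r2 must lie in [0, 1)")
  }
  if (any(n <= k + 1)) {
    abort("n must exceed k + 1")
  }
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Select one sentinel instrument per metabolite
#'
#' Among each metabolite's pre-declared independent signals, keeps the
#' genome-wide significant candidate (`pval < p_threshold`) with the
#' largest variance explained; ties are broken by smaller p-value, then
#' lexicographic rsid. Metabolites with no candidate below the threshold
#' are reported as `uninstrumented`, never raised as errors. The result is
#' a one-to-one mapping of instrumented metabolites to sentinels.
#'
#' @param candidates Tibble of exposure-side association records with at
#'   least `trait_id`, `rsid`, `beta`, `se`, `eaf`, `pval`, `n`; optional
#'   `gene`, `chrom`, `pos`, and `r2` (computed from `beta` and `eaf` via
#'   [variance_explained()] when absent).
#' @param p_threshold Genome-wide significance threshold (default `5e-8`).
#' @return Tibble with one row per metabolite: `metabolite_id`, record
#'   fields, `r2`, `f_stat`, `weak_flag` (`f_stat <= 10`), `status`
#'   (`"active"` or `"uninstrumented"`), and empty proxy fields.
#' @export
select_sentinels <- function(candidates, p_threshold = 5e-8) {
  candidates <- as_tibble(candidates)
  if (!"gene" %in% names(candidates)) candidates$gene <- NA_character_
  if (!"chrom" %in% names(candidates)) candidates$chrom <- NA_character_
  if (!"pos" %in% names(candidates)) candidates$pos <- NA_real_
  if (!"r2" %in% names(candidates)) {
    candidates$r2 <- variance_explained(candidates$beta, candidates$eaf)
  }
  if ("valid" %in% names(candidates)) {
    candidates <- filter(candidates, .data$valid)
  }

  chosen <- candidates |>
    filter(.data$pval < p_threshold) |>
    arrange(.data$trait_id, desc(.data$r2), .data$pval, .data$rsid) |>
    group_by(.data$trait_id) |>
    slice(1) |>
    ungroup()

  uninstrumented <- setdiff(unique(candidates$trait_id), chosen$trait_id)

  out <- chosen |>
    transmute(
      metabolite_id = .data$trait_id,
      rsid = .data$rsid,
      gene = .data$gene,
      chrom = .data$chrom,
      pos = .data$pos,
      effect_allele = .data$effect_allele,
      other_allele = .data$other_allele,
      eaf = .data$eaf,
      beta = .data$beta,
      se = .data$se,
      pval = .data$pval,
      n = .data$n,
      r2 = .data$r2,
      f_stat = f_statistic(.data$r2, .data$n),
      weak_flag = .data$f_stat <= 10,
      status = "active",
      drop_reason = NA_character_,
      proxy_rsid = NA_character_,
      proxy_r2 = NA_real_,
      proxy_allele_map = NA_character_
    )
  if (length(uninstrumented) > 0) {
    out <- bind_rows(out, tibble(metabolite_id = uninstrumented,
                                 status = "uninstrumented"))
  }
  # a shared rsid instrumenting two metabolites is legitimate input; flag it
  shared <- out$rsid[!is.na(out$rsid)][duplicated(out$rsid[!is.na(out$rsid)])]
  out$shared_rsid_flag <- !is.na(out$rsid) & out$rsid %in% shared
  arrange(out, .data$metabolite_id)
}

#' Default pleiotropy-prone exclusion regions
#'
#' Closed genomic intervals removed from the instrument set because they
#' harbor broadly pleiotropic metabolite loci: the FADS cluster
#' (chr11:61,300,000-61,900,000) and the major histocompatibility complex
#' (chr6:25,000,000-34,000,000), GRCh37 conventions. Both are configurable.
#'
#' @return Tibble with columns `region`, `chrom`, `start`, `end`.
#' @export
default_exclusion_regions <- function() {
  tibble(
    region = c("MHC", "FADS"),
    chrom = c("6", "11"),
    start = c(25e6, 61.3e6),
    end = c(34e6, 61.9e6)
  )
}

#' Remove sentinels inside excluded genomic regions
#'
#' Sentinels whose position falls inside any exclusion interval (closed on
#' both ends) are set to status `dropped_region` with the region name as
#' the audit reason. An empty region list is the identity.
#'
#' @param sentinels Sentinel tibble from [select_sentinels()].
#' @param regions Tibble of closed intervals (`region`, `chrom`, `start`,
#'   `end`); default [default_exclusion_regions()].
#' @return The sentinel tibble with updated `status` / `drop_reason`.
#' @export
apply_region_exclusions <- function(sentinels, regions = default_exclusion_regions()) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(sentinels)
  }
  hit_region <- function(chrom, pos) {
    if (is.na(chrom) || is.na(pos)) return(NA_character_)
    hit <- regions$chrom == as.character(chrom) &
      regions$start <= pos & pos <= regions$end
    if (any(hit)) regions$region[which(hit)[1]] else NA_character_
  }
  hits <- map_chr(seq_len(nrow(sentinels)),
                  function(i) hit_region(sentinels$chrom[i], sentinels$pos[i]))
  drop <- !is.na(hits) & sentinels$status == "active"
  sentinels$status[drop] <- "dropped_region"
  sentinels$drop_reason[drop] <- paste0("region:", hits[drop])
  sentinels
}

# parse "A=C,G=T" into named map: sentinel allele -> proxy allele
.parse_allele_map <- function(s) {
  if (is.na(s) || s == "") return(NULL)
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
}

.invert_allele_map <- function(m) setNames(names(m), unname(m))

#' Substitute LD proxies for sentinels missing from an outcome GWAS
#'
#' A sentinel present in the outcome file keeps the identity mapping. For
#' an absent sentinel, the outcome-present variant with the highest LD
#' r-squared strictly above `r2_min` is substituted (ties broken by
#' lexicographic rsid) and its allele correspondence is carried forward so
#' harmonization can operate on translated alleles. With no eligible
#' proxy, the sentinel's status becomes `no_outcome_match`.
#'
#' @param sentinels Sentinel tibble ([select_sentinels()] output).
#' @param outcome_rsids Character vector of rsids present in the outcome
#'   summary statistics.
#' @param ld LD table: tibble with `rsid_a`, `rsid_b`, `r2`, and
#'   `allele_map` (comma-separated `a_allele=b_allele` pairs); treated as
#'   symmetric in (a, b).
#' @param r2_min Strict lower bound on proxy r-squared (default 0.8).
#' @return The sentinel tibble with `proxy_rsid`, `proxy_r2`,
#'   `proxy_allele_map` filled where a proxy is used, and `status` set to
#'   `no_outcome_match` where none exists.
#' @export
find_proxies <- function(sentinels, outcome_rsids, ld = NULL, r2_min = 0.8) {
  ld_long <- if (is.null(ld) || nrow(ld) == 0) {
    tibble(sentinel = character(), proxy = character(), r2 = numeric(),
           allele_map = character())
  } else {
    bind_rows(
      transmute(ld, sentinel = .data$rsid_a, proxy = .data$rsid_b,
                r2 = .data$r2, allele_map = .data$allele_map),
      transmute(ld, sentinel = .data$rsid_b, proxy = .data$rsid_a,
                r2 = .data$r2,
                allele_map = map_chr(.data$allele_map, function(s) {
                  m <- .parse_allele_map(s)
                  if (is.null(m)) return(NA_character_)
                  inv <- .invert_allele_map(m)
                  paste(paste0(names(inv), "=", unname(inv)), collapse = ",")
                }))
    )
  }

  for (i in seq_len(nrow(sentinels))) {
    if (sentinels$status[i] != "active") next
    rs <- sentinels$rsid[i]
    if (rs %in% outcome_rsids) next
    cand <- ld_long |>
      filter(.data$sentinel == rs, .data$proxy %in% outcome_rsids,
             .data$r2 > r2_min) |>
      arrange(desc(.data$r2), .data$proxy)
    if (nrow(cand) == 0) {
      sentinels$status[i] <- "no_outcome_match"
      sentinels$drop_reason[i] <- "no_outcome_match"
    } else {
      sentinels$proxy_rsid[i] <- cand$proxy[1]
      sentinels$proxy_r2[i] <- cand$r2[1]
      sentinels$proxy_allele_map[i] <- cand$allele_map[1]
    }
  }
  sentinels
}

.flagged_domains <- c("neoplastic", "immune", "hematologic", "cardiometabolic")

#' Screen sentinels against prior trait associations (drop list)
#'
#' Offline pleiotropy screen against a variant-to-trait annotation table
#' (a snapshot standing in for catalog queries). A sentinel — or the proxy
#' actually carried into the outcome — with any genome-wide significant
#' annotation (`pval < gw_threshold`) in a flagged domain (neoplastic,
#' immune, hematologic, cardiometabolic) is dropped as
#' `dropped_pleiotropy`; one genome-wide significant for the target
#' outcome itself is dropped as `dropped_outcome_gwas` (checked first).
#' Retained (non-triggering) annotations are attached for reporting. The
#' screen is a pure function of its inputs: re-running changes nothing.
#'
#' @param sentinels Sentinel tibble (after [find_proxies()]).
#' @param annotations Tibble with `rsid`, `trait`, `domain` (one of
#'   neoplastic, immune, hematologic, cardiometabolic, metabolite, other),
#'   `pval`.
#' @param outcome_trait Label of the target outcome; annotations whose
#'   `trait` matches it case-insensitively trigger `dropped_outcome_gwas`.
#' @param gw_threshold Genome-wide significance threshold (default `5e-8`).
#' @param flagged_domains Domains that trigger the pleiotropy drop.
#' @return The sentinel tibble with `status`, `drop_reason`, and a
#'   `retained_annotations` column (semicolon-separated trait labels).
#' @export
screen_pleiotropy <- function(sentinels, annotations, outcome_trait,
                              gw_threshold = 5e-8,
                              flagged_domains = .flagged_domains) {
  annotations <- as_tibble(annotations)
  bad_domain <- setdiff(unique(annotations$domain),
                        c(.flagged_domains, "metabolite", "other"))
  if (length(bad_domain) > 0) {
    abort(paste0("annotation domains outside the fixed vocabulary: ",
                 paste(bad_domain, collapse = ", ")))
  }
  sentinels$retained_annotations <- NA_character_
  for (i in seq_len(nrow(sentinels))) {
    if (sentinels$status[i] != "active") next
    rs <- if (!is.na(sentinels$proxy_rsid[i])) sentinels$proxy_rsid[i] else sentinels$rsid[i]
    ann <- filter(annotations, .data$rsid == rs)
    if (nrow(ann) == 0) next
    gw <- filter(ann, .data$pval < gw_threshold)
    outcome_hit <- filter(gw, tolower(.data$trait) == tolower(outcome_trait))
    pleio_hit <- filter(gw, .data$domain %in% flagged_domains)
    if (nrow(outcome_hit) > 0) {
      sentinels$status[i] <- "dropped_outcome_gwas"
      sentinels$drop_reason[i] <- paste0("outcome_gwas:", outcome_hit$trait[1])
    } else if (nrow(pleio_hit) > 0) {
      sentinels$status[i] <- "dropped_pleiotropy"
      sentinels$drop_reason[i] <- paste0("pleiotropy:",
                                         paste(unique(pleio_hit$domain), collapse = "+"))
    } else {
      sentinels$retained_annotations[i] <- paste(unique(ann$trait), collapse = ";")
    }
  }
  sentinels
}
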