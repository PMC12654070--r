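exp_rec <- function(...) make_record(...)
out_rec <- function(...) make_record(trait_id = "CLL", n = 50000,
                                     n_cases = 100, se = 0.1, ...)

test_that("non-palindromic alignment follows the allele labels", {
  # direct match: no action
  h <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G",
                              beta = 0.5, eaf = 0.2),
                      out_rec(effect_allele = "A", other_allele = "G",
                              beta = 0.2, eaf = 0.2))
  expect_equal(h$action, "none")
  expect_equal(h$outcome_beta, 0.2)

  # swapped alleles: beta negated and eaf complemented together
  h2 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G"),
                       out_rec(effect_allele = "G", other_allele = "A",
                               beta = 0.2, eaf = 0.8))
  expect_equal(h2$action, "swap_flip")
  expect_equal(h2$outcome_beta, -0.2)
  expect_equal(h2$outcome_eaf, 0.2)

  # reverse-complement: relabel only
  h3 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G"),
                       out_rec(effect_allele = "T", other_allele = "C",
                               beta = 0.2, eaf = 0.2))
  expect_equal(h3$action, "strand_flip")
  expect_equal(h3$outcome_beta, 0.2)
  expect_equal(h3$effect_allele, "A")

  # reverse-complement and swapped: relabel plus sign/frequency flip
  h4 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G"),
                       out_rec(effect_allele = "C", other_allele = "T",
                               beta = 0.2, eaf = 0.8))
  expect_equal(h4$action, "strand_flip_and_swap")
  expect_equal(h4$outcome_beta, -0.2)
  expect_equal(h4$outcome_eaf, 0.2)

  # irreconcilable alleles
  h5 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G"),
                       out_rec(effect_allele = "A", other_allele = "C"))
  expect_equal(h5$action, "excluded")
  expect_equal(h5$exclusion_reason, "allele_mismatch")
})

test_that("palindromic pairs are resolved by allele-frequency concordance", {
  # frequencies on opposite sides of 0.5 indicate opposite strand labels:
  # align with beta negated and eaf complemented
  h <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "T",
                              eaf = 0.10),
                      out_rec(effect_allele = "A", other_allele = "T",
                              beta = 0.2, eaf = 0.88))
  expect_equal(h$action, "strand_flip_and_swap")
  expect_equal(h$outcome_beta, -0.2)
  expect_equal(h$outcome_eaf, 0.12)

  # concordant frequencies with matching labels: identity
  h2 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "T",
                               eaf = 0.10),
                       out_rec(effect_allele = "A", other_allele = "T",
                               beta = 0.2, eaf = 0.12))
  expect_equal(h2$action, "none")
  expect_equal(h2$outcome_beta, 0.2)

  # frequency near one half is unresolvable
  h3 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "T",
                               eaf = 0.10),
                       out_rec(effect_allele = "A", other_allele = "T",
                               eaf = 0.50))
  expect_equal(h3$action, "excluded")
  expect_equal(h3$exclusion_reason, "palindromic_ambiguous")

  # missing outcome frequency is unresolvable for palindromes only
  h4 <- harmonize_pair(exp_rec(effect_allele = "C", other_allele = "G",
                               eaf = 0.2),
                       out_rec(effect_allele = "C", other_allele = "G",
                               eaf = NA_real_))
  expect_equal(h4$exclusion_reason, "palindromic_ambiguous")
  h5 <- harmonize_pair(exp_rec(effect_allele = "A", other_allele = "G"),
                       out_rec(effect_allele = "A", other_allele = "G",
                               eaf = NA_real_))
  expect_equal(h5$action, "none")
})

test_that("non-ACGT alleles are excluded, never raised", {
  h <- harmonize_pair(exp_rec(effect_allele = "I"), out_rec())
  expect_equal(h$exclusion_reason, "non_acgt")
  h2 <- harmonize_pair(exp_rec(), out_rec(other_allele = "AT"))
  expect_equal(h2$exclusion_reason, "non_acgt")
})

test_that("every ordered allele configuration maps to exactly one action", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  actions <- c("none", "swap_flip", "strand_flip", "strand_flip_and_swap",
               "excluded")
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      h <- harmonize_pair(
        exp_rec(effect_allele = pairs$ea[i], other_allele = pairs$oa[i],
                eaf = 0.2),
        out_rec(effect_allele = pairs$ea[j], other_allele = pairs$oa[j],
                beta = 0.2, eaf = 0.25)
      )
      expect_true(h$action %in% actions)
      expect_equal(is.na(h$exclusion_reason), h$action != "excluded")
      if (h$action != "excluded") {
        # aligned to the exposure's alleles
        expect_equal(h$effect_allele, pairs$ea[i])
        expect_equal(h$other_allele, pairs$oa[i])
      }
    }
  }
})

test_that("harmonization is an involution and swap_flip is its own inverse", {
  set.seed(7)
  bases_pairs <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  for (ap in bases_pairs) {
    for (pres in c("none", "swap", "strand", "both")) {
      ex <- exp_rec(effect_allele = ap[1], other_allele = ap[2], eaf = 0.2)
      ou <- out_rec(effect_allele = ap[1], other_allele = ap[2],
                    beta = 0.25, eaf = 0.22)
      ou_p <- sentinelmr:::.present_record(tibble::as_tibble(ou), pres)
      h1 <- harmonize_pair(ex, ou_p)
      if (h1$action == "excluded") next
      # harmonization recovers the originally aligned numbers
      expect_equal(h1$outcome_beta, 0.25, tolerance = 1e-12)
      expect_equal(h1$outcome_eaf, 0.22, tolerance = 1e-12)
      # re-harmonizing the harmonized record is the identity
      aligned <- out_rec(effect_allele = h1$effect_allele,
                         other_allele = h1$other_allele,
                         beta = h1$outcome_beta, eaf = h1$outcome_eaf)
      h2 <- harmonize_pair(ex, aligned)
      expect_equal(h2$action, "none")
      expect_equal(h2$outcome_beta, h1$outcome_beta)
      expect_equal(h2$outcome_eaf, h1$outcome_eaf)
    }
  }

  # applying the swap transform twice restores the record exactly
  rec <- tibble::as_tibble(out_rec(beta = 0.3, eaf = 0.41))
  rec2 <- sentinelmr:::.present_record(
    sentinelmr:::.present_record(rec, "swap"), "swap")
  expect_equal(rec2, rec)
})

test_that("harmonize_all conserves sentinels and audits exclusions", {
  sen <- select_sentinels(make_table(list(
    make_record(rsid = "rs1", trait_id = "m1"),
    make_record(rsid = "rs2", trait_id = "m2", effect_allele = "A",
                other_allele = "T", eaf = 0.5),
    make_record(rsid = "rs3", trait_id = "m3", effect_allele = "C",
                other_allele = "T")
  )))
  sen <- find_proxies(sen, outcome_rsids = c("rs1", "rs2", "rs3"), ld = NULL)
  outcomes <- validate_summary_stats(make_table(list(
    out_rec(rsid = "rs1", trait_id = "CLL"),
    out_rec(rsid = "rs2", trait_id = "CLL", effect_allele = "A",
            other_allele = "T", eaf = 0.5),
    out_rec(rsid = "rs3", trait_id = "CLL", effect_allele = "C",
            other_allele = "T")
  )), trait_kind = "outcome_binary")
  pairs <- harmonize_all(sen, outcomes)
  expect_equal(nrow(pairs), 3)  # inputs = harmonized + excluded
  audit <- harmonization_audit(pairs)
  expect_equal(sum(audit$n), 3)
  expect_equal(pairs$exclusion_reason[pairs$rsid == "rs2"],
               "palindromic_ambiguous")
  expect_equal(sum(pairs$action != "excluded"), 2)
})

test_that("proxy records harmonize through the LD allele correspondence", {
  sen <- select_sentinels(make_table(list(
    make_record(rsid = "rs1", effect_allele = "A", other_allele = "G",
                eaf = 0.2)
  )))
  ld <- tibble::tibble(rsid_a = "rs1", rsid_b = "rsP", r2 = 0.9,
                       allele_map = "A=C,G=T")
  sen <- find_proxies(sen, outcome_rsids = "rsP", ld)
  # enumerate every presentation of the proxy outcome record; all must
  # recover the same aligned association
  base <- tibble::as_tibble(out_rec(rsid = "rsP", effect_allele = "C",
                                    other_allele = "T", beta = 0.3,
                                    eaf = 0.21))
  for (pres in c("none", "swap", "strand", "both")) {
    ou <- sentinelmr:::.present_record(base, pres)
    pairs <- harmonize_all(sen, validate_summary_stats(ou, "outcome_binary"))
    expect_equal(nrow(pairs), 1)
    expect_false(pairs$action == "excluded")
    expect_equal(pairs$outcome_beta, 0.3, tolerance = 1e-12)
    expect_equal(pairs$outcome_eaf, 0.21, tolerance = 1e-12)
    expect_equal(pairs$effect_allele, "A")
  }
})
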