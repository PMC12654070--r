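test_that("variance explained follows the Hardy-Weinberg closed form", {
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.3, 0.1), 2 * 0.09 * 0.09)
  expect_error(variance_explained(0.3, 0), "monomorphic")
  expect_error(variance_explained(0.3, 1), "monomorphic")
  # clamped below 1 even for absurd effects
  expect_lt(variance_explained(10, 0.5), 1)
})

test_that("closed-form R2 matches the sample R2 of a simulated cohort", {
  set.seed(42)
  n <- 1e5
  maf <- 0.1
  beta <- 0.3
  g <- rbinom(n, 2, maf)
  x <- beta * g + rnorm(n)
  x <- x / sd(x)  # SD-scale the trait
  fit <- summary(lm(x ~ g))
  # the per-allele effect of the scaled trait implies the closed-form R2
  r2_closed <- variance_explained(coef(fit)[2, 1], mean(g) / 2)
  expect_equal(r2_closed, fit$r.squared, tolerance = 0.01)
})

test_that("first-stage F has the conventional closed form and monotonicity", {
  expect_equal(f_statistic(0.1, 1001), 111)
  expect_equal(f_statistic(0, 1000), 0)
  expect_error(f_statistic(1, 1000), "r2")
  expect_error(f_statistic(0.1, 2), "n must exceed")
  # strictly increasing in r2 at fixed n, and in n at fixed r2 > 0
  r2 <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(f_statistic(r2, 5000)) > 0))
  ns <- seq(100, 10000, by = 100)
  expect_true(all(diff(f_statistic(0.05, ns)) > 0))
})

test_that("sentinel selection takes max R2 among genome-wide significant candidates", {
  cand <- sentinel_candidates()
  sel <- select_sentinels(cand)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$rsid, "rs2")  # R2 = 0.03 beats 0.01 and 0.02
  expect_equal(sel$status, "active")
  expect_equal(sel$f_stat, f_statistic(sel$r2, sel$n))

  # sub-threshold candidates are ineligible before any tie-break
  cand2 <- make_table(list(
    make_record(rsid = "rsA", pval = 1e-7),
    make_record(rsid = "rsB", pval = 1e-9)
  ))
  sel2 <- select_sentinels(cand2, p_threshold = 5e-8)
  expect_equal(sel2$rsid, "rsB")

  # equal R2, both significant: smaller p wins, then lexicographic rsid
  cand3 <- make_table(list(
    make_record(rsid = "rsZ", pval = 1e-10),
    make_record(rsid = "rsA", pval = 1e-12),
    make_record(rsid = "rsB", pval = 1e-12)
  ))
  expect_equal(select_sentinels(cand3)$rsid, "rsA")

  # nothing genome-wide significant: uninstrumented, not an error
  cand4 <- make_table(list(make_record(pval = 1e-6)))
  sel4 <- select_sentinels(cand4)
  expect_equal(sel4$status, "uninstrumented")
})

test_that("selection is one-to-one and flags an rsid shared by two metabolites", {
  cand <- make_table(list(
    make_record(rsid = "rs1", trait_id = "met_A"),
    make_record(rsid = "rs1", trait_id = "met_B"),
    make_record(rsid = "rs2", trait_id = "met_C")
  ))
  sel <- select_sentinels(cand)
  expect_equal(nrow(sel), 3)
  expect_equal(anyDuplicated(sel$metabolite_id), 0)
  expect_equal(sel$shared_rsid_flag, c(TRUE, TRUE, FALSE))
  expect_equal(sel$status, rep("active", 3))  # flagged, both retained
})

test_that("region exclusions drop MHC and FADS sentinels, keep the rest", {
  sen <- select_sentinels(make_table(list(
    make_record(rsid = "rs_mhc", trait_id = "m1", chrom = "6", pos = 30e6),
    make_record(rsid = "rs_fads", trait_id = "m2", chrom = "11", pos = 61.5e6),
    make_record(rsid = "rs_ok", trait_id = "m3", chrom = "1", pos = 30e6),
    make_record(rsid = "rs_edge", trait_id = "m4", chrom = "6", pos = 25e6)
  )))
  out <- apply_region_exclusions(sen)
  expect_equal(out$status[out$rsid == "rs_mhc"], "dropped_region")
  expect_equal(out$status[out$rsid == "rs_fads"], "dropped_region")
  expect_equal(out$status[out$rsid == "rs_ok"], "active")
  # intervals are closed: the boundary position is excluded
  expect_equal(out$status[out$rsid == "rs_edge"], "dropped_region")
  # empty region list is the identity
  expect_equal(apply_region_exclusions(sen, regions = NULL)$status,
               sen$status)
})

test_that("proxy lookup takes the best r2 strictly above the bound", {
  sen <- select_sentinels(make_table(list(make_record(rsid = "rs1"))))
  ld <- tibble::tibble(
    rsid_a = c("rs1", "rs1", "rs1"),
    rsid_b = c("rsP1", "rsP2", "rsP3"),
    r2 = c(0.85, 0.92, 0.80),
    allele_map = c("A=A,G=G", "A=C,G=T", "A=A,G=G")
  )
  got <- find_proxies(sen, outcome_rsids = c("rsP1", "rsP2", "rsP3"), ld)
  expect_equal(got$proxy_rsid, "rsP2")  # highest r2 wins
  expect_equal(got$proxy_r2, 0.92)

  # r2 = 0.80 exactly is not eligible (strict inequality)
  got2 <- find_proxies(sen, outcome_rsids = "rsP3", ld)
  expect_equal(got2$status, "no_outcome_match")

  # sentinel present in the outcome: identity, no proxy
  got3 <- find_proxies(sen, outcome_rsids = "rs1", ld)
  expect_equal(got3$status, "active")
  expect_true(is.na(got3$proxy_rsid))

  # LD table is symmetric: the sentinel may appear as rsid_b
  ld_rev <- tibble::tibble(rsid_a = "rsP9", rsid_b = "rs1", r2 = 0.9,
                           allele_map = "C=A,T=G")
  got4 <- find_proxies(sen, outcome_rsids = "rsP9", ld_rev)
  expect_equal(got4$proxy_rsid, "rsP9")
  expect_equal(got4$proxy_allele_map, "A=C,G=T")  # orientation inverted
})

test_that("the pleiotropy screen applies the drop rules exactly at threshold", {
  sen <- select_sentinels(make_table(list(
    make_record(rsid = "rs1", trait_id = "m1"),
    make_record(rsid = "rs2", trait_id = "m2"),
    make_record(rsid = "rs3", trait_id = "m3"),
    make_record(rsid = "rs4", trait_id = "m4")
  )))
  sen <- find_proxies(sen, outcome_rsids = paste0("rs", 1:4), ld = NULL)
  ann <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    trait = c("chronic lymphocytic leukemia", "LDL cholesterol",
              "LDL cholesterol", "plasma metabolite level"),
    domain = c("neoplastic", "cardiometabolic", "cardiometabolic",
               "metabolite"),
    pval = c(1e-9, 2e-8, 1e-7, 1e-30)
  )
  out <- screen_pleiotropy(sen, ann,
                           outcome_trait = "Chronic lymphocytic leukemia")
  expect_equal(out$status[out$rsid == "rs1"], "dropped_outcome_gwas")
  expect_equal(out$status[out$rsid == "rs2"], "dropped_pleiotropy")  # 2e-8 < 5e-8
  expect_equal(out$status[out$rsid == "rs3"], "active")              # 1e-7 kept
  expect_equal(out$status[out$rsid == "rs4"], "active")              # benign domain
  expect_match(out$retained_annotations[out$rsid == "rs4"], "metabolite level")

  # pure function: re-screening changes nothing, and every sentinel is
  # accounted for across kept and dropped categories
  out2 <- screen_pleiotropy(out, ann,
                            outcome_trait = "Chronic lymphocytic leukemia")
  expect_equal(out2$status, out$status)
  expect_equal(sort(out$metabolite_id), sort(sen$metabolite_id))

  expect_error(screen_pleiotropy(sen, dplyr::mutate(ann, domain = "misc"),
                                 outcome_trait = "x"),
               "vocabulary")
})
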