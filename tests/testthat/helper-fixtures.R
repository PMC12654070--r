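# shared in-code fixtures for the test suite

# canonical association record with overridable fields
make_record <- function(...) {
  rec <- list(
    rsid = "rs1", chrom = "1", pos = 1e6, effect_allele = "A",
    other_allele = "G", eaf = 0.2, beta = 0.3, se = 0.03, pval = 1e-20,
    n = 8299, n_cases = NA_real_, trait_id = "met_001"
  )
  utils::modifyList(rec, list(...))
}

make_table <- function(records) {
  dplyr::bind_rows(lapply(records, tibble::as_tibble))
}

# write a canonical TSV fixture and return its path
write_fixture <- function(tbl, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

# a tiny three-candidate exposure table for one metabolite
sentinel_candidates <- function() {
  make_table(list(
    make_record(rsid = "rs1", beta = sqrt(0.01 / (2 * 0.2 * 0.8)), eaf = 0.2),
    make_record(rsid = "rs2", beta = sqrt(0.03 / (2 * 0.2 * 0.8)), eaf = 0.2,
                pos = 2e6),
    make_record(rsid = "rs3", beta = sqrt(0.02 / (2 * 0.2 * 0.8)), eaf = 0.2,
                pos = 3e6)
  ))
}
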