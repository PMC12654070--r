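---
title: "Single-sentinel Mendelian randomization: model, design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sentinel Mendelian randomization: model, design, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentinelmr)
library(dplyr)
```

## The model

sentinelmr implements a two-sample Mendelian randomization (MR) screen in
which each quantitative exposure — a plasma metabolite, SD-scaled — is
instrumented by exactly one genetic variant, its *sentinel*: the
genome-wide significant variant (p < 5·10⁻⁸) with the largest variance
explained among the exposure's pre-declared independent signals. With one
instrument the causal effect of a 1-SD higher exposure on a binary
outcome's log-odds is estimated by the Wald ratio

$$\hat\beta_{MR} = \hat\beta_{GY} / \hat\beta_{GX},$$

where $\hat\beta_{GX}$ is the per-allele association with the exposure
(SD units, from a cohort of $n_{exp}$ individuals) and $\hat\beta_{GY}$
the per-allele log-odds association with the outcome in an independent
cohort. Results are reported as odds ratios per 1-SD genetically
predicted exposure with normal-theory confidence intervals.

The validity of the design rests on the three instrumental-variable
assumptions: the sentinel is strongly associated with its metabolite
(checked by R² and the first-stage F, never filtered on beyond the
genome-wide significance threshold), it is independent of confounders of
the metabolite-outcome relation, and it affects the outcome only through
the metabolite (exclusion restriction). The last assumption cannot be
tested with one instrument, which is why the pipeline includes an
explicit annotation-based drop list (below) and why multi-variant
diagnostics (IVW, Egger, weighted median, heterogeneity, Steiger
filtering) are deliberately out of scope: they require multiple
instruments per exposure.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `gw_sig` | 5e-8 | p-value | conventional genome-wide significance; used for instrument eligibility and the pleiotropy screen |
| `proxy_r2_min` | 0.8 | LD r² | proxies require r² strictly above 0.8 in a matched-ancestry reference; the best candidate wins, ties by rsid |
| `ambiguity_window` | [0.42, 0.58] | allele frequency | a palindromic variant whose frequency lies this close to 0.5 carries no usable strand information; a symmetric window near 0.5 operationalizes "adequate allele-frequency information" conservatively |
| `alpha` | 0.05 | level | family-wise level; also the suggestive threshold |
| `se_method` | first_order | — | `se_y / |b_x|`, the conventional single-variant Wald SE; `second_order` adds exposure-side uncertainty and is reported side-by-side |
| exclusion regions | MHC chr6:25–34 Mb; FADS chr11:61.3–61.9 Mb | GRCh37 | named pleiotropy-prone regions; the coordinates are conventions, hence configurable |
| power targets | OR 0.90, 1.20, 1.50 | odds ratio | prespecified effect sizes for the post hoc power table |

The Bonferroni threshold is never hard-coded: it is `alpha / n_tests`
with `n_tests` recomputed per outcome from the number of Wald tests
actually performed. With the canonical 83 metabolites it equals
`r signif(multiplicity_config(83)$bonferroni_threshold, 3)`.

## Harmonization rules

Exposure and outcome records are aligned to the exposure's effect allele.
For non-palindromic variants the labels decide: direct match (no action),
swapped alleles (negate beta, complement frequency — always together),
reverse-complement match (relabel), or both. Palindromic variants (A/T,
C/G) are label-ambiguous, so minor/major-frequency concordance decides;
inside the ambiguity window, or with a missing outcome frequency, the
pair is excluded as `palindromic_ambiguous`. Strandedness is inferred
from reverse-complement matching because summary files carry no strand
column. Every one of the 144 ordered allele-pair configurations maps to
exactly one action or exclusion, harmonization is an involution, and a
double swap restores the record exactly — all covered by brute-force
enumeration in the test suite. Proxy records are first translated into
sentinel allele space through the LD allele correspondence (extended to
reverse complements, so a strand-flipped proxy report still translates).

## Pleiotropy screen

The screen is an offline, reproducible stand-in for live catalog queries:
a user-supplied table of (variant, trait, domain, p) annotations with a
fixed domain vocabulary. A sentinel (or the proxy actually used) with any
genome-wide significant annotation in a flagged domain — neoplastic,
immune, hematologic, cardiometabolic — is dropped (`dropped_pleiotropy`);
a genome-wide significant association with the target outcome itself is
dropped first (`dropped_outcome_gwas`). Benign annotations (metabolite,
other) are retained and attached for interpretation. The screen is a pure
function of its inputs; re-running never changes the drop list.

## The synthetic-data generator

The generator emulates the statistical structure the estimator assumes,
with known ground truth:

- **Exposure side.** Genotypes in Hardy-Weinberg proportions,
  `G ~ Binomial(2, maf)`; exposure `X = beta_gx * G + e`, `e ~ N(0,1)`,
  standardized to unit variance; per-variant slope, SE and p from an
  individual-level linear regression of `X` on allele count at
  `n_exp = 8299`.
- **Outcome side.** An independent cohort in which disease arises via
  `logit P(D=1) = alpha + theta * X + delta * G`, `alpha` solved so the
  expected case count matches the target. Genotypes are drawn as
  multinomial cell counts and case status as binomial counts within each
  genotype cell, using the exact per-cell disease probability obtained by
  Gauss-Hermite integration over the non-genetic exposure component. This
  cell-level sampling is *distributionally identical* to simulating
  individuals one at a time: genotype is the only regressor, disease
  status is conditionally iid within a cell, and the logistic fit on the
  2×3 table is exactly the individual-level maximum-likelihood fit (the
  cell counts are sufficient). It is exact finite-sample sampling, not an
  asymptotic approximation.
- **LD proxies** are simulated at the summary level of a variant whose
  allelic correlation with the sentinel is `r = sqrt(r²)`: the genetic
  effect attenuates by `r` and the residual exposure spread inflates
  correspondingly. No richer LD structure is modeled.

Default study conditions, chosen once: 83 metabolites; exposure GWAS of
8299; four outcome cohorts (AML, CML, ALL, CLL) with case fractions
preserved from the 731/793,587, 474/793,588, 313/706,277 and
1585/793,582 meta-analyses but cohorts scaled to 50,000 so a full screen
simulates in seconds (a `outcome_n_total = NULL` flag restores full
sizes); instrument strength log-uniform over a target first-stage F range
of 50–4000, bracketing the 36.5–4013 range typical of strong metabolite
instruments; 10% palindromic sentinels; 10% sentinels absent from the
outcome files (each with a best proxy, a frequent decoy proxy, and a
sub-threshold decoy); outcome records re-presented with random allele
order and strand so the harmonizer is always exercised. Three planted
causal effects (log-OR +1.0 on CLL, +1.2 on AML, −1.2 on CML) are given
strong instruments (R² = 0.25) so the scaled-down screen has
near-complete power to recover them; everything else is null.
Flagged-domain annotation contamination is zero in the clean default and
configurable for tests.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: population stratification and relatedness,
sample overlap between the two GWAS, LD beyond a single pairwise proxy,
metabolite-ratio construction from correlated components, winner's-curse
bias in the exposure effects, and ancestry mismatch between exposure and
outcome panels.

## Estimand and non-collapsibility

The Wald ratio on a logistic-scale outcome targets the conditional
log-OR of disease per 1-SD exposure, which differs from the generating
`theta` under non-collapsibility. The recovery benchmark is therefore
never `theta` itself but the coefficient of an independent oracle —
`glm(D ~ X, binomial)` on a large simulated cohort — and the
`theta`-vs-oracle discrepancy is reported, not hidden. In the rare-disease
regime of all four outcomes (case fraction ≤ 0.002) the log-OR
approximates the log-RR and the discrepancy is small.

## Post hoc power

No closed form is canonical for single-instrument MR power on a binary
outcome; the package adopts the standard non-centrality approximation

$$\text{power} = \Phi\!\big(|\ln OR|\sqrt{N R^2 K(1-K)} - z_{1-\alpha/2}\big),$$

which carries the case-control ratio through `K(1-K)`. An optional mirror
tail `Φ(−ncp − z)` makes the two-sided rejection exact near the null. The
formula is cross-validated against a Monte-Carlo oracle (10,000 simulated
Wald tests per grid point over case fractions 0.001–0.1) and agrees
within ±0.02 everywhere tested; with the first-order Wald SE the MR
z-statistic equals the outcome-side z-statistic, so the oracle's
rejection indicator does not depend on the exposure draw.

## Numerical choices

- Normal, not t, reference distribution for p-values and CIs: summary
  statistics come from cohorts of thousands; flagged as a sensitivity
  choice since the source convention is unstated.
- The 2×3 logistic fits use Newton-Raphson on the cell counts (40
  iterations, 1e-10 tolerance), cross-checked against `glm` in the test
  suite; degenerate tables (zero or all cases, separation with |b| > 15)
  report `se = Inf`, p = 1 rather than spurious estimates.
- Emitted p-values are floored at 1e-300 so extreme associations do not
  underflow to an invalid exact zero.
- The intercept that fixes the expected case count is solved by uniroot
  to 1e-12 on the logit scale; cell probabilities use 40-node
  Gauss-Hermite quadrature.
- Tie-breaks are deterministic everywhere: max criterion, then smaller p,
  then lexicographic rsid.
- Seeds: one master seed; child seeds derived by fixed arithmetic on the
  replicate/metabolite index, kept below 2³¹.

## Design choices where the design was open

- *Sentinel ties*: the selection rule (max R², then min p, then rsid) is
  fully deterministic; the convention is ours.
- *A variant instrumenting two metabolites* is flagged
  (`shared_rsid_flag`) and both are retained.
- *Missing outcome allele frequency* excludes only palindromic pairs;
  non-palindromic pairs resolve by allele identity alone.
- *Bonferroni family size* is the number of tests actually performed per
  outcome, not a constant.
- *Uninstrumented metabolites* (no genome-wide significant candidate) are
  reported as such, never errors, and stay visible in the audit.
- *The filtering audit reports its own conserved counts*; it does not try
  to reproduce any externally reported filtering narrative, which would
  require the original data.

## Validation problem sizes

The test suite validates the estimator at these sizes, chosen so a full
run completes on a laptop in a few minutes: parameter recovery and CI
coverage at 500 replicates against a 10⁷-individual oracle; type-I error
at 2,000 replicates; family-wise error of the 83-metabolite Bonferroni
screen at 500 replicated screens; power formula vs Monte-Carlo at 12 grid
points × 10,000 replicates; plus the brute-force harmonization
enumeration and the worked-value consistency checks, which are instant.

## Known limitations

- Single-instrument design: no heterogeneity or directionality
  diagnostics are possible, by construction.
- The pleiotropy screen is only as good as the annotation snapshot
  supplied to it.
- First-order SEs ignore exposure-side uncertainty; with the strong
  instruments the screen requires (F ≫ 10) the difference is below 1%,
  and the second-order SE is available for sensitivity.
- The generator's two cohorts are ideal: same ancestry, no overlap, no
  stratification. Real-data departures from these assumptions are not
  detectable by this package's tests.
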