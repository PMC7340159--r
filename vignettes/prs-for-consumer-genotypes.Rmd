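---
title: "Polygenic risk scores from consumer genotype files: model, normalization and failure modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk scores from consumer genotype files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtcprs)
```

## The problem

A polygenic risk score (PRS) summarizes the small contributions of many
common variants into one measure of genetic liability. Computing one from a
consumer genotype export is deceptively simple — a weighted sum of allele
counts — and deceptively fragile. The raw files come in different dialects,
report alleles on either DNA strand, and cover vendor-specific SNP subsets
that rarely match the SNP set a scoring model was trained on. A score is
also meaningless in isolation: it only acquires interpretation relative to
the score distribution of an ancestry-matched population. This vignette
describes the model `dtcprs` implements, the choices made where the design
was genuinely open, and what the simulation results do and do not show.

## Score model

For each SNP the inputs are an effect allele, an effect size `beta` (a log
odds ratio for binary traits or a per-allele effect for quantitative ones),
and the effect-allele frequency `f` in each 1000 Genomes super-population
(AFR, AMR, EAS, EUR, SAS). With diploid effect-allele dosage
`g` in {0, 1, 2}:

* per-SNP population score: `f * 2 * beta` — the expected contribution of
  that SNP for a member of the population under Hardy–Weinberg proportions;
* zero-centered score: `sum(beta * g - f * 2 * beta)` over SNPs with a
  usable dosage;
* Z-score: the centered score divided by a population scale.

Panels come in two modes. *Top-SNP* panels hold the LD-clumped genome-wide
significant subset (p < 5e-8); *all-SNP* panels carry externally derived
shrunk weights (such as LDpred output). Weight derivation is an input to
this package, never something it performs.

### The scale denominator

No closed form is universally mandated for the population standard
deviation of a PRS. Under Hardy–Weinberg and linkage equilibrium the
centered score has variance `sum(beta^2 * 2 f (1 - f))`, and we use its
square root as the analytic scale. For top-SNP panels — LD-clumped, hence
approximately independent loci — this is exact; a unit test verifies it
against the exhaustively enumerated genotype distribution of a 3-SNP panel.
For all-SNP panels with residual LD the analytic value understates the true
variance, which is one reason the package also offers *empirical*
normalization: standardizing against the centered scores of previously
processed, ancestry-matched profiles (sample SD, n − 1 denominator, minimum
30 reference scores — below that, scale estimates are too unstable to
report). When the reference cohort is drawn from the scaling population the
two normalizations agree up to sampling error, and a test asserts exactly
that.

Z-scores are reported at full precision with no winsorizing; percentile
presentation (`z_percentile()`) is a formatting concern kept out of the
computational core.

## Harmonization

Alleles are aligned to a reference panel site table (GRCh37 coordinates; the
panel is the coordinate authority — a chromosome/position mismatch at a
shared rsid rejects the site). A genotype matches directly against the
site's ref/alt pair or, failing that, after reverse complementing — a strand
flip. A/T and C/G sites are dropped unconditionally: for those the flip is
undetectable, and no strand metadata from consumer files is trustworthy
across dozens of dialects. Insertion/deletion codes are rejected (the score
equations are SNP-based), duplicate rsids keep their first occurrence, and
X/Y/MT calls are parsed but never scored, since the dosage model assumes
autosomal diploidy.

Site-level QC mirrors standard imputation-input filters: minor allele
frequency > 0.05, Hardy–Weinberg exact-test p > 1e-5, genotype yield > 0.95
and, where an imputation INFO score is available, INFO ≥ 0.9. The HWE test
is the plain two-sided exact test (no mid-p): conditional on allele counts,
the p-value sums the probabilities of all heterozygote configurations no
more probable than the observed one. MAF is estimated from cohort counts
when at least 50 genotypes are available and otherwise falls back to the
panel frequency — a single uploaded profile cannot estimate MAF.

### Missing-SNP policies

A consumer file rarely covers a scoring panel completely. Three policies are
provided:

* `skip` — missing SNPs contribute nothing; no renormalization of the scale
  or the centering constant. This mirrors naive raw-data scoring.
* `frequency_fill` — missing dosage set to `2 f`, flagged per SNP. This is a
  deliberately crude stand-in for imputation; by construction a filled SNP
  contributes `beta * 2f - 2f * beta = 0` to the centered score, *exactly*
  (the identity holds bit-for-bit, and a test asserts it), so coverage gaps
  are neutral rather than biasing.
* `fail` — any gap is an error, for pipelines that require completed
  imputation upstream.

The package does no phasing or haplotype-model imputation. A production
pipeline would call external phasing/imputation tools and require them to
complete before scoring; here, complete data is an input condition and
`frequency_fill` the degraded fallback.

## Ancestry assignment

The scaling population must match the person being scored. `dtcprs` assigns
a super-population by naive-Bayes genotype likelihood: for each population,
the sum over non-missing autosomal sites of `log P(g | f_pop)` under
Hardy–Weinberg proportions, frequencies clamped to `[1e-4, 1 - 1e-4]` so a
fixed allele cannot contribute `-Inf`. The label is the arg-max with a fixed
AFR, AMR, EAS, EUR, SAS tie-break; at least 100 usable sites are required.
PCA projection would be the more common choice in cohort settings, but it
needs external loadings; the likelihood classifier is self-contained and
fully testable against synthetic frequencies. With populations diverged at
Fst = 0.1 (Balding–Nichols model) and 500 sites, assignment accuracy on
simulated profiles is essentially perfect; admixed individuals get the
best single label, not admixture proportions — a known limitation.

## Evaluation statistics

Case/control predictive strength is summarized by Nagelkerke R² and AUC.
The logistic fits behind R² are computed by a self-contained IRLS routine
(convergence when the log-likelihood moves < 1e-10, at most 100 iterations)
so the metric stack carries no model-fitting dependency; tests compare it
against both `glm` and an independent grid-search likelihood maximizer, and
flag (quasi-)separation. AUC uses the Mann–Whitney midrank form, tested
against O(n²) pair counting. The carrier-proportion comparison uses the
pooled two-proportion z-test *with* Yates continuity correction — chosen
because the one published carrier comparison this package reproduces
(20/25 vs 33/39 carriers, p printed as 0.9) is only recovered with the
correction; the uncorrected z gives p ≈ 0.63.

## The synthetic cohort generator

The simulator is the package's test bed and defines its study conditions:

* SNP frequencies uniform on [0.05, 0.95] — the common-variant regime a
  genotyping chip measures well; betas Normal(0, 0.1²) by default.
* Genotypes Binomial(2, f), i.e. Hardy–Weinberg and linkage equilibrium.
  LE is a deliberate simplification: it makes the analytic scale exact, so
  normalization tests have a sharp target. Real LD structure is *not*
  emulated.
* Liability-threshold phenotypes: liability = `a G + e`, where `G` is the
  centered genetic score, `a` scales `Var(aG)` to the liability-scale
  heritability `h²`, `e ~ Normal(0, 1 - h²)`, and disease status is
  liability above the `1 - K` quantile for prevalence `K`. Tests recover
  `K` within binomial error and `h²` within ±0.05 at n = 5000.
* Vendor masks are random SNP subsets of configurable coverage — real chip
  manifests are proprietary to their scoring overlap, so coverage is kept
  as an explicit parameter rather than pretending to a manifest.

Default experiment conditions: n = 2000 individuals, 300 SNPs, h² = 0.4,
K = 0.3, vendor coverage 0.5, vendor mix 55/30/15, 100 mixed redraws. These
sizes keep the full test suite under a minute while leaving sampling error
well below the effects being demonstrated.

## The uniform/mixed experiment and its mechanism

`run_snpset_experiment()` evaluates three conditions: complete dosages
(FULL), everyone restricted to one vendor's SNPs (UNIFORM, once per
vendor), and per-individual vendor assignment (MIXED, redrawn 100 times).

The masked conditions are scored with a *naive fixed-reference scorer*:
the weighted sum over attained SNPs, centered by the **full panel's**
population score and divided by the full panel's SD. This models what
actually happens when raw vendor data is pushed through a scoring pipeline
built for a prespecified SNP set — the pipeline does not renormalize per
person. The distinction matters:

* Under a **uniform** SNP set the un-attained SNPs shift everyone's score
  by the same constant; ranking is preserved and roughly half the variance
  explained survives at 50% coverage (measured R² ratio ≈ 0.50).
* Under **mixed** SNP sets each vendor's missing set differs, so each
  vendor group acquires a different score offset. These offsets are of the
  same order as the genetic signal and carry no phenotype information;
  ranking across vendors collapses and virtually no predictive strength
  remains (in the worked example, R² falls from 0.30 to 0.02).

The package's user-facing `zero_centered_score()` is *adaptive*: it centers
per attained SNP, which removes those offsets. That is precisely the
renormalization the naive path lacks, and it is why the pipeline score and
the naive score coincide exactly when (and only when) the data are
complete. The FULL > UNIFORM > MIXED ordering holds in 20/20 seeded
replicates at the default conditions for both AUC and R². The *magnitude*
of the mixed-condition collapse depends on the realized mask offsets: with
three random same-size half-coverage masks, the mixed AUC excess over 0.5
averages about half of the full-data excess, while mixed R² falls to about
a quarter to a third of full — collapse magnitudes are therefore asserted
qualitatively (ordering), not as sharp constants.

Cross-vendor reproducibility is the complementary check: the same
individuals scored through two independently drawn vendor masks under
`frequency_fill` correlate at r ≈ coverage (shared panel fraction over
per-mask fraction) — analytically r ≈ q for coverage q, so r ≈ 0.8 at the
default 0.8 coverage used for this check (chosen as representative of how
much of a well-imputed scoring set a consumer chip attains), exactly 1 at
complete coverage, and ≈ 0.5 at half coverage. High-but-imperfect
reproducibility between two exports of the same person is thus an expected
property of partial SNP overlap, not a pipeline defect.

## Numerical choices and degenerate inputs

* HWE exact test: computed from log-factorials of the conditional
  distribution; ties at the observed probability are included with a 1e-12
  relative tolerance. Monomorphic sites give p = 1; an all-zero table is an
  error.
* Frequency-fill exactness relies on IEEE multiplication commutativity
  (`beta * 2f` vs `2f * beta`), so `skip` and `frequency_fill` give
  bit-identical centered scores.
* Zero-variance panels (all betas 0, or all frequencies fixed) make the
  Z-score undefined and raise a classed error rather than returning `Inf`.
* A profile overlapping a panel at zero SNPs returns a centered score of 0
  flagged `empty_overlap`, with a warning — a number is still produced for
  pipeline robustness but marked uninformative.
* All simulation entry points require an explicit seed and restore the
  caller's RNG state; every generator is bit-reproducible under a fixed
  seed.

## Limitations

* No build liftover: coordinates are GRCh37 throughout, and a mismatched
  build is the caller's error.
* No LD-aware scoring or weight shrinkage; all-SNP weights are inputs.
* The vendor masks are random subsets, so the experiment is a structural
  analog of the mixed-upload problem, not a replication of any specific
  chip combination.
* The dialect grammars cover one representative fixture per vendor; vendors
  have shipped multiple header variants over the years, and the `generic`
  four-column fallback is the safety net.
* Passing tests on simulated cohorts demonstrate internal consistency under
  HWE/LE and clean genotypes; they do not certify performance on real data
  with LD, genotyping error, or admixed ancestry.
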