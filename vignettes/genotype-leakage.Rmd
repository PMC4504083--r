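---
title: "Auditing methylomes for genotype leakage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing methylomes for genotype leakage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methleakr)
library(dplyr)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reports, for every CpG, the fraction
of reads in which the cytosine survived bisulfite conversion — the methylation
rate. Openly released methylation tracks are usually treated as epigenetic
summaries that carry no genetic information. They are not. When the CpG
cytosine itself is polymorphic, the "methylation" measured at that dyad is a
deterministic function of the individual's genotype: a C>A, C>G or C>T allele
either removes reads from the counting or injects reads that are scored
unmethylated. Such CpG-disrupting SNPs make a methylation track a partial
genotyping array, which matters both for biological interpretation
(genotype masquerading as inter-individual "differential methylation") and for
participant privacy (tracks become linkable to identified genotype data).

methleakr implements the full audit around that observation: a ground-truthed
simulator of strand-specific WGBS cohorts, a screen for genotype-like CpGs, a
linear genotype–methylation model with per-genotype predictive accuracy, a
bisulfite genotype caller operating on strand-resolved count summaries, an
audit of how much pairwise differential methylation is attributable to
variants, and a sanitizer that removes direct genetic variation from tracks
before release.

## Strand read-accounting at a polymorphic CpG

All downstream machinery rests on one accounting model
(`apply_disruption_accounting()`). For a diploid genotype at the forward-strand
C of a dyad with true C-allele methylation $m$:

* a **C** allele contributes counted reads on both strands at rate $m$;
* an **A/G** allele contributes *no* counted forward reads (the read carries
  the alternate base, not a cytosine) and contributes reverse reads whose
  normal unmethylated cytosine converts — counted at rate 0;
* a **T** allele is indistinguishable on the forward strand from a converted
  unmethylated C, so its forward reads are counted at rate 0, while its
  reverse reads report methylation of a newly created CpH context at rate
  `cph_methylation_rate`.

Hence at a fully methylated CpG a C/A or C/G heterozygote measures forward
$\approx m$ but reverse $\approx m/2$ — a ~50 percentage-point strand
asymmetry — while a C/C homozygote is strand-concordant, and a C/T
heterozygote is concordant near $m/2$ on *both* strands and therefore
invisible to strand comparison:

```{r}
apply_disruption_accounting(c("C/C", "A/C", "C/T"), true_meth = 1,
                            cph_methylation_rate = 0.01)
```

The `fwd_coverage_factor` column records the countable fraction of forward
reads (0.5 for a C/A het, 0 for hom-alt A/A — the simulator still emits a
zero-coverage forward record there, so "unmeasurable" stays distinguishable
from "unsequenced").

What rescues the C/T case is the reverse-strand *base* composition at the
forward-C position: reverse reads physically carry the complement of the
allele (C→G, A→T, G→C, T→A), so any non-G base is direct genotype evidence
(`simulate_reverse_base_evidence()`).

**Error model.** Measurement error enters as a symmetric per-read miscall:
a read's methylation call flips with probability
$\varepsilon = \texttt{non\_conversion\_rate} + \texttt{sequencing\_error\_rate}$,
i.e. the measured rate is $r(1-\varepsilon) + (1-r)\varepsilon$. Real
bisulfite non-conversion is asymmetric (it only inflates unmethylated sites),
but at the default magnitudes (0.5% + 0.1%) the distinction is immaterial for
every quantity this package computes, and the symmetric form gives clean
closed forms for tests (a fully methylated hom-ref site at non-conversion
0.5% measures 0.995). Both rates are exposed as parameters.

## The cohort simulator

`simulate_cohort()` generates the statistical structure the analysis assumes
rather than reads: per (individual, tissue) sample and per CpG it draws
per-strand Poisson coverage, binomial methylated counts around the accounting
rates above, and multinomial reverse-strand base counts. Defaults, and why:

* **5 individuals × 10 tissues** — mirrors the multi-tissue-per-individual
  reference design (~50 tissue samples across five individuals) that makes
  "static within individual, variable between individuals" assessable.
* **Baseline methylation**: two-component Beta mixture, 70% mass near 1
  (Beta(10, 0.5)) and 30% near 0 (Beta(0.5, 10)) — somatic methylomes are
  strongly bimodal.
* **Coverage**: per-strand Poisson with mean 15 — matches the coverage
  regimes the thresholds downstream refer to (≥4, ≥10, ≥15 reads) without
  read-level simulation.
* **Error rates**: non-conversion 0.5%, sequencing error 0.1%, CpH
  methylation 1% — typical published WGBS values.
* **Genotypes**: Hardy–Weinberg sampling with alternate-allele frequency
  drawn from Beta(1, 3) folded at 0.5. MZ twin pairs receive identical
  genotypes; DZ pairs are full siblings simulated through explicit parental
  transmissions (each parental allele shared with probability 1/2).
* **CpG-disrupting SNPs**: a fraction of SNPs (default 20%) are placed at a
  CpG cytosine with C>A/C>G/C>T alleles drawn uniformly.
* **Indirect meQTLs**: a fraction of CpGs (default 10%) receive an additive
  per-alt-allele shift (default ±0.3, sign randomized) from a SNP placed
  within ±10 kb, clipped to [0, 1] — mirroring the linear model the analysis
  fits.
* **Tissue effects**: per-(CpG, tissue) Gaussian shifts shared by all
  individuals, SD 0.10. This is deliberately large enough that a realistic
  minority of CpGs differ by >30 percentage points between tissues —
  otherwise within-individual pairs would have no differential CpGs at all
  and the pair-type audit would be vacuous.
* **Residual noise**: per-sample SD 0.02 on the true methylation.

Everything is deterministic given the design (which includes the seed).

What the generator does *not* emulate: read-level artifacts (overhang repair,
adapter underconversion, mapping bias), base qualities, hydroxymethylation,
linkage disequilibrium between SNPs, correlated methylation along the genome,
and consistency between the reverse-strand base counts and the reverse
methylation counts (they are drawn as separate summaries of the same
coverage). Additive meQTL effects are clipped at the [0, 1] boundary, so for
CpGs with extreme baselines the true dose–response is weakly nonlinear —
passing tests demonstrate correctness of the analysis under its own model,
not robustness to every artifact of real libraries.

## The static-methylation screen

`screen_static_cpgs()` flags CpGs whose pooled-strand methylation is static
within individuals but variable between them. A site is a candidate when

1. strictly more than half of the *assessable* individuals (those with at
   least 3 measured samples at the site) have within-individual SD < 0.07,
   and
2. the range across **all** measured samples is ≥ 0.15,

with samples below 4 combined-strand reads treated as missing. Decisions worth
recording: "over half" is strict and is evaluated over assessable individuals
at that site (with five individuals, "three out of five" is consistent with
either reading); the range is computed after excluding low-coverage samples;
and the SD is the population SD (divisor $n$) so results are exactly
reproducible. `derive_screen_thresholds()` provides the percentile-based
calibration variant (SD threshold = bottom 70% of within-individual SDs,
range threshold = top 35% of site ranges), and `permutation_null_yield()`
estimates the false-positive yield by permuting the sample-to-individual map.

## The genotype–methylation model

`fit_cpg_snp()` treats each SNP allele as carrying its own methylation rate,
so a diploid's methylation is the average over its two alleles — ordinary
least squares of methylation on alternate-allele dosage. $r$ is the Pearson
correlation with a $t_{n-2}$ p-value; the fitted line extrapolates mean
methylation for all three genotypes even when a dosage class is absent; and
`predict_genotype()` assigns each observation the nearest fitted mean (ties
toward the smaller dosage). Predictive accuracy defaults to resubstitution —
no held-out scheme is part of the reference analysis — with a leave-one-out
mode available.

`scan_window()` tests all SNPs within ±10 kb (inclusive at exactly 10 kb —
the boundary convention is a package decision) and ranks by $|r|$, ties by
proximity then SNP id. `classify_candidates()` keeps each CpG's best SNP and
applies the fixed thresholds: *correlated* means $|r| > 0.5$ and $p < 0.05$
(both strict; $|r|$ rather than signed $r$ because the sign of the slope is
an artifact of alt-allele coding), *highly predictive* additionally requires
accuracy > 0.98. P-values are raw by default; Benjamini–Hochberg adjustment
is available but off, matching the fixed-threshold convention.

```{r}
fit <- fit_cpg_snp(c(0.08, 0.12, 0.47, 0.52, 0.91, 0.88), c(0, 0, 1, 1, 2, 2))
glance(fit)
```

`pairwise_sample_correlation()` is the array-style view of the same leakage:
at genotype-driven CpGs, methylation vectors of monozygotic twins correlate
almost perfectly, dizygotic twins less, unrelated pairs least — the
fingerprint that makes such probes identifying.

## The bisulfite genotype caller

`call_genotypes()` is a deliberately simplified caller in the spirit of
published bisulfite SNP callers: it consumes per-site count summaries (no
base-quality recalibration, no realignment) and genotypes only the forward-C
position of the dyad (the G position is symmetric by construction). The
posterior over the ten diploid genotypes combines, per site:

* a multinomial likelihood of the reverse-strand base counts under the
  genotype's complementary base mixture with per-read error `error_rate`
  (default 0.1%, must be positive);
* binomial likelihoods of the methylated counts on each strand under the
  accounting rates above, with the unknown methylation level marginalized
  uniformly over a grid (default $\{0, 0.5, 1\}$, configurable finer) — the
  methylation is a nuisance parameter here;
* for genotypes with no countable forward allele (A/A, A/G, G/G), observed
  counted forward reads can only be errors: each contributes
  $\log(\texttt{error\_rate})$ plus an uninformative 1/2 methylated split.
  Dropped forward reads are unobservable, so no coverage-proportion term is
  modelled for the other genotypes;
* a prior: `"rare"` mode puts $1-\theta$ on C/C and splits $\theta$ (default
  0.001, a standard human heterozygosity prior) over the nine variants — the
  worst-case assumption of rare SNPs with no external information;
  `"catalog"` mode uses Hardy–Weinberg priors from catalog allele
  frequencies where available. Catalog priors raise heterozygote sensitivity
  at common variants and never lower it, at the price of trusting the
  catalog.

Calls are flagged `LOW_COV` below 10 total reads (low coverage is the
dominant source of miscalls), `AMBIGUOUS` below posterior 0.9 (a package
choice: a release-gating call should be near-certain), `PASS` otherwise.
`evaluate_calls()` scores heterozygote sensitivity (PASS call equal to the
true het genotype) and the false-variant rate (PASS non-reference calls that
are wrong, over all compared positions).

The C/T case is the reason this caller exists at all: strand rates alone
cannot see it (both strands sit near $m/2$), but the reverse-strand adenines
identify it — a property asserted directly in the test suite.

## Differential-methylation audit and sanitization

`differential_cpgs()` applies the stated filters exactly as printed:
pooled-strand coverage ≥ 15 in *both* samples (non-strict) and rate
difference > 0.30 (strict). Strands are pooled before the coverage cut.
`audit_pair()` then counts differential CpGs carrying a non-reference PASS
call in one or both samples, and classifies the pair as same-individual /
same-tissue / both-differ. On simulated cohorts this reproduces the
qualitative ordering: comparing the same tissue between individuals shows the
highest variant overlap, tissues within an individual the lowest, with mixed
pairs in between.

`sanitize_track()` removes dyads before release, with a fixed reason
precedence so counts are reproducible: `called_variant` (non-reference PASS
call in the dyad) > `catalog` (known SNP in the dyad) > `unclear_context`.
"Unclear cytosine context" is not formally defined by the reference analysis;
the package's explicit definition is: an `AMBIGUOUS` genotype call, or strand
discordance (|difference| > 0.2 and exact-test $p < 0.01$) with no resolving
PASS genotype. Removal is dyad-level — a variant at either base compromises
both strand records. `LOW_COV` calls do not trigger removal: absence of
evidence is not evidence of a variant; releasing decisions about such sites
belong to coverage filters, not the sanitizer. `verify_sanitized()` is the
idempotence-based release gate.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains simulate → screen → correlate → call → audit →
sanitize under a single nested configuration (list or YAML), propagates one
seed to every stochastic stage, and emits a JSON summary whose counts equal
the per-stage tables. Identical configuration implies byte-identical results.

Numerical choices collected in one place: population SD in the screen;
strict/non-strict inequalities exactly as stated above; window inclusive at
±10,000 bp; prediction ties toward dosage 0; best-SNP ties by distance then
id; caller `error_rate` strictly positive (an exact-zero error model makes
three-base evidence impossible for every genotype); log-space likelihoods
with row-wise log-sum-exp; Fisher's exact test for the two-proportion
comparison (exact enumeration, no normal approximation).

The test suite and the examples in this vignette run on deliberately small
designs (hundreds to ~1,500 CpGs, 4–6 individuals, up to ~200 individuals
for the single-tissue parameter-recovery experiment, coverage 15–60×) —
sizes chosen so the whole suite re-runs in minutes while every property
being tested (binomial convergence, OLS sampling theory, caller posterior
calibration, pair-type ordering, twin correlation ordering) is already
well-resolved at that scale. The parameter-recovery experiment uses common
variants and mid-range baselines so the additive model is exact (no [0, 1]
clipping); with rare variants or extreme baselines the slope error acquires
a heavy-tailed, clipping-limited component that no estimator avoids.

## Known limitations

* The caller is not a production variant caller: no indels, no
  multi-allelic sites, no base qualities, no somatic/germline tiering.
* The simulator's independence assumptions (sites independent, base counts
  and methylation counts drawn separately) mean calibration statements are
  about the model, not about any particular sequencing pipeline.
* Sanitization removes *detected* direct variation; indirect (meQTL-driven)
  genetic signal and undetected rare variants remain in released tracks by
  construction — the screen and correlation modules exist precisely to
  quantify that residual.
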