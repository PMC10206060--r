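---
title: "Methods: simulated-progeny cross selection with genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated-progeny cross selection with genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and known
limitations of `ocselect`. It states no empirical result that the test
suite does not itself compute.

## The problem

In inbred crop breeding the number of possible bi-parental crosses grows
quadratically with the parent panel (100 parents → 4,950 crosses), while
a program can realize only a handful per season and learns a cross's
value only years later, after inbred progeny reach yield trials. The
package predicts each cross's value before it is made: it simulates the
inbred progeny a cross would generate, predicts their genomic breeding
values from a training population of genotyped, phenotyped lines, and
summarizes the cross by a usefulness criterion.

## Marker data and quality control

Genotypes are allele counts 0/1/2 of the nucleotide that is first in
alphabetical order at each SNP, the convention of chip-style exports; a
VCF importer applies the same rule to REF/ALT so both sources code
identically. QC removes markers with minor allele frequency below 0.06
or more than 20 % missing calls — thresholds typical for mid-density
chips on inbred panels. MAF is computed over observed calls only, which
is the only reading under which a joint MAF/missingness filter is
self-consistent, and makes the filter exactly symmetric under allele
relabelling (c → 2 − c). A marker failing both filters is booked under
missingness (checked first) so report counts are disjoint. Residual
missing calls are filled by a deliberately naive per-marker imputer
(mode, or rounded mean); haplotype-phasing imputation is out of scope —
at ≤ 20 % missingness per marker on inbred material the choice has
little influence downstream, and heterozygous calls are kept verbatim
(inbred panels show minimal heterozygosity).

## Phenotypic mixed model

Entry values for training come from
`y = μ + E + M + E(r) + G + E(G) + e`, with environment E (year ×
location), maturity M (days from planting, one linear covariate — the
minimal reading of a "maturity" adjustment) and replicate-within-
environment fixed, and genotype G and G×E random. Fitting is REML via
**lme4**, the standard tool for exactly this model class; the package
adds input validation, a single logged outlier pass (|standardized
residual| > 4 by default), and dropping of records without maturity.
With one environment the G×E term is inestimable; it is reported as 0
and flagged. Entry-mean heritability is
`H² = σ²G / (σ²G + σ²GxE/e + σ²R/(e·r))` for `e` environments and `r`
replicates. BLUPs are returned on the deviation scale and consumed as
such by the validation module; only differences between lines matter for
rank-based accuracy.

## Meiosis and single seed descent

Each candidate cross is realized in silico as F5-derived RILs. Per
chromosome, crossover counts are Poisson with mean equal to the map
length in Morgans and positions are uniform on the map — the
no-interference (m = 0) limit of the chi-squared interference family,
equivalent to Haldane's model. This is the only reading consistent with
simultaneously invoking the chi-squared model and assuming no
interference; no obligate chiasma is enforced. At the marker loci this
process is Markov along the chromosome with switch probability
`r = (1 − e^(−2d))/2` per interval, which is what the vectorized
population sampler uses; the exported single-gamete function implements
the literal count-location process, and the two are equal in
distribution at the markers (verified against the Haldane fraction and a
16-state two-locus selfing chain in the tests).

Single seed descent advances each progeny independently: one gamete from
each parent forms its F1, then four selfing rounds (two independent
gametes per round) produce the F5, which retains residual
heterozygosity — about 1/16 per originally segregating locus — rather
than being forced to fixation. Heterozygous parental calls are phased by
a seeded coin per chromosome before meiosis; for the nearly homozygous
parents this tool targets, the phasing choice is immaterial.

## Genomic prediction models

All models use centered marker scores (call − 1, centering by
training-set column means, applied unchanged to prediction genotypes).

* **RR-BLUP** solves `y = 1μ + Zu + e` with i.i.d. marker effects by
  REML on the variance ratio, through the spectral form of the
  equivalent kernel model `K = ZZ'` (the RR-BLUP/GBLUP identity, which
  the tests assert to 1e−6).
* **GBLUP / EGBLUP** use the VanRaden-style additive kernel
  `G = ZZ'/c`, `c` = mean diagonal, so `mean(diag(G)) = 1`, and for
  EGBLUP additionally the Hadamard square `H = (G∘G)/s` rescaled the
  same way — the standard kernel for additive×additive epistasis (PSD by
  the Schur product theorem). Matching diagonal scales make the two
  variance components directly comparable. REML maximizes the profiled
  likelihood over log variance ratios; we use bounded quasi-Newton
  (L-BFGS-B, |log γ| ≤ 15) rather than EM because near-boundary
  solutions (σ²aa → 0 is common) stall EM while the profiled surface is
  smooth and low-dimensional. Unphenotyped progeny are scored by the
  kernel projection `g_new = K_new,train (K_train,train + εI)^{-1}
  g_train` per kernel (ε = 1e−8), which the tests show equals the joint
  mixed-model solve.
* **BayesRR / BayesB** are Gibbs samplers (compiled, seeded through R's
  RNG so chains are bit-reproducible) with 1,500 iterations and 500
  burn-in by default. BayesRR shares one effect variance across markers;
  BayesB mixes a point mass at zero (prior π = 0.95, configurable; the
  source material does not state it) with per-marker variances. Both
  variances carry scaled-inverse-χ² priors with ν = 4.2 and scales set
  from `var(y)` so the prior splits phenotypic variance roughly in half
  between markers and residual — declared defaults, not inferred ones.
  With variances held fixed the sampler's posterior mean is the ridge
  solution, which anchors the implementation to a closed form in the
  tests. At these chain lengths posterior means are stable to within the
  between-seed spread; users needing tighter posteriors can raise
  `iterations`.

## Cross evaluation and ranking

A cross is scored from `n` simulated progeny (default 500, emulating the
100–300 progeny rows programs typically grow, with Monte-Carlo headroom)
by the usefulness criterion `UC = μ + iσ_g`, operationalized as the mean
of the top `k = max(1, round(i·n))` predicted GEBVs (round half away
from zero; at the default n = 500 the 10 % and 20 % cuts are exact).
`i = 0` is the progeny mean (MV). The progeny genetic SD is reported
alongside. One progeny set per (cross, seed) is shared across criteria
and across models within a run, so method comparisons see identical
segregation noise. Ranking sorts by the chosen criterion with a
lexicographic cross-id tie-break, making output order fully
deterministic.

## Validation design

Observed cross values are the mean entry BLUP of a cross's phenotyped
progeny; which progeny count is the caller's explicit choice (the
progeny-set argument), since programs differ in which trial stages they
admit. Accuracy is the Spearman correlation (average ranks on ties)
between predicted and observed cross values. Each validation replicate
samples crosses without replacement, rebuilds the training composition,
refits every model and rescores the sample. Compositions: FTS keeps all
candidate lines; WFS removes all direct progeny (by recorded
cross-of-origin; grandprogeny stay) of the predicted crosses, never
parents; RTS removes the same number of lines sampled uniformly among
non-progeny, non-parents — a size control isolating relatedness.
RTS removals are re-sampled per replicate under the replicate seed.
Summary statistics are means and SDs over replicates; family-wise
multiple-comparison tables are presentation-layer statistics and out of
scope.

## Synthetic scenarios: what they emulate and what they do not

The generator stands in for a real breeding program: inbred founders on
a 20-chromosome, 125 cM-per-chromosome map with counted-allele
frequencies U(0.1, 0.9) (echoing a chip designed so most markers stay
polymorphic, without modeling ascertainment); ~700 training lines bred
by two rounds of random crossing each followed by single seed descent;
a polygenic yield-like trait (100 additive QTL with standard-normal
effects plus 30 additive×additive pairs sampled among them, the form
EGBLUP targets); residual noise scaled so the realized genetic/phenotypic
variance ratio hits the target heritability (default 0.51, a typical
multi-test mean for yield) exactly on the sample; and 42 validation
crosses with 16 phenotyped RIL progeny each. QTL default to being
markers themselves; `mask_qtl = TRUE` hides them to emulate marker–QTL
LD. Epistatic QTL-pair counts and founder-pool size are not dictated by
any source and were chosen once as plausible for a yield trait.

Not emulated: population structure, ascertainment bias, genotype ×
environment trait architecture, selection during inbreeding, multi-trait
genetics. A green validation test therefore establishes that the
pipeline recovers known synthetic signal under stated conditions — not
that any particular real-data accuracy value is reproduced; the original
breeding data behind this method are not publicly deposited, so headline
real-data accuracies are explicitly out of scope.

## Numerical and interface choices

* Variance-ratio optimization bounded at e^±15; kernel inversion jitter
  ε = 1e−8; kernels accepted as PSD down to −1e−8 relative eigenvalue.
* Imputation mode ties break toward the lower call, deterministically.
* Master seeds spawn per-stage streams by hashing (stage, index) into a
  31-bit integer, so one stage's output is stable under unrelated
  configuration edits; every CLI output carries a resolved-config JSON
  echo sufficient to reproduce it byte-for-byte.
* CLI configuration files are JSON rather than YAML: no YAML parser is
  available in the dependency envelope, and jsonlite is.
* Filtering precedes imputation; whether QC was computed before or after
  imputation is ambiguous in the source material, and filtering first is
  the conservative order.

## Known limitations

Dense kernel algebra bounds practical training sets at a few thousand
lines; Bayesian chains of 1,500 iterations favor speed over posterior
tail accuracy; the naive imputer is not a substitute for
haplotype-based imputation at high missingness; selfed crosses are
excluded from enumeration by default (allowed explicitly elsewhere);
and interference models with m > 0, sex-specific maps and doubled
haploids are out of scope.
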