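---
title: "Methods: diversity, divergence and relatedness scans for inbred SNP panels"
author: "panelscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, divergence and relatedness scans for inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscan)
```

# Scope and data model

`panelscan` characterizes structured panels of (near-)inbred lines
genotyped on a biallelic SNP array, the situation of a maize breeding
program: a few hundred lines, tens of thousands of markers, strong group
structure (e.g. temperate versus tropical germplasm), long shared
haplotypes from common founders, and residual heterozygosity and
missingness of a few percent.

The central container, `GenotypePanel`, extends `SummarizedExperiment`
with SNPs as rows and lines as columns. The single assay is an integer
dosage matrix counting copies of the designated second allele
(`allele_b`): 0 and 2 for the homozygotes, 1 for a heterozygote, `NA`
missing. Every statistic is a function of this matrix and the SNP map,
and every statistic that is symmetric in allele labelling is tested to
be invariant to the choice of which allele is designated — dosage `d`
and `2 - d` give identical results throughout.

Coordinates are 1-based inclusive physical positions. All genomic
binning converts internally to 0-based half-open bins
`[k·binSize, (k+1)·binSize)`, so a "130 Mb" bin is the bin starting at
130,000,000 and a position `p` falls in bin `(p - 1) %/% binSize`.
This tiling is exclusive: no SNP is ever counted in two bins.

# Per-locus statistics and quality control

Allele frequencies are counted from non-missing calls; a heterozygote
contributes one copy of each allele, a missing call nothing. A SNP with
zero calls keeps `NA` frequencies and never produces a division by zero.

Gene diversity (expected heterozygosity) at a locus with allele
frequencies $\tilde p_u$ is estimated as

$$\hat D = \Big(1 - \sum_u \tilde p_u^2\Big) \Big/ \Big(1 - \frac{1+f}{n}\Big),$$

where $f$ is the inbreeding coefficient and $n$ the sample size. The
**uncorrected** form (numerator only) is the package default: the
attainable biallelic maxima are then exactly 0.500 for gene diversity
and 0.375 for PIC, which is how per-group ranges are conventionally
printed for array panels of this kind; the corrected form would exceed
these bounds and is available through `correct = TRUE`. PIC is

$$\widehat{PIC} = 1 - \sum_u \tilde p_u^2 - \sum_{u<v} 2\,\tilde p_u^2 \tilde p_v^2 ,$$

which for a biallelic locus satisfies $0 \le PIC \le \hat D \le 0.5$
with equality only at monomorphism.

Two filtering tiers are provided, with boundary semantics following the
printed inequalities verbatim:

* `filterPrimary()` **excludes** SNPs with missing rate > 0.20,
  heterozygosity > 0.20 or MAF < 0.05 — boundary values are kept;
* `filterStructureSubset()` **keeps** SNPs with missing rate < 0.05 and
  gene diversity > 0.45 — boundary values are dropped.

Both filters are idempotent, and the structure-subset gene diversity is
the uncorrected panel-wide estimate (the subset is selected once on the
whole panel).

# Genome scans

`binnedScan()` averages any per-SNP value over 10-Mb bins (default).
Bins holding fewer than `minSnpsPerBin` SNPs are flagged `dropped` and
carry no statistic, a statistical-power guard. The default of 30 SNPs
per bin is appropriate at full array density (roughly 20+ SNPs/Mb);
analyses of the reduced-scale demonstration panel (about 3 SNPs/Mb, 30
expected per bin) use `binSpec(1e7, 10)` so that Poisson fluctuation in
bin occupancy does not randomly censor bins — the same power rule scaled
to the density.

`callHotspots()` flags bins strictly below 0.25 as low-diversity and
strictly above 0.40 as high-diversity hotspots (ties at the cutoff are
not hotspots), and reports the bins flagged identically in every scan
supplied (e.g. entire panel, temperate, tropical) as the *common*
hotspot set.

# Allele-frequency divergence

`groupAlleleCounts()` counts allele copies per SNP in two named groups
(Mixed lines are excluded — the comparison is between the two named
gene pools). `chisqDivergence()` applies the Pearson chi-square test
(df = 1, no continuity correction) to each 2×2 allele-count table at a
per-SNP significance level of 0.001; **no multiple-testing correction**
is applied, since the fixed per-SNP level is itself the screening rule.
The test operates on allele counts (two per line): in a near-fully
inbred panel allele and line counts are proportional, and the empirical
size of the test at the 0.001 level is verified by simulation in the
acceptance suite. Tables with a zero marginal are marked untestable and
excluded from numerators and denominators of binned ratios; expected
counts below 5 set an advisory flag only.

A *unique SNP* is one polymorphic in one group and monomorphic in the
other. The wording of this definition in the field is ambiguous about
which group the SNP is credited to; `screenUniqueSnps()` defaults to
crediting the **polymorphic** group (a private-allele reading) and
offers `credit = "monomorphic"` for the inverse convention.

`topVariantSnps()` ranks by absolute between-group frequency
difference, ties broken by (chromosome, position) ascending.
`binnedVariantRatio()` emits per-bin variant and non-variant SNP ratios
among testable SNPs.

# Linkage disequilibrium

LD is the squared Pearson correlation of dosage vectors over lines
called at both SNPs (composite/dosage r²). No phasing is attempted: for
inbred lines with heterozygosity capped at 20% by the primary filter,
dosage r² and haplotype r² coincide almost exactly, and no phasing step
exists in the workflow this package supports. Pairs in which either SNP
is monomorphic within the jointly called lines are skipped with a tally.

`decayProfile()` bins pairs by physical distance on a fixed grid — the
union of the interval bounds conventionally reported for such panels:
0–0.1, 0.1–0.25, 0.25–0.5, 0.5–0.75, 0.75–1, 1–1.5, 1.5–2, 2–2.5,
2.5–3, 3–3.5, 3.5–4, 4–5, 5–10 Mb and beyond. The decay distance is
reported as the **first** interval (ascending) whose mean r² drops
strictly below 0.1. Whether later intervals must stay below the cutoff
is not standardized; the default does not require it, and
`requireSustained = TRUE` provides the stricter variant. Pair
enumeration is capped at 50 Mb by default (decay decisions occur well
below 10 Mb); pass `maxDistanceBp = Inf` for all pairs.

# Similarity, conserved segments and kinship

The identity-by-state similarity of two lines scores each SNP 1 when
both calls are present and identical as unordered genotypes — a
heterozygote matches only a heterozygote — and 0 otherwise. The
denominator is the number of SNPs called in **both** lines (default):
with the literal fixed-total denominator, per-line missingness deflates
ratios asymmetrically; that variant remains available as
`denominator = "all"`. Similarity never imputes.

`mostSimilarLines()` selects the k nearest lines to a focal line
(descending similarity, id-ascending ties), `binnedSimilarity()`
restricts ratios to 10-Mb bins, and `conservedRegions()` reports
maximal runs of adjacent non-dropped bins whose subset mean strictly
exceeds 0.85 — the breeding-conserved segments a founder passed to its
derived lines. A dropped bin breaks a run.

The genomic relationship matrix follows VanRaden:
$K = ZZ^\top / (2\sum_k p_k(1-p_k))$, with $Z$ the dosage matrix
column-centred by $2p_k$ and monomorphic SNPs excluded from numerator
and denominator. Missing dosages are mean-imputed (to zero after
centring) — for kinship only. `kinshipDistribution()` clips negative
estimates to zero in the *report* (producing the conventional
point-mass at zero) while the stored matrix always keeps raw values for
downstream modelling.

# Genetic distance and trees

Nei's distance between *lines* treats each line's genotype as its
allele-frequency vector at each locus — (1, 0), (0.5, 0.5), (0, 1) —
and skips loci missing in either line. Which Nei variant legacy
software computes is ambiguous, so both are provided: the 1972 standard
distance $D = -\ln(J_{xy}/\sqrt{J_x J_y})$ (default) and the 1983 DA
distance. Lines fixed for opposite alleles everywhere give $J_{xy} = 0$
and an infinite distance sentinel; such loci should be filtered before
tree building, and `neighborJoining()` refuses non-finite matrices with
that advice.

Neighbor joining is the Saitou–Nei agglomeration with the
Studier–Keppler criterion $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$,
deterministic tie-breaking by the smallest (i, j) index pair, and
negative branch-length estimates floored at zero (with a message;
disable via `clampNegative = FALSE`). On additive matrices the
generating tree is reconstructed exactly — verified against an
independent implementation over random additive and non-additive
matrices in the test suite. Trees are returned as `ape` `phylo`
objects; `writeNewick()` emits standard Newick with single-quoting of
labels containing metacharacters.

# Admixture post-processing

`deltaK()` computes the Evanno statistic
$\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / s(K)$ from
replicate log-likelihoods (sd with the $n-1$ denominator); endpoints
and zero-spread K values are undefined. The Bayesian admixture MCMC
itself is out of scope — only its tabular outputs are consumed.
`assignGroups()` assigns each line to its maximal-membership component
when that membership reaches the threshold, else to `"Mixed"`. The
appropriate threshold depends on the breeding background and is not
universal; the default 0.6 is a conventional admixture cut, and the
threshold used should be recorded with any analysis.

# The synthetic-panel generator

Because panels of this kind are rarely deposited, every stage is
exercisable against `simulatePanel()`, which draws from a fully
specified generative model and returns a truth manifest alongside the
genotypes:

* **Group divergence** follows the Balding–Nichols model: ancestral
  frequencies uniform on (0.05, 0.95) — an array-like spectrum — and
  per-group frequencies Beta$(p(1-F)/F,\ (1-p)(1-F)/F)$. Larger $F$
  means stronger drift from the ancestral pool and hence *lower*
  within-group diversity.
* **Linkage disequilibrium** is induced by a first-order latent-Gaussian
  Markov process along each chromosome: the latent correlation between
  SNPs at distance $d$ is $e^{-d/\lambda}$, thresholded at the normal
  quantile of the SNP's group frequency. This produces monotone r²
  decay with correlation length $\lambda$ at a fraction of the cost of
  coalescent simulation; it does not produce coalescent-accurate
  genealogies, recombination hot/cold spots, or allele-frequency–LD
  coupling, so passing recovery tests demonstrate *method* correctness,
  not realism of any particular maize panel.
* **Inbreeding** is modelled by drawing one haplotype per line and
  doubling it, then flipping calls to heterozygous at the residual rate
  (default 2%) and masking at the missing rate (default 1%). A
  consequence worth knowing: heterozygous flips perturb allele
  frequencies by $h(1-2p)/2$, so frequency-recovery checks in the test
  suite disable them.
* **Admixed lines** draw per-chromosome ancestry with the configured
  proportions — coarse, but it preserves within-chromosome LD.
* **Planted truth**: divergent windows force a fixed between-group
  frequency gap; founder segments copy the founder's calls into derived
  lines with a per-SNP retention probability. The manifest records all
  coordinates, line identities and generating frequencies.
* **Ascertainment**: a post-hoc panel MAF floor of 0.05 mimics array
  SNP selection; `ascertainGroup` additionally discards SNPs
  monomorphic in a designated discovery group, mimicking
  discovery-panel bias.

`demoPanelConfig()` fixes the demonstration conditions used throughout
the tests: ten 150-Mb chromosomes, 5,000 SNPs (about 300 kb/SNP — a
reduced-scale version of a 50k array on a 2.3-Gb genome), a
temperate-like group of 140 lines with $F = 0.25$ and
$\lambda = 1.5$ Mb, a tropical-like group of 120 lines with $F = 0.15$
and $\lambda = 0.3$ Mb (the five-fold $\lambda$ ratio and the
lower-diversity/longer-LD temperate pattern mirror the selection
history of elite temperate material), 20 admixed lines, a 130–140 Mb
divergence window on chromosome 2 with frequency gap 0.8, and one
tropical founder passing a 30–120 Mb chromosome-7 segment to 30 derived
lines at retention 0.95.

# Numerical choices and problem sizes

* Frequency vectors must sum to 1 within 1e-9.
* Chi-square statistics are computed in closed form on the 2×2 table;
  p-values come from the χ² distribution with 1 df.
* Pairwise-deletion correlations for LD are computed with BLAS
  cross-products (exact for integer dosages).
* Tie-breaks are deterministic everywhere: Q-criterion ties by smallest
  index pair, ranking ties by (chromosome, position) or line id.
* All simulation draws run under a caller-isolated RNG seeded from the
  configuration; identical seeds give identical panels.
* Test problem sizes were chosen for desk-scale runs: oracle
  equivalence uses ≥ 1,000 randomized cases per estimator, test
  calibration 100,000 null SNPs, truth recovery the 5,000-SNP/280-line
  demonstration panel with 20 seeds for the LD-direction check.

# Known limitations

* Only biallelic SNPs are supported end to end; the diversity
  estimators accept multi-allelic frequency vectors, but the container
  does not.
* The generator's LD model is exchangeable across lines within a group;
  it cannot create pedigree-structured kinship beyond the explicit
  founder segments.
* Group-wise statistics assume the group assignment is correct;
  assignment uncertainty (membership coefficients) is not propagated.
* The similarity statistic is identity-by-state, not identity-by-
  descent: high similarity from parallel fixation is not distinguished
  from shared ancestry.
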