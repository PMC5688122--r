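---
title: "Quantifying parental mosaicism from micro-droplet digital PCR"
author: "mosaicDDPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parental mosaicism from micro-droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicDDPCR)
```

## The problem

A "de novo" pathogenic mutation in a child is often not de novo at all: it
can be a postzygotic (mosaic) mutation carried by one parent in a fraction
of their cells, including germ cells. For a severe monogenic epilepsy such
as Dravet syndrome, where most probands carry an *SCN1A* mutation, the
distinction matters clinically: a mosaic parent has a substantially
elevated recurrence risk in future pregnancies, and the mutant allelic
fraction (MAF) measured in the father's sperm is a direct estimate of the
transmission probability per conception.

The difficulty is scale. A parent can transmit a mutation carried by well
under 1% of blood cells — below the reach of Sanger sequencing (about 5%)
and of standard amplicon deep sequencing (about 0.5%). Micro-droplet
digital PCR (mDDPCR) partitions millions of template molecules into
droplets that each report mutant or wild-type, so mutant molecules are
counted individually and fractions of 10^-4^ and below become measurable.
This package implements the statistical machinery around that assay: MAF
estimation with exact intervals, mosaic calling, cross-platform
validation, the transmission-conditioned sperm-vs-blood comparison,
cohort-level tests, multi-tissue clustering, and a synthetic-data
generator that makes every stage testable.

## MAF estimation from droplet counts

A droplet run is gated into four classes: mutant-only positive, wild-type-only
positive, double-positive, and empty (`DropletCounts`). By default each
double-positive droplet contributes one molecule proxy to each channel, and

$$\widehat{\mathrm{MAF}} = \frac{n_{\mathrm{mu}} + n_{\mathrm{db}}}
  {n_{\mathrm{mu}} + n_{\mathrm{wt}} + 2\,n_{\mathrm{db}}}.$$

At high template load droplets hold several molecules; setting
`lambdaCorrect = TRUE` in `estimateMaf()` replaces raw counts with the
per-channel Poisson occupancies $\lambda = -\log(1 - \text{positive
fraction})$ (`poissonLambda()`). The two estimates agree within 1%
relative whenever fewer than ~5% of droplets are positive, which holds at
the default loading (10^6^ templates in 10^7^ droplets).

Confidence intervals are exact central binomial (Clopper-Pearson) from
beta quantiles (`clopperPearson()`). Exactness is not pedantry here:
mosaic calls at the 10^-4^ threshold are decided at mutant-droplet counts
of about 1-10, where normal approximations misbehave. The Wilson score
interval is available behind a flag for comparison. The Clopper-Pearson
interval is conservative by construction; the test suite verifies
coverage at least 95% across true fractions from 10^-4^ to 0.5.

### Homology correction

Some *SCN1A* exons sit in regions with near-identical genomic copies. A
TaqMan target that also amplifies those copies draws wild-type signal from
every copy but mutant signal only from the target, deflating the raw MAF
by the copy count. `correctHomology()` multiplies the point estimate and
both interval bounds by the integer copy count (clamped at 1). Copy
counts are assay configuration (`AssayConfig`), determined externally by
sequence search — they are never inferred from the droplet data. The
packaged cohort stores both corrected and raw values where the original
table printed them; per-assay ratios in that table deviate slightly from
integers (e.g. 3.007, 4.5), which we attribute to rounding of the printed
values and do not model.

### Calling rule

`callSample()` calls a sample *mosaic* when the 95% CI lower bound of the
corrected MAF is at or above `detectThreshold` (default 10^-4^) and the
point estimate is below the heterozygous band (40-60%); a corrected MAF
inside the band is a constitutional *heterozygote*; anything else is *not
detected*. The threshold comparison is inclusive (`>=`): the study's
methods wording is inclusive while its results wording ("higher than
0.01%") is strict, and we follow the methods. Probands below the band are
flagged putative mosaic probands. `calibrateThreshold()` optionally raises
the threshold to the largest CI upper bound seen across negative-control
runs, floored at 10^-4^.

## PASM cross-validation

The orthogonal platform, amplicon deep resequencing (PASM), is modelled
with a beta-binomial posterior (`posteriorMaf()`): a configurable
`Beta(alpha, beta)` prior (default uniform) on the MAF, with the MAP
point estimate and a central 95% credible interval. This deliberately
simplifies the published hierarchical site-specific error model to a
single prior; the full prior structure lives in the original caller's
lineage and is out of scope here. Under the uniform prior the MAP equals
the binomial MLE, so droplet and amplicon point estimates are directly
comparable; `platformConcordance()` fits the OLS regression between
platforms. On the packaged parental blood measurements the corrected
droplet MAFs and PASM MAFs give R^2^ about 0.95 over the 57 complete
pairs (the study's own comparison used 79 samples including probands and
controls, most of whose unrounded values are not published, so the test
asserts the qualitative claim R^2^ > 0.9 rather than a digit).

## The transmission-conditioned sperm-vs-blood comparison

All 10 mosaic fathers with semen samples in the packaged cohort show
sperm MAF at or above blood MAF. A naive paired one-tailed Wilcoxon
signed-rank test of that ordering (exact: `pairedWilcoxon()`) gives
p = 1/1024 = 0.000977 — the exact null distribution, enumerating all
2^10^ sign assignments, is what reproduces the published figure, not the
continuity-corrected normal approximation (about 0.003), so exact is the
default whenever there are at most 25 tie-free nonzero differences.

That test ignores an ascertainment bias: every father in the cohort is
there *because* he transmitted the mutation. Transmission is more likely
from the compartment with the larger MAF, so conditioning on it weakens
the evidence that sperm exceeds blood. With equal prior odds for the two
orderings, Bayes' rule gives the per-father conditional probability

$$P_{sp\mid T} \;=\;
  \frac{\mathrm{MAF}_{\mathrm{large}}}
       {\mathrm{MAF}_{\mathrm{large}} + \mathrm{MAF}_{\mathrm{small}}},$$

(`conditionalTerm()`), and the probability of observing the sperm-high
ordering in *all* fathers given transmission is the product across
fathers (`correctedTransmissionP()`). On the packaged rounded MAFs the
product is 0.0357; the study's computation on unrounded per-sample values
prints 0.033. The roughly 8% gap is input rounding (two fathers have
blood MAFs printed as 0.00%, which forces their terms to exactly 1), and
the package reports the value its inputs support rather than the printed
one.

`sqrtMafRegression()` fits sperm on blood MAFs after a square-root
transform, which stabilises the variance of small fractions; on the
packaged pairs R^2^ is 0.844 (0.87 in the study from unrounded values),
with confidence and prediction bands returned for plotting.

## Cohort-level counting and tests

`summarizeCohort()` implements the counting rules behind the cohort's
descriptive fractions. Choices that the printed table leaves open are
resolved as follows and pinned by golden tests: "highest tissue"
comparisons use strict inequality (a tie loses); the mosaic parent's
peripheral-tissue census covers oral epithelium, saliva, hair follicle
and urine only (blood and sperm are separate compartments); a father's
semen measurement in a maternal-origin family is stored verbatim but
never counted as a sperm mosaic (one family carries such a value). The
blood-called and sperm-called flags are part of the packaged data — the
study's own classification — rather than being recomputed from point
MAFs, because calling requires the original droplet-level interval, which
the printed table does not carry. One consequence worth noting: the
blood MAF range over blood-called mosaic parents includes a 0.06%
borderline mother, whereas the study quotes 0.82% as the smallest
parental blood MAF; the package reports what the rule yields.

Exact tests are delegated to the standard implementations
(`binom.test`, `fisher.test`, `wilcox.test`) behind thin interfaces
(`exactBinomialTest()`, `fisherExact()`, `mannWhitneyU()`), with
two-sided p-values under the minimum-likelihood rule and, for Fisher's
test, both the sample odds ratio $ad/bc$ and the conditional MLE odds
ratio. Each is checked against an independent full-enumeration oracle in
the tests for all small instances. The epilepsy comparison between
mosaic fathers and mothers uses the published per-sex fractions (8 of 18
fathers, 4 of 11 mothers); the larger mosaic-vs-non-mosaic comparison
(odds ratio 10.8) depends on per-family phenotype records that are not
published, so that contingency table is never hard-coded — the function
is generic over user-supplied labels.

## Multi-tissue clustering

`mafMatrix()` assembles the tissue-by-family MAF matrix for the families
whose mosaic parent donated peripheral tissues; `sqrtTransform()`,
`mafDistances()` and `clusterTissues()` perform square-root
transformation, Euclidean distances and agglomerative clustering. Two
decisions were genuinely open:

* **Missing cells.** Tissue columns have many gaps (sperm exists only for
  fathers; not every tissue was donated). The default policy computes
  each pair's distance over its shared columns and rescales by
  $\sqrt{n_{\mathrm{cols}}/n_{\mathrm{shared}}}$, which keeps all 13
  tissue-donating families informative; dropping incomplete columns is
  available and is the policy under which the triangle inequality is
  tested.
* **Linkage.** Unspecified in the source; we default to average linkage
  (UPGMA), with complete and single available. The golden test pins the
  qualitative topology to the default: blood and saliva are mutual
  nearest neighbours, and hair follicles join the sperm branch before the
  blood/saliva branch — the adjacency pattern described for the original
  figure.

Ties in merge distances are broken deterministically by lexicographic
label order. Dendrograms export as Newick with branch lengths from merge
height differences (`dendrogramNewick()`).

## The synthetic cohort generator

`generatorConfig()` fixes the study conditions the generator emulates;
these defaults are chosen once, from the study's own quantities, and are
not tuning knobs:

| Parameter | Default | Basis |
|---|---|---|
| `nFamilies` | 112 | families screened by droplet PCR |
| `mosaicFamilyFraction` | 29/112 | validated mosaic families |
| `paternalFraction` | 18/29 | paternal share of mosaicisms |
| `divisionWeights` | 0.35/0.30/0.20/0.10/0.05 on divisions 1-5 | MAF histogram peaks at 25% and 12.5% imply mass on the first cleavages, decaying for later ones |
| `spermElevation` | 1.5 | typical sperm/blood MAF ratio among the mosaic fathers |
| `tissueNoiseSd` | 0.05 (sqrt scale) | spread of a parent's tissue MAFs around their base value |
| `nTemplates`, `nDroplets` | 10^6^, 10^7^ | droplet-generator capacity; occupancy 0.1 |
| `pasmDepth` | 10,000 | typical amplicon depth |
| `platformLimits` | 5%, 0.5%, 0.005% | benchmarked detection limits |
| `epilepsySlope`, `epilepsyIntercept` | 16, -2.75 | logistic link reproducing 6% epilepsy at MAF 0 and ~41% at the mosaic parents' mean MAF |

A mutation in one daughter cell of cleavage division $d$ is expected to
reach a bulk MAF of $2^{-(d+1)}$ (`embryonicMaf()`): 25% for the first
division, 12.5% for the second. A simulated mosaic parent draws a
division, takes the implied base MAF, adds independent tissue noise on
the square-root scale (truncated to [0,1] — chosen to mirror the
analysis transform and keep small MAFs non-negative), and, if male,
multiplies the germline MAF by `spermElevation` before noise — a single
multiplicative factor, the simplest mechanism consistent with the linear
sqrt-sqrt sperm-blood relation; no spermatogonial selection dynamics are
modelled. Probands are heterozygous at exactly 0.5.

`simulateDropletRun()` draws the four droplet class counts in a single
multinomial step whose cell probabilities come from the per-channel
Poisson occupancies; because the total template count is Poisson, this
is exactly the marginal law of the molecule-by-molecule model (Poisson
total, binomial mutant thinning, uniform assignment to droplets), at a
cost independent of template count. Randomness flows through R's session
RNG; `GeneratorConfig` carries an optional seed which `simulateCohort()`
applies, and reruns with the same seed are bit-identical.

What the generator does *not* emulate: false-positive droplets (probe
cross-reactivity, gating bleed-through), per-assay homology artefacts,
paternal-age effects, and real inter-tissue correlation structure beyond
a shared base value with independent noise. Passing parameter-recovery
tests on synthetic cohorts therefore demonstrates that the estimators
are consistent under the assumed generative model, not that the assay's
real error modes are handled.

### Detection-limit benchmark

`detectionPower()` estimates each platform's probability of detecting a
given true MAF. Sanger is a hard threshold (detected iff the MAF exceeds
5%) since only a limit is reported for it. For the counting platforms,
"detected" means the run shows mutant signal (at least one mutant read or
droplet) *and* the 95% interval upper bound reaches the platform's
nominal limit — i.e. the signal is statistically compatible with a MAF at
or above the limit. This criterion is deliberately distinct from the
cohort calling rule, which requires the CI *lower* bound to clear the
background threshold: applied at a true MAF equal to the limit itself,
the calling rule would by construction have near-zero power (the lower
bound sits below the truth 97.5% of the time), and no rule of that form
can both call at 10^-4^ and detect the benchmarked 0.005% standard. With
the benchmark criterion, power is at least 95% at each platform's limit,
near zero one ten-fold dilution below it, and exactly zero at MAF 0
(there is no false-positive model). On the dilution ladder
(5% ... 0.00005%) this reproduces the ordering: Sanger detects none of
the standards, PASM reaches 0.5%, and droplet PCR with 10^7^ templates
reaches 0.005%.

## Numerical and interface conventions

* MAFs are fractions in [0,1] internally; percent appears only at I/O
  boundaries (`readCohort()`/`writeCohort()` with explicit units,
  `maf_percent` column naming).
* Coordinates are 1-based hg19 as printed; VCF export keeps 1-based
  positions and left-anchors indels with an `N` padding base, since the
  flanking reference base is not part of the data.
* `NA` (not available) and `ND` (assay run, nothing detected) both parse
  to missing, with the original token kept in a provenance column and
  preserved across write/read round trips.
* Degenerate inputs error early with context: saturated droplet runs
  (occupancy undefined), zero informative droplets, all-zero MAF pairs,
  row pairs sharing no observed columns, duplicate sample keys (listing
  the offenders).
* Problem sizes in the test suite: enumeration oracles cover signed-rank
  tests to m = 10, binomial and Fisher tests to n = 20; interval coverage
  uses 2,000 replicates per true fraction against exactly computed
  coverage; droplet parameter recovery uses one run at 10^6^ templates;
  the benchmark uses 100 replicates per dilution step.

## Known limitations

* The beta-binomial PASM model ignores site-specific sequencing error;
  its credible intervals are optimistic at depths where error dominates.
* Homology correction assumes the co-amplified copies are perfectly
  wild-type and equally amplifiable; fractional effective copy numbers
  are not modelled.
* The conditional transmission correction assumes equal prior odds of
  the two orderings and independence across fathers.
* The clustering golden tests pin a qualitative topology under the
  default linkage and missing-data policy; other settings are supported
  but not pinned.

## Reproducing the headline numbers

```{r reproduce, eval = FALSE}
library(mosaicDDPCR)
reproducePaper()
```

`scripts/acceptance.R` recomputes the transmission-conditioned
probability and the first-division expected MAF from the installed
package and writes them as JSON; see the README for invocation.
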