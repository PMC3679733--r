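---
title: "QTL mapping in an F2 line cross: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping in an F2 line cross: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossqtl)
```

## The mapping problem

`crossqtl` implements line-cross QTL mapping for an F2 intercross between two
divergent, outbred founder lines — the classic design for dissecting a trait
difference such as growth rate between a slow-growing indigenous chicken
breed and a fast-growing commercial broiler line. Divergent founders (call
them line A and line B) are crossed to produce F1 hybrids; inter-mating the
F1s produces an F2 generation in which founder-line alleles segregate.
Regressing F2 phenotypes on the expected founder-line composition at each
genome position locates the loci behind the line difference.

The pipeline has six analysis stages, each exposed as ordinary functions (and
mirrored by the `crossqtl` command-line tool):

1. genotype quality control on the pedigreed SNP panel (`apply_qc`),
2. founder-line allele-frequency estimation (`estimate_line_frequencies`),
3. multipoint line-origin probabilities on a cM grid (`compute_line_origin`),
4. one-dimensional Haley–Knott scans with iterative cofactor selection
   (`scan_genome`, `forward_scan`, `test_linked_pair`),
5. an exhaustive two-locus epistasis scan (`scan_pairs`,
   `decompose_epistasis`, `genotype_phenotype_map`),
6. permutation machinery: genome-wide thresholds
   (`permutation_threshold`) and a region-placement enrichment test
   (`region_overlap_permutation`).

A seventh, first-class component is the synthetic-cross generator
(`simulate_cross`, `simulate_phenotypes`), which provides ground truth for
every stage.

## Statistical models

### Non-genetic (null) model

For each trait the non-genetic model is

$$y = \mu + \beta F + \gamma C + \varepsilon,$$

with fixed-effect factors $F$ (sex, hatch batch, family) and covariates $C$.
`select_null_model()` retains only terms significant at $\alpha = 0.05$ by
backward elimination with partial F-tests; the procedure for choosing terms
is not dictated by the design itself, and backward elimination from the full
candidate set is the conventional choice. The retained model supplies the
residuals $\tilde y$ and the residual mean square $MS_R$ used downstream.

### Line-origin probabilities

At any position an F2 individual carries one of four line-origin states —
AA, AB, BA, BB — where the first letter is the maternal-gamete origin.
Because the founder lines are outbred, single markers are only partially
informative, so the state is inferred multipoint: a hidden Markov model per
individual per chromosome with

* hidden state: the pair of gamete origins; prior ¼ per state at the
  chromosome start (the F2 expectation);
* transitions: independent per gamete, with switching probability equal to
  the Haldane recombination fraction $r = (1 - e^{-2d})/2$ for the cM gap
  $d$ (in Morgans) — no crossover interference, matching the first-order
  Markov structure of the model;
* emissions: the probability of the observed biallelic call given the state
  and the founder-line allele frequencies; missing calls emit 1. An optional
  per-call error rate `epsilon` (default 0) mixes the emission with a
  uniform miscall; chips do miscall, but the default stays at 0 so that the
  model matches the noise-free generator exactly and error handling is an
  explicit user decision.

Posteriors are evaluated by a forward–backward pass, with grid positions
between markers inserted as pseudo-loci that emit nothing. Founder-line
frequencies are estimated from the genotyped F0 with a pseudocount of 0.5
per allele, keeping emissions off the 0/1 boundary so that one miscalled
founder cannot make an observation strictly impossible.

From the posteriors the regression indicators are
$A = \Pr(AA) - \Pr(BB) \in [-1, 1]$ and
$D = \Pr(AB) + \Pr(BA) \in [0, 1]$. The AB/BA orientation convention
(maternal gamete first) never affects results: emissions and transitions are
symmetric in the two heterozygous states, so their posteriors are equal and
only their sum $D$ enters any model.

### One-dimensional scan

At each grid position (1 cM step) the Haley–Knott model

$$y = \mu + \beta F + \gamma C + aA + dD + \varepsilon$$

is fitted by least squares and compared with the null model by an F-test
with 2 numerator degrees of freedom. The sign convention is that $a > 0$
means the line-A allele increases the trait. Cofactor selection iterates:
the most significant peak above the 5% genome-wide threshold is frozen (its
$A$ and $D$ columns enter the model) and the genome is rescanned until no
peak exceeds the threshold. Two peaks on one chromosome are accepted as
separate QTL only if both partial F-tests remain significant when the two
are fitted jointly (`test_linked_pair`).

Variance explained follows the nested mean-square form

$$\mathrm{Var\%} = \frac{MS'_R - MS_F}{MS_R} \times 100,$$

where $MS'_R$ is the residual mean square of the reduced model (null terms
plus the other QTL), $MS_F$ that of the full model, and $MS_R$ that of the
null model alone. The numerator is parenthesised as written; this is the
only reading that yields sensible percentages (a few to ~18% for strong
QTL), and such estimates carry a known slight upward bias at a few hundred
individuals.

### Two-dimensional scan

For every admissible pair of grid positions (5 cM step; same-chromosome
pairs at least two grid steps apart as a collinearity guard) the marginal
model (both loci's $a$, $d$ terms) is compared with the full model adding
the four interaction indicators

$$I_{A_1A_2} = A_1 A_2,\quad I_{A_1D_2} = A_1 D_2,\quad
I_{D_1A_2} = D_1 A_2,\quad I_{D_1D_2} = D_1 D_2,$$

an F-test with 4 numerator degrees of freedom. Significant pairs exceed the
2D permutation threshold; pairs with $F > 8$ are reported separately as
suggestive. Adjacent significant grid pairs within 20 cM on both axes are
merged into peak regions, because interactions belong to QTL-peak regions
rather than single grid points; each region is reported at its maximum-F
pair, where the four interaction terms are decomposed by t-statistics.

The two-locus genotype–phenotype map discretises line origin: an individual
enters the 3×3 table only when one genotype's posterior probability exceeds
0.8 at both loci (strictly), with the AB/BA classes pooled before
thresholding — pooling matches the definition of $D$, and an
orientation-resolved 4×4 table is available via `pool_het = FALSE`. Cell
entries are counts and means of the null-model residuals $\tilde y$.

### Permutation thresholds

Genome-wide significance uses permuted datasets: null-model residuals are
shuffled among individuals while the indicator matrices stay fixed, so the
fixed-effect structure is preserved under the null. The genome-wide (or
pair-wide) maximum F per permutation forms the null distribution; the
threshold is its empirical $(1-\alpha)$ quantile (1000 permutations by
default; the calibration studies use 200). Thresholds are computed once per
trait from the cofactor-free first round and reused across forward-selection
rounds: under the null the maximum-F distribution changes negligibly when a
true QTL is absorbed, and recomputing per round would multiply the dominant
cost of the analysis.

### Region-overlap enrichment

Whether QTL regions contain more pathway genes than chance allows is tested
by re-placing the observed regions at random: each region is assigned a
chromosome uniformly with replacement; region sizes are drawn without
replacement from the observed size vector; a validation step re-samples the
chromosome whenever the summed sizes would exceed it; start positions are
uniform with rejection of overlaps and overruns; a region scores when it
shares at least one base with a gene (closed 1-based intervals). The
reported tail probability is $\Pr(\text{count} \ge \text{observed})$, with
the exact-count probability also available, since a histogram reader may
intend either. On a single-chromosome toy (chromosome $L$, one gene of
length $g$, one region of width $w$) the per-replicate overlap probability
has the closed form $\min\{1, (g + w - 1)/(L - w + 1)\}$, which the test
suite checks at 10,000 replicates.

## The synthetic-cross generator

`simulate_cross()` emulates a reciprocal two-line F2 design: by default 4
cocks and 12 hens per founder line, 56 F1 birds selected for breeding (split
equally between the A-sire and B-sire cross types, with each F2 produced by
an F1 sire and dam of opposite types), roughly 48 full-sib families, and 500
F2 offspring in 6 hatch batches. Meiosis follows a Poisson crossover process
consistent with the map's cM distances under the Haldane map function — the
same no-interference assumption the inference model makes. Founders are
simulated unrelated within line; real founders are sibs, but relatedness
does not enter any estimator tested here, and independence makes the
allele-frequency checks exact. A configurable fraction of markers (default
0.3) is fully diagnostic; the rest have allele-1 frequencies uniform on
[0.6, 1] versus [0, 0.4], reflecting lines divergent under selection but
still segregating. Genotype calls are dropped at random (default 2%) to
exercise QC, and `simulate_phenotypes()` exposes a random dropout rate for
phenotype attrition — the attrition mechanism in real studies (deaths,
lost records) is rarely documented, so nothing more structured is imposed.

True line origin is retained per F2 gamete as crossover breakpoints, so
truth can be queried at any position (`true_origin`, `true_indicators`).
Phenotypes are built from the *true* indicators: trait =
mean + fixed effects + covariates + $\sum (aA^* + dD^*)$ + interaction terms
+ Gaussian noise. `simulate_growth_traits()` adds a longitudinal body-weight
series (hatch to 12 weeks, biweekly, means rising from ~35 g to ~2 kg with
realistic dispersion), and per-window feed intake generated as gain × (true
feed-conversion ratio + noise), which is the natural generative direction
when intake recording granularity is unknown.

What the generator does *not* emulate: selection among F1s on body weight,
hatch-batch environmental autocorrelation, sex chromosomes, crossover
interference, and genotyping error bias (miscalls are random). Passing
parameter-recovery tests on this generator therefore demonstrates
correctness of the estimators under the stated model, not robustness to
every artefact of real SNP-chip data.

## Phenotype cleaning

Outliers are flagged by the boxplot rule — more than 1.5 interquartile
ranges beyond the quartiles, with quartiles by linear interpolation of order
statistics (R's default type 7; Tukey hinges would shift the fences
slightly, so the convention is explicit and configurable). A flagged value
is retained when the same individual is flagged on the same side at two or
more consecutive ages (the deviation is a reproducible feature of the bird)
or when at least K = 5 individuals are flagged on the same side at the same
age (a clustered event); these two rules operationalise the qualitative
practice of keeping "consistent" and "clustered" extreme points, and K is
configurable. Growth rate is the weight gain over a window; feed conversion
ratio is intake over gain, set missing with a warning when the gain is zero
or negative.

## Quality control

Retention requires (strict inequalities): individual call rate > 0.9, marker
call frequency > 0.9, minor allele frequency > 0.05, and
parent–offspring-incompatibility rate < 0.05 for both individuals and
markers. Individuals are filtered before markers because one bad sample
distorts every marker's statistics, while the reverse effect is tiny; the
order is recorded in the QC report so counts are auditable. MAF is computed
among F2 only by default: the founder lines are divergent by design, and a
pooled MAF would count line divergence as polymorphism. Inheritance-error
rates use the number of non-missing parent–offspring comparisons as the
denominator, not the marker count.

## Numerical choices

* All fits go through pivoted QR; rank-deficient designs report aliased
  coefficients rather than failing.
* A full-model residual sum of squares at or below $10^{-10}$ of the
  reduced-model RSS marks a degenerate (perfect) fit: F is reported as
  infinite and flagged, never as a number from a 0/0 ratio.
* Scan ties are broken towards the smallest linkage-group number, then the
  smallest cM.
* Map-summary rates are rounded half away from zero to one decimal, and the
  cM/Mb rate is suppressed for groups physically smaller than 3 Mb, where
  the ratio is dominated by the tiny denominator.
* Permutation quantiles use the default empirical quantile (type 7).
* The forward–backward pass renormalises at every locus, so posteriors are
  exact up to floating error (the test suite checks agreement with
  exhaustive enumeration to 1e-10 on small chromosomes).

## Scale of the validation studies

The bundled studies (`study_recovery_1d`, `study_null_calibration`,
`study_epistasis_recovery`) run on a reduced genome chosen to keep a full
run in minutes: 5 linkage groups of 100 cM with markers every 5 cM and 500
F2 individuals. At that marker density the inferred indicators track the
truth closely but not perfectly (the posterior-calibration test quantifies
this); a dense SNP chip on a real cross does better, so the studies mildly
*understate* achievable localisation. Known consequence: for the two-locus
interaction test, the detection power of a pair explaining 6% of phenotypic
variance at n = 500 against the reduced genome's own 5% permutation
threshold (about F = 6.8 with 4 numerator df) has a theoretical ceiling near
0.76 even with perfect line-origin information —
`1 - pf(6.8, 4, 490, ncp = 500 * 0.0638)` — so the epistasis-recovery study
reports a rate below that ceiling. The interaction decomposition itself is
reliable: when the pair is detected, the additive-by-additive term is
correctly dominant. Raising the simulated effect or shrinking the scan
multiplicity would push the measured rate up, but the study conditions are
fixed in advance and reported as measured.

## Known limitations

* Regression-based (Haley–Knott) mapping only; no EM/maximum-likelihood
  interval mapping, no interval estimates of QTL location.
* Autosomes only; no sex-chromosome origin model.
* The line-origin model assumes the genetic map is correct and ignores
  crossover interference.
* No genotype imputation or phasing; QC removes, never repairs.
* Multiple-testing control is genome-wide permutation thresholds only — no
  FDR machinery.
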