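---
title: "Line-cross QTL mapping and candidate-gene dissection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-cross QTL mapping and candidate-gene dissection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linecross)
```

## The problem

An F2 intercross between two breeds that differ sharply in a quantitative
trait — here, pig ear surface in cm², with a small-eared paternal line and
a large-eared maternal line — creates a population in which every F2
chromosome is a mosaic of the two founder breeds.  A locus that
contributes to the breed difference shows up as an association between
the *breed origin* of the chromosome segment an animal carries and its
phenotype.  `linecross` implements the whole dissection chain for such a
cross: locating the quantitative trait locus (QTL) by interval mapping on
line-origin coefficients, calibrating significance and localisation, and
then asking which candidate polymorphism under the peak behaves like the
causal variant.

## Line-origin probabilities

Marker data rarely reveal breed origin directly.  For each F2 gamete the
package first resolves, marker by marker, whether the transmitted allele
descends from the first or the second founder breed (Mendelian deduction
through the phased F1 parent; markers whose alleles cannot distinguish
the two grandparental haplotypes in that family are dropped for that
gamete).  Between informative markers the origin probability is obtained
by conditioning on the nearest informative flank on each side under the
Haldane (no-interference) model, where a distance $d$ cM converts to a
recombination fraction $r = \tfrac12(1 - e^{-2d/100})$.  For flanking
origins $O_L, O_R$ at recombination fractions $r_L, r_R$ from the query
point and $r_{LR}$ between the flanks,

$$P(\text{origin } W) =
  \frac{t(r_L, O_L{=}W)\; t(r_R, O_R{=}W)}{t(r_{LR}, O_L{=}O_R)},
  \qquad t(r, \text{same}) = \begin{cases}1-r & \text{same}\\
  r & \text{different.}\end{cases}$$

Because crossovers are assumed interference-free, the origin process is
Markov along the chromosome and conditioning on the nearest flanks is
exactly equivalent to conditioning on all informative markers jointly;
the test suite verifies this against brute-force enumeration of crossover
patterns.  Outside the outermost informative marker the single nearest
marker is used, and a gamete with no informative marker at all falls back
to probability 1/2 (the "half-informative family" rule).  When both
parents are heterozygous for the same alleles, the transmitting parent of
each allele of a heterozygous offspring is ambiguous and the marker is
dropped for both gametes of that individual — per-gamete information is
deliberately conservative.

The two gametes are independent given the parental marker data, so the
three origin-genotype probabilities of an F2 animal are products, and the
regression coefficients are $c_a = p_{WW} - p_{EE}$ (expected origin
dosage) and $c_d = p_{WE}$ (heterosis probability).

## The scan and the four models

The association framework uses four nested fixed-effect models of ear
size $y$:

* model 1: $y = \mu + \text{batch} + \text{sex} + \text{PPARD} + \beta\,cw + e$
* model 2: model 1 $+\; c_a a + c_d d$
* model 3: model 1 $+\; \text{CGL}_g$ (candidate genotype classes)
* model 4: model 3 $+\; c_a a + c_d d$

with six batches, two sexes, the genotype of a previously established
unlinked QTL (PPARD) as a three-class fixed effect, and carcass weight
$cw$ (kg) as a covariate.  All fits are ordinary least squares with
treatment contrasts; aliased columns are dropped and reported, records
with missing values are dropped with a count.  Every test is an F ratio
of residual sums of squares between nested models,
$F = \frac{(RSS_r - RSS_f)/(df_r - df_f)}{RSS_f / df_f}$.

`scan_qtl()` evaluates the model 2 vs model 1 ratio on a 1-cM grid
(default; both map ends always included), giving the F curve whose peak
locates the QTL; ties go to the smallest position.  The additive effect
$a$ is half the difference between the two homozygous line-origin
classes, and with the founder labels ordered `c("W", "E")` a negative
$a$ means the first (paternal, small-eared) breed's origin lowers the
trait.  Variance explained is reported as the residual-variance
reduction relative to the base model, $100\,(RSS_1 - RSS_2)/RSS_1$, the
natural RSS-based analogue of the printed "percent of phenotypic
variance"; no claim is made that the original software used the same
internal formula.

Significance is calibrated by permutation (default 1000 rounds): each
round shuffles whole phenotype records — response together with its
fixed-effect covariates — against the line-origin states, rescans, and
records the maximum F; the threshold is the empirical $1-\alpha$
quantile of those maxima.  Family structure is ignored in the
permutation unit, the classical genome-scan scheme.  Localisation uses a
bootstrap (default 2000 rounds) over individuals with replacement; the
95% confidence interval is the 2.5/97.5 percentile pair of the
re-scanned peak positions, with degenerate resamples (base design loses
rank) skipped and counted.

## Candidate-gene tests

For a candidate SNP genotyped across the cross:

* **Standard test** (`standard_assoc`): model 3 vs model 1.  In a line
  cross this is confounded by between-breed linkage disequilibrium — any
  breed-differentiated variant under the QTL scores.
* **Marker-assisted test** (`marker_assisted_assoc`): model 4 vs model 2
  with the line-origin terms held at the QTL peak, absorbing the
  between-breed signal.  If the genotype adds no rank beyond
  $(c_a, c_d)$ the test reports $F = 0$, $P = 1$ (the collinearity
  limit).
* **F-drop test** (`f_drop_test`): how much of the QTL F survives when
  the SNP genotype is a fixed effect — $F_\text{qtl}$ is the peak of the
  model 2 vs 1 curve, $F_\text{drop}$ the model 4 vs 3 ratio, and the
  drop fraction is $(F_\text{qtl} - F_\text{drop})/F_\text{qtl}$.  A
  causal (or perfectly tagging) SNP collapses the curve almost entirely.

A genuinely open design choice: should $F_\text{drop}$ be read at the
position where the original curve peaks, or at the maximum of its own
curve?  The package defaults to the original peak position — the
like-for-like reading of "the F value dropped from X to Y" — because the
maximum of an essentially null residual curve is biased upward by the
multiplicity of scan positions (its expectation is the expected maximum
of a handful of correlated 2-df F variables, around 3, rather than
~1), which makes the fraction systematically understate the collapse.
The curve-maximum variant remains available via `at = "curve_max"`.

Additive SNP effects are estimated inside the model-3 layout
re-parameterised on allele dosage with a separate heterozygote term, so
the reported effect is half the adjusted difference between the two
homozygote classes, signed by a declared reference allele (flipping the
reference negates the effect exactly).  Ranking candidate genes uses the
ratio of model-3 RSS values (`rss_ratio`): the gene closest to the QTL
leaves the least residual variance.  For outbred confirmation lines,
`outbred_assoc` runs a one-way ANCOVA per line (lines are analysed
separately — stratification is never pooled away), with Tukey-adjusted
pairwise contrasts and compact letters; Tukey's HSD is the package's
choice where the original procedure is unnamed.

## Haplotypes

Tightly linked SNPs inside a candidate gene span far less than a
centiMorgan, so within families the window is treated as
recombination-free.  `phase_f2()` enumerates the haplotype pairs
consistent with each genotype and filters them against the parents'
possible haplotypes to a fixpoint: a retained pair must be transmissible
without recombination inside the window.  Individuals whose pair is not
unique after filtering are excluded, never imputed; because the true
pair always survives filtering when the window really is
recombination-free, every resolved assignment is logically forced, and
simulation checks recover truth essentially perfectly.

Phenotypes are first corrected for batch, sex, carcass weight and the
additive infinitesimal (polygenic) effect by solving the mixed-model
equations with animal effects $u \sim N(0, A\sigma^2_a)$, where $A$ is
the pedigree relationship matrix (tabular method; sparse inverse by
Henderson's rules with inbreeding) and
$\lambda = \sigma^2_e/\sigma^2_a = (1-h^2)/h^2$.  The package takes the
heritability as an input (default 0.4, the simulator's truth) rather
than estimating variance components — a deliberate choice that keeps the
correction deterministic and testable; at $h^2 = 0$ the correction
reduces exactly to fixed-effects OLS residuals.

Corrected residuals are regressed on the copy number (0/1/2) of each
haplotype *separately* — one simple regression per haplotype, taking the
description of the original analysis literally — with Bonferroni
correction by the number of haplotypes, capped at 1.  The joint variance
explained by all haplotypes drops one copy column (rows sum to 2) and
reports $100 \cdot SS_\text{model}/SS_\text{total}$ with the overall F
test.

## The simulator

`simulate_cross()` mirrors the study design: 2 founder sires of the
small-eared breed × 17 dams of the large-eared breed, 68 F1 of which 9
boars and 59 sows (full-sib matings avoided) produce 1912 F2, 1029 of
them phenotyped.  Meiosis draws crossovers independently per interval at
the Haldane rate (the analysis model and the generative model share the
same no-interference assumption by construction).  Microsatellites carry
4–8 alleles with breed-divergent sparse Dirichlet frequencies
(divergence is a knob; allele counts follow the study's marker
descriptions, per-breed frequencies were never published).  The
candidate window holds three SNPs at the QTN coordinate — the window is
placed at a single map position because its real span (~10⁻⁴ cM) is far
below map resolution, making it exactly recombination-free — with the
causal SNP fixed for alternative alleles in the two breeds and the
flankers segregating in both.

The phenotype model is the generative mirror of model 1 plus the QTN:
mean 280 cm²; batch effects (0, 6, −4, 10, −8, 3); sex effects (0, −10);
carcass weight ~ N(80, 10²) kg with β = 1.2 cm²/kg; an unlinked
PPARD-like diallelic QTL (±12 cm², breed frequencies 0.85/0.15); QTN
additive effect a = 32.84 cm² (the published estimate's magnitude) and
d = 0 at 60.7 cM, the mid-QTL marker position; polygenic variance 920
and residual 1380 cm⁴.  These defaults put the QTN at
539/(539+920+1380) ≈ 19% of the variance remaining after fixed effects —
inside the reported 17–20% band — and the polygenic share of the
remainder at 0.4, which is also the default heritability used for
infinitesimal correction.  Polygenic values are generated recursively
(parent average plus Mendelian sampling scaled by parental inbreeding),
which makes them exactly consistent with the relationship matrix.

What the simulator does *not* emulate: genotyping error, selective
phenotyping, sex chromosomes, crossover interference, within-window
recombination, and real microsatellite allele-frequency spectra.
Passing tests therefore demonstrate correctness of the estimators under
the declared generative model, not robustness to artefacts of real
genotype data.

## Numerical choices and problem sizes

The scan engine residualises the $(c_a, c_d)$ columns against an
orthonormal basis of the base design once and solves the per-position
2×2 normal equations in closed form; positions where the added columns
are numerically rank-deficient (relative tolerance $10^{-9} n$) fall
back to the dominant column, and the F curve keeps 2 numerator df
throughout so the curve is comparable across positions.  Permutations
re-residualise the permuted state columns (a handful of BLAS calls per
round); bootstrap rounds redo the QR of the resampled base design.
Probability states close to 1 within 10⁻⁹ by construction; quantiles
use the inverse-empirical-CDF convention (type 1), which gives the
documented edge behaviour (`alpha = 1` → minimum of the maxima; a
single bootstrap round → a zero-width interval).

The validation suite runs the full study-scale design where the claim
depends on it (F-drop collapse, effect recovery at n = 1029) and scales
the Monte-Carlo layers to keep runtimes reasonable: 1000 null crosses of
400 F2 with 200 permutations each for threshold calibration, 100 crosses
of 600 F2 with 200 bootstrap rounds for CI coverage, 20 replicates for
the F-drop criterion, 50 for effect recovery.

## Known limitations

Per-gamete origin tracking discards the joint information in
origin-heterozygous F2 at breed-diagnostic markers (the unordered origin
pair is known even when the transmitting parents are not), so the grid
is slightly less informative than a full joint-likelihood method; the
regression remains unbiased, only marginally less powerful.  The
permutation scheme ignores family structure, as in the classical
reference; under strong polygenic clustering its thresholds are
approximate.  REML variance-component estimation, multi-QTL scans on one
chromosome, interference models and population-scale statistical phasing
are out of scope.
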