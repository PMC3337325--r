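# linecross

QTL fine-mapping and candidate-gene dissection in F2 line crosses.

## The problem

Crossing two breeds that differ strongly in a quantitative trait — the
motivating case is pig ear surface, with a small-eared paternal breed and
a large-eared maternal breed — produces an F2 population in which every
chromosome is a mosaic of the two founder lines.  A quantitative trait
locus (QTL) reveals itself as an association between the *breed origin*
of a chromosome segment and the phenotype.  `linecross` is for
geneticists dissecting such crosses: it locates the QTL by interval
mapping on line-origin coefficients, calibrates significance and
localisation, and then tests which candidate polymorphism under the peak
behaves like the causal variant.

## The model

At scan position *x*, each F2 animal gets breed-origin genotype
probabilities (p_WW, p_WE, p_EE) computed from its two gametes'
informative flanking markers under the Haldane map function, and the
phenotype is regressed on the line-origin coefficients
c_a = p_WW − p_EE and c_d = p_WE:

    model 1:  y = mu + batch + sex + PPARD + beta*cw + e
    model 2:  model 1 + c_a*a + c_d*d
    model 3:  model 1 + CGL_g          (candidate genotype classes)
    model 4:  model 3 + c_a*a + c_d*d

Every test is an F ratio of residual sums of squares between nested
models: the QTL scan is model 2 vs 1 along the chromosome (peak =
QTL position, with permutation thresholds and bootstrap confidence
intervals); the **standard association test** of a candidate SNP is
model 3 vs 1; the **marker-assisted test** is model 4 vs 2 (between-breed
linkage disequilibrium absorbed); and the **F-drop test** compares the
QTL F with and without the SNP genotype as a fixed effect — a causal SNP
collapses it almost entirely.  Tightly linked candidate SNPs are phased
through the pedigree and their haplotype copy numbers regressed on
infinitesimal-corrected residuals with Bonferroni correction.

A forward simulator of the full three-generation cross (pedigree,
no-interference meiosis, breed-divergent microsatellites, a planted QTN,
an unlinked second QTL, polygenic and residual variance) generates every
input with known truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(linecross)
set.seed(2026)

cross <- simulate_cross()                     # 2x17 F0, 9x59 F1, 1912 F2
phen  <- simulate_phenotypes(cross)           # 1029 phenotyped F2
tracks <- tracks_from_genotypes(cross$pedigree, cross$genotypes, cross$map)
grid   <- line_origin(tracks, step = 1)

scan <- scan_qtl(ear_size ~ batch + sex + ppard + carcass_weight, phen, grid)
summary(scan)
#> line-cross QTL scan: ear_size ~ batch + sex + ppard + carcass_weight
#>   1029 individuals, 117 positions (0.0-115.2 cM)
#>   peak F(2, 1017) = 130.75 at 60.0 cM
#>   a = -33.79 (se 2.10), d = -4.51 (se 3.12)
#>   nominal P = 2.93E-51; variance explained = 20.45%

permutation_threshold(scan, n_perm = 1000, seed = 1)
#> permutation thresholds from 1000 permutations:
#>    5%
#> 5.135

bootstrap_ci(scan, n_boot = 2000, seed = 2)
#> bootstrap of QTL position (2000 iterations): 95% CI 58.0-62.0 cM

qtn <- with(cross$snp_genotypes, data.frame(id = id, a1 = qtn_1, a2 = qtn_2))
f_drop_test(phen, qtn, grid, ear_size ~ batch + sex + ppard + carcass_weight)
#> F-drop test (qtl_peak): F_qtl = 130.75 -> F_drop = 0.47 (drop 99.6%)

estimate_snp_effects(phen, qtn,
                     ear_size ~ batch + sex + ppard + carcass_weight,
                     ref_allele = "A")
#> additive effect of allele [A]: -35.34 +/- 2.06 cm2 (n = 1029)
```

Reading the output: the scan peaks at 60.0 cM — the simulator plants the
causal variant (QTN) at 60.7 cM — with F = 130.8 against a 5%
genome-scan threshold of 5.1, explaining 20% of the residual phenotypic
variance; the bootstrap localises the QTL to a 4-cM interval.  Adding
the QTN's own genotype to the model collapses the QTL F by 99.6%, the
signature of a causal (or perfectly tagging) variant, and its additive
effect is estimated at −35.3 ± 2.1 cm² for the small-eared breed's
allele (simulated truth: −32.84).

`run_pipeline()` drives the same stages from delimited input files (or a
named simulation scenario) and writes the scan curve, association and
haplotype tables, and a JSON summary; see the methods vignette
(`vignettes/linecross-methods.Rmd`) for the statistical details and
design choices.

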