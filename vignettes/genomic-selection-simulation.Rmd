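---
title: "Simulating genomic selection in a pulse breeding program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection in a pulse breeding program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pulsegs` is a stochastic simulator of an inbred, self-pollinating pulse
(lentil-style) breeding program. Its purpose is to compare conventional
phenotypic selection (PS) against genomic selection (GS) strategies that
differ in how fast parents are recycled into the crossing block, and to
quantify the price each strategy pays in genetic diversity. This vignette
explains the model, the main design decisions, and what the simulator does
and does not capture.

## The breeding program

Both pathways run in repeated breeding cycles over a shared germplasm pool
that starts as the synthetic base population (the stand-in for a real panel
of inbred lines) and grows by 80 lines per completed cycle.

* **PS** — 150 parents are chosen from the pool on trial phenotypes;
  300 primary crosses are made by random mating with each parent used at
  most 4 times; 20 F2 seeds per family are bulked within family to F5;
  30% of F5 single plants are culled on a noisy single-plant seed-yield
  record; 800 random survivors enter the preliminary yield trial (PYT);
  phenotype-index selection takes 800 → 400 (Stage 1) → 200 (Stage 2) → 80
  lines into the pool. One cycle takes 8 years.
* **GS** — marker effects are estimated from past Stage trials; 150 parents
  are chosen on GEBV index (or by the diversity-preserving genetic
  algorithm); 300 primary crosses are picked by optimal haploid value (OHV)
  from all 11,175 possible pairs under the same usage cap; 200 F1
  intercross pairs are picked from all F1 pairs by in-silico projection to
  F8; each selected intercross is selfed for 20 F2 seeds (4,000 bulk-up
  lines); single seed descent (SSD, 4 years in the field, or accelerated
  glasshouse aSSD, 1.5 years) takes them to F6; GEBV selection fills the
  PYT (4,000 → 800), GS is applied again at PYT → Stage 1 and at Stage 2,
  with phenotype-index selection at Stage 1 → Stage 2. Parents are recycled
  to the pool at Stage 2, F6, F2 or F1, giving generation intervals of
  8.5/6, 5/2.5, 1 and 0.5 years (SSD/aSSD; see `timeline()`).

Early recycling (F2, F1) runs far ahead of phenotyping: a cycle's Stage-2
phenotypes mature only `pipeline_years` (8.5 or 6) after its crossing, so
the calendar — not the cycle counter — decides which phenotypes a marker
-effect fit may use. With a 1-year interval, every GS cycle trains on the
same three warm-start cycles, and prediction accuracy decays; this is the
behaviour the optional F2-family phenotyping is designed to repair.

## Trait model

Three traits (disease resistance, grain weight, grain yield) are simulated
in two environments with narrow-sense heritabilities 0.5, 0.75 and 0.25.
Each trait–environment combination is controlled by about 1,000 additive
QTL (300 at desk scale); a common core of 70% of each set is shared by all
six sets, so the locus overlap between traits and between environments is
70%. Effects are N(0, 1); for shared loci the two environments' effects are
drawn from a bivariate normal with correlation 0.8 (disease resistance,
grain weight) or 0.4 (grain yield — strong genotype-by-environment
interaction), while between traits effects are independent. The true
breeding value is `g = M a` over QTL doses, and phenotypes add a residual
with variance `(1 - h2)/h2 * sigma_g^2`, so `h2 = sigma_g^2 / (sigma_g^2 +
sigma_e^2)` holds exactly in the base population. Two readings in this
model deserve a note:

* `sigma_g^2` is **frozen** at the founder-population value per trait and
  environment. Residual noise therefore does not shrink as selection
  depletes genetic variance; re-estimating it each cycle would implicitly
  raise realized heritability late in the program.
* QTL and markers are **disjoint** locus sets: the 30,000-marker panel
  (2,000 at desk scale) predicts only through linkage disequilibrium with
  QTL, as in real data.

Genetic gain is reported in units of the base population's additive SD of
the environment-mean TBV per trait, aggregated with the selection-index
weights (0.3, 0.3, 0.4).

## Meiosis and the synthetic base population

Gametes recombine with a Poisson(1) crossover count per chromosome,
positions uniform on the map length, no interference, and an optional
per-locus mutation flip (rate 0.001 per gamete). The mutation rate's unit
is not uniquely determined by its verbal description; the per-locus reading
is implemented (about 30 flips per 30,000-locus gamete) and the rate is
configurable. Zero-crossover chromosomes transmit intact haplotypes; no
doubled haploids are simulated.

The base population is synthetic because the real panel it emulates is not
public. Ancestral allele frequencies are drawn from a symmetric Beta(0.2,
0.2) (a U-shaped spectrum typical of diversity panels), a random-mating
population of twice the line count is gene-dropped for 50 generations to
build within-chromosome linkage disequilibrium, and each line is finished
by doubling one sampled gamete — fully homozygous by construction. Loci
with realized MAF < 0.01 are dropped, mirroring the panel filters (call
rate ≥ 0.5 and MAF ≥ 0.01 on the loading path). The generator reproduces
the two properties the downstream machinery relies on — an allele-frequency
spectrum with a MAF floor, and LD decaying with map distance — but **not**
population structure, subfamilies, selection footprints or imputation
artefacts of a real panel. Passing tests therefore validate the machinery
under a clean panmictic base, not performance on any particular real
germplasm.

## Prediction, OHV and the projection

Marker effects are the posterior mean of a Bayesian ridge regression with a
known variance ratio, i.e. the SNP-BLUP solution `(Xc'Xc + lambda I) beta =
Xc'(y - ybar)` with `lambda = 2 sum p(1-p) (1 - h2_eff)/h2_eff`, where
`h2_eff` is the reliability of a 4-plot entry mean. The closed form is
deterministic and equivalent to the sampling estimator for point
prediction; a single-site Gibbs backend exists for fidelity checks. With
fewer records than markers the dual `n x n` system is solved. Training sets
take the 400 Stage-1 entrants per cycle (their pooled Stage-1/Stage-2 entry
means) from the three most recent phenotyped cycles; the description of the
source population is internally inconsistent in its counts (Stage 2 holds
200 entries but 400 are said to be taken from it per cycle), and the
400-entrant reading is used with the count configurable.

OHV splits each chromosome's marker panel into 5 segments of equal marker
count (±1; map-length-balanced segments would be the alternative; equal
counts keep every segment informative) and sums, per candidate, the better
haplotype value of each segment. Primary crosses are scored by the OHV of
the virtual cross — the per-segment maximum over the union of the parents'
haplotypes, which for inbred parents is exactly the F1's OHV and
generalizes smoothly to the heterozygous parents that early recycling puts
in the pool. The usage cap is enforced greedily (descending score with
skips); a repair step re-pairs stranded capacity when the cap is exactly
tight. Greedy is deterministic and near-optimal here; an integer program
would be overkill for a constraint described only as "restricted use".

Intercross selection projects each candidate F1 pair to F8 by simulated
single seed descent (mutation off) and ranks pairs by the mean plus one SD
of the virtual lines' GEBV index — the more operational of the two
descriptions of this step, preferring crosses that combine a high mean with
transgressive variance. Descendant haplotypes are tracked as breakpoint
mosaics of the four parental haplotypes and scored through prefix sums of
the marker effects; this is an exact implementation of the same
recombination process, chosen purely for speed, and is cross-checked in the
tests against the literal per-locus meiosis path. Virtual F8 lines are
scored by GEBV rather than OHV: at F8 residual heterozygosity is 1/128, so
the two coincide up to a factor the selection is invariant to. Projection
runs on the marker loci only — restricting the recombination process to a
locus subset is its exact marginal.

## Diversity metrics and the genetic algorithm

Cohort diversity is tracked as the VanRaden genomic relationship matrix's
mean off-diagonal, the number of marker alleles fixed (NAF) within the
cohort, and TBV variances. The GRM is centred with the **base population's**
allele frequencies: centring each cohort on its own frequencies makes the
centred doses sum to zero, which pins the off-diagonal mean structurally
near `-(1+F)/(n-1)` no matter how related the cohort has become, so
relatedness accumulating over breeding cycles is only visible against a
fixed reference panel. (The `grm()` function itself accepts any reference
frequencies.) The same base-frequency centring is used inside the
genetic-algorithm fitness, which also puts the relationship penalty on the
reported scale. The diversity-preserving parent
selector maximizes `f = mean(index) - lambda1 * meanREL - lambda2 * NAF`
over 150-line subsets with a genetic algorithm (population 2,000, 1,000
iterations at full scale; 200 x 100 at desk scale; mutation 0.001; the
fittest 20% survive and are randomly crossed with one-point crossover).
Membership bit-vectors are repaired to exact cardinality by toggling the
lowest-index members (or highest-index outsiders), which preserves the
fitness signal and keeps the operator deterministic given the RNG stream.
The initial population is seeded with the truncation-selection subset, so
with penalties off the GA can never do worse than plain truncation, and the
best-ever subset is tracked across iterations. `f` is read with the index
term as the subset mean of individual indices and NAF counted within the
selected subset over the marker panel (QTL are unobserved).

## Experiment design and reporting

Each replicate resamples the 150 cycle-1 parents from the base population
and resamples the QTL architecture. PS runs cycles 1–8; every GS scenario
branches from the end of PS cycle 3 with a bit-identical warm start, runs
cycles 4–8, and closes with a final parent selection. Gain and diversity
are measured on the 150 parents at each cycle start — the one cohort every
scenario defines — and annual rates are `(end - start) / elapsed years`
over the post-branch phase, so a GS scenario's first-cycle parent choice is
its baseline and the comparison isolates per-cycle machinery plus cycle
time. Percentage comparisons against PS divide mean rates.

## Problem sizes

The package's desk preset runs 500 founder lines, a 2,000-marker panel,
300 QTL per trait–environment, 1,000 bulk-up lines per GS cycle, a 0.1
mid-parent pre-filter on the F1-pair enumeration, a 200 x 100 genetic
algorithm and 10 replicates — sizes chosen so a full seven-branch
comparison runs on a desktop core in well under an hour while preserving
the full program's selection-intensity profile at every stage that matters
(the trial ladder is unchanged; only the bulk-up entering it is thinner).
The full-scale configuration (1,568 lines, 30,000 markers, 1,000 QTL,
4,000 bulk-up lines, full enumeration, 2,000 x 1,000 GA, 50 replicates) is
expressible through the same configuration objects.

## Numerical choices and degenerate inputs

* Ties in truncation selection break by ascending candidate position;
  selection indices standardize by cohort SD and zero out traits whose SD
  is below `1e-10` (with a warning) rather than dividing by noise.
* The ridge solver refuses fewer than 2 records and returns zero effects
  (with a warning) for constant phenotypes.
* `accuracy()` raises a hard error if the cohort intersects the training
  records, enforcing leave-cycle-out evaluation by construction.
* Random mating under a tight usage cap uses slot shuffling with self-pair
  repair; greedy OHV selection repairs stranded cap slots; both fail loudly
  when the configuration is infeasible.
* All randomness flows through R's RNG; experiments are bit-reproducible
  from `(configuration, base seed)`, and branch comparisons across runs
  sharing founders and base seed are paired.

## Known limitations

Only additive gene action is simulated (no dominance or epistasis); the two
environments are fixed effects with no year-to-year variation; trial
designs are idealized (independent plot residuals, no spatial field
structure); the mutation-rate unit follows the per-locus reading; the base
population is panmictic rather than structured; cost modelling, genotype
imputation and exotic-germplasm introgression are out of scope.
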