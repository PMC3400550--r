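---
title: "Inferring interlocus gene conversion in a young duplicated gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring interlocus gene conversion in a young duplicated gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant immune receptors often guard host proteins that pathogens attack; the
guarded protein itself can then become the target of balancing selection,
and young duplicates of such genes are common. When a gene has duplicated
recently, its copies can exchange sequence tracts by **interlocus gene
conversion**, which homogenizes the coding regions while the flanking
regions keep recording the duplication history. Standard single-locus
population genetics then misleads: polymorphism is shared between loci,
allele genealogies cross locus boundaries, and neutrality tests need null
distributions that account for both demography and conversion.

`paraconv` implements the complete inference chain for this situation on a
panel of sequenced alleles from two paralogous loci:

1. a structured-coalescent simulator for two paralogs with conversion,
   a duplication event and stepwise population expansion;
2. classical summary statistics, including cross-locus classification of
   polymorphisms into shared, private and fixed;
3. approximate Bayesian computation (ABC) to estimate the population
   conversion rate and to compare conversion vs no-conversion models;
4. demography-aware null distributions for Tajima's D;
5. a per-SNP general-linear-model association scan for phenotype panels;
6. a synthetic-data generator producing panels with the structure the
   analysis assumes, so every stage can be validated end to end.

## The coalescent model

### State space and events

Backward in time each ancestral lineage carries segments of sampled
material and resides at locus A or locus B. Three event types occur:

* **Coalescence.** Two lineages at the same locus merge at rate 1 per pair
  (time in units of $2N$ generations).
* **Gene conversion.** For each lineage, conversion tracts initiate at rate
  $L\,C/(2\lambda)$, with a uniform start site, geometric length with mean
  $\lambda$ (truncated at the locus end), and the covered ancestral
  material switches residence locus. This is an ancestral-recombination-
  graph move: the tract and the remainder become separate lineages.
* **Duplication.** At time $t_{dup}$ every locus-B lineage relabels to A;
  the duplicate does not exist earlier. We implement the fixed-duplication
  limit of the copy-number-variation model: the duplication is treated as
  instantaneous and fixed, and segregating copy number is out of scope.

The parameterisation of $C$ is chosen so that $C = 4Nc$ is the rate at
which *a given site* is covered by a tract. The per-site marginal process
is then exactly a two-island migration model with rate $C$, which yields a
closed-form oracle: for a single site with an infinitely old duplication,
a pair of lineages at the same locus has $E[T] = 2$ and a pair at
different loci $E[T] = 2 + 1/C$ (in $2N$ units; `two_lineage_oracle()`).
The simulator is tested against this identity by Monte Carlo.

Two numerical caveats follow from the tract construction. First, because
tract starts are uniform on the locus, the first $\sim\lambda$ sites at
the left edge are covered at a slightly lower rate than $C/2$ per lineage;
the identity above is exact for $L = 1$ (with $\lambda = 1$) and for
interior sites. Second, tract lengths are geometric with support
$\{1, 2, \dots\}$, so $\lambda \ge 1$ is required whenever $C > 0$.

### Demography and mutation

The population changes size instantaneously: relative size 1 for
$t < t_{exp}$ and $1/f$ earlier ($f \ge 1$ is the expansion factor), so
pairwise coalescence accelerates by $f$ in the ancestral epoch. Mutations
are Poisson on ancestral material at rate $\theta/2$ per site per $2N$
generations, giving the standard neutral expectation
$E[S] = \theta L a_n$ with $a_n = \sum_{i<n} 1/i$ for a constant-size
single locus. Infinite-sites mutations are mapped to the $L$ discrete
sites; a mutation landing on an already-mutated site is re-placed
(collisions are rare for $\theta L \approx 10$ and the total mutation
count is preserved). All user-facing times are in $4N$ generations and
converted internally.

### Default parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `n_A`, `n_B` | sampled alleles per locus | count | 14, 9 |
| `L` | sites per locus | bp | 1000 |
| `theta` | $4N\mu$ per site | — | 0.0085 |
| `C` | $4Nc$ per site (tract coverage) | — | 0 |
| `lambda_tract` | mean tract length | bp | 500 |
| `t_dup` | duplication time | $4N$ gen. | 0.5 |
| `growth_factor` | current / ancestral size | — | 1 |
| `t_exp` | expansion time | $4N$ gen. | 0 |

The sample sizes and `theta` mirror the motivating allele panel (14 + 9
alleles, Watterson estimate 0.0085 per site); `t_dup` = 0.5 encodes a
recent duplication on the coalescent scale while still letting each locus
largely coalesce internally first. Intralocus crossing-over is fixed at
zero: recombination between the paralogs is modelled as conversion only.

## Summary statistics

Per locus: segregating sites $S$, mean pairwise differences $\pi$ (total
and per site), Watterson's $\theta_W = S/(a_n L)$, Tajima's D and the
outgroup-polarized Fu & Li's D. Between groups: Hudson's
$F_{ST} = 1 - H_w/H_b$ from mean within- and between-group pairwise
differences. Across loci: each homologous column is classified as shared
(segregating in both loci), private (one locus) or a fixed difference,
with derived-allele spectra polarized by the outgroup.

Missing data (gaps, N) are handled by pairwise deletion throughout, the
convention of the desktop tools this mirrors; gap columns are never called
as SNPs. $\pi$ is reported uncorrected (no multiple-hits correction);
whether to apply a Jukes–Cantor correction is left to the user. Tajima's D
is undefined at $S = 0$ and reported as `NA` rather than an error.
Sliding windows default to 100 bp advancing by 25 bp and are fully
configurable.

The ABC statistic bundle is
$(S_A, S_B, \pi_A, \pi_B, D_A, D_B, n_{shared}, n_{fixed}, n_{private})$:
the cross-locus counts are the statistics most directly informative about
conversion (conversion creates shared polymorphism and erases fixed
differences), while the per-locus statistics anchor $\theta$-scale
variation. The set is configurable via the `stat_set` argument.

## ABC: estimation and model choice

`rejection()` standardizes each statistic by its standard deviation across
the reference table, retains the $k$ simulations with the smallest
Euclidean distance $\delta$ to the observed vector (ties broken by row
index), and `regression_adjust()` applies the local-linear correction:
each parameter is regressed on the standardized statistics with
Epanechnikov weights $1 - (\delta/\delta_{max})^2$, and the retained draws
are shifted by the fitted trend evaluated at the observed statistics.
Statistics that are constant among the retained set are inestimable and
contribute no trend; a fully singular design falls back to the unadjusted
draws with a warning. Adjusted draws are clamped to the prior support.
Posterior summaries are the mode of a Gaussian kernel density (Silverman
bandwidth, 512-point grid over the prior support) and the empirical
2.5%/97.5% quantiles.

Model choice pools the no-conversion and conversion reference tables,
standardizes jointly, retains the best $k$ overall and reports the
acceptance-ratio Bayes factor $BF = k_{M2}/k_{M1}$; when no $M_1$
simulation is retained the value is reported as a lower bound $> k$.

Priors are uniform and default to $C \sim U(0, 20)$,
$\lambda \sim U(50, 2000)$ bp and $t_{dup} \sim U(0.05, 2)$, with $\theta$
fixed at the observed Watterson estimate. Production scale is $10^5$
simulations retaining 500; the test suite and the acceptance script use a
scaled-down profile of $2\times10^4$ simulations retaining 200, at which
the package's own calibration study finds 95%-interval coverage of a true
$C = 1$ in roughly 19 of 20 repetitions, with the regression adjustment
reducing the posterior-mean RMSE relative to plain rejection.

Demography is **not** included inside the conversion ABC by default: the
expansion parameters enter the neutrality nulls (below), while the
conversion tables assume constant size. Both choices are available through
`SimParams`, so a user can run the conversion ABC under a fitted expansion
if preferred.

### Power of the model choice, honestly stated

Single-dataset model discrimination at this scale is limited. With
$n = 23$ alleles, $L = 1000$ and $\theta = 0.0085$ a dataset carries only
~30 SNPs, and two effects blur the models: a no-conversion model with a
very recent duplication also produces shared polymorphism, and ~25% of
true-conversion datasets at $C = 2$ carry few shared polymorphisms by
chance. In the package's simulation study the probability that the Bayes
factor exceeds 1 for data generated with conversion is ~0.6 at $C = 1$,
~0.8 at $C = 2$, ~0.98 at $C = 4$ and ~1 at $C = 8$, while data generated
without conversion give $BF < 1$ in ~95% of datasets. Observed panels with
strong conversion signal (many shared polymorphisms, no fixed
differences) yield large Bayes factors; borderline rates near $C \approx
1$–2 should be interpreted with the posterior interval, not the Bayes
factor alone.

## Demographic calibration

`fit_demography()` estimates $(\theta, f, t_{exp})$ from a panel of
unlinked single-copy reference loci. The observed vector is the mean and
variance across loci of $(S, \pi_{site}, D)$; each simulated dataset is
the same number of independent neutral single-locus coalescents under the
drawn demography, followed by the same rejection/adjustment machinery.
Loci with no segregating sites contribute to the $S$ and $\pi$ moments but
are dropped from the $D$ moments.

## Neutrality testing

`null_distribution()` simulates the fitted demography (with conversion for
coding-region nulls, without for flanking regions) and records Tajima's D
per replicate; undefined replicates are counted and excluded from
quantiles. Empirical p-values use the add-one convention
$p = (1 + \#\{D_{null} \ge D_{obs}\})/(reps + 1)$, which cannot return 0
from a finite simulation. Because the tail convention for a
balancing-selection test is a judgement call, `neutrality_test()` reports
upper, lower and two-sided p-values together with the 95% and 99%
empirical intervals; the upper tail is the default (balancing selection
predicts high D).

## Association scan

Phenotype classes follow the four functional categories of the motivating
panel: I = no protein accumulation (pseudogenes), II = protease not
inhibited by the pathogen effector, III = inhibited with attenuated
hypersensitive response, IV = inhibited with strong response. Two binary
contrasts are analysed: effector sensitivity (II vs III+IV) and HR
strength (III vs IV); class I alleles are excluded. Each marker is tested
by ordinary least squares of the contrast on the {0,1} genotype,
$R^2$ and the $F(1, n-2)$ p-value are reported raw alongside
Bonferroni-corrected values (the number of tests is the number of markers
actually tested), and significance is flagged at corrected 0.05 and 0.01.

The minor-allele-frequency filter is strict (`maf > threshold`) and the
threshold is a parameter (default 0.25). We deliberately expose it rather
than hard-coding: a published filter of ">25%" can be inconsistent with
individually interesting low-frequency variants, and the correct
denominator (all alleles vs phenotyped alleles) is a dataset-level
decision. No population-structure covariates are fitted, matching the
plain-GLM design this reproduces.

## The synthetic-data generator

`generate_gene_family()` produces a panel *shaped like* the observed data:

* binary coalescent haplotypes mapped onto a bundled ~1.1 kb synthetic
  ORF with one intron and a valid reading frame (alternative bases at
  exonic sites are drawn so that mutation noise never creates in-frame
  stop codons — pseudogene status is controlled explicitly);
* a balanced intronic dimorphism: all intronic variation is replaced by
  two haplotypes diverged at `type_divergence` per site (default 5%),
  assigned at intermediate frequency within each locus. The dimorphism is
  overlaid deterministically because the simulator is neutral; simulating
  the balancing selection that would maintain it is out of scope. A
  consequence worth knowing: intronic variation in synthetic panels comes
  *only* from the dimorphism;
* pseudogene alleles created by a 1-bp deletion (frameshift) or an
  injected in-frame stop;
* an outgroup carrying the ancestral state at every site;
* phenotype classes driven by designated causal SNPs with configurable
  penetrance and label misclassification; pseudogenes are always class I.

Passing tests on synthetic panels therefore demonstrate that the
pipeline's stages are mutually consistent and recover planted truth; they
do not demonstrate robustness to features the generator lacks — sequencing
error, alignment uncertainty, intralocus crossing-over, selection on the
coding region, or copy-number segregation.

## Numerical choices and degenerate inputs

* Sequence-type assignment uses deterministic complete-linkage clustering
  on intron-restricted pairwise distances (label 1 = larger group, ties
  broken by the lexicographically smallest allele id) instead of tree
  building with external software; a monomorphic intron returns an
  explicit "untyped" result.
* Pseudogene flagging reports "frameshift" when the gap-stripped coding
  length is not a multiple of three, otherwise "premature stop" when
  translation stops before the terminal codon; codons containing N are
  never called as stops.
* Replicates whose summary vector contains undefined values (e.g. D at
  $S = 0$) are re-simulated when building ABC reference tables, so tables
  contain no missing values.
* $F_{ST}$ returns 0 when there is no variation at all and `NA` only when
  within-group variation exists but between-group differences are zero.
* Simulation sizes in the shipped tests: 2000 replicates for calibration
  and null distributions, 10 000 for the conversion-time oracle,
  $2\times10^4$/200 for ABC — sizes at which the Monte-Carlo error is
  well below the assertion tolerances.

## Known limitations

* Total sample size is capped at 64 haplotypes (descendant sets are
  bitmasks); the motivating panels are far smaller.
* The duplication is fixed, not segregating; copy-number variation
  trajectories are not modelled.
* Fu & Li's D requires an outgroup; the outgroup-free D* variant is not
  implemented.
* Model-choice power at $C \lesssim 2$ is limited at single-dataset scale
  (see above).
* The left edge of a locus is covered by conversion tracts at a slightly
  reduced rate; analyses of tract-position fine structure should keep
  this in mind.
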