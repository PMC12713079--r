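---
title: "Gene-level association mapping in indexed EMS mutant populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level association mapping in indexed EMS mutant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsburden)
```

## The problem

EMS (ethyl methanesulfonate) mutagenesis saturates a crop genome with point
mutations — predominantly G/A and C/T transitions — and a sequenced
("indexed") mutant library records every line's full mutation catalogue.
That makes forward genetics a lookup problem in principle, but a hard
statistical problem in practice: each induced variant is carried by a
handful of lines out of thousands, so site-level minor allele frequency is
far below what any association test can use. The central move implemented
here is to collapse mutations to the **gene** level: the fraction of lines
carrying *some* mutation in a given gene is several-fold higher than any
single site's frequency, and it is the gene, not the site, whose disruption
drives the phenotype.

`emsburden` implements that full path: variant-table ingestion and
filtering, gene-level burden matrices, a dual-pathway association engine
with permutation-calibrated significance, spikelet-trajectory geometry
typing, and gene-level epistasis networks. A synthetic EMS-population
generator with known ground truth backs every stage, so the whole pipeline
is testable without any external data.

## Filtering the mutation table

Two filters precede any analysis.

**Quality.** Records with `QUAL < 50` or read depth `< 5` are removed
(`filter_by_quality()`; both cutoffs configurable, boundaries inclusive on
the keep side).

**Population frequency.** True EMS mutations are essentially private;
a site shared by many lines is almost certainly a calling artefact or
residual natural variation. Rather than fixing a cutoff by eye,
`null_frequency_threshold()` calibrates one by permutation: each line's
mutations are reassigned uniformly at random over the site catalogue
(preserving the line's mutation count), per-site carrier frequencies are
recomputed, and an upper-tail summary — the `per_perm_tail`-th largest
frequency over the whole catalogue — is retained per permutation. The
threshold is the `rank`-th largest summary across `n_perm` permutations
(defaults 1000 permutations, tail 500, rank 5). The published description
of this calibration is ambiguous about what exactly is ranked, so both the
tail size and the rank are explicit parameters rather than hard-wired
choices. `filter_by_population_frequency()` then removes every record at a
site whose frequency **strictly exceeds** the threshold — at the canonical
0.7% cutoff in a 1000-line population, a site seen in 8 lines goes, a site
seen in 7 stays.

## Gene burden matrices

`aggregate_by_gene()` produces three genes × lines matrices: raw mutation
counts, a 0/1 presence matrix, and an impact-weighted burden
$\sum_{k} e_k$, where $e_k$ is a numeric weight for the SnpEff impact class
of mutation $k$. Impact classes are categorical upstream, so the weights
are a package choice, recorded in every output: HIGH = 1.0, MODERATE =
0.66, LOW = 0.33, MODIFIER = 0.1. They are fully configurable
(`weighted_burden()`); the sum is not capped per gene. When one variant
carries several annotations, the most severe impact wins
(HIGH > MODERATE > LOW > MODIFIER), the usual burden-test convention.

## The dual-pathway association

Two independent views of the same question validate each other.

**Reverse pathway (phenotype → genotype).** The population is split into
phenotypically *deviant* and non-deviant lines: a line is deviant when its
trait value lies at least `z_threshold` (default 1.5) population standard
deviations from the reference centre (population mean by default, wild-type
mean optionally). No published tolerance exists for this split; 1.5 SD
keeps both groups non-trivially populated at EMS-typical effect sizes and
is exposed as a flag. Per gene, with `Obs` the carriers among deviant lines
and `Exp` the carrier count expected under independence, the literal
single-cell statistic

$$\chi^2 = \frac{(Obs - Exp)^2}{Exp}$$

is available (`mode = "literal"`), but it has no calibrated null
distribution, so the default is the standard 1-df 2×2 contingency
chi-square on carrier × deviant (`mode = "contingency"`); both are exposed
and the permutation threshold calibrates either.

**Forward pathway (genotype → phenotype).** Per gene, ordinary least
squares of the trait on the per-line burden predictor,

$$y_l = a \cdot \textstyle\sum_k e_{kl} + b + \varepsilon_l,$$

with a two-sided t-test on the slope $a$. The predictor is the weighted
burden by default; raw counts or 0/1 presence (the "mixed/binary" variant)
are flags. Wild-type reference lines enter at zero burden. This regression
reading — slope on the summed mutational effect — is the only
interpretation under which the published model statement is fittable; it is
a design decision, not a transcription.

**Permutation thresholds.** Trait values are permuted across lines
(default 1000 times); per permutation the most extreme per-gene statistic
is recorded, and the threshold is the $\lceil \alpha \, n_{perm}
\rceil$-th largest maximum, so strictly exceeding it has family-wise
probability $\approx \alpha$ under the null. Which multiplicity scope the
original method intended is unstated; the max-statistic family-wise null is
the default here because it is the conservative, self-calibrating choice,
and per-gene pointwise thresholds are available via
`statistic = "pointwise"`. Note the consequence, visible in the package's
own calibration runs: with ~15 carriers per gene, the contingency
chi-square saturates well below the family-wise cutoff over 1000 genes, so
moderate planted effects populate the candidate *pool* (the top-K
intersection) reliably, while the post-threshold candidate list is sparse
unless effects are large or thresholds pointwise. Both sets are returned
(`run_gla()$pool`, `run_gla()$candidates`).

**Intersection and prioritisation.** Genes are ranked per pathway by
p-value (ties broken lexicographically), the top K (default 300) per
pathway are intersected into the candidate pool, pool members beyond both
thresholds become candidates, and `prioritize_by_expression()` ranks
candidates by their maximum FPKM over tissues of interest (candidates
missing from the expression matrix are retained and flagged, never silently
dropped). Selection precedes the threshold filter; traits are analysed
independently with no cross-trait correction, matching per-trait reporting
practice.

## Spikelet trajectory geometry

Spikes differ in spikelet number, so per-line ordered measurements (angle
to the rachis in degrees, or gap along it in mm) are placed on a common
axis: spikelet $i$ of $n$ maps to $20(i-1)/(n-1) \in [0, 20]$. A
least-squares quartic summarises the trajectory (5 coefficients; at least 5
spikelets required, lines below that excluded with a flag), the curve is
evaluated at the 21 integer nodes, and the nodes are averaged over four
fixed sequential regions of 3, 8, 8 and 2 nodes (bottom, lower-middle,
upper-middle, top). The region sizes follow the published grouping; the
variance-based motivation behind them comes with no recomputation rule, so
they are constants with an override argument.

Each region is typed **I**ncreased / u**N**changed / **D**ecreased against
the population mean of that region (per-region by default; a whole-spike
grand mean by flag, since the published wording is ambiguous).
"Approximately equal" is operationalised as a ±2.5% relative band
(`rel_tolerance`, configurable; no published tolerance exists), falling
back to an absolute band when a population mean is zero. Four letters give
a spike-type code in an 81-code space (`spike_code_space()`). Profile
clustering is hierarchical (Ward linkage, Euclidean distance on the 21
nodes) — the published analysis names no algorithm, and Ward/Euclidean is
deterministic and standard for smooth profile matrices.

## Epistasis networks

For every pair of genes with at least `min_carriers` (default 5) carrier
lines, the trait is regressed on both presence indicators and their
product; the two-sided t-test on the interaction coefficient is the edge
statistic. This full-design OLS test is exactly reproducible and is pinned
against an independent normal-equations oracle in the test suite (the
correlation-shortcut implementations popular for speed agree with it on
centred inputs). The `N` smallest-p edges per trait (default 1000, ties
lexicographic) form the network; parallel edges from different traits are
merged for topology but keep their trait labels in the edge table. Degree
and shortest-path betweenness come from igraph, cross-checked in tests
against a hand-written BFS path-counting oracle. `node_removal_simulation()`
deletes one node per step (highest-degree hub, random candidate, or uniform
random) and records the average-degree trajectory; hub and random
trajectories start equal on the intact graph and are compared from step 1
on.

## The synthetic EMS population

`sim_config()` + `simulate_genotypes()` emulate the headline features of a
sequenced wheat EMS library: per-line mutation counts Poisson around a mean
of 4072 (the published per-line average; the count *distribution* is not
published, so Poisson is this package's choice, with a fixed-count option
for exact tests); sites uniform over a gene catalogue; 88.9% canonical EMS
transitions (G>A / C>T); impact classes drawn with MODERATE = 0.597 and
the remainder split equally over HIGH/LOW/MODIFIER (only the MODERATE share
is published; the equal split of the remainder is a package default, fully
configurable). Ref/alt, impact, QUAL and depth are site-level properties,
as in a real multi-sample VCF. Phenotypes follow an additive burden model
plus optional pairwise epistasis plus Gaussian noise, with wild-type rows
at zero burden by construction; spikelet tables are sampled from quartic
template trajectories with Gaussian noise.

What the generator does **not** emulate: recombination and selection,
chromatin-context mutation bias, mutation-density gradients along
chromosomes, genotyping error structure, shared-ancestry artefacts, or any
image-derived measurement process. Tests passing on this generator
demonstrate the statistical machinery under its stated model, not
robustness to those real-data complications.

## Problem sizes and calibration choices

The package's own calibration suites (test suite and
`scripts/acceptance.R`) use desk-scale versions of the study design, chosen
as the smallest sizes at which the statistical claims are sharp:
null calibration on 300 lines × 1000 genes at gene frequency ≈ 0.03 with
200 permutations and 100 replicate traits (family-wise error within the
95% binomial band of α = 0.05; regression p-values KS-uniform — the
chi-square pathway's statistic is discrete at these carrier counts, so
uniformity is asserted on the regression pathway); planted-effect recovery
with 10 causal genes of 2 phenotype units (≈ 1.4 trait SD) in 500 lines;
a planted pure interaction of 1.5 units among 1225 pairs in 400 lines;
simulator fidelity at >1e5 distinct sites; and 50 scale-free graphs of 60
nodes for the removal contrast. These sizes were fixed from power
calculations before the suites were run and are not tuned quantities.

## Numerical and degenerate-input choices

* Site identity is (chrom, pos, alt); coordinates are 1-based inclusive.
* Mutation tables are kept in canonical site-major order so VCF
  round-trips compare byte-identical.
* A constant trait yields an empty deviant set (warning), and no gene ever
  exceeds a permutation threshold.
* Zero-variance predictors, `Exp = 0` cells and collinear interaction
  designs are skipped with flags, never silently zeroed.
* Correlations in the vectorised permutation engine are clamped away from
  ±1 before the t transform to avoid 0/0.
* All stochastic entry points take explicit seeds and restore the caller's
  RNG state; fixed seed implies bitwise-identical output.

## Known limitations

No kinship or population-structure correction is provided (EMS populations
have essentially none, which is the method's premise); indel normalisation
and multi-allelic decomposition are upstream concerns (the reader takes the
first ALT); transcript-level collapsing, GO enrichment and homology-based
candidate annotation are out of scope. The literal single-cell chi-square
is reported for fidelity to the published formula but should not be used
for inference without its permutation threshold.
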