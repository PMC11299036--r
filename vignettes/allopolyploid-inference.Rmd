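---
title: "Discriminating ancient allopolyploidy from lineage sorting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating ancient allopolyploidy from lineage sorting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohybrid)
```

## The inference problem

When a clade carries subgenomes from two parental lineages — the signature
of allopolyploidization — its single-copy gene trees disagree with each
other in a characteristic way.  Loci that retained the copy inherited from
parent 1 place the focal clade B sister to superclade A; loci retaining
the other copy place it sister to superclade C; and loci in which both
homoeologous copies were homogenized (or that track the pre-hybridization
ancestor) place B sister to the clade (A, C) as a whole, diverging at the
parental split.  Incomplete lineage sorting (ILS) also generates
discordance, but with different quantitative fingerprints.  `paleohybrid`
implements the full chain of analyses that separates the two explanations:

1. ortholog filtering (redundancy clustering, two-step paralog removal, a
   substitution-saturation screen);
2. classification of rooted gene trees into the three topology-defined
   gene sets and frequency diagnostics;
3. Ks (synonymous-divergence) distributions with a high-identity cutoff
   and Gaussian-mixture peak detection;
4. an invariant-based site-pattern test for hybridization that estimates
   the inheritance probability $\gamma$;
5. a fixed-topology one-reticulation triplet fit;
6. fossil-calibrated strict-clock dating with a split-time concordance
   diagnostic.

A multispecies-coalescent (MSC) simulator on a one-reticulation species
network generates every input, so each stage is tested end to end with no
external data.

## The species network and the simulator

A `SpeciesNetwork` is a rooted ultrametric backbone tree (heights in
coalescent units, CU) plus one hybrid clade whose stem attaches to two
parental edges; a gene lineage reaching the reticulation follows the
parent-1 side with probability $\gamma$.  Lineages coalesce within each
population at rate $\binom{k}{2}$ per CU.  The packaged nine-taxon
case-study network mirrors the dated scenario the pipeline is designed
for: root at 370 Ma, earliest surviving split at 304 Ma, parental
superclade split at 268 Ma, hybridization at 248 Ma, with
$\gamma = 0.4511$.  Two free choices cannot be derived from the dated
scenario and are fixed once:

* **Coalescent scale: 20 Ma per CU.**  This places the parental split one
  CU above the reticulation, so routed loci show apprec. ILS
  ($\tfrac{2}{3}e^{-1} \approx 25\%$ discordance among routed loci) —
  discordance is present but does not swamp the signal, which is the
  regime in which the diagnostics are interesting.
* **Clock rate: 0.02 substitutions/site/CU (0.001 /site/Ma).**  The root
  then sits at 0.37 substitutions/site, deep enough that saturation and
  homoplasy are realistic concerns without making the outgroup unusable.

Both values are recorded in the generator's `truth.json` rather than
asserted as biological estimates.

The generator's locus classes (`both`, `parent1`, `parent2`, default
proportions 0.3746/0.2334/0.3919 applied by exact quota; a multinomial
mode is available) are **realized-topology classes**: each locus is
rejection-sampled until its backbone topology matches its class, mirroring
the fact that empirical gene sets are themselves observed-topology
partitions.  Consequently classification on true gene trees is exact by
construction — a property the test suite asserts — and the generator's
internal topology check is deliberately a separate, minimal code path
from the user-facing classifier.  "Both-retained" loci are modeled as a
topology class (the hybrid lineage injected into the ancestral population
at the parental split), not as sequence-level gene conversion.

What the simulator does **not** emulate: recombination within loci,
rate variation among lineages or sites, base-composition heterogeneity,
alignment error, and assembly artifacts other than the near-identical
redundant transcripts used for the Ks cutoff.  Passing tests therefore
demonstrate correctness of the inference chain under the MSC with a
strict clock, not robustness to every feature of real transcriptome data.

## Gene-set classification

`classifyFocalPosition()` prunes a rooted tree to A ∪ B ∪ C, requires B
monophyletic, and reads the class off the taxon content of B's sister
clade.  Taxa outside the three superclades are pruned first, because the
three candidate positions are defined relative to the superclades only.
The support threshold defaults to 0 (the tree is taken as given): support
semantics differ between ML bootstrap and the synthetic trees, so the
threshold is exposed rather than hard-coded.  When a threshold is set,
support is read from the original (unpruned) tree at the smallest clade
containing B and its sister content, which avoids relying on node-label
bookkeeping through pruning.

`ilsVsHybridPattern()` encodes the qualitative fingerprints: with sorted
counts $n_1 \ge n_2 \ge n_3$, ILS predicts the two minority topologies
nearly equal ($n_2 \approx n_3$, $n_1$ clearly ahead), while
hybridization predicts two high, nearly equal frequencies with one clear
minority.  Both comparisons use exact two-sided binomial tests at
$\alpha = 0.05$.  Under the quota class mix the hybrid verdict is
deterministic; under multinomial sampling at a few hundred loci the
near-equal top pair occasionally blurs the call, which the test suite
documents.

## Ks estimation and peak detection

`ng86Ks()` implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction.  Per position, the synonymous-site fraction is the share of
synonymous changes among the changes that do not create a stop codon
(stop-codon changes are not countable), so every codon contributes
S + N = 3 sites.  Multi-hit codons average the observed synonymous and
nonsynonymous differences over all minimal mutational pathways that avoid
stops, with equal weights; if every pathway is blocked, all pathways are
used with stop-entering steps counted nonsynonymous.  NG86 was chosen
over ML codon models because it is fully determined by counting rules and
hence verifiable against an exhaustive-enumeration oracle to 1e-12 —
which the suite does on 500 random pairs.

The paralog-pair generator inverts the estimator: for a drawn target Ks
it applies exactly the number of synonymous single-site differences that
yields the Jukes–Cantor-expected proportion
$p_s = \tfrac{3}{4}(1 - e^{-4K_s/3})$, using only site-count-preserving
changes so the realized estimate lands on the target (empirically within
±0.03).  Contaminant pairs — stand-ins for redundant transcripts and
splice forms — are near-identical copies (identity ≥ 0.90 by
construction, 2–9.5% random differences), which is what the identity
> 0.90 cutoff is designed to remove before mixture fitting.  Peaks are
fitted with unequal-variance Gaussian mixtures selected by BIC
(`mclust`); the default window [0.05, 5] excludes the near-zero mass
where redundancy, not divergence, dominates.  `Ks1` labels the oldest
(largest-mean) peak, `Ks2` the next.  Estimates beyond Ks ≈ 3 are close
to the Jukes–Cantor saturation boundary ($p_s = 3/4$) and intrinsically
noisy; the saturated flag is set at that boundary rather than returning
an extrapolated value.

## The site-pattern test for hybridization

Order the roles (outgroup, P1, hybrid, P2) and collapse alignment columns
into the three two-pair classes ABBA (P1 with hybrid), AABB (hybrid with
P2) and ABAB (P1 with P2).  Under the coalescent mixture model of hybrid
origin, conditional on the displayed parental tree, the two classes that
are discordant for that tree have equal probability (the hybrid and the
sister parent are exchangeable once they fail to coalesce on the internal
branch).  The excesses over the shared discordant class are therefore
proportional to the mixture weights:

$$\hat\gamma = \frac{n_\mathrm{ABBA} - n_\mathrm{ABAB}}
                    {n_\mathrm{ABBA} + n_\mathrm{AABB} - 2\,n_\mathrm{ABAB}},$$

clamped to [0, 1].  The tree null ($\gamma \in \{0, 1\}$) predicts one
excess to vanish, so the test is intersection–union: Z is the smaller of
the two standardized excesses and the one-sided p-value its upper normal
tail.  Standard errors come from a block jackknife whose blocks follow
the supermatrix partition map (one block per locus): sites within a locus
share one gene tree, and a multinomial variance would understate the
uncertainty substantially.  With several individuals per role, counts sum
over all role-respecting quartets, and the individual bootstrap reweights
the stored quartet-by-block count array, so 1,000 replicates cost no
recounting.  $\gamma$ is always reported as the share inherited from the
P1 (superclade A) side.

## The triplet network fit and its identifiability

For rooted-triplet counts $(n_{AB}, n_{BC}, n_{AC})$ the one-reticulation
MSC model gives

$$P(AB|C) = \gamma\left(1 - \tfrac{2}{3}e^{-t_A}\right) + (1-\gamma)\tfrac{1}{3}e^{-t_C},$$

and symmetrically for the other two topologies.  Three counts carry two
degrees of freedom, while the unconstrained model has three parameters
$(\gamma, t_A, t_C)$: the likelihood surface is an exact ridge (for any
$\gamma$ in an interval, branch lengths can be chosen to fit the observed
frequencies perfectly), so $\gamma$ is **not identifiable** without a
constraint.  The default fit therefore constrains $t_A = t_C$ — a single
hybridization time, which is also how the case-study network is built —
under which $\gamma$ is exactly identified, with closed form
$\hat\gamma = (n_{AB} - n_{AC})/(n_{AB} + n_{BC} - 2 n_{AC})$.  The
unconstrained fit remains available and reports `identifiable = FALSE`
when the profile likelihood over $\gamma$ is flat (e.g. symmetric
counts).  Parameter recovery under the constrained fit is within ±0.03 at
10,000 loci in the suite.

Note that when both-retained loci are present (the full case study), the
pure one-reticulation triplet model is misspecified — those loci inflate
$n_{AC}$ — and the fit collapses toward a boundary.  The pipeline reports
the fit as computed; the site-pattern estimate is the headline $\gamma$.

## Strict-clock dating and the concordance diagnostic

`strictClockDates()` dates a tree by mean path lengths: node depth is the
mean distance (substitutions/site) to descendant tips, the rate is the
least-squares fit through the origin of depth against age over the
calibrated nodes, ages are depth/rate with child ages clamped below
parents, and fossil ages are applied as fixed node ages.  On clock trees
this is exact (asserted to 1e-9).  Two practical choices matter on
estimated (NJ) trees:

* **The outgroup is dropped before dating.**  Rooting places the root
  somewhere along the outgroup branch, but its position there is not
  identifiable without a clock; keeping it would distort the mean-path
  depth of the root and hence the rate.  The deepest retained split is
  calibrated instead (304 Ma in the default configuration).
* **Coalescent depths exceed species split times** by the waiting time to
  coalescence (about one CU here).  The inflation applies to the
  calibration node and the nodes of interest alike, so the concordance
  *differences* the diagnostic uses are robust even though absolute ages
  are mildly biased.

The diagnostic itself dates the two conflicting gene sets separately:
gene set B (focal clade sister to A) yields the A–C split and the
focal-vs-A divergence; gene set C yields the A–C split and the
focal-vs-C divergence.  Under hybridization both pairs agree; under ILS
the deepest-coalescence geometry pushes the two parental-split estimates
apart.  "Very close" is operationalized as a relative difference of at
most 5% of the pair mean (the published ages this mirrors differ by
0.4%); the threshold is a tunable argument.

## Numerical and degenerate-input policy

* Jukes–Cantor distances with $p \ge 3/4$ are saturated: `Inf` by
  default, or an error under `saturated = "error"`.  Gap and ambiguity
  columns are excluded pairwise, maximizing usable sites.
* Negative NJ branch-length estimates are clamped to zero.
* Supermatrix columns are 0-based half-open in the partition map; taxa
  missing from a gene are gap-filled.
* All stochastic operations require an explicit seed, and the case-study
  builder writes byte-identical output for a given configuration.
* Mixture fitting refuses fewer than 50 usable Ks values or degenerate
  variance; the symmetric triplet-count case is flagged unidentifiable
  rather than returning an arbitrary interior optimum.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on simulated data
at sizes chosen to make the stochastic assertions stable: 10,000 gene
trees for coalescent frequency checks and the triplet fit, 500 loci ×
1,000 sites for site-pattern $\gamma$ recovery, 200 tree-like replicates
for the test's type-I error, 2,000 paralog pairs for the Ks-cutoff
experiment, the full 347-locus case study for classification (with
10,000-site loci for the NJ accuracy check), and 50 replicate case
studies of 120 loci × 500 sites for the dating concordance rates.

## Known limitations

The strict clock, equal base frequencies and JC/HKY models are the
simulator's world, not a claim about real transcriptomes; absolute ages
from real data are explicitly out of reach of the mean-path-length dater.
The saturation screen is an entropy index against a full-randomization
null, not a reimplementation of the published index it stands in for.
The one-reticulation triplet fit assumes the network topology; it
estimates parameters, it does not search network space.  Finally, the
site-pattern test assumes the outgroup is a true outgroup at every locus;
extremely deep ILS involving the outgroup would violate its
polarization.
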