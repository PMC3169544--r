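---
title: "Diagnosing hybrid speciation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrid speciation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridhallmarks)
```

## The scientific problem

A putative hybrid species — a reproductively distinct daughter lineage
founded by interbreeding between two parental species — leaves a
characteristic set of genomic signatures that separate it from a
contemporary hybrid swarm:

* **balanced genome-wide admixture**: roughly equal ancestry from both
  parents, yet forming its own genetic cluster rather than a smear between
  the parental ones;
* **low linkage disequilibrium (LD)**: admixture LD decays by half each
  generation at unlinked loci, so an old hybrid sits at the parental
  background while fresh laboratory crosses and recent swarms are elevated;
* **private variation**: enough isolation time to accumulate
  species-specific polymorphisms and haplotypes, at rates approaching the
  parents';
* **a sex-linked mosaic**: in ZW systems (Lepidoptera: males ZZ, females
  ZW; the W and the mitochondria are co-inherited maternally), one parent
  can dominate the maternal line while the other dominates the Z.

`hybridhallmarks` implements the full battery of diagnostics — AMOVA
fixation indices with permutation tests, ancestry-informative marker
classification, a Gibbs-sampler admixture model for dominant markers,
pairwise exact LD tests, species-specific diversity statistics with
one-way ANOVAs, neighbor-joining phylogenies with bootstrap support and
Fitch parsimony trait mapping, and a molecular-clock split-time
calibration — together with a structured-coalescent simulator of the
hybrid-speciation demography, so that every diagnostic can be validated
on data whose ground truth is known.

## The AMOVA fixation index

For a locus with pairwise sequence distances $d_{ij}$ and populations as
groups, the total sum of squared distances is partitioned into
within-group and among-group components; with $\sigma^2_w$ and
$\sigma^2_a$ the respective variance components,

$$\Phi_{ST} = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_w}.$$

Significance comes from permuting group labels over sequences: the
p-value is the fraction of permutations whose $\Phi_{ST}$ reaches the
observed one, with the plus-one correction for finite permutation counts
(so the smallest attainable p is $1/(n_{perm}+1)$; the default is 10,000
permutations). With `n_perm = Inf` all label permutations are enumerated
and the p-value is exact — the test suite verifies this equivalence on
every instance with up to 8 sequences. Design choices:

* sequence distance is the number of differing polymorphic sites, with an
  indel event of any length counting once and pairwise deletion of
  missing data;
* binary markers are treated as haplotypes of length one (0/1 distance),
  so dominant-marker and sequence AMOVAs share one machinery;
* negative variance components are reported as computed, with a flag,
  because truncation would break the exchangeability of the permutation
  test;
* haploid (female Z, mtDNA) and diploid (male Z) sequences enter the same
  haplotype-level decomposition.

## The admixture model

Bands are modeled as haploid binary observations: individual $i$'s band
at marker $m$ originates from cluster $k$ with probability $q_{ik}$ and
is present with that cluster's band frequency $p_{km}$. The Gibbs sweep
samples origins $z$, then $p$ from its Beta(1,1)-conjugate full
conditional, then each $q$ row from its Dirichlet($\alpha$) full
conditional ($\alpha = 1$, fixed). Posterior means over the collection
sweeps are reported; label switching across runs is resolved post hoc by
greedy matching of `q` columns (`align_labels()`), never inside the
sampler.

Treating the dominant genotype as the allele itself is a deliberate
simplification: it keeps every full conditional conjugate and is the main
caveat of the module — a dominance-aware genotype likelihood (band
present given one *or* two presence alleles) is a stated non-goal. The
consequence worth knowing about is that F1 individuals, which show the
band at every marker where either parent is fixed for presence, only read
as 50:50 mixtures when presence alleles are about equally split between
the parental backgrounds, which is what both the simulator and real AFLP
panels produce.

Scaled-down defaults (burn-in 5,000, 20,000 collection sweeps) are
desk-size; analyses of the published scale (200,000 / 1,000,000) are
reachable through the same arguments.

## The structured-coalescent simulator

Three demes — two parents that split `T_parent_split` generations ago and
a hybrid founded at `T_hybrid_origin` — with, going backward in time:
lineages in the hybrid deme migrating into a parent at the per-generation
immigration fractions (`m_A_to_H`, `m_B_to_H`; migration *into* the
parents is zero — introgression is unidirectional); at the founding time
each remaining hybrid lineage assigned to parent A with probability
`alpha` (maternal loci use `alpha_maternal`); at the parental split all
lineages merging into the ancestral deme. Mutations follow the
infinite-sites model projected onto finite sequences (distinct sites per
locus; collisions resolved by redraw), with `theta_per_locus` calibrated
so a panmictic deme of parent A's size has expected pairwise diversity
$\theta$ — the suite checks $E[\pi] = \theta$ against 200 replicate loci.

Inheritance is implemented by copy-number bookkeeping rather than explicit
pedigrees: autosomes have $2N_e$ copies (two per sampled individual), Z
loci $1.5\,N_e$ (two per sampled male, one per female), mitochondria
$N_e/2$ (females only, one per sample, with the W chromosome represented
by the mtDNA proxy, as their co-inheritance justifies). One generation
equals one year — both focal swallowtail species are essentially
univoltine or bivoltine. Dominant markers are single biallelic autosomal
loci conditioned on segregating (one mutation placed on the genealogy
with probability proportional to branch length), with the presence allele
assigned at random and the band shown iff at least one presence allele is
carried.

Defaults are the desk-scale study conditions: $N_e = 1{,}000$ for every
deme, parental split at $4N_e$ generations, hybrid origin at $0.7N_e$
(preserving the published ratio of a much younger hybrid origin than the
parental split), founding fraction 0.5 from each parent, immigration
fractions scaled from the published population migration rates
($2Nm = 2.3$ and $1.8$), one mitochondrial plus six Z-linked loci,
$\theta = 5$ per locus, and 20 sampled individuals per population.
Effective sizes are not published for this system; they are surfaced in
`scenario_params()` and never hard-coded in any analysis.

What the generator emulates: the demographic topology, sex-linked
inheritance, dominance, laboratory F1/F2 crosses (gametes drawn from
genotype pools, free recombination), and forward-time recent swarms with
parent-B maternal founding. What it does not emulate: physical linkage
among markers, within-locus recombination, selection, band-size
homoplasy and scoring error in real AFLP gels, and range dynamics.
Passing tests therefore validate the statistical machinery under the
stated demography, not the field realities of AFLP data.

## Scenario choices for the end-to-end checks

Three scenario configurations are fixed once and used by the acceptance
checks; each is the package's reading of the study system it represents.

**Old hybrid species (admixture recovery).** Founding admixture
`alpha = 0.5` followed by isolation (`m = 0`), sampled after $0.7N_e$
generations, with an 800-marker panel (genome-wide AFLP panels run to
thousands of markers; roughly a quarter of simulated markers are lost to
the band-polymorphism filter). Isolation after a founding burst is the
study's own conclusion for this system — a brief hybridization episode
with little backcrossing; continuous migration at the published $2Nm$
would also double-count the founding pulse, because an
isolation-with-migration estimator absorbs an admixture-founding event it
cannot represent into its migration rates. Under this scenario the
sampler recovers mean hybrid ancestry within [0.4, 0.6] at $K=2$, gives
the hybrid its own cluster at $K=3$ (mean own-cluster $q > 0.9$ across
seeds), and keeps laboratory F2s split between the parental clusters at
$K=3$ — the qualitative contrast that distinguishes an old hybrid species
from fresh hybrids. The marker count matters: ancestry balance at $K=2$
is estimated against marker-specific drift noise that shrinks as
$1/\sqrt{M}$, and at a few hundred markers single datasets can wander
outside [0.4, 0.6] by drift alone.

**Linkage-disequilibrium ordering.** Laboratory hybrids are 30 F1 plus 30
F2 offspring descended from three breeding pairs per species — few
founding parents, as in real crossing designs. With unlinked markers the
lasting LD in cross cohorts comes from exactly this brood structure
(co-segregation of the few founder genomes), while the old hybrid, a
large random-mating population, sits at the parental background. The
parental split is set at $2.5N_e$ here so the parents retain appreciable
within-species polymorphism for the founders to segregate. One hundred
replicates give the published ordering (laboratory hybrids above the old
hybrid, old hybrid within one percentage point of the parental
background) in at least 95. Within-gene sequence LD is deliberately not
used for this ordering: without intralocus recombination, haplotype-block
LD persists in the old hybrid — which is exactly the pattern the study
reports for Z-linked genes, where the old hybrid matches one parent
rather than decaying.

**Sex-linked mosaic.** Deep parental split ($8N_e$), very recent hybrid
origin ($0.06N_e$), maternal founding entirely from parent A
(`alpha_maternal = 1`), nuclear founding mostly parent B
(`alpha = 0.2`), weak symmetric trickle migration. This recovers
near-zero mtDNA $\Phi_{ST}$ against the maternal parent with near-fixed
differentiation from the other parent, and the reverse ordering at Z
loci. The recency matters: mtDNA has effective size $N_e/2$, so an older
origin would let maternal drift erase the "$\approx 0$" half of the
pattern.

## Marker and genotype classification

Ancestry-informative markers are those significantly differentiated
between the parents (AMOVA permutation p ≤ 0.05 by default, the
conventional screen level). Against the hybrid, the four-way
classification is driven by the two significance outcomes: parent-A-like
(different from B, not from A), parent-B-like (the mirror), different
(both), intermediate (neither, with the hybrid frequency inside the
closed parental interval). The residual case — significant against
neither parent but a frequency outside the parental interval — is not
covered by the four published categories; it is flagged
`outside_nonsignificant`, counted with `intermediate` in headline totals,
and reported separately for audit. Ties (hybrid frequency exactly equal
to a parental one) resolve by the significance pattern alone.

Per-individual genotype classes at sequence polymorphisms use a stricter
gate (parental p ≤ 0.001, as conventional for per-site displays), code
each allele by the parent in which it is more frequent, call ZZ males
carrying one allele of each class heterozygous, and code alleles seen in
neither parent as missing with a warning count. Note a finite-sample
subtlety the test suite documents: an allele "diagnostic" in a parental
sample need not be fixed in the parental population, so a small minority
of deep-coalescing hybrid lineages can legitimately miscode even when
ancestry is pure.

## Linkage disequilibrium

The concrete pair test is Fisher's exact two-sided test on the 2×2 band
table (computed by direct hypergeometric enumeration and verified against
`stats::fisher.test` on every table with total ≤ 12), with pairwise
deletion of missing individuals; pairs monomorphic after deletion leave
the denominator. This replaces the EM-based genotypic exact test some
legacy software applies to unphased diploid data — AFLP bands and
haploid/phased sequences give unambiguous tables, so the simpler test is
the right one here, and the divergence is documented. The published
summary phrase "average percentage of polymorphisms significantly
associated with each other" is ambiguous between pairs and
per-polymorphism averages; both are computed (the percent of significant
pairs is headline; per-polymorphism fractions, whose mean ± SD mirror the
published table layout, feed the one-way ANOVA between populations).

## Diversity statistics and calibration

A site counts as a species' polymorphism when the species is variable
there or is fixed for an allele found in no other species; it is
species-specific when the species' minor (or fixed private) allele occurs
in no other species. Haplotypes are distinct full-locus sequences within
the species, compared over polymorphic sites with missing calls
mismatch-neutral. Proportions enter the one-way ANOVA as exact fractions
(7/11, not 64%), untransformed — this recovers the published F statistics
(1.90 and 3.47 on 2 and 18 df) from the published counts; an arcsine or
logit transform is deliberately not applied. The packaged count table
(`swallowtail_diversity_counts()`) ships as plain text so those summaries
are recomputable exactly.

The split-time calibration is the two-lineage clock quotient
$T = d / (2r)$: 3.17% average outgroup divergence at 1.15% per lineage
per million years dates the outgroup split at 1.38 ≈ 1.4 Myr. The
hybrid-zone fraction is reported against the phenotypically pure count
(16/286 = 5.6%), the reading that reproduces the published value; the
grand-total alternative (16/302) is also returned.

## Phylogeny and trait mapping

There is no substitution model for anonymous dominant bands, so the tree
is distance-based: mean character difference (the standard default for
such data; Jaccard available) into Saitou–Nei neighbor joining, which
recovers any additive matrix exactly — verified on random additive trees
— with negative branch lengths clamped to zero, the deficit moved to the
sibling edge, and the clamp flagged. Bootstrap support resamples marker
columns with replacement (2,000 pseudo-replicates at the published
scale) and counts original bipartitions among replicate trees.

Binary ecological traits (mimicry, diapause, voltinism, and the like) map
onto the tree rooted at the declared outgroup by minimal-change (Fitch)
parsimony, implemented as a unit-cost dynamic program that yields both
the minimal change count and, per node, the full set of states attained
by some most-parsimonious reconstruction — so genuinely ambiguous
histories (a trait gained twice versus gained once and lost) are reported
as sets, not collapsed to one history. The change count is verified
against exhaustive enumeration over all ancestral labelings on small
trees and against an independent parsimony implementation. A putative
hybrid taxon does not belong on a bifurcating species tree: it is dropped
from the pass and its states reported post hoc next to the
reconstruction.

## Pipeline and reproducibility

`run_all()` drives simulate → AMOVA → marker/genotype classification →
admixture → LD → diversity → tree from one `run_config()` with a
mandatory master seed. Each stage draws from a named substream of that
seed (`substream_seed()`), so stages are individually reproducible and
the manifest is byte-identical across reruns of the same configuration;
timings and warnings go to the log, never the manifest. Stage failures
are logged and dependent stages skipped, with the bundle reporting per-
stage status.

Problem sizes used by the shipped end-to-end checks (the package's
choices, documented here once): exhaustive AMOVA instances at 6–8
sequences; 500 null loci for p-value calibration; the three scenario
configurations above with 800, 80 and a handful of markers/loci
respectively; MCMC at 1,000 + 4,000 sweeps; 100 LD replicates; 100
random additive matrices; 200 bootstrap pseudo-replicates.

## Known limitations

* The admixture likelihood ignores dominance (haploid-band
  simplification) and uses the uncorrelated-frequency model with fixed
  prior weight; no model choice for K is provided.
* Sequence loci are non-recombining blocks; LD between sites of one locus
  never decays.
* Markers are unlinked; physical-linkage LD in real genome-wide panels is
  not represented.
* The species-specific counting rule and the N-wildcard haplotype
  clustering are greedy, order-stable conventions; other defensible
  readings of "species polymorphism" exist and would shift counts
  slightly.
* Isolation-with-migration estimation (divergence times, migration rates
  from real data) is out of scope; the calibration here is the simple
  clock quotient.
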