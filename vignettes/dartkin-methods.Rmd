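---
title: "Fingerprinting, kinship and ploidy-aware parentage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting, kinship and ploidy-aware parentage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartkin)
library(dplyr)
```

## The problem

Germplasm collections of clonally propagated crops (apples are the
motivating case) accumulate three kinds of redundancy and hidden structure
that curators need to resolve: *clones and duplicates* (the same cultivar
accessed several times, or somatic mutants, "sports"), *mislabelled or
mis-collected accessions*, and *undocumented close relationships* —
including heteroploid ones, where a triploid cultivar arose from a diploid
parent via an unreduced gamete. dartkin implements a complete analysis
chain for such collections from two complementary marker systems:

* **dominant presence/absence markers** (DArT-style): thousands of binary
  band calls per accession, blind to allele dosage, used for pairwise
  similarity;
* **codominant SSR profiles**: a small panel of microsatellite loci (the
  defaults assume twelve, each on a different chromosome) scored as
  fragment sizes in bp, used for exclusion-based parentage verification.

## Jaccard similarity on dominant calls

For accessions $x$ and $y$, over the markers observed in both, let $a$ be
the number of shared band presences and $b$, $c$ the counts present in
exactly one accession. The similarity is

$$ J(x,y) = \frac{a}{a+b+c}. $$

Joint absences are excluded: for a dominant marker, the shared *absence* of
a band is homozygosity for the null allele and carries far less information
about co-ancestry than a shared presence, and the Jaccard coefficient (not
simple matching, and not Dice) is the intended statistic. This is stated
explicitly because dominant-marker workflows sometimes silently substitute
one for another.

Missing calls are handled pairwise-complete: each pair is scored on the
markers observed in both, and the co-observed count `n_shared` is exported
so users can filter low-overlap pairs. A pair with no co-observed
informative marker gets `NA`, never an arbitrary number.

## Thresholds and relationship calling

The default thresholds are the calibrated values for collections of this
kind: `clone = 0.90`, `borderline = 0.88`, `close = 0.80`.

* $[0.90, 1]$ — clone or duplicate. The band is closed at the bottom on
  purpose: a documented triploid offspring of a diploid cultivar can reach
  exactly 0.90 against its parent, and such a call must be *resolved* by
  independent evidence (SSR, ploidy), not silently demoted.
* $[0.88, 0.90)$ — borderline; raises a review flag only, because some
  true clone sets (notably of triploid cultivars) score in this band.
* $[0.80, 0.88)$ — closer than a standard parent-offspring or
  full-sibling relationship. Ordinary first-degree pairs concentrate well
  below 0.80; pairs above it usually carry extra co-ancestry (inbreeding)
  or a transmitted unreduced gamete.

**Clone collapse** builds single-linkage components over clone-band edges
and keeps one representative each (the lexicographically lowest id, with a
user keep-list override — the choice is arbitrary in substance, so it is
made deterministic). An edge is *severed*, and both accessions retained
with a `collecting_error_suspect` flag, when the pair is indistinguishable
by dominant markers yet differs at two or more co-scored SSR loci or has
conflicting known ploidies. This is what distinguishes a true duplicate
from a collecting error, and what keeps a diploid parent from being merged
with a high-scoring triploid offspring.

**Close groups** are single-linkage components over edges in
$[\mathrm{close}, \mathrm{clone})$ on the collapsed collection. Single
linkage is a deliberate formalisation: heteroploid families are held
together by the shared gamete-donating parent even when peripheral
offspring–offspring pairs dip below the threshold (in simulations the
within-family range is roughly 0.70–0.90). Groups are partitioned by
ploidy into `diploid_sibling_group`, `heteroploid_group` and
`mixed_unknown`.

## Ploidy-aware SSR parentage rules

All parentage logic is exclusion-based: a candidate parent is rejected
only when a scored locus *cannot* be reconciled with any gamete the
candidate could produce. Three gamete models are implemented:

| model | transmits | offspring | typical use |
|---|---|---|---|
| `haploid` | 1 allele/locus | diploid | ordinary trio checks |
| `unreduced_diploid` | both alleles | triploid | first-division restitution |
| `triploid` | full 3x complement | tetraploid | triploid-gamete offspring |

Key conventions, each of which matters in practice:

* **Homozygosity is never assumed.** A single reported size means "at
  least one copy, possibly homozygous"; loci whose consistency relies on
  possible homozygosity get the distinct status
  `consistent_homozygous_ambiguous` so downstream counts can separate
  proven from ambiguous support.
* **Tolerance.** Under the polyploid models one absent parent allele per
  pair is tolerated by default (`tolerance = 1`, status
  `tolerated_missing`, overall `plausible_with_tolerance`): a single
  allele can be lost by a crossover during restitution, and the strict
  mode (`tolerance = 0`) is one switch away. Tolerance is monotone: the
  strict verdict is never more permissive.
* **Missing data are never wildcards.** Loci unscored in either profile
  are `no_data` and excluded from all counts.
* **Allele equality is exact** (integer bp). A 2 bp "one-repeat-shift"
  near-miss is annotated (`shift_2bp`), because such shifts are known to
  arise by mutation without invalidating a pedigree — it warns, never
  rescues or excludes.

`infer_missing_parent()` computes, per locus, the residual alleles the
unknown parent must supply given the accepted parent and gamete model, and
screens a panel: a candidate survives iff no scored locus excludes it. A
*unique* survivor is the classical exclusion standard for proposing a
pedigree, and the pipeline never auto-asserts a parent otherwise.
`full_sib_plausible()` unifies two offsprings' residuals and asks whether a
single diploid genotype (at most two distinct alleles per locus) could
have fathered both. Timeline checks compare documented origin years and
only ever *flag* conflicts — historic dates are frequently `pre`-dated
upper bounds.

## Evanno delta-K

From replicate clustering runs $(K, r, L_r(K))$, the per-replicate second
difference $L''_r(K) = L_r(K{+}1) - 2L_r(K) + L_r(K{-}1)$ gives

$$ \Delta K = \frac{\mathrm{mean}_r\,|L''_r(K)|}{\mathrm{sd}_r\,L_r(K)}. $$

Endpoints carry no $\Delta K$; zero replicate SD or a single replicate is
flagged rather than silently dropped. All local maxima are reported with a
prominence measure (peak over median), not just the argmax — secondary
peaks at much larger K can capture real finer structure and deserve to be
visible. `plateau_k()` operationalises the visual "ln P stops improving"
criterion as the smallest K whose next relative gain falls below `rel_tol`
(default 0.01, exposed and recorded in the output). The statistic is
invariant to shifting and positive scaling of the log probabilities and to
row order of the input, which the tests assert.

## The simulator and what it does (and does not) emulate

`simulate_collection()` plants a known truth — founders, clone sets,
diploid full-sib/half-sib families, unreduced-gamete triploid families and
triploid-gamete tetraploids — and renders it exactly in the formats the
analysis consumes. Defaults are the study conditions the package is
calibrated for, chosen once and not revisited:

* 562 dominant marker loci; presence-allele frequencies uniform in
  $[0.05, 0.95]$; founders in Hardy–Weinberg proportions, so the rendered
  band frequency follows $1-(1-p)^c$ for $c$ copies (checked in tests).
* 12 SSR loci, 8 alleles each spaced 2 bp, symmetric-Dirichlet
  frequencies.
* clone flip rate $\varepsilon = 0.005$ per marker — calibrated so clone
  pairs land in the 0.97–1 replicate-similarity band.
* per-locus homozygosity loss $\lambda = 0.05$ in unreduced gametes —
  matching the observation that a missing parental allele in a triploid
  profile is possible but rare (about one allele in a 12-locus profile
  for a few percent of offspring).
* missingness 0.01 per dominant call; SSR rendering is dosage-blind
  (distinct sizes only) and complete.
* unreduced gametes are maternal by default, reflecting the evidence that
  triploid apple hybrids generally receive the diploid gamete from the
  mother; configurable per cross.

Crossover loss is modelled as per-locus homozygosity substitution, not
positional recombination: the SSR panel sits on different chromosomes, so
linkage is irrelevant at this scale. What the simulator does *not*
emulate: population structure and admixture among founders, genotyping
batch effects, allele dropout in SSR scoring, coalescent-realistic
history, or selection. Passing tests therefore demonstrate correctness of
the inference rules under idealised random mating — not robustness to
structured real-world collections, where thresholds may sit closer to the
tier boundaries.

With these defaults the simulated similarity tiers reproduce the expected
ordering (unrelated < half-sibs < parent–offspring < full sibs <
triploid-offspring pairs < clones), with unrelated pairs around 0.6–0.7,
parent–triploid-offspring pairs around 0.85–0.91, and clones above 0.97 —
the same qualitative geometry that motivates the 0.80/0.90 thresholds.

## Numerical and degenerate-input choices

* Similarity is reported to three decimals in written outputs (0.901 vs
  0.902 is a meaningful difference at the clone boundary); full precision
  is kept in memory.
* KDE uses a Gaussian kernel with the bandwidth as the kernel SD on a
  512-point grid spanning $[\min - 3h, \max + 3h]$; the bandwidth applies
  on whatever scale the caller passes (0.75 on a 0–100 scale equals
  0.0075 on the 0–1 scale). Degenerate all-equal input is flagged.
* Component numbering and representatives are deterministic (ordered by
  lowest member id), so reruns are byte-identical.
* An accession pair with no co-observed informative marker is `NA`
  end-to-end; an SSR pair with no commonly scored locus raises an
  indeterminate error rather than returning a verdict.
* All randomness flows from a single configuration seed;
  `simulate_collection()` is a pure function of its configuration.

## Worked example

```{r example}
b <- simulate_collection(sim_config(seed = 7, n_founders = 20))
res <- run_pipeline(b$markers, b$meta, b$ssr, screen = FALSE)
res

res$close_groups |> select(group_id, n_members, group_class)

res$heteroploid_assessments |>
  filter(model == "unreduced_diploid") |>
  select(parent_id, offspring_id, overall) |>
  head()

res$tier_summary
```

The heteroploid group contains the planted diploid mother and her eight
triploid offspring plus the derived tetraploid; the SSR complement check
names the true mother plausible for every offspring, and the triploid
gamete donor of the tetraploid is the only non-excluded candidate among
the group's triploids.

Problem sizes used throughout the package's own validation: 50 random
20-by-50 fixtures for the oracle-equivalence check; 1,000 clone and 1,000
unrelated pairs at 562 markers for band separation; 50 collections of one
unreduced-gamete family of eight for heteroploid recovery; 100 trios
against 200-candidate panels at 12 loci for exclusion power; 100 seeded
ladders for elbow recovery.

## Known limitations

* The identical-call-vector rule is a stand-in for sequence-based marker
  redundancy screening; when an authoritative non-redundant marker list
  exists, pass it via `redundancy = "provided_list"`.
* Shared-gamete detection between two triploids (possible triploid
  sibling pairs sharing a full diploid profile) is not implemented beyond
  what shared-allele counts reveal.
* Likelihood-based parentage (LOD scores), linkage-aware inheritance and
  chromosome-level aneuploidy modelling are out of scope; the exclusion
  rules are deliberately assumption-light.
* The Bayesian admixture clustering itself is not run here; only its
  replicate log-probability summaries are consumed.
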