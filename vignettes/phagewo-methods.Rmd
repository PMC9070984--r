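---
title: "Methods: phage WO typing, transfer and recombination"
author: "phagewo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phage WO typing, transfer and recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagewo)
```

## The problem

Phage WO is the only bacteriophage known to infect *Wolbachia*, the
maternally inherited endosymbiont of a large fraction of arthropods. A
short amplicon of the phage's minor capsid gene *orf7* serves as a typing
marker: cloning and sequencing the amplicon from a *Wolbachia*-infected
insect yields a sample of the phage haplotypes ("WO types") its symbiont
carries. From such a marker set, three questions follow:

1. **Typing** — how many distinct phage types does each host (each
   *Wolbachia* strain) carry?
2. **Horizontal transfer** — which types recur in hosts carrying
   *different* *Wolbachia* strains (identified by their MLST sequence
   type, ST), which is only explicable by lateral movement of the phage?
3. **Intragenic recombination** — which types are mosaics of other types
   found in the same host, and where are the breakpoints?

`phagewo` implements this pipeline as composable functions plus a
synthetic-data generator with planted ground truth, so that every stage
can be validated without any external data.

## Pseudogene filtering

*orf7*-like sequences with internal stop codons are relic prophage
fragments rather than functional capsid genes; they are flagged and
excluded from typing. A record is a pseudogene when, read in frame with
its own gaps removed, it contains TAA/TAG/TGA strictly before its final
complete codon — the amplicon is an internal gene fragment, so a stop in
the last codon is not disqualifying. The frame is auto-detected as the
lowest frame in which the majority consensus of the alignment is free of
internal stops; if no frame qualifies the user must supply one
(`flag_pseudogenes(aln, frame = )`).

## Distances and typing

Pairwise distances use the Kimura two-parameter model with **pairwise
deletion**: columns where either sequence has `-` or `N` are dropped,
and with transition proportion $P$ and transversion proportion $Q$ over
the $n_\mathrm{eff}$ remaining sites,

$$ d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big]. $$

When the logarithm's argument is non-positive (saturation) the distance
is *undefined* and treated as larger than any threshold, so saturated
pairs never merge. The implementation returns $P$, $Q$, $n_\mathrm{eff}$
and the raw mismatch count for every pair; it is cross-checked in the
test suite against an independent single-pair counting oracle and
against `ape::dist.dna(model = "K80", pairwise.deletion = TRUE)`.

Two sequences belong to the same **phage WO type** when their distance
is at most `type_threshold` (default 0.015, i.e. 1.5% divergence or
98.5% identity). Because a pairwise rule is not transitive, a linkage
convention is needed; the default is **single linkage** (connected
components of the threshold graph), which reproduces the field's
"identical or one base substitution" groupings conservatively, with
complete linkage available (`linkage = "complete"`), and
`overlimit_pairs()` reporting any intra-type pair beyond the threshold.
An alternative `identity_mode = "p_identity"` clusters on uncorrected
identity instead of the K2P distance; in the small-distance regime the
two agree except exactly at the threshold boundary. Output is
deterministic: types are ordered by size (then lexicographically
smallest member id) and named `WO` + host abbreviation (first letter of
the genus + first two letters of the epithet) + index, e.g. `WOPma-1`.

Typing is run per species for naming and counting, and globally (all
species jointly) for transfer detection; `scope` selects between the
two. A host shows a *multiple phage infection* when it carries strictly
more than two types; `multi_infection_pct()` reports the percentage of
such hosts, rounded to integer for display.

## Horizontal-transfer enumeration

One **transfer event** is one global phage type whose member sequences
occur in hosts with at least two distinct strain keys. Strain keys are
MLST STs; species whose ST could not be resolved are kept as their own
pseudo-strain (keyed by species and *wsp* allele) so they can still
participate, and events whose strain contrast rests only on
pseudo-strains are flagged `st_unresolved` rather than dropped. Events
record the species, strain and supergroup composition
(`cross_supergroup` when both A and B are involved) and the minimum
between-host distance inside the type. A stricter tally
(`mode = "strict_identity"`, at most one base difference) is also
available, since shared types are in practice near-identical across
hosts. No directionality is inferred. `shared_types_within_strain()`
gives the complementary within-strain view: which types are shared
between the host species of one strain and which are private.

## Recombination detection

Recombination is sought **within species** (types co-residing in one
host are the ones that can physically recombine), among the type
representative sequences, for every species with at least three
functional types. For every (child; parent pair) triplet the
*informative sites* are the columns where the parents differ and the
child matches exactly one of them. Five statistics are computed per
triplet:

* **MaxChi** — maximum over all cuts (and both parents) of the 2×2
  chi-square (match/mismatch × left/right) of the child-versus-parent
  match vector on the triplet's variable sites, no continuity
  correction.
* **Chimaera** — the same cut scan on the binary "child matches parent 1
  vs parent 2" vector over informative sites only.
* **3Seq-style walk** — informative sites encoded ±1; the statistic is
  the larger of the maximum ascent and maximum descent of the cumulative
  walk. (The original method's exact hypergeometric tables are *not*
  used; significance comes from the same permutation machinery as the
  other methods.)
* **GENECONV-style run scan** — the best maximal run of consecutive
  informative sites matching a single parent, scored as run length
  weighted by its column span.
* **BootScan** — a sliding window (default 200 columns, step 20; windows
  shrink to a quarter of the alignment with a warning when the alignment
  is shorter). In each window the quartet of child, both parents and one
  outgroup (the species' first remaining type) is resolved by the
  neighbor-joining four-point criterion on within-window distances; the
  window's *support* for the (child, parent 1) grouping is the
  probability that a bootstrap resample of the window's columns favours
  that grouping. Because the bootstrap sum is a sum of iid per-column
  scores, that probability is evaluated in closed form through its
  Gaussian limit — supports are therefore deterministic, free of
  resampling noise, and identical between the observed profile and the
  permutation null (the test suite checks the approximation against
  direct multinomial resampling). A signal is a partner switch with
  ≥ 70% support on both flanks; the statistic is the range of the
  support profile and the breakpoint is where the interpolated profile
  crosses 1/2.

**Significance.** Every statistic gets a seeded permutation p-value
(default `n_perm = 1000`): site order (or label order) is shuffled,
destroying spatial structure while preserving composition, and
$p = (1 + k)/(1 + n)$ where $k$ permutations reach the observed
statistic. Permutations run in batches with sequential early stopping
(once 25 exceedances accrue the p-value is already far above any usable
cutoff and sampling stops), which keeps clearly-null triplets cheap
while signal-bearing triplets still receive the full permutation count.
Per-triplet RNG streams are derived from the run seed and the triplet's
(sorted) type names, so p-values are reproducible and invariant to input
order and to swapping the parent roles. These permutation p-values are a
deliberate, uniform replacement for the original methods' heterogeneous
analytic approximations: they are testable under one mechanism, but they
will not numerically match p-values produced by the original tools.

**Consensus and breakpoints.** Within a species, each method's p-values
are Bonferroni-corrected for the species' triplet count; a triplet with
at least `consensus_min_methods` (default 3) methods at corrected
$p \le \alpha$ (default 0.05) is a candidate event. Candidates with the
same child and begin-breakpoint within 10 columns are merged; the parent
appearing most often across merged candidates is the major parent, the
rest (at most four) minor parents. Breakpoints follow the begin-of-
transferred-segment convention; since the true splice lies somewhere
between the last site of one parental tract and the first site of the
next, the midpoint of those bracketing sites is reported, halving the
expected error relative to either endpoint. When a method's best
segment is anchored at the first informative site, the switch is at the
segment's end, so the complementary segment's start is reported
instead. A detected recombinant
can itself appear as a parent in other events — mirror signals of this
kind are a real feature of recombination scans, not an artifact.

## Trees and congruence

Phylogenies are bootstrap neighbor-joining trees on K2P distances:
`nj_tree()` wraps `ape::nj` (clamping negative branch lengths to zero,
transferring the magnitude to the sibling edge) and
`bootstrap_support()` resamples alignment columns (default 1000
replicates, seeded) and scores each internal bipartition by its
replicate percentage. This is a deliberate substitution for
likelihood-based tree search: the incongruence question asked of these
trees is threshold-free, so the cheaper, deterministic estimator is
adequate and fully testable. `congruence()` collapses the phage-type
tree to strain labels, reports the normalised Robinson–Foulds distance
to the symbiont (MLST) tree, and lists tanglegram crossing candidates:
types strictly closer to a foreign-strain type than to any type of their
own strain (types whose strain carries no other type have no yardstick
and are never flagged).

## The synthetic-data generator

`simulate_phage_data()` emulates the survey's structure: several host
species, each carrying a single *Wolbachia* strain, with per-species
pools of phage types.

* Sequences evolve under **K80** (transition/transversion ratio
  `kappa = 2`) — the same two-parameter model whose distance the typing
  uses, so distance estimation is unbiased by construction. An ancestral
  stop-free open reading frame is sampled; each planted type's ancestor
  evolves half the between-type divergence (`between_type_div = 0.08`)
  from the root, and each member evolves half the within-type divergence
  (`within_type_div = 0.003`) from its type ancestor, giving expected
  pairwise divergences at the stated values.
* Nonsense changes in functional sequences are reverted to the parental
  codon (purifying selection against premature stops); only planted
  pseudogenes — member copies given one internal stop by a single
  substitution — are stop-bearing. Pseudogenes would co-cluster with
  their source type if not filtered, which makes the filter's necessity
  itself testable.
* Planted types are guaranteed to *be* types: ancestors are redrawn
  until every pair of distinct planted types (recombinant children
  included) is at least `min_type_separation = 0.0225` apart, i.e. 1.5×
  the typing threshold. Without this floor, the recombinant child —
  whose expected distance to each parent is only half the between-type
  divergence — occasionally lands within the threshold of a parent by
  Poisson chance, and the planted truth would be wrong, not the
  pipeline.
* Transfers copy a donor type's ancestor into a recipient species with a
  different strain before member noise, so transferred types are
  identical or near-identical across strains — the signature the
  transfer module looks for.
* Recombinant ancestors are spliced from two parent ancestors at a
  stated breakpoint (default column 200 of 399, central).

The default configuration — four species in two families, strains
ST-1 (supergroup A), ST-2 (B, shared by two species) and ST-3 (B); three
or two base types per species with five members each; two transfers (one
crossing supergroups); one recombinant; two pseudogenes — was sized so
that the dataset stays desk-scale (~72 sequences), within-type pairs
number well over 100 for divergence calibration, and the recombinant's
species has four types (12 triplets), which keeps Bonferroni-corrected
permutation significance attainable at `n_perm = 1000`. Everything is a
deterministic function of the configuration and its seed.

What the generator does **not** emulate: indels (the alignment is gap
free by construction), rate heterogeneity across sites, selection beyond
stop avoidance, sequencing error, chimeric PCR artifacts, and uneven
sampling depth per host. Passing the recovery suite therefore
demonstrates correctness of the inference machinery under the model's
assumptions, not robustness to every artifact of real amplicon data.

## Numerical choices and degenerate inputs

* Chi-square tables with an empty margin score zero; permutation
  p-values are exact-style estimates $(1+k)/(1+n)$, never zero.
* Triplets with fewer than two informative sites return $p = 1$ with no
  breakpoint; BootScan additionally requires an outgroup and at least
  four usable columns, otherwise it abstains ($p = 1$).
* Undefined (saturated) K2P distances are errors in tree building but
  merely "never merge" in clustering.
* Ties in cluster ordering are broken lexicographically; the
  representative of a type is its first-seen member.
* Alignment coordinates are 1-based inclusive columns everywhere,
  including reported breakpoints.

## Problem sizes used in the shipped checks

The packaged validation (test suite and `scripts/acceptance.R`) runs the
generator's default conditions over 20 seeds for end-to-end recovery,
1,000 randomized pairs for the K2P oracle, ~1,400 randomized cases for
the recombination-statistic oracles, and 100 random 6–10-leaf additive
matrices for tree reconstruction — sizes chosen to exercise every code
path with comfortable statistical resolution on a single CPU.

## Known limitations

* Alignment is an input contract; the pipeline does not align and
  rejects unequal-length input.
* Per-method p-values are permutation-based and not comparable to the
  analytic p-values of the original recombination tools, although the
  consensus calls target the same events.
* The transfer count depends on the typing criterion (cluster threshold
  vs strict identity); both tallies are reported but not reconciled.
* With a single marker there is no power to infer transfer
  directionality, and none is attempted.
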