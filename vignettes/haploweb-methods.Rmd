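---
title: "Delimiting species with haplowebs and bipartition congruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting species with haplowebs and bipartition congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploweb)
```

## The delimitation criterion

Species can be viewed as *fields for recombination* (FFRs): groups of
interbreeding individuals whose allele pools are mutually exclusive.
During divergence, two populations become distinguishable at a
co-dominant nuclear locus as soon as they no longer share any allele —
a condition reached *before* reciprocal monophyly, which is what makes
this criterion attractive for recently separated species that
tree-based methods cannot yet resolve.

Operationally, for one diploid locus:

1. Phased allele sequences (two per individual) are collapsed into
   haplotypes.
2. Haplotypes found co-occurring in a heterozygous individual are
   linked; chains of such links (plus allele sharing through
   homozygotes) connect haplotypes into **allele pools**.
3. Each individual's alleles lie in exactly one pool; the preimages of
   the pools partition the sample into **single-locus FFRs (sl-FFRs)**.
   Individuals in different sl-FFRs share no allele at the locus.

The *haploweb* is the graphical form of this computation: a
median-joining haplotype network with co-occurrence curves drawn on
top. The package deliberately computes pools from co-occurrence and
allele sharing only — never from network topology. Network edges are
inferred evolutionary paths, not observations of recombination, and
median vectors are unobserved sequences: two homozygotes whose
haplotypes are connected only through a median vector therefore remain
in separate pools.

Haploid (organelle) markers cannot recombine, so no haploweb is
defined for them; individuals are instead sorted into **haplogroups**
by exact haplotype identity. No distance threshold is applied:
haplotypes one mutation apart yield distinct haplogroups. (A distance
threshold could be bolted on, but exact identity is the only choice
that requires no tuning and matches how such markers are convention-
ally reported; anything coarser should be an explicit upstream
decision.)

## Multi-marker congruence by bipartition scoring

A single locus can mislead (selection, introgression, shared ancestral
polymorphism), so support must come from independent markers. Merging
sl-FFRs across loci — the transitive "same block at some locus"
closure, computed here as the partition-lattice join (`ml_ffr_join()`)
— synthesises all markers but is fragile: one aberrant dataset
collapses everything it touches.

The congruence analysis avoids this by scoring **bipartitions**. A
bipartition splits the n samples into two complementary non-empty
groups; a marker partition with k blocks supports exactly those
bipartitions whose sides are unions of its blocks, i.e.
2^(k-1) − 1 of them. Each bipartition supported by at least one
marker is scored by the fraction of independent datasets supporting
it (`score_bipartitions()`); bipartitions with support strictly above
a cutoff (default 50%) are kept and intersected into the final
grouping (`reconcile()`).

Numerical conventions, fixed for reproducibility:

* Bipartitions are canonicalized as the side *not* containing the
  lexicographically smallest sample id, giving set semantics without
  double counting. (Printed side sizes therefore depend on which side
  holds that sample; the unordered split does not.)
* Support is kept as an exact fraction; the printed percentage rounds
  half-up (1/3 → 33%).
* The threshold comparison is strict (`support > threshold`), so a
  1/3-supported row falls below a 0.5 cutoff unambiguously while 2/3
  survives.
* Kept bipartitions are checked for pairwise compatibility (some
  corner of the 2×2 intersection table must be empty). Incompatible
  sets cannot arise when one bipartition is unanimous and the cutoff
  exceeds 1/2, but at low thresholds they can; the package reports
  the conflicting pairs and returns the meet, which over-splits
  rather than silently resolving the conflict.
* Every input partition counts as one independent dataset. Linked
  regions (e.g. two mitochondrial fragments) must be concatenated by
  the caller into a single marker before scoring; scoring them
  separately would double-weight one genealogy.
* Bipartition scoring requires all markers to cover the same
  individuals. With `restrict_to_common = TRUE` the analysis is run
  on the intersection of the universes instead of erroring.

The 74-sample coral worked example ships as
`clipperton_partitions()`: ITS2 sl-FFRs of 55/17/1/1, ATPSβ sl-FFRs
of 57/17, mitochondrial haplogroups of 52/17/3/2. Scoring yields 13
supported bipartitions — one unanimous (100%), twelve at 33% — and
reconciliation at 50% leaves two groups of 57 and 17 individuals:

```{r clipperton}
parts <- clipperton_partitions()
st <- score_bipartitions(unname(parts))
st
reconcile(st)
block_sizes(ml_ffr_join(list(parts$ITS2, parts$ATPSb)))
block_sizes(partition_meet(unname(parts)))
```

The published record names only six individuals explicitly; the
membership of the shared 17-individual group is chosen arbitrarily
(the 17 smallest sample names not among the six). All derived counts
are invariant under renaming of individuals, so this choice cannot
affect any result — the test suite asserts that invariance directly.

## Median-joining networks

For display, haplonets are built with a re-implementation of the
median-joining algorithm over multi-state characters (each alignment
column is a character; gaps are by default a fifth state). The
procedure iterates:

1. the ε-relaxed minimum-spanning network over the current node set —
   an edge is kept when its length is within ε of the minimal
   connecting length of its endpoints; at ε = 0 this is exactly the
   union of all minimum spanning trees;
2. for every mutually connected node triplet, the column-wise
   majority-consensus median; three-way ties resolve to the state of
   the triplet member with the smallest node index, making the
   construction deterministic;
3. medians that strictly lower the *connection cost* — defined here as
   the minimum-spanning-tree total weight over the node set — are
   admitted; the loop repeats until no median helps, then medians of
   degree ≤ 1 are pruned.

Connection cost is measured on an MST rather than on the emitted
relaxed network because the relaxed network is a union of spanning
trees: its summed edge weight can exceed any single tree's weight even
when no median is worth adding, which would make "cost reduction"
ill-defined. With MST cost the invariant is clean: the final node
set's connection cost never exceeds that of the observed haplotypes
alone. Since every admission lowers an integer-valued cost, the
iteration terminates; a generous round cap guards against logic
errors rather than genuine non-convergence.

ε defaults to 0 and is exposed; published figures built with external
tools rarely report their ε or gap handling, so bit-identical network
reproduction is out of reach and the tests instead compare against a
brute-force re-derivation of the same definition on small inputs
(≤ 6 haplotypes, length ≤ 8), with igraph supplying the independent
spanning-tree machinery.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates the regime the criterion assumes:
species allele pools that are mutually exclusive but not necessarily
monophyletic. Per marker, a root sequence acquires disjoint blocks of
`inter_mutations` substitutions per species (ancestors pairwise
2·inter apart); each of `intra_haplotypes` pool members adds
`intra_mutations` private substitutions at positions sampled without
replacement. The constraint `inter ≥ 2·intra + 1` guarantees
cross-species distances stay positive, i.e. pools cannot collide;
disjointness is additionally asserted at generation. Genotypes are two
independent frequency-weighted draws per individual (Hardy–Weinberg),
one for haploid markers.

Defaults — 2 species × 20 individuals, three markers (two diploid,
one haploid), 300 bp, 4 haplotypes/species/marker, 2 intra and 20
inter mutations, Dirichlet concentration 1 — mirror a modest
multi-marker study of two closely related species; the mitochondrial
divergence of the worked example (16 mutations between species'
haplotypes) sits at the same scale as the inter-species default. These
sizes keep the full test suite (including a 20-seed recovery sweep and
the brute-force oracles) in the tens of seconds.

Anomaly injection reproduces the known failure modes at the sequence
level, then re-collapses: an F1 hybrid (one allele from each parental
population at every nuclear marker — drawn from the *sampled* copies,
so each allele is genuinely shared with its source species, and
frequency-weighted, so the hybrid typically links two common
haplotypes by a thin weight-1 curve); an introgressed allele (one
allele of one individual at one marker replaced by a haplotype
observed in the other species); a shared ancestral haplotype (one
other-species individual carrying a haplotype observed in species 1).
The expected consequences — join collapse from a single hybrid, the
species split dropping to 2/3 support but surviving a 50% cutoff
after single-marker contamination — are asserted by running the
pipeline, not assumed.

The generator is a star-genealogy approximation, not a coalescent: no
recombination within a marker, no back-mutation, no selection, no
shared polymorphism unless injected. Passing tests therefore show the
machinery is correct under clean mutual exclusivity and under the
modelled contaminations; they do not show robustness to deep
coalescent variance, alignment error, or phasing error, all of which
real data can carry (phasing is assumed done upstream).

## Degenerate inputs and edge conventions

* Haplotype identity is exact case-insensitive string equality with
  gaps as a fifth state and no ambiguity-code expansion (ambiguities
  trigger a warning). Upstream trimming of hypervariable regions is
  supported via an explicit column-exclusion list, never guessed.
* A diploid individual represented by a single sequence is accepted
  as an assumed homozygote, loudly messaged — the common wet-lab
  convention for clean chromatograms.
* Haplotype ids are assigned in order of first appearance after
  sorting records by sequence id, so outputs are byte-stable across
  record orderings.
* A single-haplotype marker yields one node and no edges; a
  single-block partition supports no bipartitions; reconciling an
  empty support table returns one all-inclusive group.
* The bipartition enumerator refuses k > 20 blocks (2^(k−1) growth)
  unless the cap is raised explicitly.
* Rendering is a pure function of (object, style, layout seed):
  identical inputs give byte-identical SVG. Node *diameter* — not
  area — is linear in haplotype count, following the field's
  convention for these figures; an area mode is available for
  perceptually honest scaling.

## Limitations

F1 hybrids are invisible to congruence scoring (they are wrong at
*every* marker consistently); they must be spotted in the haplowebs
as rare links between common haplotypes and removed. Support
percentages carry no statistical calibration — they are dataset
counts, and with three markers the only possible values are 33%, 67%
and 100%. Morphological or behavioural groupings can enter as extra
partitions, but the equal-weight treatment assumes independence that
may not hold for such characters.
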