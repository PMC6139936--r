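---
title: "Diagnostic-substitution subfamily analysis of SVA retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic-substitution subfamily analysis of SVA retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Retrotransposon families expand from a small number of active *source
elements*. Every mutation a source element carries is copied into all of
its offspring, so a set of substitutions shared by a group of copies and
absent from the ancestral consensus — *diagnostic substitutions* — marks a
subfamily, and diagnostics accumulate strictly sequentially along source
lineages: a younger subfamily carries all of its ancestor's diagnostics
plus its own. Random post-insertion mutations, by contrast, are private
to individual copies and are more numerous in older copies. These two
signals — shared-by-descent versus private-by-age — are what the whole
analysis separates.

The package applies this model to SVA elements in the three hominines
(gorilla `gg`, chimpanzee `pt`, human `hs`), working on the SINE-R domain
as the sorting region, and adds the comparative layers the conclusions
need: cross-species orthology of insertion loci, target-site-duplication
forensics, and detection of non-canonical 5' ends created by exon
capture.

# Reference-anchored alignment (`align_to_reference`)

Every element copy is aligned to a single reference consensus
(semi-global: the element is aligned end to end against the best window
of the reference), then expressed as a per-position state vector in
reference coordinates with states `A/C/G/T`, `-` (deleted) and `.`
(missing). Three rules matter downstream:

* reference positions beyond a truncated element's ends are **missing,
  never deleted** — truncation must not masquerade as a diagnostic
  deletion;
* `N` and IUPAC ambiguity codes are missing — an ambiguous base is never
  evidence for or against a diagnostic;
* internal gaps are deletions reported as single maximal-run events, so
  the 20-bp hallmark deletion is one event, not twenty.

Scoring defaults are match +1, mismatch −2, gap open −6, gap extend −1
(a gap of length L costs 6 + (L−1)); copies of interest are ≥ 90%
identical to their reference, so any standard affine scheme separates
homology from noise. Alignments below 60% identity are retried as
reverse complement and flagged unalignable if still below the floor.
Copies covering less than half of the reference are excluded from
sorting; exactly half is kept.

# Sorting into subfamilies (`sort_subfamilies`)

The classifier automates manual diagnostic-residue sorting as a
greedy-recursive search:

1. among all candidate variants relative to the current consensus
   (substitutions, and deletion events by default), find the variant set
   whose **joint carrier set** is largest. A carrier matches every
   variant of the set it covers and covers at least `min(2, |set|)` of
   them. The search seeds with the best-supported pair (best single
   variant at nested levels) and hill-climbs, adding the variant that
   keeps the carrier count highest; ties prefer more variants, then
   lower positions. Absorbing all co-segregating diagnostics into one
   set makes the subfamily *more* tolerant of truncated members, which
   only need two covered diagnostics.
2. if the carriers number at least `min_members` (default 10), they form
   a subfamily; its majority-rule consensus becomes the reference for
   sorting inside it (`min_shared_nested = 1` additional diagnostic),
   and the remainder of the group is searched again at the same level
   (`min_shared_root = 2`).
3. recursion stops when no qualifying set remains.

Membership follows the manual convention for truncated elements: all
*covered* diagnostics must match, and at least two (or all, for
single-diagnostic subfamilies) must be covered; a copy covering one of
two diagnostics stays at the parent.

Majority-rule consensus treats deletion as a state; ties resolve to the
parent state, as do all-missing columns. One consequence worth knowing:
when a derived clade outnumbers its ancestor inside a node, the node's
majority consensus adopts the derived state at a diagnostic position, so
a nested "diagnostic" can be the ancestral state viewed from a
derived-polarity consensus. The flat partition is unaffected; polarity
should be read from `sequentiality_check()` and the network, not from a
single nested label.

`sequentiality_check()` verifies that child diagnostics never revert an
ancestor's diagnostic — the argument that disqualifies a proposed
ancestry in which a derived state would have to mutate back.
`cosegregation_scan()` partitions variants shared across consensuses
into groups with identical carrier sets, the pattern behind the hallmark
A/G pair at positions 228/242 relative to the DR consensus.

# Median-joining networks (`median_joining`)

Consensus (or element) sequences are projected onto a common reference,
condensed to variable columns (identical columns merge with summed
weight; identical sequences collapse with multiplicity), and connected
by the minimum spanning network at tolerance ε (default 0 — "default
settings"; ε = 0 yields the union of all minimum spanning trees). Gaps
are a fifth character state, so the 20-bp deletion separates the D2
clade in the network exactly as a substitution would. Quasi-medians of
MSN-connected triplets (per-column majority where one exists, otherwise
every observed state) are evaluated and the median vector that most
reduces the total connection cost is added, one at a time, to a fixed
point; equal-cost medians and a bounded two-median lookahead handle
plateaus where two Steiner points only help together. Obsolete medians
are purged (removal must not raise the connection cost), capped at
10,000 vectors with an explicit error beyond.

After adding medians, a minimum spanning tree over the *samples alone*
need not survive edge-for-edge (the three-haplotype star replaces all
weight-2 links), so the MST property is implemented and tested as: the
final network always contains a subtree spanning all sampled haplotypes
of total weight ≤ their MST weight.

`mp_postprocess()` retains exactly the links and medians lying on at
least one minimum-total-weight tree connecting the samples within the
network (computed exactly by enumerating median subsets, practical to
~18 medians), never removes a sample, and is idempotent.
`root_network()` flags the outgroup haplotype and orients links by
weighted graph distance.

**Limits.** Median joining is a heuristic. On conflict-free (compatible)
characters it reproduces the perfect phylogeny — tree topology,
parsimony length, additive path distances — in every random instance we
generate. On random *incompatible* matrices its internal spanning cost
matches an exhaustive Dreyfus–Wagner Steiner enumeration in roughly 96%
of small instances; in the remainder the canonical construction cannot
reach the optimum at all (the MSN-connected triplets generate no new
quasi-median, while the optimum needs two mutually supporting Steiner
points), and this package deliberately stays a median-joining
implementation rather than a Steiner-tree solver. The achieved cost is
always bracketed by the Steiner optimum below and the sample MST above.

# Orthology from flanks (`match_loci`, `classify_presence`)

Instead of genome-coordinate lift-over, orthology is decided from the
50-nt flanks of each insertion: a cross-species pair is the same
integration event only if both flanks are reciprocal best hits at ≥ 90%
identity (16-mer seeds, low-complexity seeds masked so A-tracts do not
seed everything against everything) *and* the insertion-point offset in
the aligned flank frames is 0. The offset tolerance is deliberately
zero: the case against a single long-lived master element rests on two
loci where the integration sites differ by exactly one nucleotide, so
1-nt-offset pairs must be reported as distinct sites, never merged. TSD
sequence is *not* required to match across species — the two copies
mutate independently after insertion. Ambiguous multi-hit flanks are
flagged unresolvable rather than guessed. Presence patterns get
Dollo-style history calls on the fixed tree ((hs, pt), gg): presence
spanning the root is ancestral-hominine; an ancestral locus absent from
one species was lost there (incomplete lineage sorting or, less likely,
precise deletion); presence in human and chimpanzee only maps to their
common ancestor.

# Target-site forensics (`extract_tsd`, `compare_tsd`)

The TSD is the longest suffix of the 5' flank matching a prefix of the
3' flank within one mismatch (lengths 5–30; ties to longer, then fewer
mismatches). Comparisons against an inferred pre-integration site are
end-gap tolerant: the shorter sequence slides along the longer, the
placement with fewest internal substitutions wins, ties keep the gap at
the 3' end, and the terminal length difference is reported separately —
a 15-nt TSD against a 16-nt ancestral site with one internal change
counts one mutation, not two. A single extra base extending a
homopolymer run of ≥ 3 is reported as replication slippage. Positions
are 1-based from the TSD 5' end. An element-leading G unaccounted for by
the target-site copy is the untemplated-G capping signature;
`a_tract_distance()` reports the distance from the nearest upstream
A-tract (≥ 6 A, 50-nt window) to the insertion point, 0 meaning directly
adjacent.

Freshly inserted copies have exactly identical 5'/3' TSD copies; their
divergence grows with age — the young-insertion signature the
master-element analysis exploits.

# Exon capture (`annotate_domains`, `detect_noncanonical_5p`)

Domains are annotated by grammar: ≥ 2 tandem TCTCCC-like units (one
mismatch per unit tolerated, scanning a few leading bases for an
untemplated G), local alignment for Alu-like and SINE-R (no SINE-R hit
means not an SVA), the tandem-repeat region between Alu-like and SINE-R
as VNTR, and a trailing A-run as polyA. A non-canonical 5' end is the
maximal region upstream of the first recognisable anchor failing to
align to the hexamer/Alu-like references (identity < 60%). Because donor
exon and Alu-like sequence can agree by chance at the boundary — for the
whole family at once, since all copies share the donor — the junction is
refined to the nearest downstream splice-acceptor `AG` within the
ambiguity window. Donor assignment requires the segment's 3' end to
coincide with an exon's 3' end within ±2 nt (the splice criterion);
sequence 5' of the exon match is additional transduction, and the
acquired length is measured from the exon-match start to the exon end
(both the exon-anchored and transduction-boundary measures are
recoverable from the call). Capture families may contain canonical
members; family membership is a SINE-R question, capture status an
attribute. Acquired-length histograms deduplicate identical lengths.

# The simulator (`simulate_expansion`)

The generator is the study's ground truth, not a tuning knob. It
emulates: a fixed species tree ((hs, pt), gg); source lineages acquiring
planned diagnostics sequentially at previously untouched positions
(reversions impossible by construction); copies as the source plus
Poisson(age × rate × length) random substitutions; insertion into
generated A-rich contexts with exact TSDs (length 8–18) a small distance
downstream of an A-tract; copies of pre-split lineages emitted in every
descendant species, each instance mutating independently and lost per
species with probability 0.1 (the lineage-sorting proxy); 20% of copies
5'-truncated by a uniform fraction up to one half; untemplated 5' G with
probability 0.15; and optional capture founders replacing everything 5'
of a junction with an exon suffix. A single master seed feeds named
substreams (lineages, placement, mutation) so stages vary independently;
identical configuration and seed give byte-identical output.

The default lineage plan has 15 lineages with 2–3 diagnostics each
(matching published subfamily tables, where nested subfamilies carry 1–3
species-specific substitutions), copy numbers 30–200, one 20-bp-deletion
founder, one 11-bp-deletion founder on the chimpanzee–human branch, and
ages set so copies carry 0.5–2% post-insertion divergence at the default
rate of 0.005 substitutions per site per age unit. Ages are relative
units; calendar calibration is out of scope. Not modelled: CpG
hypermutability (an optional concern the sorting does not weight), VNTR
subunit evolution, selection, and genome-scale sequence context — so
passing tests demonstrate recovery of the planted expansion process, not
performance on real genome assemblies.

# What recovery looks like, and a known limitation

On noise-free simulations the sorter recovers the planted partition
exactly (adjusted Rand index 1.0) and every planted source consensus
byte-identically. Under the full study conditions (0.5–2% divergence,
20% truncation) exact consensus recovery stays at 100%, but the ARI
settles around 0.77–0.89 depending on where the planted diagnostics fall
relative to the truncation window: the membership rule is strict — one
back-mutated diagnostic, or truncation below two covered diagnostics at
any node on the path, legitimately demotes a copy to an ancestor — and
roughly a tenth of copies are displaced this way. We examined relaxing
the rule by absorbing near-unanimous (≥ 90% agreement) variants into a
node's diagnostic set; it measurably *hurts* recovery, because the
absorbed diagnostics' few violators are exiled out of the subtree
altogether and regroup as spurious shadow subfamilies. The strict rule
is also the property that makes the method immune to the "back-sorting"
and subfamily-splitting artefacts of similarity-threshold clustering, so
we keep it and document the trade-off.

Problem sizes throughout (about 2,200 simulated copies over a 490-nt
sorting region, 100 compatible-matrix and 30 exhaustive-Steiner network
instances, 30-copy capture families) were chosen to exercise every code
path at desk scale while each analysis completes in minutes.
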