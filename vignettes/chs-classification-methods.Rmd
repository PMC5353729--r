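---
title: "Classifying fungal chitin synthases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fungal chitin synthases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chsfam)
```

## The problem

Fungal chitin synthases (CHS) are multidomain membrane enzymes whose
family structure reflects repeated gene duplication, domain recombination
and domain accretion. Classifying a proteome's CHS complement into the
seven recognized classes (I–VII, three divisions) plus the basal CHS23b
group requires two independent signals, because neither suffices alone:
phylogenies of the conserved catalytic region (CON1) resolve the deep
divisions but not always the classes, and domain architectures recur
independently in distant lineages (the Type B1 architecture, a bare CS2
domain, arises both in the genuine Division 3 / Class VI clade and as
scattered lineage-specific duplicates). `chsfam` encodes the combined
procedure as deterministic, testable rules.

## Screening

A candidate protein passes when all three filters hold:

1. **Characteristic domain** — at least one hit to PF03142 (CS2), its CDD
   alias cd04190, or PF01644 (CS1), with E-value ≤ `evalue_max`
   (default 1e-5). PF01644 is included because Division 1 proteins carry
   only a truncated CS2 remnant fused to CS1 — demanding an intact
   PF03142 would reject the whole division. The E-value default is a
   conventional profile-search acceptance threshold; the upstream HMM
   sweep these tables come from is typically run permissively and
   filtered here.
2. **CON1 motifs** — an extractable CON1 region (below).
3. **Duplicate collapse** — within a species, proteins with identical
   full-length sequences collapse to the lexicographically smallest id.
   Only exact within-species duplicates are removed; near-identical
   paralogs are biology, not redundancy, and cross-species identity is
   informative.

## CON1 extraction

The motifs QxxEY, EDRxL and QxRRW (`x` = any residue) anchor the region.
All occurrences of each motif are scanned, overlapping ones included.
Among all ordered, non-overlapping (start, middle, end) triples, the
minimal-span triple wins; remaining ties resolve to the leftmost start,
then middle, then end hit. The region runs from the start motif's first
residue to the end motif's last, so its minimum length is 15 aa; no
maximum is imposed because genuine CON1 regions vary widely (roughly
100–1,200 aa in large surveys, mean ≈ 141 aa). Two decisions here were
genuinely open:

* Whether the three motifs must be adjacent or may be arbitrarily
  separated: arbitrary separation is allowed, with minimal span as the
  disambiguator, since real CON1 regions embed long variable segments.
* The looser motif variants sometimes quoted (QxxEY, (E/D)Dx, Q(R/Q)xRW)
  are available as the `"alternate"` pattern set of `con1_patterns()`,
  but the stricter set governs screening by default; the two sets are
  kept distinct rather than merged.

## Architecture typing

Hits to the six focal domains are merged per accession (overlapping
same-accession hits union), then cross-accession overlaps resolve
greedily by descending bit score (ties by accession, then start — purely
to fix determinism). Non-focal accessions are recorded but never
influence the type: in large surveys they show no consistent
distribution. The CON1 token enters the element list exactly when the
region is *not* contained in a retained intact PF03142 hit; a PF03142 hit
contained *in* the region is the truncated remnant and is replaced by the
token. This single containment rule reproduces the Group A
(CS1 + remnant) versus Group B (intact CS2) dichotomy. The type table is
a pure function of the focal multiset, with order enforced only where the
architecture definitions require it (CS1 immediately followed by CON1 for
Group A; A3's intact CS2 after the token). One published figure labels
the PF08407-PF01644-CON1 structure inconsistently across panels; the
panel defining the types (that structure = A2) is followed.

## Phylogenetic placement

**Alignment.** CON1 regions are aligned progressively: profile–profile
Needleman–Wunsch with BLOSUM62 column scores (frequency-weighted,
gap-vs-residue scored zero), affine gaps (open −10, extend −1, the
classic BLOSUM62 pairing), merged along an average-linkage guide tree on
3-mer distances. This is intentionally a small deterministic aligner, not
an iterative refiner: CON1 regions are short and mostly indel-free, and
externally computed alignments can be imported. Traceback prefers
match over gap-in-second over gap-in-first profile, fixing determinism.

**Distances.** p-distance = mismatches / compared sites, computed over
sites where both rows carry a residue (gaps and X are missing data).
`"partial_deletion"` first drops columns under 95% occupancy (the common
convention; configurable); the Poisson correction d = −ln(1 − p) is
available for multiple hits. A saturated pair (p = 1) is capped with a
warning rather than propagating an infinite distance; a pair with zero
comparable sites is an error naming the pair.

**Neighbor joining.** Standard Saitou–Nei agglomeration. Two numerical
rules make it reproducible and well-behaved: equal minimal Q values are
broken by lexicographic order of the joined clusters' smallest leaf
names, and a negative branch-length estimate is clamped to zero with the
deficit moved to its sister so the pair distance is conserved. Trees are
built via Newick fragments serialized at 12 significant digits, which
round-trips the additive cases exactly at test tolerance.

**Bootstrap.** Alignment columns are resampled with replacement; each
internal edge of the point tree is annotated with the percentage of
replicate trees containing the same bipartition. All stochastic steps
take explicit seeds and restore the caller's RNG state.

**Placement.** A query joins the reference by profile alignment; the
joint NJ tree is rebuilt with bootstrap. The host is the smallest clade
containing the query plus the complete reference set of exactly one class
label, and the reported support is that clade's edge. Three open choices
were resolved as follows:

* The >60% support rule is applied to the class clade's edge (not the
  query's attachment edge), since the class clade is the unit being
  asserted; the inequality is strict by default (configurable).
* If two labels qualify simultaneously — possible only in the degenerate
  two-label reference — the placement is ambiguous and no host is called.
* The placement records whether the query attached *interior* to the
  reference clade (breaking the pure reference-only bipartition) or
  merely basal to it. Class calls accept either, but the Type-B1
  noise exemption requires interior attachment: a B1 sequence genuinely
  clustered within Division 3 is Class VI material, whereas one hanging
  off the clade's stem is indistinguishable from the root-adjacent
  scattered duplicates the survey excluded. Without the interior
  requirement, simulated no-signal B1 sequences occasionally attach basal
  to the Division 3 clade with support above threshold, which would leak
  planted noise into Class VI.

A query whose CON1 exactly equals a reference sequence is assigned that
reference's label directly with support 100, mirroring the practice of
deleting repeat sequences before rebuilding per-species trees.

**Classification.** A class is called iff the host label's expected
architecture matches the protein's type ({I,II,III,23b}↔A2, IV↔B2,
{V,VII}↔B4, VI↔B1) and support passes; otherwise the protein is
unclassified. The exclusion rule is the deterministic surrogate for
"randomly scattered": A1, A3 and B3 are always flagged as noise; B1 is
flagged unless placed interior to the Division 3 clade with support;
other types never. The class call and the noise flag are deliberately
independent outputs — combining them (e.g. counting flagged proteins as
unclassified) is a one-line summary choice left to the caller, because
the survey bookkeeping treats "excluded from the phylogeny" and
"unclassifiable" as overlapping but distinct notions.

## Family dynamics and synteny

Per-species class counts include an all-zero row for every species in the
taxonomy (species without CHSs are data, not absence of data). Taxon
means are reported half-up to one decimal, matching the precision used in
published tables. Presence fractions (multiple/one/none per class) must
sum to one and are asserted to.

Head-to-head means divergently transcribed adjacency: same contig,
opposite strands with the left gene on "−" and the right on "+" (5′ ends
facing), and at most `max_intervening` (default 1) annotated genes
strictly between — encoding the observation that such pairs have either
no gene or a single hypothetical gene between them. No distance cap is
imposed by default (none is stated in the surveys); one is configurable.
Intervening genes are counted over the full annotation, including genes
with no protein product. Species with several V or VII copies produce
per-pair calls flagged ambiguous. Intron status is exon-count driven:
≥2 exons true, 1 false, unknown otherwise.

## The synthetic generator

`simulate_family()` emulates exactly the structure the analysis assumes:

* A root CON1 (default 141 aa, the reported survey mean) carrying the
  three motifs is evolved down a fixed two-level tree — three divisions,
  then classes, with 23b basal to the II+III pair and V/VII as a tandem
  pair — scaled by `between_class_divergence` (default 0.5
  substitutions/site); within-class copies are drawn at
  `within_class_divergence` (default 0.05). Each member sits at half the
  divergence from its class consensus, so a same-class pair spans the
  configured value.
* Substitutions are Jukes–Cantor-style for proteins: per mutable site a
  Poisson(t) number of events, each uniform over the 19 alternative
  residues, so the expected observed p-distance has the closed form
  `expected_p_distance(t)` = (19/20)(1 − e^(−20t/19)) and p-distances are
  unbiased. Motif columns are frozen, and every generated CON1 is
  rejection-sampled to contain exactly one occurrence of each motif, so
  extraction recovers planted coordinates exactly.
* Full proteins are flank + class-appropriate domain segments + CON1 +
  flank, with a domain-hit table emitted to match the planted
  architecture (including the truncated CS2 remnant inside Division 1
  CON1 regions); each assembled protein is checked end-to-end against the
  extractor and reassembled if a chance motif in a random segment would
  shift the minimal-span triple.
* Decoys lack either the motif complement or any characteristic domain;
  noisy B1 copies draw their CON1 at between-class divergence straight
  from the root, i.e. with no class signal.
* Default repertoires are one member per class for dikarya-like species
  and an expanded, B1-heavy repertoire (17 CHSs/species) for
  early-diverging-like species, reflecting the reported contrast between
  ~7 CHSs per filamentous species and ~16.5 in early-diverging fungi.
  Head-to-head V/VII pairs are planted at rate 0.95 with an intervening
  hypothetical gene at rate 17/95, the proportions reported for
  Pezizomycotina.

What the generator does **not** emulate: indels within CON1 (alignments
of simulated data are trivially gap-free), rate heterogeneity across
sites or lineages, WAG-like exchangeabilities, domain-annotation noise,
or assembly/annotation artifacts in gene models. Passing tests therefore
demonstrate the pipeline's logic and its statistical behavior under a
clean substitution model — not robustness to alignment error or
annotation noise in real proteomes.

## Problem sizes and determinism

Tests and the acceptance script run at desk scale: references default to
3 sequences per class label (24 leaves), placements use 100 bootstrap
replicates, and the recovery experiment uses 13 species whose default
repertoires yield exactly 100 planted class members (plus 24 noise-B1 and
26 decoys). Oracle checks enumerate all unrooted topologies up to 6 taxa
and all motif triples on random layouts. Every stochastic stage takes an
explicit seed; pipeline reruns with the same config are bitwise identical,
and the pipeline log records seeds and parameters rather than timestamps.

## Known limitations

* The built-in tree method is NJ on corrected p-distances, not maximum
  likelihood; the classification contract (single-label clade + support
  threshold) is preserved and externally built trees can be imported, but
  published ML trees are not reproduced node-for-node.
* The progressive aligner has no iterative refinement; for highly
  indel-rich inputs an external alignment should be imported.
* The interior-attachment requirement for the B1 exemption slightly
  over-flags genuine Class VI members whose placement falls on the clade
  stem; with tight references this affects a minority of B1 placements
  and errs on the side the survey erred (exclusion).
* "Unclassified" here is exactly the complement of the compatibility-and-
  support rule; published surveys additionally used manual judgment whose
  criteria are not fully recoverable.
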