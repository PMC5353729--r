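# chsfam — chitin synthase gene-family classification and profiling

Chitin synthases (CHS) catalyze the final step of chitin biosynthesis and
form one of the most complex gene families in fungi: yeasts carry 1–3
copies, filamentous fungi around 7, and some early-diverging fungi more
than 20. Surveys of fungal proteomes classify these proteins into seven
classes (I–VII) grouped in three divisions, plus a basal group (CHS23b),
by combining two signals:

* **Domain architecture.** Six focal Pfam domains — PF08407, PF01644
  (CS1), PF03142 (CS2), PF00173 (cytochrome-b5-like), PF00063 (myosin
  motor-like) and PF08766 (DEK_C-like) — define Group A types
  (A1–A3, CS1 followed by the CON1 remnant of a truncated CS2) and
  Group B types (B1–B4, an intact CS2).
* **Phylogeny of the CON1 region.** Every CHS carries a conserved
  catalytic region (CON1) delimited by the motifs QxxEY, EDRxL and QxRRW.
  Queries are placed into a labeled reference tree of CON1 regions;
  a class is called when the query joins a single-class reference clade
  whose edge has bootstrap support above 60%.

`chsfam` implements this survey as a reusable, fully tested R pipeline:

1. **Screening** — three false-positive filters: a characteristic CHS
   domain hit (PF03142 / its CDD alias cd04190 / PF01644) at E ≤ 1e-5, an
   extractable CON1 region, and within-species collapse of identical
   sequences.
2. **CON1 extraction** — all motif occurrences are scanned (overlaps
   included) and the minimal-span ordered (QxxEY, EDRxL, QxRRW) triple
   delimits the region.
3. **Architecture typing** — ordered focal-domain content with the CON1
   token; the Group/Type table maps content to A1–A3 / B1–B4.
4. **Placement and classification** — progressive profile alignment of
   CON1 regions (BLOSUM62, affine gaps), p-distance (optionally Poisson
   corrected, d = −ln(1 − p)), Saitou–Nei neighbor joining with
   deterministic tie-breaking, column-resampling bootstrap, and the
   type-compatibility table ({I,II,III,23b}↔A2, IV↔B2, {V,VII}↔B4,
   VI↔B1). Types A1/A3/B3 — and B1 outside the Division 3 clade — are
   flagged as phylogenetic noise, reproducing the survey's exclusion rule.
5. **Family dynamics** — per-species class counts, per-taxon means and
   multiple/one/none presence fractions.
6. **Synteny** — detection of the head-to-head (divergently transcribed,
   5′ ends facing, ≤1 intervening gene) *ChsV*/*ChsVII* arrangement and
   intron status.
7. **Synthetic data** — a generator that evolves a motif-anchored CON1
   root down a fixed division/class tree (motif columns frozen,
   Jukes–Cantor-style residue substitution), assembles full proteins with
   class-appropriate architectures, plants decoys, noisy Type-B1 copies
   and head-to-head gene pairs, and records complete ground truth.

## Worked example

```r
library(chsfam)

ds     <- simulate_family(sim_config(seed = 42, n_species = 4))
con1   <- extract_con1_all(ds$proteins)
screen <- filter_candidates(ds$proteins, ds$domain_hits, con1)
sum(screen$accepted)                      # 39 of 47 candidates pass
acc  <- ds$proteins[screen$accepted, ]
arch <- architecture_table(acc, ds$domain_hits, con1)
table(arch$type_label)
#> A2 B1 B2 B4
#> 14 11  6  8

asn <- classify_species_set(acc, con1,
                            setNames(arch$type_label, arch$protein_id),
                            ds$reference, n_reps = 100, seed = 1)
summarize_classification(asn)$class_counts
#>    I   II  III   IV    V   VI  VII  23b unclassified
#>    4    4    6    6    4    4    4    0            7

calls <- detect_head_to_head(ds$gene_models, asn)
summarize_synteny(calls)[c("head_to_head_species", "with_intervening",
                           "without_intervening")]
#> $head_to_head_species [1] 4
#> $with_intervening     [1] 1
#> $without_intervening  [1] 3

prof <- profile_counts(asn, ds$taxonomy)
taxon_summary(prof, ds$taxonomy, "early_diverging")
#> early_diverging: 1 species, mean 18.0 CHSs/species
taxon_summary(prof, ds$taxonomy, "Pezizomycotina")
#> Pezizomycotina: 3 species, mean 7.0 CHSs/species
```

The 4 simulated species carry one member per class (dikarya-like) or an
expanded repertoire rich in unclassifiable Type-B1 copies
(early-diverging-like), plus planted decoys; the 8 rejected candidates
are the decoys, the 7 unclassified proteins are noise-planted B1 copies,
and the early-diverging-like species shows the expected family expansion.
The whole chain can also be driven from one declarative config via
`run_pipeline(pipeline_config(...), "all")`, which writes TSV/JSON
artifacts and is bitwise reproducible for a fixed seed.

Real datasets enter through the same interfaces: `parse_sequences()`
(FASTA), `parse_domain_hits()` (HMMER `--domtblout` or a documented TSV),
`parse_gene_models()` (GFF3), `parse_taxonomy()` (TSV) and
`parse_con1_reference()` (labeled FASTA); externally built alignments and
trees can be imported with `read_alignment()` and `parse_tree()`.

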