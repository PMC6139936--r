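# svatools

Phylogenetic analysis of SVA retrotransposon expansion in hominine
primates (gorilla, chimpanzee, human), organised as an analysis workflow
over an R package.

SVAs are composite non-autonomous retrotransposons (hexameric repeats,
*Alu*-like domain, VNTR, SINE-R, polyA) mobilised in trans by LINE-1.
They evolve as hierarchical subfamilies: mutations accumulated in an
active source element are inherited by all of its offspring, so shared
**diagnostic substitutions** relative to an ancestral consensus identify
subfamilies, and the order in which diagnostics accumulate records the
phylogeny of the source elements. This package automates that analysis
and everything the conclusions rest on:

- **Subfamily sorting** (`sort_subfamilies()`): reference-anchored
  alignment of every element copy (semi-global, free end gaps; truncated
  ends are *missing*, never deletions), then greedy-recursive detection of
  co-segregating variant sets. A root-level subfamily needs >= 2 shared
  substitutions and >= 10 members; nested subfamilies need one additional
  diagnostic; majority-rule consensuses become the reference for the next
  level. Hallmark deletions (20 bp SINE-R, 11 bp *Alu*-like) count as
  single diagnostic events.
- **Median-joining networks** (`median_joining()`, `mp_postprocess()`,
  `root_network()`): minimum spanning network plus quasi-median (Steiner)
  vectors, maximum-parsimony pruning, outgroup rooting; gaps are a fifth
  character state so a shared deletion separates subfamilies in the
  network.
- **Orthology from flanking sequence** (`match_loci()`,
  `classify_presence()`, `parsimony_history()`): cross-species insertions
  are the same integration event only if both 50-nt flanks are reciprocal
  best hits at >= 90% identity *and* the insertion points coincide exactly
  — insertions one nucleotide apart are distinct events, the observation
  that undermines a long-lived single "master element". Presence patterns
  get Dollo-style history calls on ((human, chimp), gorilla).
- **Target-site forensics** (`extract_tsd()`, `compare_tsd()`,
  `detect_untemplated_g()`, `a_tract_distance()`): TSD extraction,
  comparison with inferred pre-integration sites (end-gap tolerant,
  replication slippage recognised), untemplated 5' G from cap reverse
  transcription, and insertion distance from upstream A-tracts.
- **Non-canonical 5' ends** (`annotate_domains()`,
  `detect_noncanonical_5p()`, `assign_exon_source()`): domain grammar
  annotation and detection of elements whose hexamer/*Alu*-like region was
  replaced by a captured first exon spliced to an acceptor at the
  *Alu*-like 3' end (the SVA_F1 / pt_SVA_D6 pattern).
- **A forward simulator** (`simulate_expansion()`): subfamily expansion on
  the hominine tree with sequentially acquired diagnostics, age-scaled
  post-insertion mutation, truncation, TSD-flanked insertion into A-rich
  contexts, lineage-specific loss, and exon-capture founders — full ground
  truth for scoring every stage (`score_partition()`, `score_presence()`).

## Worked example

```r
library(svatools)

## synthetic consensus panel encoding the subfamily relationships
pan <- synthetic_consensus_panel()
diagnostic_distance(pan$sequences["SVA_DR"], pan$sequences["SVA_D1"], pan$reference)
#> [1] 3          # three substitutions on the path from D1 to DR
diagnostic_distance(pan$sequences["SVA_C"], pan$sequences["SVA_D1"], pan$reference)
#> [1] 12         # the outgroup SVA_C is 12 events from D1

## the D2 hallmark: one 20-bp deletion in the SINE-R
p <- align_to_reference(pan$sequences["SVA_D2"], pan$reference)
subset(call_variants(p, pan$reference), kind == "del")
#>   kind pos len                  ref alt
#> 1  del 301  20 TAAATACGAGTATTTCAATG   -

## co-segregation scan of the A-G subfamilies against the DR consensus
cosegregation_scan(pan$sequences[grep("^AG_", names(pan$sequences))], pan$dr)
#>   positions        variants                      carriers n_variants n_carriers
#> 1   228,242 228:G>A,242:A>G AG_1,AG_2,AG_3,AG_4,AG_5,AG_6          2          6

## a TSD against its inferred pre-integration site
compare_tsd("AAAAATACAGAAAATT", "AAAAATACAAAAAATT")$substitutions
#>   pos ancestral observed
#> 1  10         A        G
```

The co-segregating pair at positions 228/242 marks the subfamilies that
dominate lineage-specific expansion in gorilla and chimpanzee; the single
A-to-G difference at TSD position 10 is the orangutan-specific mutation
that distinguishes its target-site duplication from the inferred
pre-integration state.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # expansion + loci + ground truth
Rscript analysis/02_sort_subfamilies.R
Rscript analysis/03_networks.R
Rscript analysis/04_orthology.R
Rscript analysis/05_tsd_forensics.R
Rscript analysis/06_exon_capture.R
```

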