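#!/usr/bin/env Rscript

# Simulate the default hominine SVA-like expansion: 15 source lineages on
# ((hs, pt), gg), 30-200 copies each, 0.5-2% post-insertion divergence,
# 20% 5'-truncated copies, TSD-flanked insertions in A-rich contexts, and
# ten cross-species decoy loci whose insertion points differ by 1 nt.
# Writes the element FASTA, the locus table and the ground truth.

suppressPackageStartupMessages(library(svatools))

seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(ref_length = 490L, lineages = default_lineage_plan(),
                         n_decoy_pairs = 10L, seed = seed)
sim <- simulate_expansion(cfg)

write_elements(sim$elements, file.path(out, "elements.fa"))
writeLines(c(">SINE_R_root", cfg$reference), file.path(out, "reference.fa"))
write_locus_table(sim$elements[, c("id", "species", "flank5", "flank3",
                                   "locus_label")],
                  file.path(out, "loci.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d element copies from %d lineages (%d loci)",
                nrow(sim$elements), nrow(cfg$lineages),
                length(unique(sim$truth$locus_id))))
message(sprintf("species counts: %s",
                paste(names(table(sim$elements$species)),
                      table(sim$elements$species), collapse = ", ")))
message("outputs under ", out)
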