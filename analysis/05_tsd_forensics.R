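#!/usr/bin/env Rscript

# Target-site forensics: extract TSDs from the simulated loci, compare
# young vs old copies (identical TSD copies are the young-insertion
# signature), measure insertion distance from the upstream A-tract, and
# print the four published NPLOC4 TSD comparisons.

suppressPackageStartupMessages(library(svatools))

simdir <- "results/sim"
out <- "results/tsd"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(simdir, "loci.tsv")))

loci <- read_locus_table(file.path(simdir, "loci.tsv"))
truth <- read.delim(file.path(simdir, "truth.tsv"))

rows <- lapply(seq_len(nrow(loci)), function(i) {
  tp <- extract_tsd(loci$flank5[i], loci$flank3[i])
  if (is.null(tp)) return(NULL)
  data.frame(id = loci$id[i], tsd5 = tp$tsd5, tsd3 = tp$tsd3,
             length = tp$length, mismatches = length(tp$mismatch_positions))
})
tsds <- do.call(rbind, rows)
write.table(tsds, file.path(out, "tsds.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

m <- merge(tsds, truth, by = "id")
ident <- tapply(m$tsd5.x == m$tsd3.x, m$age, mean)
message(sprintf("TSDs recovered for %d/%d loci", nrow(tsds), nrow(loci)))
message("fraction of identical 5'/3' TSD copies by copy age:")
for (a in names(ident)) message(sprintf("  age %s: %.2f", a, ident[[a]]))

ex <- npl_tsd_examples()
message("NPLOC4 worked examples:")
message(sprintf("  orangutan 5' TSD vs PIS: %d substitution at position %s",
                ex$pabe_5p$count, ex$pabe_5p$substitutions$pos))
message(sprintf("  3' TSD vs PIS: %d substitutions at positions %s",
                ex$tsd_3p$count,
                paste(ex$tsd_3p$substitutions$pos, collapse = " and ")))
message(sprintf("  P. abelii vs P. pygmaeus 5' allele: position %s",
                ex$pabe_vs_ppyg$substitutions$pos))
message(sprintf("  human TSD vs PIS: %d substitution, %d nt shorter",
                ex$human$count, -ex$human$length_diff))
message("outputs under ", out)
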