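#!/usr/bin/env Rscript
# Classify the simulated proteins by cysteine signature, assign receptor
# families from domain hits, apply the phylogeny-inclusion filters, and
# score everything against the generators' truth tables.

library(chemosensr)

sim <- "results/sim"
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

recs <- read_fasta(file.path(sim, "proteins.fa"), "protein")
ann <- read_annotation(file.path(sim, "annotations.tsv"))
keep <- match(recs$id, ann$id)
recs$signal_peptide <- ann$signal_peptide[keep]
recs$domain_hits <- ann$domain_hits[keep]

message("Motif classification ...")
tab <- classify_proteins(recs)
write.table(tab, file.path(out, "motif_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- read.delim(file.path(sim, "truth_proteins.tsv"))
want <- c(Classical = "Classical", MinusC_upstream = "MinusC",
          MinusC_downstream = "MinusC", Dimer = "Dimer", CSP = "CSP",
          decoy = "None")[truth$class]
message(sprintf("  planted-class agreement: %.1f%% (%d records)",
                100 * mean(tab$subclass == want), nrow(tab)))
message("  subclass tally: ",
        paste(names(table(tab$subclass)), table(tab$subclass),
              sep = "=", collapse = ", "))

message("Receptor family assignment and phylogeny filters ...")
calls <- assign_families(ann)
rtruth <- read.delim(file.path(sim, "truth_receptors.tsv"))
rc <- calls[match(rtruth$id, calls$id), ]
message(sprintf("  family agreement: %.1f%% (%d receptors)",
                100 * mean(rc$family == rtruth$family), nrow(rtruth)))
filt <- filter_phylo_candidates(calls)
write.table(filt[, setdiff(names(filt), "residues")],
            file.path(out, "family_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
gr_in <- sum(filt$family == "GR" & filt$phylo_included)
message("  GRs passing the transmembrane filter: ", gr_in, " of ",
        sum(filt$family == "GR"))
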