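#!/usr/bin/env Rscript
# Generate the synthetic study inputs: planted-motif proteins with their
# annotation table, a receptor annotation table, a four-condition count
# matrix with planted head enrichments, and candidate gene-family trees.
# Truth tables are written separately so downstream steps can score
# themselves against them.

library(chemosensr)

seed <- 2020
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Planting OBP/CSP motifs and decoys ...")
gp <- gen_proteins(list(Classical = 34, MinusC_upstream = 7,
                        MinusC_downstream = 1, Dimer = 1, CSP = 5,
                        decoy = 60), seed = seed)
write_fasta(gp$records, file.path(out, "proteins.fa"))
gr <- gen_receptor_annotations(n_or = 44, n_gr = 27, n_ir = 34,
                               n_gr_no_tm = 4, seed = seed + 1)
ann <- rbind(gp$records[, c("id", "signal_peptide", "tm_count",
                            "domain_hits", "completeness")],
             gr$annot)
write_annotation(ann, file.path(out, "annotations.tsv"))
write.table(gp$truth, file.path(out, "truth_proteins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gr$truth, file.path(out, "truth_receptors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  ", nrow(gp$records), " proteins (carrier-class composition ",
        "mirrors the 43 OBP + 5 CSP study tally), ",
        nrow(gr$annot), " receptor annotations")

message("Simulating the four-condition count matrix ...")
gc <- gen_counts(2500, seed = seed + 2)  # 10% enriched, lfc 4, depth 1000
write.table(data.frame(transcript = rownames(gc$counts),
                       length = gc$lengths, gc$counts),
            file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(gc$truth, file.path(out, "truth_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  ", nrow(gc$counts), " transcripts, ",
        sum(gc$truth$enriched), " with a planted head enrichment")

message("Simulating gene-family trees ...")
for (fam in c("obp", "or", "gr", "ir")) {
  gt <- gen_tree(24, outgroup_size = if (fam == "obp") 0 else 2,
                 long_branch_tips = 1,
                 seed = seed + 10 + match(fam, c("obp", "or", "gr", "ir")))
  writeLines(gt$newick, file.path(out, paste0("tree_", fam, ".nwk")))
  writeLines(c(paste("outgroup", paste(gt$truth$outgroup, collapse = ",")),
               paste("long_branches",
                     paste(gt$truth$long_branches, collapse = ","))),
             file.path(out, paste0("truth_tree_", fam, ".txt")))
}
message("Done; inputs under ", out)
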