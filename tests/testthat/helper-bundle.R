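# Write a small synthetic input bundle (FASTA + annotations + counts +
# tree) to `dir` and return the matching pipeline_config plus truth tables.
make_bundle <- function(dir, seed = 7, n_tx = 250) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- gen_proteins(list(Classical = 6, MinusC_upstream = 3,
                          MinusC_downstream = 2, Dimer = 2, CSP = 4,
                          decoy = 8), seed = seed)
  write_fasta(gp$records, file.path(dir, "proteins.fa"))
  gr <- gen_receptor_annotations(n_or = 5, n_gr = 6, n_ir = 4,
                                 n_gr_no_tm = 2, seed = seed + 1)
  ann <- rbind(gp$records[, c("id", "signal_peptide", "tm_count",
                              "domain_hits", "completeness")],
               gr$annot)
  write_annotation(ann, file.path(dir, "annotations.tsv"))

  gc <- gen_counts(n_tx, seed = seed + 2)
  cts <- data.frame(transcript = rownames(gc$counts),
                    length = gc$lengths, gc$counts)
  utils::write.table(cts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gt <- gen_tree(10, outgroup_size = 2, long_branch_tips = 1,
                 seed = seed + 3)
  writeLines(gt$newick, file.path(dir, "tree.nwk"))

  cfg <- pipeline_config(
    proteins_fasta = file.path(dir, "proteins.fa"),
    annotations_tsv = file.path(dir, "annotations.tsv"),
    counts_tsv = file.path(dir, "counts.tsv"),
    manifest_tsv = system.file("extdata", "sample_manifest.tsv",
                               package = "chemosensr"),
    trees = list(
      ir = list(path = file.path(dir, "tree.nwk"), rooting = "outgroup",
                outgroup = gt$truth$outgroup),
      obp = list(path = file.path(dir, "tree.nwk"), rooting = "midpoint")),
    seed = seed)
  list(config = cfg, proteins = gp, receptors = gr, counts = gc, tree = gt)
}
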