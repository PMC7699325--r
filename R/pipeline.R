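#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Input paths left
#' `NULL` disable the corresponding stage. All thresholds are logged into
#' the report so any deviation from the defaults is visible.
#'
#' @param proteins_fasta Protein FASTA of candidate transcripts.
#' @param annotations_tsv Annotation table (see [read_annotation()]).
#' @param counts_tsv Count table: `transcript  length  fh  fb  mh  mb`.
#' @param manifest_tsv Optional sample manifest:
#'   `accession  label  read_pairs  bases`.
#' @param trees Named list of tree specs, each a list with `path` (Newick
#'   file) and either `rooting = "midpoint"` or `rooting = "outgroup"` plus
#'   `outgroup` (tip labels).
#' @param identity_threshold Unigene collapsing identity (default 0.98).
#' @param alpha,lfc_min DE significance thresholds (defaults 0.01 and 2).
#' @param dispersion Assumed NB dispersion for the no-replicate exact test.
#' @param trim_m,trim_a TMM trim fractions.
#' @param cut_fraction,linkage Expression-cluster cut and linkage.
#' @param long_branch_factor Pendant-length multiple for long-branch flags.
#' @param seed Integer seed recorded in the run log.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins_fasta = NULL, annotations_tsv = NULL,
                            counts_tsv = NULL, manifest_tsv = NULL,
                            trees = list(),
                            identity_threshold = 0.98,
                            alpha = 0.01, lfc_min = 2, dispersion = 0.16,
                            trim_m = 0.30, trim_a = 0.05,
                            cut_fraction = 0.6, linkage = "complete",
                            long_branch_factor = 10, seed = 1L) {
  cfg <- list(proteins_fasta = proteins_fasta,
              annotations_tsv = annotations_tsv,
              counts_tsv = counts_tsv, manifest_tsv = manifest_tsv,
              trees = trees,
              identity_threshold = identity_threshold,
              alpha = alpha, lfc_min = lfc_min, dispersion = dispersion,
              trim_m = trim_m, trim_a = trim_a,
              cut_fraction = cut_fraction, linkage = linkage,
              long_branch_factor = long_branch_factor, seed = seed)
  validate_config(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos never silently fall back to defaults.
#'
#' @param path YAML file with any subset of the [pipeline_config()] keys.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, user)
}

validate_config <- function(cfg) {
  stopifnot(cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$lfc_min >= 0,
            cfg$dispersion >= 0,
            cfg$trim_m >= 0, cfg$trim_m < 0.5,
            cfg$trim_a >= 0, cfg$trim_a < 0.5,
            cfg$cut_fraction > 0, cfg$cut_fraction <= 1,
            cfg$long_branch_factor > 0)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full chemosensory annotation and enrichment pipeline
#'
#' Executes classify -> quantify -> differential enrichment -> direction
#' table -> cluster -> phylogeny post-processing on the inputs named in the
#' config, and writes a report bundle: per-family counts, DE tables per
#' comparison, a direction table, expression clusters, a log2(TPM+1) heat
#' map matrix, rooted trees with long-branch flags, a human-readable
#' summary, and a machine-readable run log with all thresholds and the
#' seed. Output is deterministic for a fixed config and seed (no
#' timestamps). Any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param out_dir Report directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  log_df <- data.frame(
    key = c("package_version", "seed", "identity_threshold", "alpha",
            "lfc_min", "dispersion", "trim_m", "trim_a", "cut_fraction",
            "linkage", "long_branch_factor"),
    value = c(as.character(utils::packageVersion("chemosensr")),
              config$seed, config$identity_threshold, config$alpha,
              config$lfc_min, config$dispersion, config$trim_m,
              config$trim_a, config$cut_fraction, config$linkage,
              config$long_branch_factor),
    stringsAsFactors = FALSE)
  .write_tsv(log_df, file.path(out_dir, "run_log.tsv"))

  summary_lines <- character(0)

  if (!is.null(config$manifest_tsv)) {
    man <- .stage("manifest", {
      if (!file.exists(config$manifest_tsv)) {
        stop("manifest file not found: ", config$manifest_tsv)
      }
      utils::read.delim(config$manifest_tsv, stringsAsFactors = FALSE)
    })
    tot <- summarize_manifest(man)
    res$manifest <- tot
    .write_tsv(man, file.path(out_dir, "manifest.tsv"))
    summary_lines <- c(summary_lines,
                       sprintf("Sequencing manifest: %d samples, %s read pairs, %s bases",
                               nrow(man), format(tot$read_pairs, big.mark = ","),
                               format(tot$bases, big.mark = ",")))
  }

  if (!is.null(config$proteins_fasta)) {
    cls <- .stage("classify", {
      recs <- read_fasta(config$proteins_fasta, "protein")
      ann <- if (!is.null(config$annotations_tsv)) {
        read_annotation(config$annotations_tsv)
      } else {
        recs[, c("id", "signal_peptide", "tm_count", "domain_hits",
                 "completeness")]
      }
      keep <- match(recs$id, ann$id)
      ok <- !is.na(keep)
      recs$signal_peptide[ok] <- ann$signal_peptide[keep[ok]]
      recs$tm_count[ok] <- ann$tm_count[keep[ok]]
      recs$domain_hits[ok] <- ann$domain_hits[keep[ok]]
      recs$completeness[ok] <- ann$completeness[keep[ok]]
      motif <- classify_proteins(recs)
      fam <- assign_families(ann)   # includes annotation-only records
      merged <- merge(motif, fam[, c("id", "family", "tm_count",
                                     "full_length")],
                      by = "id", all = TRUE,
                      suffixes = c("_motif", "_domain"))
      merged$family_motif[is.na(merged$family_motif)] <- "none"
      merged$subclass[is.na(merged$subclass)] <- "None"
      merged[order(merged$id), , drop = FALSE]
    })
    res$classification <- cls
    .write_tsv(cls, file.path(out_dir, "classification.tsv"))
    # motif families take precedence over bare domain hits for OBP/CSP
    fam_final <- ifelse(cls$family_motif != "none", cls$family_motif,
                        cls$family_domain)
    counts_tab <- as.data.frame(table(family = fam_final),
                                stringsAsFactors = FALSE)
    names(counts_tab) <- c("family", "n")
    sub_tab <- as.data.frame(table(subclass = cls$subclass),
                             stringsAsFactors = FALSE)
    names(sub_tab) <- c("subclass", "n")
    res$family_counts <- counts_tab
    .write_tsv(counts_tab, file.path(out_dir, "family_counts.tsv"))
    .write_tsv(sub_tab, file.path(out_dir, "subclass_counts.tsv"))
    summary_lines <- c(summary_lines, "Family tally:",
                       sprintf("  %-5s %d", counts_tab$family, counts_tab$n))
  }

  if (!is.null(config$counts_tsv)) {
    de_bundle <- .stage("quantify", {
      if (!file.exists(config$counts_tsv)) {
        stop("counts file not found: ", config$counts_tsv)
      }
      ct <- utils::read.delim(config$counts_tsv, stringsAsFactors = FALSE)
      need <- c("transcript", "length", "fh", "fb", "mh", "mb")
      miss <- setdiff(need, names(ct))
      if (length(miss)) stop("counts table missing columns: ",
                             paste(miss, collapse = ", "))
      counts <- as.matrix(ct[, c("fh", "fb", "mh", "mb")])
      rownames(counts) <- ct$transcript
      nf <- tmm_factors(counts, config$trim_m, config$trim_a)
      eff <- colSums(counts) * nf
      ab <- compute_abundance(counts, ct$length, lib_sizes = eff)
      list(counts = counts, lengths = ct$length, nf = nf, ab = ab)
    })
    res$norm_factors <- de_bundle$nf
    .write_tsv(data.frame(sample = names(de_bundle$nf),
                          tmm_factor = unname(de_bundle$nf)),
               file.path(out_dir, "tmm_factors.tsv"))
    .write_tsv(data.frame(transcript = rownames(de_bundle$counts),
                          de_bundle$ab$tpm),
               file.path(out_dir, "abundance_tpm.tsv"))
    .write_tsv(data.frame(transcript = rownames(de_bundle$counts),
                          de_bundle$ab$fpkm),
               file.path(out_dir, "abundance_fpkm.tsv"))

    de <- .stage("de", {
      lapply(list(c("fh", "fb"), c("mh", "mb"), c("fh", "mh")),
             function(pr) {
               exact_test_de(de_bundle$counts, pr,
                             norm_factors = de_bundle$nf,
                             dispersion = config$dispersion,
                             alpha = config$alpha,
                             lfc_min = config$lfc_min)
             })
    })
    res$de <- de
    for (d in de) {
      .write_tsv(d, file.path(out_dir,
                              paste0("de_", d$comparison[1], ".tsv")))
    }
    dir_tab <- .stage("direction_table", build_direction_table(de))
    res$direction_table <- dir_tab
    .write_tsv(dir_tab, file.path(out_dir, "direction_table.tsv"))
    summary_lines <- c(summary_lines,
      sprintf("Differential enrichment (adj p < %g, |log2FC| >= %g):",
              config$alpha, config$lfc_min),
      sprintf("  %s: %d significant", vapply(de, function(d)
        d$comparison[1], character(1)),
        vapply(de, function(d) sum(d$significant), integer(1))))

    sig_any <- unique(unlist(lapply(de, function(d) d$id[d$significant])))
    if (length(sig_any) >= 2) {
      part <- .stage("cluster", {
        cluster_partition(de_bundle$ab$fpkm[sig_any, , drop = FALSE],
                          cut_fraction = config$cut_fraction,
                          linkage = config$linkage)
      })
      res$clusters <- part
      .write_tsv(data.frame(transcript = names(part$clusters),
                            cluster = unname(part$clusters)),
                 file.path(out_dir, "clusters.tsv"))
      summary_lines <- c(summary_lines,
                         sprintf("Expression clusters (cut at %g of max height): %d",
                                 config$cut_fraction, part$n_clusters))
    }
    hm <- heatmap_matrix(de_bundle$ab$tpm)
    .write_tsv(data.frame(transcript = rownames(hm$values)[hm$row_order],
                          hm$values[hm$row_order, hm$col_order,
                                    drop = FALSE]),
               file.path(out_dir, "heatmap_log2tpm.tsv"))
  }

  if (length(config$trees)) {
    phylo <- .stage("phylo", {
      out <- list()
      for (nm in names(config$trees)) {
        spec <- config$trees[[nm]]
        tree <- parse_newick(spec$path)
        flags <- flag_long_branches(tree, config$long_branch_factor)
        rooted <- if (identical(spec$rooting, "outgroup")) {
          outgroup_root(tree, spec$outgroup)
        } else {
          midpoint_root(tree)
        }
        write_newick(rooted, file.path(out_dir,
                                       paste0("tree_", nm, "_rooted.nwk")))
        out[[nm]] <- list(rooted = rooted, long_branches = flags)
      }
      out
    })
    res$phylo <- phylo
    lb <- data.frame(
      tree = rep(names(phylo), vapply(phylo, function(x)
        length(x$long_branches), integer(1))),
      tip = unlist(lapply(phylo, `[[`, "long_branches"), use.names = FALSE),
      stringsAsFactors = FALSE)
    .write_tsv(lb, file.path(out_dir, "long_branches.tsv"))
    summary_lines <- c(summary_lines,
                       sprintf("Trees processed: %d; long-branch flags: %d",
                               length(phylo), nrow(lb)))
  }

  writeLines(c("chemosensory pipeline report", "", summary_lines),
             file.path(out_dir, "summary.txt"))
  invisible(res)
}
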