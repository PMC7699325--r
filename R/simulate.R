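# Seeded generators producing inputs with known truth for every pipeline
# stage. Truth tables are emitted alongside the data, never embedded in it.

.aa_no_cys <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]

.rand_flank <- function(range) {
  paste(sample(.aa_no_cys, sample(range[1]:range[2], 1), replace = TRUE),
        collapse = "")
}

.spacer_seg <- function(len) {
  if (len == 0) return("")
  paste(sample(.aa_no_cys, len, replace = TRUE), collapse = "")
}

# Assemble C<seg>C<seg>... from spacer gap lengths; optionally convert the
# residue at `alt_at` (1-based within the assembled motif) to a cysteine.
.build_motif <- function(gaps, alt_at = NULL) {
  segs <- vapply(gaps, .spacer_seg, character(1))
  motif <- paste0("C", paste0(segs, "C", collapse = ""))
  if (!is.null(alt_at)) substr(motif, alt_at, alt_at) <- "C"
  motif
}

#' Generate protein sequences with planted cysteine-signature classes
#'
#' Plants Classical, Minus-C (both alternate-cysteine variants), dimer OBP,
#' and CSP motifs with spacers sampled uniformly within the admissible
#' ranges, embedded in cysteine-free random flanks so the planted cysteines
#' are the only anchors. Decoys either carry no cysteine at all or carry six
#' cysteines whose spacing violates every pattern bound (optionally with
#' extra random cysteines sprinkled into the flanks in `hard_decoys` mode).
#' Annotations are consistent with the planted class: carriers are flagged
#' as secreted with no transmembrane domain and the matching domain hit.
#'
#' @param n_per_class Named integer vector/list with any of `Classical`,
#'   `MinusC_upstream`, `MinusC_downstream`, `Dimer`, `CSP`, `decoy`.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param flank_range Length range of the cysteine-free flanks.
#' @param hard_decoys Sprinkle extra cysteines into spacing-violating decoy
#'   flanks.
#' @return List with `records` (record table), `truth` (data.frame `id`,
#'   `class`, `variant`), and the count requested per class.
#' @export
gen_proteins <- function(n_per_class, seed, flank_range = c(5, 25),
                         hard_decoys = FALSE) {
  classes <- c("Classical", "MinusC_upstream", "MinusC_downstream",
               "Dimer", "CSP", "decoy")
  n <- stats::setNames(integer(length(classes)), classes)
  n[names(n_per_class)] <- unlist(n_per_class)
  if (any(is.na(n)) || any(n < 0)) stop("class counts must be >= 0")
  unknown <- setdiff(names(n_per_class), classes)
  if (length(unknown)) stop("unknown classes: ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  seqs <- character(0); cls <- character(0); var <- character(0)
  classical_gaps <- function() {
    c(sample(26:34, 1), 3L, sample(25:38, 1), sample(8:11, 1), 8L)
  }
  for (cl in classes) {
    for (i in seq_len(n[[cl]])) {
      core <- switch(cl,
        Classical = .build_motif(classical_gaps()),
        MinusC_upstream = {
          g <- c(sample(30:38, 1), sample(25:38, 1), sample(17:20, 1))
          # anchors at 1, g1+2, g1+g2+3, g1+g2+g3+4; alt 7 before C4
          c4 <- sum(g[1:2]) + 3L
          .build_motif(g, alt_at = c4 - 7L)
        },
        MinusC_downstream = {
          g <- c(sample(30:38, 1), sample(25:38, 1), sample(17:20, 1))
          c6 <- sum(g) + 4L
          .build_motif(g, alt_at = c6 - 6L)   # expected C5 (c6 - 9) + 3
        },
        Dimer = paste0(.build_motif(classical_gaps()),
                       .spacer_seg(sample(8:15, 1)),
                       .build_motif(classical_gaps())),
        CSP = .build_motif(c(6L, 18L, 2L)),
        decoy = {
          if (i %% 2 == 0) {
            .spacer_seg(sample(60:120, 1))   # cysteine-free decoy
          } else {
            .build_motif(c(22L, 1L, 22L, 5L, 5L))  # violates every bound
          }
        })
      left <- .rand_flank(flank_range); right <- .rand_flank(flank_range)
      if (hard_decoys && cl == "decoy" && i %% 2 == 1) {
        for (fl in c("left", "right")) {
          f <- get(fl)
          for (j in seq_len(sample(0:2, 1))) {
            at <- sample(nchar(f), 1)
            substr(f, at, at) <- "C"
          }
          assign(fl, f)
        }
      }
      seqs <- c(seqs, paste0(left, core, right))
      cls <- c(cls, cl)
      var <- c(var, switch(cl, MinusC_upstream = "alt_upstream_C4",
                           MinusC_downstream = "alt_downstream_C5",
                           NA_character_))
    }
  }
  ids <- sprintf("syn_%04d", seq_along(seqs))
  is_carrier <- cls != "decoy"
  records <- new_seq_records(
    ids, seqs, "protein",
    signal_peptide = is_carrier,
    tm_count = 0L,
    domain_hits = ifelse(cls == "CSP", "CSP_domain",
                         ifelse(is_carrier, "OBP_domain", "")),
    completeness = "full")
  truth <- data.frame(id = ids, class = cls, variant = var,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, n_per_class = as.list(n))
}

#' Generate a receptor-family annotation table with known composition
#'
#' Emits annotation rows for odorant, gustatory, and ionotropic receptors
#' with domain hits from the controlled vocabulary and transmembrane counts
#' consistent with each family (ORs 4-7 TM; a configurable number of GRs
#' carry 0 TM, mirroring membrane-less assembly artifacts; the rest carry
#' 1-7).
#'
#' @param n_or,n_gr,n_ir Family sizes.
#' @param n_gr_no_tm How many GRs lack a transmembrane domain.
#' @param seed Integer seed.
#' @return List with `annot` (annotation data.frame) and `truth`
#'   (`id`, `family`, `no_tm`).
#' @export
gen_receptor_annotations <- function(n_or = 44, n_gr = 27, n_ir = 34,
                                     n_gr_no_tm = 4, seed = 1) {
  if (n_gr_no_tm > n_gr) stop("n_gr_no_tm cannot exceed n_gr")
  set.seed(seed)
  fam <- c(rep("OR", n_or), rep("GR", n_gr), rep("IR", n_ir))
  ids <- sprintf("rec_%04d", seq_along(fam))
  hits <- c(OR = "OR_7tm", GR = "GR_chemo_trehalose", IR = "IR_iGluR")[fam]
  tm <- integer(length(fam))
  tm[fam == "OR"] <- sample(4:7, n_or, replace = TRUE)
  gr_tm <- c(rep(0L, n_gr_no_tm),
             sample(1:7, n_gr - n_gr_no_tm, replace = TRUE))
  tm[fam == "GR"] <- sample(gr_tm)
  tm[fam == "IR"] <- sample(3:4, n_ir, replace = TRUE)
  annot <- data.frame(id = ids, signal_peptide = FALSE, tm_count = tm,
                      domain_hits = unname(hits),
                      completeness = sample(c("full", "partial_5p"),
                                            length(fam), replace = TRUE,
                                            prob = c(0.8, 0.2)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, family = fam, no_tm = tm == 0L,
                      stringsAsFactors = FALSE)
  list(annot = annot, truth = truth)
}

#' Generate a four-condition count matrix with planted enrichments
#'
#' Emulates the single-replicate female/male x head/body design: baseline
#' per-transcript means are drawn log-normally around the target depth,
#' head-appendage means of enriched transcripts are scaled by
#' `2^planted_lfc` (in both sexes, so the head-vs-head comparison stays
#' null), and counts are drawn from a negative binomial at the stated
#' dispersion (Poisson when 0).
#'
#' @param n_transcripts Number of transcripts.
#' @param enriched_fraction Fraction with a planted head enrichment.
#' @param planted_lfc Planted log2 fold change (>= 0).
#' @param depth Mean baseline count per transcript.
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param seed Integer seed.
#' @param baseline_sdlog Log-scale sd of the baseline means.
#' @param length_range Transcript length range (bp).
#' @return List with `counts` (matrix, columns `fh`, `fb`, `mh`, `mb`),
#'   `lengths`, and `truth` (`id`, `enriched`, `planted_lfc`).
#' @export
gen_counts <- function(n_transcripts, enriched_fraction = 0.1,
                       planted_lfc = 4, depth = 1000, dispersion = 0.16,
                       seed = 1, baseline_sdlog = 1,
                       length_range = c(300, 3000)) {
  if (planted_lfc < 0) stop("planted_lfc must be >= 0")
  if (depth <= 0) stop("depth must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  n <- n_transcripts
  ids <- sprintf("tx_%05d", seq_len(n))
  base <- stats::rlnorm(n, log(depth) - baseline_sdlog^2 / 2, baseline_sdlog)
  enriched <- seq_len(n) %in% sample(n, round(n * enriched_fraction))
  head_mu <- base * ifelse(enriched, 2^planted_lfc, 1)
  draw <- function(mu) {
    if (dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  counts <- cbind(fh = draw(head_mu), fb = draw(base),
                  mh = draw(head_mu), mb = draw(base))
  rownames(counts) <- ids
  lengths <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  truth <- data.frame(id = ids, enriched = enriched,
                      planted_lfc = ifelse(enriched, planted_lfc, 0),
                      stringsAsFactors = FALSE)
  list(counts = counts, lengths = lengths, truth = truth)
}

#' Generate a random tree with optional planted outgroup and long branches
#'
#' Random ingroup topology with exponential branch lengths; a designated
#' outgroup (when requested) is attached as a clade separable by a single
#' edge, and designated long-branch tips have their pendant edge set to
#' `long_factor` times the median pendant length so they are unambiguously
#' flaggable.
#'
#' @param n_tips Total tips (>= 3).
#' @param outgroup_size Tips in the planted outgroup clade (< `n_tips`).
#' @param long_branch_tips Number of planted long-branch ingroup tips.
#' @param seed Integer seed.
#' @param rate Exponential rate for branch lengths.
#' @param long_factor Pendant-length multiple for planted long branches
#'   (default 20).
#' @return List with `tree` (unrooted `phylo`), `newick`, and `truth`
#'   (`outgroup`, `long_branches`).
#' @export
gen_tree <- function(n_tips, outgroup_size = 0, long_branch_tips = 0,
                     seed = 1, rate = 5, long_factor = 20) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  if (outgroup_size >= n_tips) stop("outgroup_size must be < n_tips")
  ing_n <- n_tips - outgroup_size
  if (ing_n < 2) stop("need at least 2 ingroup tips")
  if (long_branch_tips > ing_n) stop("too many long-branch tips")
  set.seed(seed)
  brfun <- function(k) stats::rexp(k, rate)
  strip <- function(tr) sub(";$", "", ape::write.tree(tr, digits = 10))
  ing <- ape::rtree(ing_n, tip.label = sprintf("t%02d", seq_len(ing_n)),
                    br = brfun)
  if (outgroup_size == 0) {
    tree <- ing
  } else {
    og_lab <- sprintf("og%02d", seq_len(outgroup_size))
    og_txt <- if (outgroup_size == 1) {
      paste0(og_lab, ":", format(stats::rexp(1, rate), digits = 10))
    } else {
      strip(ape::rtree(outgroup_size, tip.label = og_lab, br = brfun))
    }
    e <- stats::rexp(2, rate)
    tree <- ape::read.tree(text = paste0(
      "(", strip(ing), ":", format(e[1], digits = 10), ",",
      og_txt, ":", format(e[2], digits = 10), ");"))
  }
  tree <- ape::unroot(tree)   # unroot first: it merges the two root edges
  long <- character(0)
  if (long_branch_tips > 0) {
    long <- sample(sprintf("t%02d", seq_len(ing_n)), long_branch_tips)
    idx <- match(match(long, tree$tip.label), tree$edge[, 2])
    # median of the final pendant vector: the planted lengths will be the
    # largest, so masking them as +Inf gives the post-planting median
    pl <- pendant_lengths(tree)
    pl[long] <- Inf
    tree$edge.length[idx] <- long_factor * stats::median(pl)
  }
  list(tree = tree, newick = write_newick(tree),
       truth = list(outgroup = if (outgroup_size)
                      sprintf("og%02d", seq_len(outgroup_size))
                    else character(0),
                    long_branches = sort(long)))
}
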