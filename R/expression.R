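#' Summarize a sequencing sample manifest
#'
#' Totals read pairs and bases over samples, optionally checking the
#' paired-end arithmetic `bases = read_pairs * cycle_bases` (e.g. 250 bases
#' per pair for 125 bp x 2 chemistry).
#'
#' @param manifest Data.frame with columns `accession`, `label`,
#'   `read_pairs`, `bases`. Labels are expected from
#'   `{female_head, female_body, male_head, male_body}`.
#' @param cycle_bases Bases per read pair; when supplied, per-sample
#'   consistency is reported in the `consistent` field.
#' @return List with `read_pairs`, `bases`, and `consistent` (`NA` when
#'   `cycle_bases` is not given).
#' @export
summarize_manifest <- function(manifest, cycle_bases = NULL) {
  if (!nrow(manifest)) {
    return(list(read_pairs = 0, bases = 0, consistent = NA))
  }
  if (any(manifest$read_pairs < 0) || any(manifest$bases < 0)) {
    stop("negative read or base counts in manifest")
  }
  consistent <- if (is.null(cycle_bases)) NA else {
    all(manifest$bases == manifest$read_pairs * cycle_bases)
  }
  list(read_pairs = sum(as.numeric(manifest$read_pairs)),
       bases = sum(as.numeric(manifest$bases)),
       consistent = consistent)
}

#' Transcript-per-million and FPKM abundance measures
#'
#' TPM per column: length-normalized rates rescaled so each column sums to
#' one million. FPKM per column: counts per kilobase of transcript per
#' million library reads, `c / (len/1e3 * lib/1e6)`. A zero-count column
#' yields an all-zero TPM column with a warning (the measure is undefined).
#'
#' @param counts Numeric matrix, transcripts x samples.
#' @param lengths Transcript lengths in bp (all > 0).
#' @param lib_sizes Library sizes for FPKM; defaults to column sums.
#'   Effective (TMM-scaled) library sizes may be supplied.
#' @return List with matrices `tpm` and `fpkm`.
#' @export
compute_abundance <- function(counts, lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("zero-count column(s): TPM undefined, emitting zeros for ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  fpkm <- sweep(counts / (lengths / 1e3), 2, lib_sizes / 1e6, "/")
  list(tpm = tpm, fpkm = fpkm)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors robust to a minority of differentially
#' expressed genes. The reference sample is the one whose upper-quartile of
#' library-scaled counts is closest to the mean upper-quartile. For each
#' sample, genes with a zero in either the sample or the reference are
#' removed, M (log2 expression ratio) and A (average log2 abundance) values
#' are computed on library-scaled counts, the tails of M (default 30%) and A
#' (default 5%) are trimmed, and the factor is 2 to the
#' precision-weighted mean of the surviving M values. Factors are rescaled
#' to geometric mean 1, so depth alone (proportional columns) is absorbed by
#' library size, not the factor.
#'
#' @param counts Numeric matrix, transcripts x samples (>= 2 samples).
#' @param trim_m,trim_a Tail fractions trimmed from M and A (defaults 0.30
#'   and 0.05).
#' @param lib_sizes Library sizes; defaults to column sums.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least two samples")
  allzero <- colSums(counts) == 0
  if (any(allzero)) {
    stop("column(s) of all zeros: ",
         paste(if (is.null(colnames(counts))) which(allzero)
               else colnames(counts)[allzero], collapse = ", "))
  }
  uq <- apply(sweep(counts, 2, lib_sizes, "/"), 2, stats::quantile,
              probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    .tmm_pair(counts[, k], counts[, ref], lib_sizes[k], lib_sizes[ref],
              trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: trimmed, precision-weighted mean of M.
.tmm_pair <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (!length(y)) return(1)
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  # asymptotic (delta-method) inverse variance of M
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1; hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1; hi_a <- ng + 1 - lo_a
  rm_ <- rank(m)
  ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) keep2 <- rep(TRUE, ng)      # degenerate tiny input
  wk <- 1 / w[keep2]
  wk[!is.finite(wk)] <- max(wk[is.finite(wk)], 1)
  2 ^ (sum(wk * m[keep2]) / sum(wk))
}

#' No-replicate negative-binomial conditional exact test
#'
#' Two-sided exact test for a pair of libraries, one sample per condition
#' (the single-replicate design). Counts are scaled to the geometric mean of
#' the two effective library sizes; conditional on the pair total, the first
#' count follows a symmetric beta-binomial under the null (negative binomial
#' with the supplied dispersion), reducing to Binomial(total, 1/2) when
#' `dispersion = 0`. The p-value is the doubled smaller tail, capped at 1.
#' log2 fold changes are computed from the scaled counts with a prior count
#' of 0.5 added to both, so zeros never produce infinite fold changes.
#' Benjamini-Hochberg adjustment is applied across all transcripts, and a
#' transcript is significant iff `adj_p < alpha` and `|log2FC| >= lfc_min`.
#'
#' @param counts Count matrix with named columns; rownames are transcript
#'   ids.
#' @param pair Character vector of the two column names to compare; the
#'   first is condition A (positive log2FC = higher in A).
#' @param lib_sizes Library sizes (defaults to column sums of `counts`).
#' @param norm_factors TMM factors per column (default all 1); effective
#'   library size = `lib_sizes * norm_factors`.
#' @param dispersion Negative-binomial dispersion (>= 0). The
#'   single-replicate design cannot estimate it, so it must be assumed;
#'   the default 0.16 corresponds to a biological CV of 0.4.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param lfc_min Absolute log2FC threshold (default 2).
#' @param comparison Comparison label, e.g. `"fh_vs_fb"`.
#' @return Data.frame with `id`, `comparison`, `log2FC`, `p`, `adj_p`,
#'   `significant`, `direction` (`"A>B"`-style label or `"ns"`).
#' @export
exact_test_de <- function(counts, pair,
                          lib_sizes = colSums(counts),
                          norm_factors = NULL,
                          dispersion = 0.16, alpha = 0.01, lfc_min = 2,
                          comparison = paste0(pair[1], "_vs_", pair[2])) {
  counts <- as.matrix(counts)
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(pair) != 2L || anyDuplicated(pair)) {
    stop("exactly one sample per group is required; for replicated designs ",
         "use a GLM-based tool instead")
  }
  if (!all(pair %in% colnames(counts))) {
    stop("pair columns not found in counts: ",
         paste(setdiff(pair, colnames(counts)), collapse = ", "))
  }
  if (is.null(norm_factors)) {
    norm_factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
  if (is.null(names(norm_factors))) names(norm_factors) <- colnames(counts)
  eff <- lib_sizes[pair] * norm_factors[pair]
  common <- sqrt(prod(eff))
  y1 <- counts[, pair[1]]; y2 <- counts[, pair[2]]
  s1 <- y1 * common / eff[1]; s2 <- y2 * common / eff[2]
  lfc <- log2((s1 + 0.5) / (s2 + 0.5))
  p1 <- round(s1); p2 <- round(s2)
  p <- vapply(seq_along(p1), function(i) {
    .pair_exact_p(p1[i], p2[i], dispersion)
  }, numeric(1))
  adj <- stats::p.adjust(p, method = "BH")
  sig <- adj < alpha & abs(lfc) >= lfc_min
  data.frame(id = if (is.null(rownames(counts)))
               as.character(seq_along(y1)) else rownames(counts),
             comparison = comparison,
             log2FC = unname(lfc), p = unname(p), adj_p = unname(adj),
             significant = unname(sig),
             direction = ifelse(!sig, "ns",
                                ifelse(lfc > 0,
                                       paste0(pair[1], ">", pair[2]),
                                       paste0(pair[2], ">", pair[1]))),
             stringsAsFactors = FALSE)
}

# Doubled smaller conditional tail for one transcript. Under the null the
# two (library-adjusted) counts are exchangeable NB draws; conditioning on
# the total gives a symmetric beta-binomial (binomial at dispersion 0).
.pair_exact_p <- function(y1, y2, dispersion) {
  s <- y1 + y2
  if (s == 0) return(1)
  # the null conditional distribution is symmetric, so the smaller tail is
  # the lower tail of the smaller count; evaluating it that way makes the
  # p-value bitwise invariant under a sample swap
  ymin <- min(y1, y2)
  if (dispersion == 0) {
    return(min(1, 2 * stats::pbinom(ymin, s, 0.5)))
  }
  r <- 1 / dispersion
  k <- 0:s
  lp <- lgamma(k + r) - lgamma(k + 1) + lgamma(s - k + r) - lgamma(s - k + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, 2 * sum(pr[k <= ymin]))
}

#' Build the tissue-direction table from DE results
#'
#' One row per (transcript, significant comparison), with the winning
#' condition spelled out (`"fh > fb"`, `"fb > fh"`, ...) and the absolute
#' log2 fold change: the layout used to tally head-enriched versus
#' body-enriched sets.
#'
#' @param results One DE result data.frame (from [exact_test_de()]) or a
#'   list of them; comparison labels must come from
#'   `{fh_vs_fb, mh_vs_mb, fh_vs_mh}`.
#' @return Data.frame with `id`, `comparison`, `direction`, `abs_log2FC`,
#'   ordered by comparison then id; empty when nothing is significant.
#' @export
build_direction_table <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  res <- do.call(rbind, results)
  valid <- c("fh_vs_fb", "mh_vs_mb", "fh_vs_mh")
  bad <- setdiff(unique(res$comparison), valid)
  if (length(bad)) {
    stop("unknown comparison label(s): ", paste(bad, collapse = ", "))
  }
  res <- res[res$significant, , drop = FALSE]
  if (!nrow(res)) {
    return(data.frame(id = character(0), comparison = character(0),
                      direction = character(0), abs_log2FC = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ab <- strsplit(res$comparison, "_vs_", fixed = TRUE)
  a <- vapply(ab, `[`, character(1), 1L)
  b <- vapply(ab, `[`, character(1), 2L)
  out <- data.frame(id = res$id, comparison = res$comparison,
                    direction = ifelse(res$log2FC > 0,
                                       paste(a, ">", b), paste(b, ">", a)),
                    abs_log2FC = abs(res$log2FC),
                    stringsAsFactors = FALSE)
  out[order(match(out$comparison, valid), out$id), , drop = FALSE]
}

#' Partition transcripts into expression clusters
#'
#' Rows are transformed to `log2(x + 1)` and centered by their row mean,
#' then agglomerated hierarchically (Euclidean distance; complete linkage by
#' default) and the dendrogram is cut at a fraction of its maximum merge
#' height. A fraction of 1 yields a single cluster; a fraction approaching 0
#' yields singletons.
#'
#' @param expr Expression matrix (e.g. FPKM), transcripts x samples, >= 2
#'   rows.
#' @param cut_fraction Fraction of the maximum merge height at which to cut
#'   (default 0.6).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param center Center rows by their mean after the log transform
#'   (default `TRUE`).
#' @return List of class `cluster_partition`: `hclust`, `clusters` (named
#'   integer vector), `cut_height`, `cut_fraction`, `n_clusters`.
#' @export
cluster_partition <- function(expr, cut_fraction = 0.6,
                              linkage = "complete", center = TRUE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop("cluster_partition requires >= 2 rows")
  if (cut_fraction <= 0 || cut_fraction > 1) {
    stop("cut_fraction must be in (0, 1]")
  }
  x <- log2(expr + 1)
  if (center) x <- x - rowMeans(x)
  hc <- stats::hclust(stats::dist(x), method = linkage)
  h <- cut_fraction * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  structure(list(hclust = hc, clusters = cl, cut_height = h,
                 cut_fraction = cut_fraction,
                 n_clusters = length(unique(cl))),
            class = "cluster_partition")
}

#' Log-transformed TPM matrix with dendrogram orders for heat maps
#'
#' @param tpm Non-negative TPM matrix.
#' @param linkage Agglomeration method for the row/column dendrograms.
#' @return List of class `heatmap_matrix`: `values` (`log2(TPM + 1)`),
#'   `row_order`, `col_order`.
#' @export
heatmap_matrix <- function(tpm, linkage = "complete") {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be >= 0")
  v <- log2(tpm + 1)
  row_order <- if (nrow(v) > 1L) {
    stats::hclust(stats::dist(v), method = linkage)$order
  } else 1L
  col_order <- if (ncol(v) > 1L) {
    stats::hclust(stats::dist(t(v)), method = linkage)$order
  } else 1L
  structure(list(values = v, row_order = row_order, col_order = col_order),
            class = "heatmap_matrix")
}
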