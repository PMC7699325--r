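#' Gap-constrained cysteine signature patterns
#'
#' A motif pattern is an ordered series of cysteine anchors with an
#' admissible range of spacer residues (residues strictly between
#' consecutive cysteines) for each gap. Positions are 1-based.
#'
#' @param name Pattern name.
#' @param spacers Two-column integer matrix (or list of length-2 vectors) of
#'   `(min, max)` spacer ranges; one row per inter-cysteine gap.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, spacers) {
  if (is.list(spacers)) spacers <- do.call(rbind, spacers)
  spacers <- matrix(as.integer(spacers), ncol = 2,
                    dimnames = list(NULL, c("min", "max")))
  if (nrow(spacers) < 1L) {
    stop("pattern configuration error: at least one spacer range required")
  }
  if (any(spacers[, 1] < 0L) || any(spacers[, 2] < spacers[, 1])) {
    stop("pattern configuration error: require 0 <= min <= max per spacer")
  }
  structure(list(name = name,
                 n_anchors = nrow(spacers) + 1L,
                 spacers = spacers),
            class = "motif_pattern")
}

#' @describeIn motif_pattern The six-cysteine Classical OBP signature,
#'   spacers (26-34), (3), (25-38), (8-11), (8).
#' @export
obp_classical_pattern <- function() {
  motif_pattern("obp_classical",
                rbind(c(26L, 34L), c(3L, 3L), c(25L, 38L),
                      c(8L, 11L), c(8L, 8L)))
}

#' @describeIn motif_pattern The Minus-C OBP backbone: the Classical pattern
#'   with C2 and C5 deleted, merging the flanking spacers to (30-38) between
#'   C1 and C3 and (17-20) between C4 and C6.
#' @export
obp_minusc_pattern <- function() {
  motif_pattern("obp_minusc",
                rbind(c(30L, 38L), c(25L, 38L), c(17L, 20L)))
}

#' @describeIn motif_pattern The four-cysteine CSP signature, spacers
#'   (6), (18), (2).
#' @export
csp_pattern <- function() {
  motif_pattern("csp", rbind(c(6L, 6L), c(18L, 18L), c(2L, 2L)))
}

#' Scan a protein sequence for a cysteine-spacing motif
#'
#' Leftmost-greedy complete search: the first anchor is tried at each
#' cysteine from left to right and each subsequent anchor takes the smallest
#' admissible gap, backtracking when an extension cannot complete. The first
#' match reported is therefore the lexicographically smallest valid anchor
#' tuple, and a match is found whenever any valid tuple exists. Successive
#' matches may not share residues: each scan resumes after the previous
#' match's last anchor.
#'
#' @param seq Protein residue string.
#' @param pattern A [motif_pattern()].
#' @return List of matches, each a list with `pattern_name`, `cys_positions`
#'   (1-based anchor indices) and `span` (first to last anchor, inclusive).
#' @export
match_pattern <- function(seq, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"),
            is.character(seq), length(seq) == 1L)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seq)) {
    stop("sequence contains non-amino-acid characters")
  }
  cys <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
  k <- pattern$n_anchors
  spac <- pattern$spacers
  matches <- list()
  from <- 1L
  repeat {
    tuple <- .find_anchor_tuple(cys[cys >= from], spac, k)
    if (is.null(tuple)) break
    matches[[length(matches) + 1L]] <-
      list(pattern_name = pattern$name,
           cys_positions = tuple,
           span = c(tuple[1L], tuple[k]))
    from <- tuple[k] + 1L
  }
  matches
}

# Depth-first search for the lexicographically smallest anchor tuple among
# the candidate cysteine positions; complete (backtracks), so it fails only
# when no valid tuple exists.
.find_anchor_tuple <- function(cys, spac, k) {
  if (length(cys) < k) return(NULL)
  extend <- function(path) {
    j <- length(path)
    if (j == k) return(path)
    prev <- path[j]
    cand <- cys[cys >= prev + spac[j, 1L] + 1L &
                cys <= prev + spac[j, 2L] + 1L]
    for (p in cand) {
      res <- extend(c(path, p))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (c1 in cys) {
    res <- extend(c1)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Re-validate a motif match against its pattern
#'
#' Independent checker used to enforce the match invariants: every anchored
#' residue must be a cysteine and every inter-anchor gap must lie within the
#' pattern's spacer range.
#'
#' @param seq Protein residue string.
#' @param pattern A [motif_pattern()].
#' @param match A match as returned by [match_pattern()].
#' @return `TRUE` or `FALSE`.
#' @export
validate_match <- function(seq, pattern, match) {
  pos <- match$cys_positions
  if (length(pos) != pattern$n_anchors) return(FALSE)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(pos < 1L | pos > length(res)) || any(res[pos] != "C")) return(FALSE)
  gaps <- diff(pos) - 1L
  all(gaps >= pattern$spacers[, 1L] & gaps <= pattern$spacers[, 2L])
}

# Does a >= min_anchors prefix of the pattern match with no room left on the
# sequence to complete the remaining anchors? Used to annotate truncated
# proteins whose motif runs off the missing end.
.partial_prefix_match <- function(seq, pattern, min_anchors = 3L) {
  k <- pattern$n_anchors
  for (j in seq(k - 1L, min_anchors)) {
    pre <- motif_pattern(pattern$name, pattern$spacers[seq_len(j - 1L), ,
                                                       drop = FALSE])
    m <- match_pattern(seq, pre)
    if (length(m)) {
      last <- m[[1L]]$cys_positions[j]
      need <- sum(pattern$spacers[j:(k - 1L), 1L] + 1L)
      if (last + need > nchar(seq)) return(TRUE)
    }
  }
  FALSE
}

#' Classify a protein as a Classical, Minus-C, or dimer OBP
#'
#' Subclass priority is Dimer > Classical > Minus-C > None. A dimer is two
#' or more non-overlapping Classical matches (a fused double motif is never
#' reported as a single Classical OBP); its two domains are returned as
#' sub-sequences labeled `"a"` (N-terminal) and `"b"`. A Minus-C call
#' requires a match to the merged five-cysteine backbone (C2 and C5 deleted)
#' plus an alternate cysteine at `alt_offset_upstream` positions before C4
#' (variant `alt_upstream_C4`) or `alt_offset_downstream` positions after
#' the expected C5 (variant `alt_downstream_C5`); the expected C5 sits 9
#' positions before C6 because the C5-C6 spacer is fixed at 8. Signal
#' peptide presence never gates classification.
#'
#' @param record One row of a protein record table (or a list with `id`,
#'   `residues`, optionally `completeness`).
#' @param alt_offset_upstream,alt_offset_downstream Position offsets of the
#'   Minus-C alternate cysteine (defaults 7 and 3).
#' @param alt_tolerance Allowed deviation from the exact offsets (default 0).
#' @return A list of class `obp_call`: `id`, `subclass` (`Classical`,
#'   `MinusC`, `Dimer`, or `None`), `matches`, `minus_c_variant`,
#'   `dimer_domains` (named character vector `a`/`b`), `partial_motif`.
#' @export
classify_obp <- function(record, alt_offset_upstream = 7L,
                         alt_offset_downstream = 3L, alt_tolerance = 0L) {
  if (!is.null(record$moltype) && !all(record$moltype == "protein")) {
    stop("classify_obp requires a protein record")
  }
  seq <- record$residues
  id <- record$id
  cys <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
  cls <- match_pattern(seq, obp_classical_pattern())

  call <- list(id = id, subclass = "None", matches = cls,
               minus_c_variant = NA_character_,
               dimer_domains = NULL, partial_motif = FALSE)
  class(call) <- "obp_call"

  if (length(cls) >= 2L) {
    call$subclass <- "Dimer"
    spans <- lapply(cls[1:2], `[[`, "span")
    doms <- vapply(spans, function(s) substr(seq, s[1], s[2]), character(1))
    names(doms) <- c("a", "b")
    call$dimer_domains <- doms
    return(call)
  }
  if (length(cls) == 1L) {
    call$subclass <- "Classical"
    return(call)
  }

  mc <- match_pattern(seq, obp_minusc_pattern())
  for (m in mc) {
    p <- m$cys_positions                 # anchors C1, C3, C4, C6
    c4 <- p[3L]; c6 <- p[4L]
    up <- abs((c4 - alt_offset_upstream) - cys) <= alt_tolerance
    down <- abs((c6 - 9L + alt_offset_downstream) - cys) <= alt_tolerance
    if (any(up)) {
      call$subclass <- "MinusC"
      call$minus_c_variant <- "alt_upstream_C4"
      call$matches <- list(m)
      return(call)
    }
    if (any(down)) {
      call$subclass <- "MinusC"
      call$minus_c_variant <- "alt_downstream_C5"
      call$matches <- list(m)
      return(call)
    }
  }
  call$matches <- list()
  call$partial_motif <- .partial_prefix_match(seq, obp_classical_pattern())
  call
}

#' Classify a protein as a chemosensory protein (CSP)
#'
#' `is_csp` is true iff the four-cysteine CSP spacing matches. The
#' `secreted` field is copied from the record's signal-peptide annotation
#' and never gates the call: a CSP without a predicted signal peptide is
#' still a CSP.
#'
#' @inheritParams classify_obp
#' @return A list of class `csp_call`: `id`, `is_csp`, `match`, `secreted`.
#' @export
classify_csp <- function(record) {
  if (!is.null(record$moltype) && !all(record$moltype == "protein")) {
    stop("classify_csp requires a protein record")
  }
  m <- match_pattern(record$residues, csp_pattern())
  structure(list(id = record$id,
                 is_csp = length(m) >= 1L,
                 match = if (length(m)) m[[1L]] else NULL,
                 secreted = if (is.null(record$signal_peptide)) NA
                            else as.logical(record$signal_peptide)),
            class = "csp_call")
}

#' Batch motif classification table
#'
#' Runs [classify_obp()] then, for records without an OBP subclass,
#' [classify_csp()] on every row of a protein record table. Classification
#' of each record depends only on that record, so the output is independent
#' of input order (beyond row order) and idempotent.
#'
#' @param records Protein record table.
#' @return A data.frame with columns `id`, `family` (`OBP`, `CSP`, `none`),
#'   `subclass`, `variant`, `cys_positions` (comma-joined), `span`,
#'   `secreted`, `partial_motif`.
#' @export
classify_proteins <- function(records) {
  records <- validate_seq_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    ob <- classify_obp(rec)
    if (ob$subclass != "None") {
      m <- ob$matches[[1L]]
      all_pos <- unlist(lapply(ob$matches, `[[`, "cys_positions"))
      span <- range(unlist(lapply(ob$matches, `[[`, "span")))
      return(data.frame(id = rec$id, family = "OBP", subclass = ob$subclass,
                        variant = ob$minus_c_variant,
                        cys_positions = paste(all_pos, collapse = ","),
                        span = paste(span, collapse = "-"),
                        secreted = as.logical(rec$signal_peptide),
                        partial_motif = FALSE, stringsAsFactors = FALSE))
    }
    cs <- classify_csp(rec)
    if (cs$is_csp) {
      return(data.frame(id = rec$id, family = "CSP", subclass = "CSP",
                        variant = NA_character_,
                        cys_positions = paste(cs$match$cys_positions,
                                              collapse = ","),
                        span = paste(cs$match$span, collapse = "-"),
                        secreted = cs$secreted,
                        partial_motif = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(id = rec$id, family = "none", subclass = "None",
               variant = NA_character_, cys_positions = "",
               span = "", secreted = as.logical(rec$signal_peptide),
               partial_motif = ob$partial_motif, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a dimer OBP into its two domains for tree building
#'
#' Returns the two fused Classical motif domains as separate protein
#' records with ids `"<id>a"` and `"<id>b"`, the labels used on
#' phylogenetic trees.
#'
#' @param record The dimer's protein record.
#' @param call Its `obp_call` (subclass must be `Dimer`).
#' @return A two-row protein record table.
#' @export
split_dimer_domains <- function(record, call) {
  if (!inherits(call, "obp_call") || call$subclass != "Dimer") {
    stop("split_dimer_domains requires a Dimer obp_call")
  }
  new_seq_records(paste0(record$id, c("a", "b")),
                  unname(call$dimer_domains), "protein")
}
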