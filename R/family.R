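#' Receptor/carrier family assignment from domain hits
#'
#' Maps controlled-vocabulary domain hits to a chemosensory family with the
#' fixed precedence OR > GR > IR > OBP > CSP, so a multi-hit record always
#' resolves deterministically. Unknown vocabulary terms raise a warning and
#' are ignored; a record with no recognized hit is assigned `none`.
#' Records with OBP/CSP domain hits are expected to be routed on to the
#' motif classifier ([classify_proteins()]) for subclassing.
#'
#' @param domain_hits Character vector of hits, or a single semicolon-joined
#'   string (the annotation-table dialect).
#' @return The family label: `"OR"`, `"GR"`, `"IR"`, `"OBP"`, `"CSP"`, or
#'   `"none"`.
#' @export
assign_family <- function(domain_hits) {
  vocab <- c(OR_7tm = "OR", GR_chemo_trehalose = "GR", IR_iGluR = "IR",
             OBP_domain = "OBP", CSP_domain = "CSP")
  if (length(domain_hits) == 1L && grepl(";", domain_hits)) {
    domain_hits <- strsplit(domain_hits, ";", fixed = TRUE)[[1]]
  }
  domain_hits <- domain_hits[nzchar(domain_hits)]
  unknown <- setdiff(domain_hits, names(vocab))
  if (length(unknown)) {
    warning("unknown domain-hit terms ignored: ",
            paste(unknown, collapse = ", "))
  }
  hit <- names(vocab)[names(vocab) %in% domain_hits]
  if (!length(hit)) "none" else unname(vocab[hit[1L]])
}

#' Assign families across an annotation table
#'
#' @param annot Annotation data.frame with at least `id`, `domain_hits`,
#'   `tm_count`, `completeness`.
#' @return The table with `family`, `full_length`, `phylo_included`
#'   (initialized `TRUE`), and `exclusion_reason` (`"none"`) columns added.
#' @export
assign_families <- function(annot) {
  annot$family <- vapply(annot$domain_hits, assign_family, character(1),
                         USE.NAMES = FALSE)
  annot$full_length <- !is.na(annot$completeness) &
    annot$completeness == "full"
  annot$phylo_included <- TRUE
  annot$exclusion_reason <- "none"
  annot
}

#' Apply phylogeny-inclusion filters to family calls
#'
#' Gustatory receptors without any predicted transmembrane domain are
#' membrane receptors in name only and are excluded from tree building
#' (`exclusion_reason = "no_tm"`). Tips flagged as long-branch artifacts by
#' the caller (see [flag_long_branches()]) are excluded with reason
#' `"long_branch"`. A GR lacking a `tm_count` annotation is treated as 0
#' transmembrane domains, with a warning. A single transmembrane domain is
#' sufficient to pass the TM filter.
#'
#' @param calls Family-call table from [assign_families()].
#' @param long_branch_ids Ids to exclude as long-branch artifacts.
#' @param min_tm_for_gr Minimum transmembrane domains for a GR to enter the
#'   phylogeny (default 1).
#' @return `calls` with `phylo_included` and `exclusion_reason` set.
#' @export
filter_phylo_candidates <- function(calls, long_branch_ids = character(0),
                                    min_tm_for_gr = 1L) {
  if (!nrow(calls)) return(calls)
  calls$phylo_included <- TRUE
  calls$exclusion_reason <- "none"
  gr <- calls$family == "GR"
  if (any(gr & is.na(calls$tm_count))) {
    warning("GR calls lacking tm_count treated as 0 transmembrane domains: ",
            paste(calls$id[gr & is.na(calls$tm_count)], collapse = ", "))
  }
  tm <- ifelse(is.na(calls$tm_count), 0L, calls$tm_count)
  no_tm <- gr & tm < min_tm_for_gr
  calls$phylo_included[no_tm] <- FALSE
  calls$exclusion_reason[no_tm] <- "no_tm"
  lb <- calls$id %in% long_branch_ids & !no_tm
  calls$phylo_included[lb] <- FALSE
  calls$exclusion_reason[lb] <- "long_branch"
  calls
}
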