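#' Read a FASTA file into an annotated sequence table
#'
#' Reads protein or nucleotide FASTA into the flat record table used
#' throughout the package: one row per entry, with the header token before
#' the first whitespace as the id and all annotation columns unset.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return A data.frame with columns `id`, `residues`, `moltype`,
#'   `signal_peptide` (logical), `tm_count` (integer), `domain_hits`
#'   (semicolon-joined string), `completeness`.
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) > 0L && !startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- tryCatch(
    if (moltype == "protein") Biostrings::readAAStringSet(path)
    else Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  new_seq_records(ids, as.character(set), moltype)
}

#' Write sequence records as FASTA
#'
#' @param records Record table as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- validate_seq_records(records)
  set <- if (all(records$moltype == "protein")) {
    Biostrings::AAStringSet(records$residues)
  } else {
    Biostrings::DNAStringSet(records$residues)
  }
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

new_seq_records <- function(id, residues, moltype,
                            signal_peptide = NA,
                            tm_count = NA_integer_,
                            domain_hits = "",
                            completeness = "unknown") {
  n <- length(id)
  data.frame(id = id, residues = residues,
             moltype = rep_len(moltype, n),
             signal_peptide = rep_len(signal_peptide, n),
             tm_count = rep_len(as.integer(tm_count), n),
             domain_hits = rep_len(domain_hits, n),
             completeness = rep_len(completeness, n),
             stringsAsFactors = FALSE)
}

validate_seq_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues", "moltype") %in% names(records)))
  if (any(!nzchar(records$residues))) stop("empty residues not allowed")
  if (any(!records$moltype %in% c("protein", "nucleotide"))) {
    stop("moltype must be 'protein' or 'nucleotide'")
  }
  if (any(!is.na(records$tm_count) & records$tm_count < 0L)) {
    stop("tm_count must be >= 0")
  }
  records
}

#' Read / write the tab-separated annotation table
#'
#' Dialect: columns `id`, `signal_peptide`, `tm_count`, `domain_hits`
#' (semicolon-joined), `completeness`, plus any extra columns appended by
#' downstream stages.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "signal_peptide", "tm_count", "domain_hits", "completeness")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  df$signal_peptide <- as.logical(df$signal_peptide)
  df$tm_count <- as.integer(df$tm_count)
  df$domain_hits[is.na(df$domain_hits)] <- ""
  df
}

#' @rdname read_annotation
#' @param df Annotation data.frame.
#' @export
write_annotation <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise percent identity between two sequences
#'
#' Global alignment with match score 1, mismatch 0, and a simple affine gap
#' model; identity is the number of exact matches divided by the length of
#' the shorter sequence (the CD-HIT denominator convention).
#'
#' @param a,b Residue strings.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, moltype = "protein") {
  if (moltype == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                    baseOnly = FALSE)
    xa <- Biostrings::DNAString(a); xb <- Biostrings::DNAString(b)
  } else {
    letters <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
    mat <- diag(1, length(letters))
    dimnames(mat) <- list(letters, letters)
    xa <- Biostrings::AAString(a); xb <- Biostrings::AAString(b)
  }
  aln <- Biostrings::pairwiseAlignment(xa, xb, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Collapse near-identical transcripts into unigenes
#'
#' Greedy longest-first clustering: records are visited in decreasing length
#' (ties broken by lexicographic id) and each record joins the first existing
#' representative it matches at `identity_threshold` or above, else founds a
#' new cluster. The representative is therefore always the longest member.
#'
#' @param records Record table (single moltype).
#' @param identity_threshold Fraction in (0, 1]; default 0.98.
#' @return A list with `members` (the input records), `representatives`
#'   (record table of retained representatives), `representative_of` (named
#'   character: collapsed id -> representative id, covering every input id)
#'   and `identity_threshold`.
#' @export
collapse_unigenes <- function(records, identity_threshold = 0.98) {
  records <- validate_seq_records(records)
  if (length(unique(records$moltype)) > 1L) {
    stop("collapse_unigenes requires records of a single moltype")
  }
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(records$residues), records$id)
  reps <- integer(0)                      # row indices of representatives
  map <- character(nrow(records)); names(map) <- records$id
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      idt <- pairwise_identity(records$residues[i], records$residues[r],
                               records$moltype[i])
      if (idt >= identity_threshold) {
        map[records$id[i]] <- records$id[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      map[records$id[i]] <- records$id[i]
    }
  }
  list(members = records,
       representatives = records[sort(reps), , drop = FALSE],
       representative_of = map,
       identity_threshold = identity_threshold)
}

#' Label ORF completeness from start/stop codon presence
#'
#' `full` when both a start and a stop codon are present, `partial_5p` when
#' only the start is missing, `partial_3p` when only the stop is missing,
#' `partial_both` when both are missing, and `unknown` when either flag is
#' `NA` (missing ORF coordinates are not an error).
#'
#' @param has_start,has_stop Logical vectors (recycled to common length).
#' @return Character vector of completeness labels.
#' @export
flag_completeness <- function(has_start, has_stop) {
  n <- max(length(has_start), length(has_stop))
  has_start <- rep_len(as.logical(has_start), n)
  has_stop <- rep_len(as.logical(has_stop), n)
  out <- rep("unknown", n)
  known <- !is.na(has_start) & !is.na(has_stop)
  out[known & has_start & has_stop] <- "full"
  out[known & !has_start & has_stop] <- "partial_5p"
  out[known & has_start & !has_stop] <- "partial_3p"
  out[known & !has_start & !has_stop] <- "partial_both"
  out
}
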