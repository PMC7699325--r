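#' Parse and write Newick trees
#'
#' Thin validated wrappers around ape's Newick reader/writer. Parsing
#' rejects malformed text (unbalanced parentheses), duplicate tip labels,
#' and negative or missing branch lengths; the round trip preserves
#' topology, labels, and branch lengths to within 1e-9.
#'
#' @param text Newick string, or a path to a file containing one.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  txt <- if (file.exists(text)) paste(readLines(text), collapse = "") else text
  nopen <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  nclose <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (nopen != nclose) {
    stop("Newick parse error: unbalanced parentheses (", nopen, " '(' vs ",
         nclose, " ')')")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error in: ", substr(txt, 1, 60))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(tree$edge.length < 0) || any(!is.finite(tree$edge.length))) {
    stop("branch lengths must be present, finite, and >= 0")
  }
  tree
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Pendant branch lengths of a tree
#'
#' @param tree A `phylo` object.
#' @return Named numeric vector, one entry per tip.
#' @export
pendant_lengths <- function(tree) {
  idx <- match(seq_along(tree$tip.label), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' Root a tree at the midpoint of its longest tip-to-tip path
#'
#' Midpoint rooting minimizes the maximum root-to-tip distance; the two ends
#' of the tree's diameter end up equidistant from the root. When the
#' midpoint falls exactly on a node the tree is rooted at that node.
#' Rooting changes neither the unrooted bipartition set nor the total tree
#' length.
#'
#' @param tree A `phylo` object with >= 2 tips and branch lengths.
#' @return The rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2L) stop("midpoint rooting requires >= 2 tips")
  if (is.null(tree$edge.length)) stop("branch lengths required")
  if (all(tree$edge.length == 0)) {
    stop("all branch lengths are zero: midpoint undefined")
  }
  phangorn::midpoint(tree)
}

#' Root a tree with a designated outgroup
#'
#' Places the root at the midpoint of the single edge separating the
#' outgroup clade from the remaining tips (any pendant edge qualifies for a
#' single-tip outgroup). Errors when the outgroup is not separable by one
#' edge ("outgroup not monophyletic"). The unrooted bipartition set and the
#' total tree length are unchanged.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup tip labels.
#' @return The rooted `phylo`.
#' @export
outgroup_root <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup tips absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(outgroup) >= length(tree$tip.label)) {
    stop("outgroup must be a proper subset of the tips")
  }
  unrooted <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(unrooted, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) stop("outgroup not monophyletic (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  # resolve.root leaves the old edge length on one side of the new root;
  # rebalance so the root sits at the separating edge's midpoint.
  root_node <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) == 2L) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Flag long-branch tips
#'
#' Flags tips whose pendant branch exceeds `factor` times the median pendant
#' branch length. The rule is scale-invariant: rescaling all branch lengths
#' leaves the flags unchanged. This is an explicit, parametric stand-in for
#' the visual "very long branch" exclusions made when curating phylogenies.
#'
#' @param tree A `phylo` object.
#' @param factor Multiple of the median pendant length above which a tip is
#'   flagged (default 10; must be > 0).
#' @return Character vector of flagged tip labels.
#' @export
flag_long_branches <- function(tree, factor = 10) {
  if (factor <= 0) stop("factor must be > 0")
  if (length(tree$tip.label) < 3L) {
    warning("tree has fewer than 3 tips; no long-branch flags assigned")
    return(character(0))
  }
  pl <- pendant_lengths(tree)
  names(pl)[pl > factor * stats::median(pl)]
}
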