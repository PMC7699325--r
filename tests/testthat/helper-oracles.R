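# Independent oracles used across the suite. These re-derive expectations by
# brute force (enumeration, step-up by hand, all-edges minimax search) and
# never call the code paths they check.

# All cysteine k-tuples compatible with a spacer-range matrix, by exhaustive
# enumeration. Returns a list of integer vectors (possibly empty).
oracle_tuples <- function(seq, spacers) {
  cys <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
  k <- nrow(spacers) + 1L
  if (length(cys) < k) return(list())
  combs <- utils::combn(cys, k, simplify = FALSE)
  Filter(function(tu) {
    gaps <- diff(tu) - 1L
    all(gaps >= spacers[, 1] & gaps <= spacers[, 2])
  }, combs)
}

# Non-overlapping greedy match list derived from the enumeration oracle:
# repeatedly take the lexicographically smallest valid tuple whose anchors
# all lie after the previous match.
oracle_greedy_matches <- function(seq, spacers) {
  out <- list()
  from <- 1L
  repeat {
    tus <- Filter(function(tu) tu[1] >= from, oracle_tuples(seq, spacers))
    if (!length(tus)) break
    ord <- do.call(order, as.data.frame(do.call(rbind, tus)))
    best <- tus[[ord[1]]]
    out[[length(out) + 1L]] <- best
    from <- best[length(best)] + 1L
  }
  out
}

# Benjamini-Hochberg step-up, written out literally.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Minimal achievable maximum root-to-tip distance, by brute force over every
# edge: split the tips at the edge, then place the root at the point that
# balances the two deepest tips (clamped to the edge).
oracle_min_max_depth <- function(tree) {
  nt <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; L <- tree$edge.length[e]
    g <- tree$edge[-e, , drop = FALSE]
    comp <- b
    repeat {
      nb <- unique(c(g[g[, 1] %in% comp, 2], g[g[, 2] %in% comp, 1]))
      new <- setdiff(nb, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    tips_b <- intersect(comp, seq_len(nt))
    tips_a <- setdiff(seq_len(nt), tips_b)
    if (!length(tips_a) || !length(tips_b)) next
    max_a <- max(d[a, tips_a]); max_b <- max(d[b, tips_b])
    x <- min(max((max_b + L - max_a) / 2, 0), L)
    best <- min(best, max(max_a + x, max_b + L - x))
  }
  best
}

# Maximum root-to-tip distance of a rooted tree.
max_root_depth <- function(tree) {
  root <- length(tree$tip.label) + 1L
  max(ape::dist.nodes(tree)[root, seq_along(tree$tip.label)])
}

# Random protein string with cysteines sprinkled at random positions.
random_cys_seq <- function(len, n_cys) {
  aa <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- paste(sample(aa, len, replace = TRUE), collapse = "")
  for (at in sample(len, min(n_cys, len))) substr(s, at, at) <- "C"
  s
}

expected_subclass <- c(Classical = "Classical", MinusC_upstream = "MinusC",
                       MinusC_downstream = "MinusC", Dimer = "Dimer",
                       CSP = "CSP", decoy = "None")
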