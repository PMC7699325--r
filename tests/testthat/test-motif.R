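X <- function(n) paste(rep("A", n), collapse = "")

motif_seq <- function(gaps) {
  paste0("C", paste0(vapply(gaps, X, character(1)), "C", collapse = ""))
}

test_that("fixed-spacer patterns match at the printed positions", {
  csp <- match_pattern(motif_seq(c(6, 18, 2)), csp_pattern())
  expect_length(csp, 1L)
  expect_equal(csp[[1]]$cys_positions, c(1L, 8L, 27L, 30L))
  expect_equal(csp[[1]]$span, c(1L, 30L))

  cls <- match_pattern(motif_seq(c(26, 3, 25, 8, 8)), obp_classical_pattern())
  expect_length(cls, 1L)
  expect_length(cls[[1]]$cys_positions, 6L)

  # first spacer one beyond its upper bound
  expect_length(match_pattern(motif_seq(c(35, 3, 25, 8, 8)),
                              obp_classical_pattern()), 0L)
})

test_that("pattern construction rejects invalid spacer ranges", {
  expect_error(motif_pattern("bad", matrix(numeric(0), ncol = 2)),
               "configuration error")
  expect_error(motif_pattern("bad", rbind(c(5, 3))), "configuration error")
  expect_error(match_pattern("MK1", csp_pattern()), "non-amino-acid")
})

test_that("every reported match re-validates against its pattern", {
  set.seed(21)
  pats <- list(obp_classical_pattern(), obp_minusc_pattern(), csp_pattern())
  for (i in 1:40) {
    s <- random_cys_seq(sample(60:300, 1), sample(4:10, 1))
    for (p in pats) {
      for (m in match_pattern(s, p)) {
        expect_true(validate_match(s, p, m))
      }
    }
  }
})

test_that("matching equals the brute-force cysteine-tuple oracle", {
  set.seed(22)
  gp <- gen_proteins(list(Classical = 5, MinusC_upstream = 5,
                          MinusC_downstream = 5, Dimer = 5, CSP = 5,
                          decoy = 10), seed = 99)
  seqs <- c(gp$records$residues,
            replicate(30, random_cys_seq(sample(40:300, 1), sample(3:9, 1))))
  pats <- list(obp_classical_pattern(), obp_minusc_pattern(), csp_pattern())
  for (s in seqs) {
    for (p in pats) {
      got <- lapply(match_pattern(s, p), `[[`, "cys_positions")
      want <- oracle_greedy_matches(s, p$spacers)
      expect_equal(got, want)
    }
  }
})

test_that("OBP subclass calls follow the Dimer > Classical > Minus-C priority", {
  rec <- function(s) list(id = "t", residues = s, moltype = "protein")
  cls_seq <- motif_seq(c(30, 3, 30, 10, 8))
  expect_equal(classify_obp(rec(cls_seq))$subclass, "Classical")

  dim_seq <- paste0(cls_seq, X(10), motif_seq(c(26, 3, 25, 8, 8)))
  call <- classify_obp(rec(dim_seq))
  expect_equal(call$subclass, "Dimer")
  expect_named(call$dimer_domains, c("a", "b"))
  # the two domains are themselves single Classical motifs
  for (d in call$dimer_domains) {
    expect_length(match_pattern(d, obp_classical_pattern()), 1L)
  }
  doms <- split_dimer_domains(rec(dim_seq), call)
  expect_equal(doms$id, c("ta", "tb"))

  # Minus-C: C1..C3 gap 34, C3..C4 gap 30, C4..C6 gap 18, alternate C 7
  # positions upstream of C4
  mc <- motif_seq(c(34, 30, 18))
  c4 <- 34 + 30 + 3
  substr(mc, c4 - 7, c4 - 7) <- "C"
  got <- classify_obp(rec(mc))
  expect_equal(got$subclass, "MinusC")
  expect_equal(got$minus_c_variant, "alt_upstream_C4")
  # oracle: the backbone is a valid minus-C tuple by enumeration
  expect_true(length(oracle_tuples(mc, obp_minusc_pattern()$spacers)) >= 1)

  # downstream variant: alternate C 3 after the expected C5 (9 before C6)
  mcd <- motif_seq(c(34, 30, 18))
  c6 <- 34 + 30 + 18 + 4
  substr(mcd, c6 - 6, c6 - 6) <- "C"
  gotd <- classify_obp(rec(mcd))
  expect_equal(gotd$subclass, "MinusC")
  expect_equal(gotd$minus_c_variant, "alt_downstream_C5")

  # backbone without any alternate cysteine is not a Minus-C OBP
  expect_equal(classify_obp(rec(motif_seq(c(34, 30, 18))))$subclass, "None")

  expect_error(classify_obp(list(id = "n", residues = "ATG",
                                 moltype = "nucleotide")),
               "protein")
})

test_that("CSP calls are independent of the signal peptide annotation", {
  rec <- function(s, sp = NA) list(id = "c", residues = s,
                                   moltype = "protein", signal_peptide = sp)
  ok <- motif_seq(c(6, 18, 2))
  expect_true(classify_csp(rec(ok))$is_csp)
  expect_false(classify_csp(rec(motif_seq(c(6, 17, 2))))$is_csp)
  call <- classify_csp(rec(ok, sp = FALSE))
  expect_true(call$is_csp)
  expect_false(call$secreted)
})

test_that("batch classification is idempotent and order-independent", {
  gp <- gen_proteins(list(Classical = 4, MinusC_upstream = 3, Dimer = 2,
                          CSP = 3, decoy = 6), seed = 5)
  tab <- classify_proteins(gp$records)
  set.seed(1)
  perm <- sample(nrow(gp$records))
  tab_perm <- classify_proteins(gp$records[perm, ])
  reord <- tab_perm[match(tab$id, tab_perm$id), ]
  rownames(reord) <- NULL
  expect_equal(reord, tab)
  expect_equal(classify_proteins(gp$records), tab)
})

test_that("truncated motifs are reported as None with a partial-motif note", {
  # Classical prefix C1..C4 running off the end of the sequence
  s <- paste0(X(5), "C", X(30), "C", X(3), "C", X(30), "C", X(4))
  call <- classify_obp(list(id = "p", residues = s, moltype = "protein"))
  expect_equal(call$subclass, "None")
  expect_true(call$partial_motif)
})
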