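manifest_fixture <- function() {
  utils::read.delim(system.file("extdata", "sample_manifest.tsv",
                                package = "chemosensr"),
                    stringsAsFactors = FALSE)
}

test_that("manifest summaries total pairs and bases with optional cycle check", {
  man <- manifest_fixture()
  tot <- summarize_manifest(man, cycle_bases = 250)
  expect_equal(tot$read_pairs, 120228949)
  expect_equal(tot$bases, 30057237250)
  expect_true(tot$consistent)

  expect_equal(summarize_manifest(man[0, ]),
               list(read_pairs = 0, bases = 0, consistent = NA))
  one <- data.frame(accession = "x", label = "female_head",
                    read_pairs = 100, bases = 25000)
  expect_equal(summarize_manifest(one, cycle_bases = 250)$bases, 25000)
  one$read_pairs <- -1
  expect_error(summarize_manifest(one), "negative")
})

test_that("TPM and FPKM follow their defining arithmetic", {
  ab <- compute_abundance(matrix(c(10, 40), ncol = 1), c(1000, 2000))
  expect_equal(ab$tpm[, 1], c(1, 2) / 3 * 1e6, tolerance = 1e-9)
  # 10 counts on a 1 kb transcript in a 1M library
  ab2 <- compute_abundance(matrix(10, 1, 1), 1000, lib_sizes = 1e6)
  expect_equal(ab2$fpkm[1, 1], 10)
  # equal counts and lengths: uniform TPM
  ab3 <- compute_abundance(matrix(5, 4, 2), rep(700, 4))
  expect_true(all(abs(ab3$tpm - 1e6 / 4) < 1e-9))
  # zero-count column: warning and all-zero TPM
  expect_warning(ab4 <- compute_abundance(cbind(a = c(3, 1), b = c(0, 0)),
                                          c(100, 200)), "zero-count")
  expect_equal(unname(ab4$tpm[, "b"]), c(0, 0))
})

test_that("TPM columns always sum to one million", {
  set.seed(31)
  counts <- matrix(rnbinom(400, mu = 50, size = 5), 100, 4)
  counts[1, 1] <- 0
  ab <- compute_abundance(counts, sample(200:3000, 100))
  expect_equal(colSums(ab$tpm), rep(1e6, 4), tolerance = 1e-6)
})

test_that("TMM factors are neutral for proportional columns and match edgeR", {
  set.seed(32)
  a <- rnbinom(500, mu = 100, size = 2) + 1
  same <- cbind(x = a, y = a)
  expect_equal(unname(tmm_factors(same)), c(1, 1), tolerance = 1e-12)
  doubled <- cbind(x = a, y = 2 * a)
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)

  skip_if_not_installed("edgeR")
  counts <- cbind(fh = rnbinom(800, mu = 80, size = 2),
                  fb = rnbinom(800, mu = 120, size = 2),
                  mh = rnbinom(800, mu = 60, size = 2),
                  mb = rnbinom(800, mu = 100, size = 2))
  keep <- rowSums(counts) > 0
  counts <- counts[keep, ]
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_equal(unname(ours), theirs, tolerance = 1e-8)

  zero <- cbind(ok = a, dead = rep(0L, 500))
  expect_error(tmm_factors(zero), "dead")
})

test_that("a single 100-fold spike is trimmed out of the TMM fit", {
  counts <- cbind(A = rep(100, 1000), B = rep(100, 1000))
  counts[1, "B"] <- 100 * 100
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  # trimming removes the spike, so effective library sizes re-balance and
  # the remaining genes compare 1:1
  expect_lt(abs(eff[["A"]] / eff[["B"]] - 1), 0.01)
})

test_that("no-replicate exact test reproduces the conditional-binomial closed form", {
  ct <- matrix(c(0, 0, 10, 0, 3, 3), ncol = 2, byrow = TRUE,
               dimnames = list(c("z", "t", "e"), c("A", "B")))
  res <- exact_test_de(ct, c("A", "B"), lib_sizes = c(A = 1e6, B = 1e6),
                       dispersion = 0)
  expect_equal(res$p[res$id == "z"], 1)
  expect_equal(res$direction[res$id == "z"], "ns")
  expect_equal(res$p[res$id == "t"], 2 * 0.5^10)
  expect_equal(res$p[res$id == "e"], 1)     # symmetric counts, capped at 1
  expect_true(all(res$adj_p >= res$p))

  expect_error(exact_test_de(ct, c("A", "B"), dispersion = -1), ">= 0")
  expect_error(exact_test_de(ct, c("A", "A")), "one sample per group")
  expect_error(exact_test_de(ct, c("A", "B", "A")), "one sample per group")
})

test_that("swapping the two samples negates log2FC and preserves p exactly", {
  set.seed(33)
  counts <- cbind(A = rnbinom(300, mu = 200, size = 4),
                  B = rnbinom(300, mu = 300, size = 4))
  rownames(counts) <- sprintf("t%03d", 1:300)
  fwd <- exact_test_de(counts, c("A", "B"), dispersion = 0.16)
  rev <- exact_test_de(counts, c("B", "A"), dispersion = 0.16)
  expect_equal(rev$log2FC, -fwd$log2FC)
  expect_identical(rev$p, fwd$p)
  expect_identical(rev$adj_p, fwd$adj_p)
})

test_that("BH adjustment equals the hand step-up rule for short vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(34)
  for (i in 1:10) {
    p <- runif(sample(1:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
    # monotone in ranked p and never below raw p
    adj <- oracle_bh(p)
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
    expect_true(all(adj >= p))
  }
})

test_that("exact-test p-values agree with edgeR's exact test at equal library sizes", {
  skip_if_not_installed("edgeR")
  set.seed(35)
  counts <- cbind(A = rnbinom(200, mu = 150, size = 4),
                  B = rnbinom(200, mu = 150, size = 4))
  counts[1:20, "A"] <- counts[1:20, "A"] * 8
  ours <- exact_test_de(counts, c("A", "B"), lib_sizes = c(A = 1e5, B = 1e5),
                        dispersion = 0.16)
  dg <- edgeR::DGEList(counts, group = c("A", "B"),
                       lib.size = c(1e5, 1e5))
  et <- edgeR::exactTest(dg, dispersion = 0.16, pair = c("B", "A"))
  # identical conditional distribution; tail conventions differ only on the
  # central atom
  expect_equal(ours$p, et$table$PValue, tolerance = 1e-6)
  expect_equal(ours$log2FC, et$table$logFC, tolerance = 0.1)
})

test_that("direction tables spell out the winning condition per significant row", {
  res <- data.frame(id = c("x", "y", "z"),
                    comparison = c("fh_vs_fb", "fh_vs_fb", "fh_vs_mh"),
                    log2FC = c(8.04, -2.5, 3.91),
                    p = 1e-6, adj_p = 1e-5,
                    significant = c(TRUE, TRUE, FALSE),
                    direction = c("fh>fb", "fb>fh", "ns"),
                    stringsAsFactors = FALSE)
  tab <- build_direction_table(res)
  expect_equal(tab$direction, c("fh > fb", "fb > fh"))
  expect_equal(tab$abs_log2FC, c(8.04, 2.5))

  res$significant <- FALSE
  expect_equal(nrow(build_direction_table(res)), 0L)
  res$comparison <- "head_vs_tail"
  expect_error(build_direction_table(res), "unknown comparison")
})

test_that("cluster partitions cut the dendrogram at a fraction of its height", {
  # two clearly separated groups of identical within-group profiles
  expr <- rbind(matrix(rep(c(1000, 1000, 5, 5), each = 3), 3, byrow = FALSE),
                matrix(rep(c(5, 5, 1000, 1000), each = 3), 3, byrow = FALSE))
  expr <- expr + matrix(runif(24, 0, 0.1), 6)
  rownames(expr) <- sprintf("g%d", 1:6)
  part <- cluster_partition(expr, cut_fraction = 0.6)
  expect_equal(part$n_clusters, 2L)
  expect_length(unique(part$clusters[1:3]), 1L)
  expect_length(unique(part$clusters[4:6]), 1L)

  expect_equal(cluster_partition(expr, cut_fraction = 1)$n_clusters, 1L)
  expect_equal(cluster_partition(expr, cut_fraction = 1e-9)$n_clusters, 6L)
  expect_error(cluster_partition(expr[1, , drop = FALSE]), ">= 2 rows")
})

test_that("heat-map matrices are log2(TPM+1) with dendrogram orders", {
  tpm <- rbind(a = c(0, 1), b = c(1023, 3))
  hm <- heatmap_matrix(tpm)
  expect_equal(unname(hm$values["a", ]), c(0, 1))
  expect_equal(unname(hm$values["b", 1]), 10)
  expect_setequal(hm$row_order, 1:2)
  expect_error(heatmap_matrix(matrix(-1)), ">= 0")
})
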