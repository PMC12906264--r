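test_that("gene_summary computes count and coding-length statistics", {
  gs <- gene_set(rbind(gene_calls("a", "c", 0, 300),
                       gene_calls("b", "c", 400, 1000)))
  s <- gene_summary(gs)
  expect_equal(s$group, "all")
  expect_equal(s$n_genes, 2L)
  expect_equal(s$mean_len_nt, 450)
  expect_equal(s$total_len_nt, 900L)
  expect_equal(s$median_len_nt, 300)     # lower-middle element for even counts

  empty <- gene_summary(gene_set())
  expect_equal(empty$n_genes, 0L)
  expect_true(is.na(empty$mean_len_nt))
  expect_equal(empty$total_len_nt, 0L)
})

test_that("coding length is the sum of exons, not the span", {
  gs <- gene_set(gene_calls("g", "c", 0, 100,
                            exons = list(cbind(c(0, 70), c(30, 100)))))
  expect_equal(gene_summary(gs)$total_len_nt, 60L)
})

test_that("grouped summaries partition the set exactly", {
  set.seed(21)
  for (rep in 1:5) {
    gs <- random_gene_set(sample(5:15, 1))
    for (g in c("category", "source_pass")) {
      s <- gene_summary(gs, g)
      expect_equal(sum(s$n_genes), n_calls(gs))
      expect_equal(sum(s$total_len_nt), sum(coding_lengths(gs)))
      expect_equal(s$group, sort(s$group))
    }
  }
})

test_that("identical predictions give perfect sensitivity and no fragmentation", {
  gs <- random_gene_set(8, seed = 50)
  ev <- compare_to_truth(gs, gs)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fragmentation, 1)
  expect_equal(ev$mean_len_ratio, 1)
})

test_that("a truth gene split across three calls is detected with fragmentation 3", {
  truth <- gene_set(gene_calls("t", "c", 0, 900))
  pred <- gene_set(gene_calls(c("p1", "p2", "p3"), "c",
                              c(0, 300, 600), c(300, 600, 900)))
  ev <- compare_to_truth(pred, truth)
  expect_equal(ev$detected, 1L)
  expect_equal(ev$fragmentation, 3)
  expect_lt(ev$mean_len_ratio, 1)
  expect_error(compare_to_truth(pred, truth, overlap_frac = 0), "\\(0, 1\\]")
  expect_error(compare_to_truth(pred, truth, overlap_frac = 1.5), "\\(0, 1\\]")
})

test_that("strand awareness excludes antisense predictions unless relaxed", {
  truth <- gene_set(gene_calls("t", "c", 0, 300, strand = "+"))
  anti <- gene_set(gene_calls("p", "c", 0, 300, strand = "-"))
  expect_equal(compare_to_truth(anti, truth)$detected, 0L)
  expect_equal(compare_to_truth(anti, truth, strand_aware = FALSE)$detected, 1L)
})

test_that("detection agrees with the per-base boolean coverage oracle", {
  set.seed(60)
  for (rep in 1:30) {
    truth <- random_gene_set(sample(2:6, 1))
    pred <- random_gene_set(sample(2:10, 1))
    pred$calls$gene_id <- paste0("p_", pred$calls$gene_id)
    frac <- sample(c(0.25, 0.5, 0.9), 1)
    ev <- compare_to_truth(pred, truth, overlap_frac = frac)
    expect_equal(ev$detected, sum(detection_oracle(pred, truth, frac)))
  }
})

test_that("translate_cds handles strand, table-11 starts and error cases", {
  ctg <- contig_set("c", "ATGAAATAA")
  expect_equal(translate_cds(gene_calls("g", "c", 0, 9), ctg), "MK")
  # same codons encoded on the minus strand
  ctg2 <- contig_set("c", revcomp("ATGAAATAA"))
  expect_equal(translate_cds(gene_calls("g", "c", 0, 9, strand = "-"), ctg2), "MK")
  # alternative initiation codons read as M under table 11
  expect_equal(translate_cds(gene_calls("g", "c", 0, 9),
                             contig_set("c", "GTGAAATAA")), "MK")
  expect_equal(translate_cds(gene_calls("g", "c", 0, 9),
                             contig_set("c", "GTGAAATAA"), table = 1), "VK")
  expect_error(translate_cds(gene_calls("g", "c", 0, 8), contig_set("c", "ATGAAATAAG")),
               "multiple of 3")
  expect_error(translate_cds(gene_calls("g", "c", 0, 9), contig_set("c", "ATGTAAAAA")),
               "internal stop")
  expect_equal(translate_cds(gene_calls("g", "c", 0, 9), contig_set("c", "ATGTAAAAA"),
                             partial = TRUE), "M*K")
})

test_that("spliced minus-strand calls translate through their exons", {
  # exons (ascending): [0,6) and [9,15); minus strand, so the CDS is
  # revcomp(seq[9:15] + seq[0:6])
  cds <- "ATGGGTTTCTAA"
  genomic <- paste0(revcomp(substr(cds, 7, 12)), "GTT", revcomp(substr(cds, 1, 6)))
  ctg <- contig_set("c", genomic)
  call <- gene_calls("g", "c", 0, 15, strand = "-",
                     exons = list(cbind(c(0, 9), c(6, 15))))
  expect_equal(translate_cds(call, ctg), "MGF")
})

test_that("translate_gene_set maps calls to their contigs", {
  ctgs <- contig_set(c("c1", "c2"), c("ATGAAATAA", "ATGTTTTGA"))
  gs <- gene_set(rbind(gene_calls("g1", "c1", 0, 9),
                       gene_calls("g2", "c2", 0, 9)))
  expect_equal(translate_gene_set(gs, ctgs), c(g1 = "MK", g2 = "MF"))
  expect_error(translate_gene_set(gene_set(gene_calls("g", "nope", 0, 9)), ctgs),
               "absent contig")
})

test_that("percent_identity matches the stated examples and properties", {
  expect_equal(percent_identity("MKV", "MKV"), 100)
  expect_equal(percent_identity("MKV", "MKL"), 100 * 2 / 3)
  expect_error(percent_identity("", "MK"), "non-empty")
  set.seed(71)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    a <- paste(sample(aas, sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:8, 1), TRUE), collapse = "")
    p <- percent_identity(a, b)
    expect_gte(p, 0); expect_lte(p, 100)
    expect_equal(p, percent_identity(b, a))
    expect_equal(percent_identity(a, a), 100)
  }
})

test_that("percent_identity equals the exhaustive alignment-outcome oracle", {
  set.seed(72)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aas, sample(1:6, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:6, 1), TRUE), collapse = "")
    expect_equal(percent_identity(a, b), pid_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("alignment scores agree with an independent global aligner", {
  set.seed(73)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(-1, 20, 20, dimnames = list(aas, aas))
  diag(mat) <- 1
  for (rep in 1:10) {
    a <- paste(sample(aas, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:12, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    p <- percent_identity(a, b)
    # recover my score from identity-free internals: rerun the DP via oracle
    expect_equal(pid_oracle_score(a, b), Biostrings::score(ref))
    expect_true(p >= 0 && p <= 100)
  }
})

test_that("align_scoring validates its parameters", {
  expect_error(align_scoring(match = -1, mismatch = 1), "exceed")
  expect_error(align_scoring(gap = 1), "negative")
})
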