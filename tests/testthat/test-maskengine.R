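two_exon_set <- function() {
  gene_set(gene_calls("g1", "ctg", 10, 90,
                      exons = list(cbind(c(10, 60), c(40, 90)))))
}

test_that("intervals_from_calls honours the policy mode", {
  gs <- two_exon_set()
  iv <- intervals_from_calls(gs, mask_policy(mode = "span"))
  expect_equal(iv$ctg, cbind(10L, 90L), ignore_attr = TRUE)
  iv <- intervals_from_calls(gs, mask_policy(mode = "exons"))
  expect_equal(iv$ctg, cbind(c(10L, 60L), c(40L, 90L)), ignore_attr = TRUE)
  expect_length(intervals_from_calls(gene_set()), 0L)
})

test_that("merge_intervals produces the sorted disjoint union", {
  expect_equal(merge_intervals(rbind(c(5, 15), c(0, 10))),
               cbind(0L, 15L), ignore_attr = TRUE)
  expect_equal(merge_intervals(rbind(c(0, 5), c(5, 10))),
               cbind(0L, 10L), ignore_attr = TRUE)     # touching intervals fuse
  expect_equal(nrow(merge_intervals(matrix(integer(0), ncol = 2))), 0L)
})

test_that("merge_gap fuses intervals separated by at most the gap", {
  m <- rbind(c(0, 5), c(8, 12))     # gap of 3
  expect_equal(nrow(merge_intervals(m, merge_gap = 2)), 2L)
  expect_equal(merge_intervals(m, merge_gap = 3), cbind(0L, 12L),
               ignore_attr = TRUE)
})

test_that("merge_intervals matches the boolean-array oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:60) {
    m <- random_intervals(sample(1:12, 1), max_pos = 80)
    if (!nrow(m)) next
    merged <- merge_intervals(m)
    # sorted, disjoint, gaps > 0
    if (nrow(merged) > 1) {
      expect_true(all(diff(merged[, 1]) > 0))
      expect_true(all(merged[-1, 1] > merged[-nrow(merged), 2]))
    }
    expect_equal(sum(merged[, 2] - merged[, 1]), union_size_oracle(m, 80))
    # identical positions covered
    expect_equal(union_size_oracle(merged, 80), union_size_oracle(m, 80))
    expect_equal(merge_intervals(merged), merged)
  }
})

test_that("apply_mask substitutes exactly the requested positions", {
  res <- apply_mask(contig_set("a", "ACGTACGTAC"), cbind(2, 5))
  expect_equal(res$contig$seq, "ACNNNCGTAC")
  expect_equal(res$masked_bases, 3L)

  res <- apply_mask(contig_set("a", "ACGTACGTAC"), matrix(integer(0), ncol = 2))
  expect_equal(res$contig$seq, "ACGTACGTAC")
  expect_equal(res$masked_bases, 0L)

  merged <- merge_intervals(rbind(c(2, 5), c(4, 8)))
  res <- apply_mask(contig_set("a", "ACGTACGTAC"), merged)
  expect_equal(res$contig$seq, "ACNNNNNNAC")
  expect_equal(res$masked_bases, 6L)

  expect_error(apply_mask(contig_set("a", "ACGT"), cbind(2, 10)),
               "out of bounds.*'a'")
  expect_error(apply_mask(contig_set("a", "ACGTACGT"), rbind(c(0, 4), c(2, 6))),
               "disjoint")
})

test_that("mask_metagenome composes the stages and accounts correctly", {
  ctgs <- contig_set(c("c1", "c2"), c(strrep("ACGT", 30), strrep("TTGA", 25)))
  gs <- gene_set(gene_calls(c("g1", "g2"), "c1", c(10, 50), c(40, 80)))
  res <- mask_metagenome(ctgs, gs)
  expect_equal(res$contigs$seq[2], ctgs$seq[2])      # untouched pass-through
  rep <- res$report
  expect_equal(rep$total_masked, sum(rep$per_contig$masked_bases))
  expect_equal(rep$fraction_masked, rep$total_masked / rep$total_bases)
  expect_equal(rep$per_contig$masked_bases, c(60L, 0L))
  expect_equal(rep$per_contig$n_intervals, c(2L, 0L))
})

test_that("masking conserves length and leaves unmasked positions byte-identical", {
  set.seed(11)
  for (rep in 1:25) {
    ctgs <- random_contigs(2, len_range = c(60, 200))
    iv <- random_intervals(sample(1:8, 1), max_pos = 60)
    gs <- gene_set(gene_calls(sprintf("g%d", seq_len(nrow(iv))), "rc1",
                              iv[, 1], iv[, 2]))
    res <- mask_metagenome(ctgs, gs)
    oracle <- mask_oracle(ctgs$seq[1], iv)
    expect_equal(nchar(res$contigs$seq), nchar(ctgs$seq))
    expect_equal(res$contigs$seq[1], oracle$seq)
    expect_equal(res$report$per_contig$masked_bases[1], oracle$masked_bases)
    # idempotence
    again <- mask_metagenome(res$contigs, gs)
    expect_identical(again$contigs$seq, res$contigs$seq)
    # call-order independence
    perm <- sample(n_calls(gs))
    shuffled <- gene_set(gs$calls[perm, , drop = FALSE])
    expect_identical(mask_metagenome(ctgs, shuffled)$contigs$seq,
                     res$contigs$seq)
  }
})

test_that("absent contigs error by default and warn when lenient", {
  ctgs <- contig_set("c1", strrep("A", 50))
  gs <- gene_set(gene_calls("g1", "ghost", 0, 10))
  expect_error(mask_metagenome(ctgs, gs), "absent contig 'ghost'")
  expect_warning(res <- mask_metagenome(ctgs, gs, lenient = TRUE), "skipped")
  expect_equal(res$report$n_skipped_intervals, 1L)
  expect_equal(res$report$total_masked, 0L)
})

test_that("mask_policy validates its fields", {
  expect_error(mask_policy(mask_char = "NN"), "single")
  expect_error(mask_policy(mask_char = "!"), "IUPAC")
  expect_error(mask_policy(merge_gap = -1), "non-negative")
})
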