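small_cfg <- function(seed = 7) {
  sim_config(n_contigs = 3, contig_len_range = c(20000, 30000),
             n_prok_genes = 12, n_euk_genes = 5, n_viral_genes = 3, seed = seed)
}

test_that("the simulator is deterministic under the seed", {
  a <- simulate_metagenome(small_cfg(7))
  b <- simulate_metagenome(small_cfg(7))
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$truth$calls, b$truth$calls)
  expect_equal(nrow(a$contigs), 3L)
  d <- simulate_metagenome(small_cfg(8))
  expect_false(identical(a$contigs$seq, d$contigs$seq))
})

test_that("planted prokaryote/virus genes re-scan as clean ORFs", {
  sim <- simulate_metagenome(small_cfg(7))
  pv <- sim$truth$calls[sim$truth$calls$category != "eukaryote", ]
  expect_equal(nrow(pv), 15L)
  for (i in seq_len(nrow(pv))) {
    s <- substr(sim$contigs$seq[sim$contigs$id == pv$contig_id[i]],
                pv$start[i] + 1, pv$end[i])
    if (pv$strand[i] == "-") s <- revcomp(s)
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_equal(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    expect_equal(nchar(s) %% 3, 0)
  }
})

test_that("planted eukaryote genes have GT..AG introns and a valid spliced CDS", {
  sim <- simulate_metagenome(small_cfg(3))
  euk <- gene_set(sim$truth$calls[sim$truth$calls$category == "eukaryote", ])
  for (i in seq_len(n_calls(euk))) {
    call <- euk$calls[i, ]
    ctg_seq <- sim$contigs$seq[sim$contigs$id == call$contig_id]
    ex <- call$exons[[1]]
    # introns are the gaps between consecutive exons, read on the gene strand
    if (nrow(ex) > 1) {
      for (j in seq_len(nrow(ex) - 1)) {
        intron <- substr(ctg_seq, ex[j, 2] + 1, ex[j + 1, 1])
        if (call$strand == "-") intron <- revcomp(intron)
        expect_equal(substr(intron, 1, 2), "GT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      }
    }
    prot <- translate_cds(call, contig_set(call$contig_id, ctg_seq))
    expect_equal(substr(prot, 1, 1), "M")
    expect_false(grepl("\\*", prot))
  }
})

test_that("planted genes never overlap on a contig", {
  sim <- simulate_metagenome(small_cfg(5))
  by_ctg <- split(sim$truth$calls, sim$truth$calls$contig_id)
  for (df in by_ctg) {
    df <- df[order(df$start), ]
    if (nrow(df) > 1) expect_true(all(df$start[-1] >= df$end[-nrow(df)]))
  }
})

test_that("infeasible packing raises an error", {
  cfg <- sim_config(n_contigs = 1, contig_len_range = c(2000, 2000),
                    n_prok_genes = 20, n_euk_genes = 0, n_viral_genes = 0,
                    prok_len_range = c(900, 900), seed = 1)
  expect_error(simulate_metagenome(cfg), "packing")
})

test_that("a lossless profile reproduces the truth and zero recall empties it", {
  sim <- simulate_metagenome(small_cfg(2))
  ident <- degrade_predictions(sim$truth,
                               mock_predictor_profile(seed = 4), sim$contigs)
  expect_equal(ident$calls$start, sim$truth$calls$start)
  expect_equal(ident$calls$end, sim$truth$calls$end)
  expect_equal(ident$calls$exons, sim$truth$calls$exons)
  none <- degrade_predictions(sim$truth,
    mock_predictor_profile(c(eukaryote = 0, prokaryote = 0, virus = 0), seed = 4))
  expect_equal(n_calls(none), 0L)
})

test_that("per-category recall thins categories independently", {
  sim <- simulate_metagenome(sim_config(n_contigs = 4,
                                        contig_len_range = c(80000, 100000),
                                        n_prok_genes = 80, n_euk_genes = 20,
                                        n_viral_genes = 0, seed = 11))
  mock <- degrade_predictions(sim$truth,
    mock_predictor_profile(c(eukaryote = 1, prokaryote = 0.25, virus = 0.25),
                           seed = 11))
  expect_equal(sum(mock$calls$category == "eukaryote"), 20L)
  kept_prok <- sum(mock$calls$category == "prokaryote")
  expect_true(kept_prok >= qbinom(5e-4, 80, 0.25) &&
              kept_prok <= qbinom(1 - 5e-4, 80, 0.25))
})

test_that("fragmentation splits kept genes into disjoint pieces within exons", {
  sim <- simulate_metagenome(small_cfg(6))
  frag <- degrade_predictions(sim$truth,
    mock_predictor_profile(fragmentation_prob = 1, seed = 6), sim$contigs)
  expect_gt(n_calls(frag), n_calls(sim$truth))
  base_id <- sub("\\.f\\d+$", "", frag$calls$gene_id)
  pieces <- split(seq_len(n_calls(frag)), base_id)
  truth_ids <- sim$truth$calls$gene_id
  for (id in names(pieces)) {
    idx <- pieces[[id]]
    t_ex <- sim$truth$calls$exons[[match(id, truth_ids)]]
    spans <- cbind(frag$calls$start[idx], frag$calls$end[idx])
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
    for (k in idx) {
      ex <- frag$calls$exons[[k]]
      for (e in seq_len(nrow(ex)))   # each piece lies inside some truth exon
        expect_true(any(t_ex[, 1] <= ex[e, 1] & ex[e, 2] <= t_ex[, 2]))
    }
  }
  # coding content is conserved by splitting
  expect_equal(sum(coding_lengths(frag)), sum(coding_lengths(sim$truth)))
})

test_that("boundary jitter stays within bounds and inside the contig", {
  sim <- simulate_metagenome(small_cfg(8))
  jit <- degrade_predictions(sim$truth,
    mock_predictor_profile(boundary_jitter_nt = 9, seed = 8), sim$contigs)
  lens <- contig_lengths(sim$contigs)
  expect_equal(n_calls(jit), n_calls(sim$truth))
  expect_true(all(abs(jit$calls$start - sim$truth$calls$start) <= 9))
  expect_true(all(abs(jit$calls$end - sim$truth$calls$end) <= 9))
  expect_true(all(jit$calls$start >= 0))
  expect_true(all(jit$calls$end <= lens[jit$calls$contig_id]))
})

test_that("degradation is deterministic under the profile seed", {
  sim <- simulate_metagenome(small_cfg(9))
  p <- mock_predictor_profile(c(eukaryote = 0.9, prokaryote = 0.3, virus = 0.5),
                              fragmentation_prob = 0.4, boundary_jitter_nt = 5,
                              seed = 21)
  a <- degrade_predictions(sim$truth, p, sim$contigs)
  b <- degrade_predictions(sim$truth, p, sim$contigs)
  expect_identical(a$calls, b$calls)
})

test_that("fixture emission round-trips through every dialect", {
  gs <- random_gene_set(5, seed = 90)
  hdr <- parse_metaeuk_headers(text = emit_fixture_files(gs, "metaeuk_headers"))
  gff <- parse_metaeuk_gff(text = emit_fixture_files(gs, "metaeuk_gff"))
  for (col in c("gene_id", "contig_id", "start", "end", "strand", "exons")) {
    expect_equal(hdr$calls[[col]], gs$calls[[col]])
    expect_equal(gff$calls[[col]], gs$calls[[col]])
  }
  expect_identical(emit_fixture_files(gene_set(), "metaeuk_headers"), "")

  single <- gene_set(gene_calls(c("a", "b"), "c", c(0, 500), c(300, 800)))
  back <- parse_prokaryotic_gff(text = emit_fixture_files(single, "prokaryotic_gff"))
  expect_equal(back$calls$start, single$calls$start)
  multi <- gene_set(gene_calls("m", "c", 0, 100,
                               exons = list(cbind(c(0, 60), c(30, 100)))))
  expect_error(emit_fixture_files(multi, "prokaryotic_gff"), "multi-exon")
})
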