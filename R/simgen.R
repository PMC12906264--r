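STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Configuration for the synthetic-metagenome generator
#'
#' The defaults emulate a mixed community assembly at test-bench scale: 20
#' contigs of 20-100 kb carrying 200 single-CDS prokaryote-like genes, 60
#' multi-exon intron-containing eukaryote-like genes and 20 viral genes
#' (generated like prokaryotic ones, labeled separately), embedded in i.i.d.
#' intergenic DNA at the stated GC. Eukaryotic exon/intron dimensions follow
#' compact microbial eukaryote genomes (few introns, short introns, exons of
#' a few hundred bp).
#'
#' @param n_contigs number of contigs.
#' @param contig_len_range min/max contig length (nt).
#' @param n_prok_genes,n_euk_genes,n_viral_genes planted gene counts.
#' @param prok_len_range min/max prokaryotic gene length (nt, multiples of 3).
#' @param euk_exon_count_range min/max exons per eukaryotic gene.
#' @param euk_exon_len_range,intron_len_range min/max exon and intron lengths
#'   (nt; introns need `>= 4` for the GT...AG dinucleotides).
#' @param gc intergenic GC content in `(0, 1)`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 20L, contig_len_range = c(20000L, 100000L),
                       n_prok_genes = 200L, n_euk_genes = 60L,
                       n_viral_genes = 20L, prok_len_range = c(300L, 1800L),
                       euk_exon_count_range = c(2L, 4L),
                       euk_exon_len_range = c(250L, 600L),
                       intron_len_range = c(60L, 150L), gc = 0.5, seed = 1L) {
  chk_range <- function(r, nm, lo = 1L) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < lo)
      stop(sprintf("invalid %s", nm), call. = FALSE)
    as.integer(r)
  }
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_len_range = chk_range(contig_len_range, "contig_len_range"),
              n_prok_genes = as.integer(n_prok_genes),
              n_euk_genes = as.integer(n_euk_genes),
              n_viral_genes = as.integer(n_viral_genes),
              prok_len_range = chk_range(prok_len_range, "prok_len_range", 6L),
              euk_exon_count_range = chk_range(euk_exon_count_range, "euk_exon_count_range"),
              euk_exon_len_range = chk_range(euk_exon_len_range, "euk_exon_len_range", 9L),
              intron_len_range = chk_range(intron_len_range, "intron_len_range", 4L),
              gc = as.numeric(gc), seed = as.integer(seed))
  if (cfg$n_contigs < 1L) stop("n_contigs must be >= 1", call. = FALSE)
  if (cfg$gc <= 0 || cfg$gc >= 1) stop("gc must lie in (0, 1)", call. = FALSE)
  if (any(c(cfg$n_prok_genes, cfg$n_euk_genes, cfg$n_viral_genes) < 0L))
    stop("gene counts must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sample_int_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n) else sample(seq.int(r[1], r[2]), n, replace = TRUE)
}

# a CDS of len nt: start codon + non-stop codons + stop codon
random_cds <- function(len, start_codon = "ATG") {
  ncod <- len %/% 3L
  mid <- sample(setdiff(all_codons(), STOP_CODONS), ncod - 2L, replace = TRUE)
  paste0(start_codon, paste(mid, collapse = ""), sample(STOP_CODONS, 1L))
}

# Build a eukaryote-like gene: exons carrying a valid CDS, introns GT...AG.
# Returns list(seq, rel_exons) with exon intervals relative to the sense
# sequence (half-open).
random_euk_gene <- function(cfg) {
  k <- sample_int_range(cfg$euk_exon_count_range)
  ex_len <- sample_int_range(cfg$euk_exon_len_range, k)
  rem <- sum(ex_len) %% 3L
  ex_len[k] <- ex_len[k] - rem
  cds <- random_cds(sum(ex_len))
  introns <- if (k > 1L) {
    vapply(sample_int_range(cfg$intron_len_range, k - 1L), function(l) {
      paste0("GT", random_dna(l - 4L, cfg$gc), "AG")
    }, character(1))
  } else character(0)
  pieces <- character(0)
  rel <- matrix(0L, k, 2L)
  pos <- 0L
  cds_off <- 0L
  for (j in seq_len(k)) {
    piece <- substr(cds, cds_off + 1L, cds_off + ex_len[j])
    cds_off <- cds_off + ex_len[j]
    rel[j, ] <- c(pos, pos + ex_len[j])
    pos <- pos + ex_len[j]
    pieces <- c(pieces, piece)
    if (j < k) {
      pieces <- c(pieces, introns[j])
      pos <- pos + nchar(introns[j])
    }
  }
  list(seq = paste(pieces, collapse = ""), rel_exons = rel)
}

place_gene <- function(occupied, contig_lens, glen, max_attempts = 500L) {
  probs <- contig_lens / sum(contig_lens)
  for (a in seq_len(max_attempts)) {
    ci <- sample.int(length(contig_lens), 1L, prob = probs)
    if (contig_lens[ci] < glen) next
    s <- sample.int(contig_lens[ci] - glen + 1L, 1L) - 1L
    e <- s + glen
    occ <- occupied[[ci]]
    if (is.null(occ) || !any(s < occ[, 2L] & occ[, 1L] < e)) {
      return(list(ci = ci, s = s, e = e))
    }
  }
  stop("infeasible packing: planted genes do not fit their contigs", call. = FALSE)
}

#' Simulate a synthetic metagenome with ground-truth genes
#'
#' Generates contigs of i.i.d. composition at the configured GC and plants
#' non-overlapping genes on random strands: prokaryote/virus genes are
#' single-exon ORFs (start codon, no internal in-frame stop, terminal stop);
#' eukaryote genes carry their CDS on 1..k exons separated by GT...AG introns.
#' The truth annotation records exact forward-strand coordinates, strand and
#' category for every planted gene. Fully deterministic under the seed, with
#' one random stream for contig composition and an independent one for gene
#' content and placement.
#'
#' @param config a [sim_config()].
#' @return A list with `contigs` (a [contig_set()]) and `truth`
#'   (a [gene_set()]).
#' @export
simulate_metagenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- sample_int_range(config$contig_len_range, config$n_contigs)
  seqs <- vapply(lens, random_dna, character(1), gc = config$gc)
  ids <- sprintf("ctg%03d", seq_len(config$n_contigs))

  set.seed(derive_seed(config$seed, 1L))
  occupied <- vector("list", config$n_contigs)
  spec <- rbind(
    if (config$n_euk_genes) data.frame(cat = "eukaryote", i = seq_len(config$n_euk_genes)),
    if (config$n_prok_genes) data.frame(cat = "prokaryote", i = seq_len(config$n_prok_genes)),
    if (config$n_viral_genes) data.frame(cat = "virus", i = seq_len(config$n_viral_genes)))
  calls <- vector("list", if (is.null(spec)) 0L else nrow(spec))
  for (g in seq_along(calls)) {
    cat <- spec$cat[g]
    if (cat == "eukaryote") {
      gene <- random_euk_gene(config)
      gid <- sprintf("euk_%03d", spec$i[g])
    } else {
      glen <- 3L * sample_int_range(config$prok_len_range %/% 3L)
      gene <- list(seq = random_cds(glen), rel_exons = cbind(0L, glen))
      gid <- sprintf("%s_%03d", if (cat == "virus") "vir" else "prok", spec$i[g])
    }
    glen <- nchar(gene$seq)
    strand <- sample(c("+", "-"), 1L)
    loc <- place_gene(occupied, lens, glen)
    occupied[[loc$ci]] <- rbind(occupied[[loc$ci]], c(loc$s, loc$e))
    insert <- if (strand == "-") revcomp(gene$seq) else gene$seq
    substr(seqs[loc$ci], loc$s + 1L, loc$e) <- insert
    rel <- gene$rel_exons
    if (strand == "-") {
      rel <- cbind(glen - rel[, 2L], glen - rel[, 1L])
      rel <- rel[order(rel[, 1L]), , drop = FALSE]
    }
    calls[[g]] <- gene_calls(gid, ids[loc$ci], loc$s, loc$e, strand = strand,
                             exons = list(rel + loc$s),
                             source_pass = "first_pass", category = cat)
  }
  truth <- gene_set(if (length(calls)) do.call(rbind, calls) else empty_calls(),
                    name = "truth",
                    provenance = list(generator = "crossmask simulator",
                                      seed = config$seed))
  list(contigs = contig_set(ids, seqs), truth = truth)
}

#' Mock-predictor degradation profile
#'
#' Emulates the behavior of a first-pass homology predictor on a truth
#' annotation: per-category recall (a eukaryote-oriented first pass recovers
#' most eukaryotic genes but only a minority of prokaryotic ones),
#' probabilistic fragmentation of recovered genes into 2-3 pieces, and
#' boundary jitter.
#'
#' @param recall_by_category named vector with entries `eukaryote`,
#'   `prokaryote`, `virus`, each in `[0, 1]`.
#' @param fragmentation_prob chance a recovered gene is split into 2-3
#'   fragments.
#' @param boundary_jitter_nt maximum boundary displacement (nt).
#' @param seed integer seed.
#' @return An object of class `mock_predictor_profile`.
#' @export
mock_predictor_profile <- function(recall_by_category = c(eukaryote = 1, prokaryote = 1, virus = 1),
                                   fragmentation_prob = 0,
                                   boundary_jitter_nt = 0L, seed = 1L) {
  need <- c("eukaryote", "prokaryote", "virus")
  if (!all(need %in% names(recall_by_category)))
    stop("recall_by_category must name eukaryote, prokaryote and virus", call. = FALSE)
  r <- as.numeric(recall_by_category[need])
  if (any(r < 0 | r > 1) || fragmentation_prob < 0 || fragmentation_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(recall_by_category = stats::setNames(r, need),
                 fragmentation_prob = as.numeric(fragmentation_prob),
                 boundary_jitter_nt = as.integer(boundary_jitter_nt),
                 seed = as.integer(seed)),
            class = "mock_predictor_profile")
}

# split one call's coding space into p contiguous chunks mapped back to
# genomic exon intervals
fragment_call <- function(row, p) {
  ex <- row$exons[[1]]
  widths <- ex[, 2L] - ex[, 1L]
  cl <- sum(widths)
  if (cl < 60L * p) return(list(row))         # too short to split sensibly
  cuts <- sort(sample(seq.int(30L, cl - 30L), p - 1L))
  bounds <- c(0L, cuts, cl)
  pieces <- lapply(seq_len(p), function(k) {
    c0 <- bounds[k]; c1 <- bounds[k + 1L]
    # walk the exon list in coding space
    out <- NULL
    off <- 0L
    for (j in seq_len(nrow(ex))) {
      a <- max(c0, off); b <- min(c1, off + widths[j])
      if (a < b) out <- rbind(out, c(ex[j, 1L] + (a - off), ex[j, 1L] + (b - off)))
      off <- off + widths[j]
    }
    out
  })
  lapply(seq_len(p), function(k) {
    nr <- row
    nr$gene_id <- paste0(row$gene_id, ".f", k)
    nr$start <- pieces[[k]][1L, 1L]
    nr$end <- pieces[[k]][nrow(pieces[[k]]), 2L]
    nr$exons <- I(list(pieces[[k]]))
    nr
  })
}

#' Degrade a truth annotation into mock predictions
#'
#' Each truth call is kept independently with its category's recall; kept
#' calls are optionally split into 2-3 non-overlapping fragments within the
#' original exons, and boundaries are jittered by at most
#' `boundary_jitter_nt` without crossing contig bounds. Deterministic under
#' the profile's seed.
#'
#' @param truth a [gene_set()].
#' @param profile a [mock_predictor_profile()].
#' @param contigs optional [contig_set()] used to clamp jittered boundaries;
#'   without it only the lower bound 0 is enforced.
#' @return A [gene_set()] with `source_pass = "first_pass"` and truth
#'   categories preserved.
#' @export
degrade_predictions <- function(truth, profile, contigs = NULL) {
  stopifnot(inherits(profile, "mock_predictor_profile"))
  set.seed(profile$seed)
  calls <- truth$calls
  rec <- profile$recall_by_category[calls$category]
  rec[is.na(rec)] <- 1       # categories outside the profile are always kept
  keep <- stats::runif(nrow(calls)) < rec
  calls <- calls[keep, , drop = FALSE]
  out <- list()
  lens <- if (!is.null(contigs)) contig_lengths(contigs) else NULL
  j <- profile$boundary_jitter_nt
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, , drop = FALSE]
    rows <- if (stats::runif(1) < profile$fragmentation_prob) {
      fragment_call(row, sample(2:3, 1L))
    } else list(row)
    for (r in rows) {
      if (j > 0L) {
        upper <- if (!is.null(lens)) lens[[r$contig_id]] else .Machine$integer.max
        ns <- max(0L, r$start + sample.int(2L * j + 1L, 1L) - j - 1L)
        ne <- as.integer(min(upper, r$end + sample.int(2L * j + 1L, 1L) - j - 1L))
        if (ns < ne) {
          ex <- r$exons[[1]]
          ex[1L, 1L] <- min(ns, ex[1L, 2L] - 1L)
          ex[nrow(ex), 2L] <- max(ne, ex[nrow(ex), 1L] + 1L)
          r$start <- ex[1L, 1L]
          r$end <- ex[nrow(ex), 2L]
          r$exons <- I(list(ex))
        }
      }
      r$source_pass <- "first_pass"
      out[[length(out) + 1L]] <- r
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty_calls()
  gene_set(calls, name = "mock_first_pass",
           provenance = list(profile = unclass(profile), n = nrow(calls)))
}

#' Emit fixture files in predictor dialects
#'
#' Writes a gene set in one of the dialects the parsers consume, so that
#' every parser can be exercised against files whose ground truth is known:
#' `metaeuk_headers` (pipe-delimited FASTA headers under the given
#' [header_dialect()]), `metaeuk_gff`, or `prokaryotic_gff` (single-exon
#' calls only). Parsing an emitted file recovers contig, span, strand and
#' exons exactly.
#'
#' @param gene_set a [gene_set()].
#' @param format target dialect.
#' @param dialect a [header_dialect()] (headers format only).
#' @param file optional output path.
#' @return Invisibly, the emitted text.
#' @export
emit_fixture_files <- function(gene_set,
                               format = c("metaeuk_headers", "metaeuk_gff",
                                          "prokaryotic_gff"),
                               dialect = header_dialect(), file = NULL) {
  format <- match.arg(format)
  calls <- gene_set$calls
  if (format == "metaeuk_gff")
    return(write_gff(gene_set, file, extra_attributes = FALSE))
  if (format == "prokaryotic_gff") {
    multi <- vapply(calls$exons, nrow, integer(1)) > 1L
    if (any(multi))
      stop(sprintf("multi-exon call '%s' cannot be emitted as prokaryotic GFF",
                   calls$gene_id[multi][1]), call. = FALSE)
    return(write_gff(gene_set, file, extra_attributes = FALSE))
  }
  from_halfopen <- function(s, e) {
    if (dialect$coordinate_base == "0-inclusive") c(s, e - 1L) else c(s + 1L, e)
  }
  fo <- dialect$field_order
  lines <- unlist(lapply(seq_len(nrow(calls)), function(i) {
    ex <- calls$exons[[i]]
    span <- from_halfopen(calls$start[i], calls$end[i])
    blocks <- paste(apply(ex, 1L, function(r) {
      paste(from_halfopen(r[1L], r[2L]), collapse = "-")
    }), collapse = ":")
    f <- character(length(fo))
    f[fo[["target"]]] <- calls$gene_id[i]
    f[fo[["contig"]]] <- calls$contig_id[i]
    f[fo[["strand"]]] <- calls$strand[i]
    f[fo[["bitscore"]]] <- format(if (is.na(calls$score[i])) 0 else calls$score[i])
    f[fo[["evalue"]]] <- format(if (is.na(calls$evalue[i])) 0 else calls$evalue[i])
    f[fo[["exon_count"]]] <- nrow(ex)
    f[fo[["low_coord"]]] <- span[1L]
    f[fo[["high_coord"]]] <- span[2L]
    f[fo[["exon_blocks"]]] <- blocks
    c(paste0(">", paste(f, collapse = dialect$field_separator)), "N")
  }), use.names = FALSE)
  emit_lines(lines %||% character(0), file)
}
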