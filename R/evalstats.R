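#' Per-group gene count and length summaries
#'
#' Counts and coding-length statistics (mean, lower-middle median, total) per
#' category, per source pass, or for the whole set. Gene length is coding
#' length: the sum of exon widths.
#'
#' @param gene_set a [gene_set()].
#' @param group_by `"none"` (one row labeled `"all"`), `"category"` or
#'   `"source_pass"`.
#' @return A data frame with columns `group`, `n_genes`, `mean_len_nt`,
#'   `median_len_nt`, `total_len_nt`.
#' @export
gene_summary <- function(gene_set, group_by = c("none", "category", "source_pass")) {
  group_by <- match.arg(group_by)
  lens <- unname(coding_lengths(gene_set))
  groups <- switch(group_by,
                   none = rep("all", length(lens)),
                   category = gene_set$calls$category,
                   source_pass = gene_set$calls$source_pass)
  labels <- if (group_by == "none") "all" else sort(unique(groups))
  if (!length(lens) && group_by == "none") labels <- "all"
  rows <- lapply(labels, function(g) {
    x <- sort(lens[groups == g])
    n <- length(x)
    data.frame(group = g, n_genes = n,
               mean_len_nt = if (n) sum(x) / n else NA_real_,
               median_len_nt = if (n) as.numeric(x[floor((n + 1) / 2)]) else NA_real_,
               total_len_nt = if (n) sum(x) else 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

exon_table <- function(gene_set) {
  calls <- gene_set$calls
  nex <- vapply(calls$exons, nrow, integer(1))
  data.frame(call = rep(seq_len(nrow(calls)), nex),
             contig = rep(calls$contig_id, nex),
             strand = rep(calls$strand, nex),
             s = unlist(lapply(calls$exons, function(m) m[, 1L])),
             e = unlist(lapply(calls$exons, function(m) m[, 2L])),
             stringsAsFactors = FALSE)
}

#' Compare predictions with a reference annotation
#'
#' A truth gene is *detected* when the union of same-contig (and, by default,
#' same-strand) predicted exon intervals covers at least `overlap_frac` of its
#' coding length. *Fragmentation* is the mean number of distinct predicted
#' calls with at least one coding-base overlap per detected truth gene; values
#' above 1 indicate genes split into pieces. `mean_len_ratio` is the mean
#' predicted coding length over the mean truth coding length.
#'
#' @param pred,truth [gene_set()] objects on a shared contig namespace.
#' @param overlap_frac detection threshold in `(0, 1]` (default 0.5).
#' @param strand_aware require predictions on the truth gene's strand
#'   (default `TRUE`).
#' @return An object of class `evaluation_report` with fields `n_truth`,
#'   `n_pred`, `detected`, `sensitivity`, `fragmentation`, `mean_len_ratio`.
#' @export
compare_to_truth <- function(pred, truth, overlap_frac = 0.5, strand_aware = TRUE) {
  if (!is.numeric(overlap_frac) || length(overlap_frac) != 1L ||
      overlap_frac <= 0 || overlap_frac > 1)
    stop("overlap_frac must lie in (0, 1]", call. = FALSE)
  pt <- exon_table(pred)
  key <- function(contig, strand) if (strand_aware) paste0(contig, "\r", strand) else contig
  pt$key <- key(pt$contig, pt$strand)
  pred_by_key <- split(pt, pt$key)
  tl <- unname(coding_lengths(truth))
  n_truth <- n_calls(truth)
  detected <- logical(n_truth)
  frags <- integer(n_truth)
  for (i in seq_len(n_truth)) {
    k <- key(truth$calls$contig_id[i], truth$calls$strand[i])
    p <- pred_by_key[[k]]
    if (is.null(p) || !nrow(p)) next
    tex <- truth$calls$exons[[i]]
    t_ir <- IRanges::IRanges(start = tex[, 1L] + 1L, end = tex[, 2L])
    p_ir <- IRanges::IRanges(start = p$s + 1L, end = p$e)
    cov <- sum(IRanges::width(IRanges::intersect(IRanges::reduce(p_ir), t_ir)))
    detected[i] <- cov >= overlap_frac * tl[i]
    hits <- IRanges::findOverlaps(p_ir, t_ir)
    frags[i] <- length(unique(p$call[S4Vectors::queryHits(hits)]))
  }
  pl <- unname(coding_lengths(pred))
  structure(list(
    n_truth = n_truth, n_pred = n_calls(pred), detected = sum(detected),
    sensitivity = if (n_truth) sum(detected) / n_truth else NA_real_,
    fragmentation = if (any(detected)) mean(frags[detected]) else NA_real_,
    mean_len_ratio = if (length(pl) && length(tl)) mean(pl) / mean(tl) else NA_real_,
    overlap_frac = overlap_frac, strand_aware = strand_aware),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d/%d truth genes detected (sensitivity %.3f)\n",
              x$detected, x$n_truth, x$sensitivity))
  cat(sprintf("  predictions: %d; fragmentation %.2f; mean length ratio %.3f\n",
              x$n_pred, x$fragmentation, x$mean_len_ratio))
  invisible(x)
}

codon_aa <- function(codons, table = 11L) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # ambiguous codon
  aa
}

#' Translate a gene call to protein
#'
#' Concatenates the call's exons in ascending order, reverse-complements for
#' minus-strand calls, and translates under the bacterial/archaeal code
#' (table 11; alternative start codons GTG/TTG read as M). The terminal stop
#' is removed; an internal stop is an error unless `partial = TRUE`, in which
#' case it is emitted as `*`.
#'
#' @param call a one-row calls data frame (one row of `gene_set$calls`).
#' @param contig the matching one-row [contig_set()].
#' @param table genetic code id (11, or 1 for the standard code's ATG-only
#'   initiation).
#' @param partial tolerate internal stops and non-multiple-of-3 tails.
#' @return A protein string.
#' @examples
#' ctg <- contig_set("c", "ATGAAATAA")
#' translate_cds(gene_calls("g", "c", 0, 9), ctg)
#' @export
translate_cds <- function(call, contig, table = 11L, partial = FALSE) {
  stopifnot(nrow(call) == 1L, inherits(contig, "contig_set"), nrow(contig) == 1L)
  if (call$contig_id != contig$id)
    stop(sprintf("call '%s' is on contig '%s', not '%s'", call$gene_id,
                 call$contig_id, contig$id), call. = FALSE)
  ex <- call$exons[[1]]
  if (any(ex[, 2L] > nchar(contig$seq)))
    stop(sprintf("call '%s' extends past the end of contig '%s'", call$gene_id, contig$id),
         call. = FALSE)
  cds <- paste0(substring(contig$seq, ex[, 1L] + 1L, ex[, 2L]), collapse = "")
  if (call$strand == "-") cds <- revcomp(cds)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (!partial)
      stop(sprintf("coding length of '%s' (%d) is not a multiple of 3", call$gene_id, n),
           call. = FALSE)
    cds <- substr(cds, 1L, n - n %% 3L)
    n <- nchar(cds)
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- codon_aa(codons, table)
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  internal <- which(aa == "*")
  if (length(internal) && !partial)
    stop(sprintf("internal stop codon at codon %d of '%s'", internal[1], call$gene_id),
         call. = FALSE)
  start_set <- if (table == 11L) c("ATG", "GTG", "TTG") else "ATG"
  if (length(aa) && codons[1] %in% start_set) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Translate every call of a gene set
#'
#' @param gene_set a [gene_set()].
#' @param contigs a [contig_set()] covering every call's contig.
#' @inheritParams translate_cds
#' @return Named character vector of protein strings (by `gene_id`).
#' @export
translate_gene_set <- function(gene_set, contigs, table = 11L, partial = FALSE) {
  idx <- match(gene_set$calls$contig_id, contigs$id)
  if (anyNA(idx))
    stop(sprintf("call references absent contig '%s'",
                 gene_set$calls$contig_id[is.na(idx)][1]), call. = FALSE)
  out <- vapply(seq_len(n_calls(gene_set)), function(i) {
    translate_cds(gene_set$calls[i, , drop = FALSE],
                  contigs[idx[i], , drop = FALSE], table = table, partial = partial)
  }, character(1))
  stats::setNames(out, gene_set$calls$gene_id)
}

#' Write protein sequences as FASTA
#'
#' @param proteins named character vector (e.g. from [translate_gene_set()]).
#' @param file optional output path.
#' @param wrap line width.
#' @return Invisibly, the FASTA text.
#' @export
write_proteins <- function(proteins, file = NULL, wrap = 60L) {
  lines <- unlist(lapply(seq_along(proteins), function(i) {
    s <- proteins[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = wrap)
    c(paste0(">", names(proteins)[i]),
      substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
  }), use.names = FALSE)
  emit_lines(lines %||% character(0), file)
}

#' Linear-gap alignment scoring
#'
#' @param match,mismatch,gap real scores; `match > mismatch`, `gap < 0`
#'   (applied per gap column, i.e. linear gaps).
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  if (!(match > mismatch)) stop("match score must exceed mismatch score", call. = FALSE)
  if (!(gap < 0)) stop("gap score must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_scoring")
}

#' Global-alignment percent identity
#'
#' Needleman-Wunsch global alignment under linear gap scoring; among
#' maximum-score alignments the one with the fewest gap columns is used.
#' Identity is `100 * matches / alignment columns` (gap columns included in
#' the denominator). Symmetric, and 100 for identical sequences.
#'
#' @param a,b non-empty protein (or DNA) strings.
#' @param scoring an [align_scoring()].
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("MKV", "MKL")
#' @export
percent_identity <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  gp <- scoring$gap
  S <- matrix(0, n + 1L, m + 1L)
  G <- matrix(0L, n + 1L, m + 1L)
  S[1L, ] <- gp * (0:m); G[1L, ] <- 0:m
  S[, 1L] <- gp * (0:n); G[, 1L] <- 0:n
  for (i in seq_len(n)) {
    sub <- ifelse(A[i] == B, scoring$match, scoring$mismatch)
    for (j in seq_len(m)) {
      cs <- c(S[i, j] + sub[j], S[i, j + 1L] + gp, S[i + 1L, j] + gp)
      cg <- c(G[i, j], G[i, j + 1L] + 1L, G[i + 1L, j] + 1L)
      best <- max(cs)
      S[i + 1L, j + 1L] <- best
      G[i + 1L, j + 1L] <- min(cg[cs == best])
    }
  }
  score <- S[n + 1L, m + 1L]
  g <- G[n + 1L, m + 1L]
  # matches are determined by (score, gap columns): with m+x = (n+m-g)/2,
  # score = M*match + x*mismatch + g*gap  =>  solve for match count M
  matches <- (score - scoring$mismatch * (n + m - g) / 2 - g * gp) /
    (scoring$match - scoring$mismatch)
  cols <- (n + m + g) / 2
  100 * matches / cols
}
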