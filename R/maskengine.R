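#' Masking policy
#'
#' Controls how predicted gene regions are turned into masked intervals.
#' `mode = "span"` (the default) masks each call's whole genomic span, introns
#' included; `mode = "exons"` masks only the exon intervals. Intervals whose
#' gap is at most `merge_gap` are fused before substitution (touching
#' intervals always fuse).
#'
#' @param mode `"span"` or `"exons"`.
#' @param mask_char single masking character (default `"N"`).
#' @param merge_gap non-negative integer fusion distance.
#' @return An object of class `mask_policy`.
#' @export
mask_policy <- function(mode = c("span", "exons"), mask_char = "N", merge_gap = 0L) {
  mode <- match.arg(mode)
  if (nchar(mask_char) != 1L || !mask_char %in% iupac_chars())
    stop("mask_char must be a single IUPAC DNA character", call. = FALSE)
  merge_gap <- as.integer(merge_gap)
  if (is.na(merge_gap) || merge_gap < 0L)
    stop("merge_gap must be a non-negative integer", call. = FALSE)
  structure(list(mode = mode, mask_char = mask_char, merge_gap = merge_gap),
            class = "mask_policy")
}

#' Collect maskable intervals from gene calls
#'
#' @param gene_set a [gene_set()].
#' @param policy a [mask_policy()]; `mode` decides span- vs exon-level
#'   intervals.
#' @return A named list (by contig id) of two-column half-open interval
#'   matrices, unmerged and in call order.
#' @export
intervals_from_calls <- function(gene_set, policy = mask_policy()) {
  calls <- gene_set$calls
  if (!nrow(calls)) return(stats::setNames(list(), character(0)))
  per_call <- if (policy$mode == "span") {
    lapply(seq_len(nrow(calls)), function(i) cbind(calls$start[i], calls$end[i]))
  } else {
    calls$exons
  }
  ids <- rep(calls$contig_id, vapply(per_call, nrow, integer(1)))
  mat <- do.call(rbind, per_call)
  lapply(split(seq_len(nrow(mat)), factor(ids, levels = unique(calls$contig_id))),
         function(idx) mat[idx, , drop = FALSE])
}

as_interval_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
    return(matrix(integer(0), ncol = 2L))
  m <- matrix(as.integer(x), ncol = 2L)
  if (any(is.na(m)) || any(m[, 1L] < 0L) || any(m[, 1L] >= m[, 2L]))
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  m
}

#' Merge half-open intervals into a disjoint sorted union
#'
#' Computes the interval union (via `IRanges::reduce`), fusing intervals whose
#' gap is `<= merge_gap`. The result is sorted ascending, pairwise disjoint
#' with gaps strictly greater than `merge_gap`, and the operation is
#' idempotent.
#'
#' @param intervals two-column matrix of half-open intervals (any order,
#'   overlaps/duplicates allowed).
#' @param merge_gap non-negative fusion distance (0 fuses touching intervals).
#' @return Two-column integer matrix of merged intervals.
#' @examples
#' merge_intervals(rbind(c(5, 15), c(0, 10)))
#' @export
merge_intervals <- function(intervals, merge_gap = 0L) {
  m <- as_interval_matrix(intervals)
  if (!nrow(m)) return(m)
  r <- IRanges::reduce(IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]),
                       min.gapwidth = as.integer(merge_gap) + 1L)
  cbind(IRanges::start(r) - 1L, IRanges::end(r))
}

mask_seq <- function(seq, intervals, mask_char = "N") {
  m <- as_interval_matrix(intervals)
  for (k in seq_len(nrow(m))) {
    substr(seq, m[k, 1L] + 1L, m[k, 2L]) <- strrep(mask_char, m[k, 2L] - m[k, 1L])
  }
  list(seq = seq, masked_bases = if (nrow(m)) sum(m[, 2L] - m[, 1L]) else 0L)
}

#' Hard-mask intervals on one contig
#'
#' Replaces every position inside the given disjoint sorted intervals with
#' `mask_char`, leaving all other positions byte-identical. Length is always
#' conserved and the operation is idempotent.
#'
#' @param contig a one-row [contig_set()].
#' @param intervals disjoint, sorted two-column half-open interval matrix.
#' @param mask_char single masking character.
#' @return A list with elements `contig` (masked one-row [contig_set()]) and
#'   `masked_bases`.
#' @examples
#' apply_mask(contig_set("a", "ACGTACGTAC"), cbind(2, 5))
#' @export
apply_mask <- function(contig, intervals, mask_char = "N") {
  stopifnot(inherits(contig, "contig_set"), nrow(contig) == 1L)
  m <- as_interval_matrix(intervals)
  L <- nchar(contig$seq)
  if (nrow(m)) {
    if (any(m[, 2L] > L))
      stop(sprintf("interval [%d, %d) out of bounds on contig '%s' (length %d)",
                   m[which(m[, 2L] > L)[1], 1L], m[which(m[, 2L] > L)[1], 2L],
                   contig$id, L), call. = FALSE)
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L] | diff(m[, 1L]) <= 0L))
      stop("intervals must be sorted and disjoint; use merge_intervals() first", call. = FALSE)
  }
  res <- mask_seq(contig$seq, m, mask_char)
  contig$seq <- res$seq
  list(contig = contig, masked_bases = res$masked_bases)
}

#' Hard-mask predicted gene regions across a metagenome
#'
#' The core masking stage: per contig, the gene calls' intervals (span- or
#' exon-level per the policy) are merged into a disjoint union and the covered
#' bases are replaced with the mask character. Contigs without calls pass
#' through byte-identical. Only one contig's sequence is transformed at a
#' time, so memory stays proportional to the largest contig.
#'
#' @param contigs a [contig_set()].
#' @param gene_set the predictions whose regions are to be masked.
#' @param policy a [mask_policy()].
#' @param lenient when `FALSE` (default) a call referencing an absent contig
#'   is an error; when `TRUE` it is skipped with a counted warning.
#' @return A list with `contigs` (masked [contig_set()]) and `report`
#'   (a `mask_report`: per-contig masked-base/interval accounting plus
#'   totals and the overall masked fraction).
#' @export
mask_metagenome <- function(contigs, gene_set, policy = mask_policy(),
                            lenient = FALSE) {
  iv <- intervals_from_calls(gene_set, policy)
  missing <- setdiff(names(iv), contigs$id)
  n_skipped <- 0L
  if (length(missing)) {
    if (!lenient)
      stop(sprintf("gene call references absent contig '%s'", missing[1]), call. = FALSE)
    n_skipped <- sum(vapply(iv[missing], nrow, integer(1)))
    warning(sprintf("skipped %d interval(s) on %d absent contig(s)",
                    n_skipped, length(missing)), call. = FALSE)
    iv <- iv[setdiff(names(iv), missing)]
  }
  masked_bases <- integer(nrow(contigs))
  n_intervals <- integer(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    if (is.null(iv[[id]])) next
    merged <- merge_intervals(iv[[id]], policy$merge_gap)
    res <- apply_mask(contigs[i, , drop = FALSE], merged, policy$mask_char)
    contigs$seq[i] <- res$contig$seq
    masked_bases[i] <- res$masked_bases
    n_intervals[i] <- nrow(merged)
  }
  lens <- nchar(contigs$seq)
  report <- structure(list(
    per_contig = data.frame(contig = contigs$id, length = lens,
                            masked_bases = masked_bases,
                            n_intervals = n_intervals,
                            fraction = ifelse(lens > 0L, masked_bases / lens, 0),
                            stringsAsFactors = FALSE),
    total_masked = sum(masked_bases),
    total_bases = sum(lens),
    fraction_masked = if (sum(lens) > 0L) sum(masked_bases) / sum(lens) else 0,
    n_skipped_intervals = n_skipped),
    class = "mask_report")
  list(contigs = contigs, report = report)
}

#' @export
print.mask_report <- function(x, ...) {
  cat(sprintf("<mask_report> %s / %s bases masked (%.2f%%) across %d contig(s)\n",
              format(x$total_masked, big.mark = ","),
              format(x$total_bases, big.mark = ","),
              100 * x$fraction_masked, nrow(x$per_contig)))
  invisible(x)
}

#' Write a per-contig mask report as TSV
#'
#' Columns: contig, length, masked_bases, n_intervals, fraction.
#'
#' @param report a `mask_report` from [mask_metagenome()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_mask_report <- function(report, file) {
  utils::write.table(report$per_contig, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
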