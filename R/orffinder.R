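#' Parameters for the built-in ORF caller
#'
#' The built-in caller is a deliberately naive six-frame longest-ORF scan
#' that stands in for an external prokaryotic predictor when none is
#' configured. The conservative default minimum length (300 nt = 100 codons)
#' makes it under-call rather than over-call relative to real predictors.
#'
#' @param min_len_nt minimum ORF length in nucleotides, stop codon included;
#'   must be `>= 6` and a multiple of 3.
#' @param start_codons,stop_codons disjoint codon sets (bacterial table 11
#'   defaults).
#' @param both_strands scan the reverse strand as well.
#' @param allow_ambiguous when `FALSE` (default) a candidate ORF containing
#'   any non-ACGT character is disqualified; this is what keeps the second
#'   pass out of hard-masked regions.
#' @return An object of class `orf_params`.
#' @export
orf_params <- function(min_len_nt = 300L,
                       start_codons = c("ATG", "GTG", "TTG"),
                       stop_codons = c("TAA", "TAG", "TGA"),
                       both_strands = TRUE, allow_ambiguous = FALSE) {
  min_len_nt <- as.integer(min_len_nt)
  if (is.na(min_len_nt) || min_len_nt < 6L || min_len_nt %% 3L != 0L)
    stop("min_len_nt must be >= 6 and a multiple of 3", call. = FALSE)
  start_codons <- toupper(start_codons)
  stop_codons <- toupper(stop_codons)
  if (length(intersect(start_codons, stop_codons)))
    stop("start and stop codon sets must be disjoint", call. = FALSE)
  structure(list(min_len_nt = min_len_nt, start_codons = start_codons,
                 stop_codons = stop_codons, both_strands = isTRUE(both_strands),
                 allow_ambiguous = isTRUE(allow_ambiguous)),
            class = "orf_params")
}

#' Reverse-complement a DNA string
#'
#' IUPAC-aware complementation (case preserved); an involution.
#'
#' @param seq character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAGN")
#' @export
revcomp <- function(seq) {
  bad <- regexpr(sprintf("[^%s%s]", IUPAC_DNA, tolower(IUPAC_DNA)), seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", substr(seq[i], bad[i], bad[i]), bad[i]),
         call. = FALSE)
  }
  from <- paste0(IUPAC_DNA, tolower(IUPAC_DNA))
  to <- paste0("TGCAYRSWMKVHDBN", tolower("TGCAYRSWMKVHDBN"))
  vapply(seq, function(s) {
    chartr(from, to, paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Scan one strand's sequence (already oriented 5'->3') in three frames.
# Returns half-open coordinates on that orientation.
scan_frames <- function(s, params) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    if (L < f + 3L) next
    pos <- seq.int(1L + f, L - 2L, by = 3L)
    codons <- substring(s, pos, pos + 2L)
    stop_i <- which(codons %in% params$stop_codons)
    if (!length(stop_i)) next
    start_i <- which(codons %in% params$start_codons)
    if (!length(start_i)) next
    prev_stop <- c(0L, stop_i[-length(stop_i)])
    # furthest-upstream start strictly after the previous in-frame stop
    cand_pos <- findInterval(prev_stop, start_i) + 1L
    cand <- ifelse(cand_pos <= length(start_i), start_i[cand_pos], NA_integer_)
    ok <- !is.na(cand) & cand < stop_i
    if (!any(ok)) next
    a <- pos[cand[ok]] - 1L           # half-open start
    b <- pos[stop_i[ok]] + 2L         # stop codon included
    keep <- (b - a) >= params$min_len_nt
    a <- a[keep]; b <- b[keep]
    if (!params$allow_ambiguous && length(a)) {
      clean <- !vapply(seq_along(a), function(k) {
        grepl("[^ACGT]", substr(s, a[k] + 1L, b[k]))
      }, logical(1))
      a <- a[clean]; b <- b[clean]
    }
    if (length(a)) out[[length(out) + 1L]] <- cbind(a, b)
  }
  if (!length(out)) matrix(integer(0), ncol = 2L) else do.call(rbind, out)
}

#' Find open reading frames in contigs
#'
#' Six-frame scan: for every in-frame stop codon, the candidate ORF runs from
#' the furthest-upstream in-frame start codon after the previous in-frame
#' stop through the stop codon inclusive. Candidates shorter than
#' `min_len_nt`, or containing any non-ACGT character (unless
#' `allow_ambiguous`), are discarded. Reverse-strand ORFs are reported in
#' forward-strand coordinates.
#'
#' @param contigs a [contig_set()] (any number of contigs).
#' @param params an [orf_params()].
#' @return A [gene_set()] of single-exon calls with
#'   `source_pass = "fallback"`.
#' @examples
#' find_orfs(contig_set("c", "TTATGAAACCCTAATT"), orf_params(min_len_nt = 12))
#' @export
find_orfs <- function(contigs, params = orf_params()) {
  all_calls <- list()
  for (i in seq_len(nrow(contigs))) {
    s <- toupper(contigs$seq[i])
    L <- nchar(s)
    if (L < params$min_len_nt) next
    fwd <- scan_frames(s, params)
    hits <- if (nrow(fwd)) cbind(fwd, 1L) else matrix(integer(0), ncol = 3L)
    if (params$both_strands) {
      rev <- scan_frames(revcomp(s), params)
      if (nrow(rev)) {
        refl <- cbind(L - rev[, 2L], L - rev[, 1L], 2L)
        hits <- rbind(hits, refl)
      }
    }
    if (!nrow(hits)) next
    strand <- c("+", "-")[hits[, 3L]]
    ord <- order(hits[, 1L], hits[, 2L], strand)
    hits <- hits[ord, , drop = FALSE]
    strand <- strand[ord]
    all_calls[[length(all_calls) + 1L]] <- gene_calls(
      paste0(contigs$id[i], "_orf", seq_len(nrow(hits))),
      contigs$id[i], hits[, 1L], hits[, 2L], strand = strand,
      source_pass = "fallback", category = "unknown")
  }
  calls <- if (length(all_calls)) do.call(rbind, all_calls) else empty_calls()
  gene_set(calls, name = "builtin_orfs",
           provenance = list(tool = "crossmask builtin ORF caller",
                             min_len_nt = params$min_len_nt,
                             both_strands = params$both_strands,
                             n = nrow(calls)))
}
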