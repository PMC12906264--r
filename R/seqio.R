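#' Build a contig collection
#'
#' A `contig_set` holds assembled metagenome contigs as a data frame with one
#' row per contig: `id` (unique token), `seq` (IUPAC DNA, case preserved) and
#' `desc` (optional free text from the FASTA header).
#'
#' @param id character vector of contig identifiers (no whitespace, unique).
#' @param seq character vector of DNA sequences (IUPAC alphabet,
#'   case-insensitive; original case is preserved).
#' @param desc optional character vector of descriptions (`NA` for none).
#' @return An object of class `contig_set` (a data frame).
#' @examples
#' contig_set(c("c1", "c2"), c("ACGT", "ggccn"))
#' @export
contig_set <- function(id = character(), seq = character(), desc = NA_character_) {
  id <- as.character(id)
  seq <- as.character(seq)
  desc <- rep_len(as.character(desc), length(id))
  if (length(seq) != length(id)) stop("'id' and 'seq' must have the same length", call. = FALSE)
  if (any(!is_token(id))) stop("contig ids must be non-empty tokens without whitespace", call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup)) stop(sprintf("duplicate contig id: %s", dup[1]), call. = FALSE)
  if (any(nchar(seq) < 1L)) stop("contig sequences must be non-empty", call. = FALSE)
  bad <- regexpr(sprintf("[^%s%s]", IUPAC_DNA, tolower(IUPAC_DNA)), seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("illegal sequence character '%s' in contig '%s' at position %d",
                 substr(seq[i], bad[i], bad[i]), id[i], bad[i]), call. = FALSE)
  }
  structure(data.frame(id = id, seq = seq, desc = desc, stringsAsFactors = FALSE),
            class = c("contig_set", "data.frame"))
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set> %d contig(s), %s bases total\n",
              nrow(x), format(sum(nchar(x$seq)), big.mark = ",")))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s  %s nt\n", show$id[i], format(nchar(show$seq[i]), big.mark = ",")))
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Contig lengths
#' @param contigs a [contig_set()].
#' @return Named integer vector of sequence lengths.
#' @export
contig_lengths <- function(contigs) {
  stats::setNames(nchar(contigs$seq), contigs$id)
}

#' Read a multi-FASTA file
#'
#' Parses (possibly line-wrapped) FASTA into a [contig_set()]. Wrapped sequence
#' lines are concatenated, record order and sequence case are preserved.
#' Duplicate identifiers and characters outside the IUPAC DNA alphabet are
#' errors.
#'
#' @param file path to a FASTA file.
#' @param text literal FASTA text (alternative to `file`).
#' @return A [contig_set()].
#' @examples
#' read_fasta(text = ">a\nACGT\n>b\nGG\nCC\n")
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  lines <- input_lines(file, text, "FASTA")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(contig_set())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA input does not start with a '>' header", call. = FALSE)
  rec <- cumsum(is_hdr)
  hdr <- sub("^>", "", lines[is_hdr])
  id <- sub("[[:space:]].*$", "", hdr)
  desc <- ifelse(grepl("[[:space:]]", hdr),
                 sub("^[^[:space:]]+[[:space:]]+", "", hdr), NA_character_)
  body <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(hdr))),
                 paste0, character(1), collapse = "")
  if (any(!nzchar(body))) {
    stop(sprintf("FASTA record '%s' has an empty sequence", id[which(!nzchar(body))[1]]),
         call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup)) stop(sprintf("duplicate FASTA id: %s", dup[1]), call. = FALSE)
  contig_set(id, unname(body), desc)
}

#' Write a multi-FASTA file
#'
#' @param contigs a [contig_set()].
#' @param file optional output path; when `NULL` the FASTA text is returned
#'   invisibly only.
#' @param wrap line width for sequence wrapping (positive integer).
#' @return Invisibly, the FASTA text.
#' @export
write_fasta <- function(contigs, file = NULL, wrap = 60L) {
  wrap <- as.integer(wrap)
  if (is.na(wrap) || wrap < 1L) stop("'wrap' must be a positive integer", call. = FALSE)
  lines <- character(0)
  if (nrow(contigs)) {
    per <- lapply(seq_len(nrow(contigs)), function(i) {
      hdr <- paste0(">", contigs$id[i],
                    if (!is.na(contigs$desc[i])) paste0(" ", contigs$desc[i]) else "")
      s <- contigs$seq[i]
      starts <- seq(1L, nchar(s), by = wrap)
      c(hdr, substring(s, starts, pmin(starts + wrap - 1L, nchar(s))))
    })
    lines <- unlist(per, use.names = FALSE)
  }
  emit_lines(lines, file)
}
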