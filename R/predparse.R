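#' Describe a MetaEuk-style FASTA header dialect
#'
#' MetaEuk encodes each prediction's location in its output FASTA headers as a
#' pipe-delimited record. Because the exact layout varies between versions,
#' the dialect is configurable: which position carries which role, the field
#' separator, and whether coordinates are 0- or 1-based inclusive.
#'
#' @param field_separator single separator character (default `"|"`).
#' @param coordinate_base `"0-inclusive"` (default; half-open end is
#'   `high + 1`) or `"1-inclusive"`.
#' @param field_order named integer vector mapping the nine roles
#'   (`target`, `contig`, `strand`, `bitscore`, `evalue`, `exon_count`,
#'   `low_coord`, `high_coord`, `exon_blocks`) to distinct positions.
#' @return An object of class `header_dialect`.
#' @export
header_dialect <- function(field_separator = "|",
                           coordinate_base = c("0-inclusive", "1-inclusive"),
                           field_order = c(target = 1L, contig = 2L, strand = 3L,
                                           bitscore = 4L, evalue = 5L,
                                           exon_count = 6L, low_coord = 7L,
                                           high_coord = 8L, exon_blocks = 9L)) {
  coordinate_base <- match.arg(coordinate_base)
  roles <- c("target", "contig", "strand", "bitscore", "evalue",
             "exon_count", "low_coord", "high_coord", "exon_blocks")
  if (!setequal(names(field_order), roles) || anyDuplicated(field_order))
    stop("field_order must map all nine roles to distinct positions", call. = FALSE)
  if (nchar(field_separator) != 1L)
    stop("field_separator must be a single character", call. = FALSE)
  structure(list(field_separator = field_separator,
                 coordinate_base = coordinate_base,
                 field_order = field_order[roles]),
            class = "header_dialect")
}

# convert an inclusive (low, high) pair under the dialect base to half-open
dialect_to_halfopen <- function(low, high, dialect) {
  if (dialect$coordinate_base == "0-inclusive") cbind(low, high + 1L)
  else cbind(low - 1L, high)
}

#' Parse MetaEuk-style prediction headers
#'
#' Reads the FASTA headers of a MetaEuk predictions file (sequence bodies are
#' ignored) and converts each header into a first-pass gene call under the
#' given [header_dialect()]. Exon blocks are colon-separated `low-high` pairs
#' in the dialect's coordinate base.
#'
#' @param file,text FASTA input (see [read_fasta()]).
#' @param dialect a [header_dialect()].
#' @param contigs optional [contig_set()]; when supplied, calls running past
#'   the end of their contig are clipped to the contig end with a warning, and
#'   the clip count is recorded in provenance.
#' @return A [gene_set()] with `source_pass = "first_pass"`.
#' @examples
#' parse_metaeuk_headers(text = ">p1|ctg7|+|250|1.2e-30|1|100|399|100-399\nN\n")
#' @export
parse_metaeuk_headers <- function(file = NULL, text = NULL,
                                  dialect = header_dialect(), contigs = NULL) {
  lines <- input_lines(file, text, "MetaEuk headers")
  hdrs <- sub("^>", "", lines[startsWith(lines, ">")])
  fo <- dialect$field_order
  nfields <- max(fo)
  calls <- lapply(hdrs, function(h) {
    f <- strsplit(h, dialect$field_separator, fixed = TRUE)[[1]]
    if (length(f) != nfields)
      stop(sprintf("header has %d field(s), expected %d: '>%s'", length(f), nfields, h),
           call. = FALSE)
    num <- function(role) {
      v <- suppressWarnings(as.numeric(f[fo[[role]]]))
      if (is.na(v)) stop(sprintf("non-numeric %s in header '>%s'", role, h), call. = FALSE)
      v
    }
    strand <- f[fo[["strand"]]]
    if (!strand %in% c("+", "-"))
      stop(sprintf("unknown strand symbol '%s' in header '>%s'", strand, h), call. = FALSE)
    span <- dialect_to_halfopen(num("low_coord"), num("high_coord"), dialect)
    blocks <- strsplit(f[fo[["exon_blocks"]]], ":", fixed = TRUE)[[1]]
    ex <- t(vapply(blocks, function(b) {
      p <- suppressWarnings(as.numeric(strsplit(b, "-", fixed = TRUE)[[1]]))
      if (length(p) != 2L || any(is.na(p)))
        stop(sprintf("malformed exon block '%s' in header '>%s'", b, h), call. = FALSE)
      p
    }, numeric(2)))
    ex <- dialect_to_halfopen(ex[, 1L], ex[, 2L], dialect)
    if (nrow(ex) != num("exon_count"))
      stop(sprintf("exon_count disagrees with exon blocks in header '>%s'", h), call. = FALSE)
    gene_calls(f[fo[["target"]]], f[fo[["contig"]]], span[1L], span[2L],
               strand = strand, exons = list(ex), source_pass = "first_pass",
               category = "unknown", score = num("bitscore"), evalue = num("evalue"))
  })
  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  prov <- list(format = "metaeuk_headers", n = nrow(calls))
  if (!is.null(contigs) && nrow(calls)) {
    clip <- clip_calls_to_contigs(calls, contigs)
    calls <- clip$calls
    prov$clipped <- clip$n_clipped
  }
  gene_set(calls, name = "metaeuk_headers", provenance = prov)
}

clip_calls_to_contigs <- function(calls, contigs) {
  lens <- contig_lengths(contigs)
  missing <- setdiff(calls$contig_id, names(lens))
  if (length(missing))
    stop(sprintf("call references absent contig '%s'", missing[1]), call. = FALSE)
  n_clipped <- 0L
  for (i in seq_len(nrow(calls))) {
    L <- lens[[calls$contig_id[i]]]
    if (calls$end[i] > L) {
      n_clipped <- n_clipped + 1L
      calls$end[i] <- L
      ex <- calls$exons[[i]]
      ex <- ex[ex[, 1L] < L, , drop = FALSE]
      ex[, 2L] <- pmin(ex[, 2L], L)
      calls$exons[[i]] <- ex
    }
  }
  if (n_clipped)
    warning(sprintf("%d call(s) extended past their contig end and were clipped", n_clipped),
            call. = FALSE)
  list(calls = calls, n_clipped = n_clipped)
}

#' Parse MetaEuk GFF3 output
#'
#' Delegates to [read_gff()] and tags every call `source_pass = "first_pass"`.
#'
#' @inheritParams read_gff
#' @return A [gene_set()].
#' @export
parse_metaeuk_gff <- function(file = NULL, text = NULL) {
  gs <- read_gff(file, text, name = "metaeuk_gff", source_pass = "first_pass")
  gs$calls$source_pass <- rep_len("first_pass", n_calls(gs))
  gs$provenance$format <- "metaeuk_gff"
  gs
}

#' Parse Prodigal / MetaGeneMark GFF3 output
#'
#' Prokaryotic predictors emit single-CDS genes; a grouped multi-CDS record is
#' a contract violation and raises an error.
#'
#' @inheritParams read_gff
#' @param flavor tool family the file came from (recorded in provenance; the
#'   two families share the dialect handled here).
#' @return A [gene_set()] with `source_pass = "second_pass"` and one exon per
#'   call.
#' @export
parse_prokaryotic_gff <- function(file = NULL, text = NULL,
                                  flavor = c("prodigal", "metagenemark")) {
  flavor <- match.arg(flavor)
  gs <- read_gff(file, text, name = paste0(flavor, "_gff"),
                 source_pass = "second_pass")
  multi <- vapply(gs$calls$exons, nrow, integer(1)) > 1L
  if (any(multi))
    stop(sprintf("prokaryotic GFF contains a multi-exon group ('%s'); single-CDS calls expected",
                 gs$calls$gene_id[multi][1]), call. = FALSE)
  gs$calls$source_pass <- rep_len("second_pass", n_calls(gs))
  gs$calls$category <- rep_len("unknown", n_calls(gs))
  gs$provenance <- list(format = "prokaryotic_gff", flavor = flavor, n = n_calls(gs))
  gs
}
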