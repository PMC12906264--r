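# Minimal GFF3 dialect: tab-separated 9-column lines, CDS features grouped
# into gene calls by Parent (preferred) or ID. Coordinates are 1-based
# inclusive on disk and 0-based half-open in memory.

parse_gff_attrs <- function(attr) {
  pairs <- strsplit(attr, ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(trimws(pairs))]
  kv <- strsplit(trimws(pairs), "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2L) paste(p[-1L], collapse = "=") else "",
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  vals
}

attr_get <- function(a, key) if (key %in% names(a)) a[[key]] else NULL

#' Read GFF3 gene annotations
#'
#' Reads CDS features from a GFF3 file and groups them into gene calls: lines
#' sharing a `Parent` attribute (or, failing that, an `ID`) become the exons of
#' one call, sorted ascending in forward-strand coordinates regardless of
#' strand. GFF 1-based inclusive coordinates are converted to 0-based
#' half-open. Optional `category` and `source_pass` attributes written by
#' [write_gff()] are restored when present.
#'
#' @param file path to a GFF3 file.
#' @param text literal GFF3 text (alternative to `file`).
#' @param name,source_pass label and default pass for the resulting set.
#' @return A [gene_set()].
#' @examples
#' read_gff(text = "##gff-version 3\nctg1\t.\tCDS\t101\t400\t.\t+\t0\tID=g1")
#' @export
read_gff <- function(file = NULL, text = NULL, name = "gff",
                     source_pass = "first_pass") {
  lines <- input_lines(file, text, "GFF3")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(gene_set(name = name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("malformed GFF line (expected 9 tab-separated fields): %s",
                 lines[which(nf < 9L)[1]]), call. = FALSE)
  m <- do.call(rbind, fields)[, 1:9, drop = FALSE]
  keep <- m[, 3L] == "CDS"
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(gene_set(name = name))
  s1 <- suppressWarnings(as.integer(m[, 4L]))
  e1 <- suppressWarnings(as.integer(m[, 5L]))
  if (any(is.na(s1)) || any(is.na(e1)))
    stop("non-numeric GFF coordinate", call. = FALSE)
  bad <- which(e1 < s1)
  if (length(bad))
    stop(sprintf("GFF record with end < start (%d < %d) on '%s'",
                 e1[bad[1]], s1[bad[1]], m[bad[1], 1L]), call. = FALSE)
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-")))
    stop(sprintf("unknown strand symbol '%s' in GFF record on '%s'",
                 strand[!strand %in% c("+", "-")][1],
                 m[!strand %in% c("+", "-"), 1L][1]), call. = FALSE)
  attrs <- lapply(m[, 9L], parse_gff_attrs)
  key <- vapply(attrs, function(a) {
    k <- attr_get(a, "Parent") %||% attr_get(a, "ID") %||% NA_character_
    if (is.na(k)) stop("GFF CDS record lacks both ID and Parent attributes", call. = FALSE)
    k
  }, character(1))
  score <- suppressWarnings(as.numeric(m[, 6L]))

  ord <- order(match(key, unique(key)))
  groups <- split(seq_len(nrow(m))[ord], factor(key[ord], levels = unique(key)))
  calls <- lapply(names(groups), function(gid) {
    idx <- groups[[gid]]
    if (length(unique(m[idx, 1L])) > 1L)
      stop(sprintf("gene '%s': CDS records on multiple contigs", gid), call. = FALSE)
    if (length(unique(strand[idx])) > 1L)
      stop(sprintf("gene '%s': CDS records on multiple strands", gid), call. = FALSE)
    ex <- cbind(s1[idx] - 1L, e1[idx])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    a <- attrs[[idx[1]]]
    gene_calls(gid, m[idx[1], 1L], min(ex[, 1L]), max(ex[, 2L]),
               strand = strand[idx[1]], exons = list(ex),
               source_pass = attr_get(a, "source_pass") %||% source_pass,
               category = attr_get(a, "category") %||% "unknown",
               score = if (all(is.na(score[idx]))) NA_real_ else max(score[idx], na.rm = TRUE),
               evalue = suppressWarnings(as.numeric(attr_get(a, "evalue") %||% NA)))
  })
  gene_set(do.call(rbind, calls), name = name,
           provenance = list(format = "gff3", n = length(calls)))
}

gff_phases <- function(ex, strand) {
  widths <- ex[, 2L] - ex[, 1L]
  if (strand == "-") widths <- rev(widths)
  ph <- (3L - cumsum(c(0L, widths[-length(widths)])) %% 3L) %% 3L
  if (strand == "-") rev(ph) else ph
}

#' Write a gene set as GFF3
#'
#' One CDS line per exon; multi-exon calls share a `Parent` attribute so that
#' [read_gff()] regroups them losslessly (round trips preserve contig, span,
#' strand, exons and gene_id exactly).
#'
#' @param gene_set a [gene_set()].
#' @param file optional output path.
#' @param extra_attributes when `TRUE` (default), `category`, `source_pass`
#'   and `evalue` are embedded as GFF attributes so the package's own files
#'   round-trip all fields; disable to emulate plain third-party output.
#' @return Invisibly, the GFF3 text.
#' @export
write_gff <- function(gene_set, file = NULL, extra_attributes = TRUE) {
  calls <- gene_set$calls
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(calls))) {
    ex <- calls$exons[[i]]
    gid <- calls$gene_id[i]
    multi <- nrow(ex) > 1L
    ph <- gff_phases(ex, calls$strand[i])
    for (k in seq_len(nrow(ex))) {
      extra <- if (extra_attributes) {
        paste0(";category=", calls$category[i], ";source_pass=", calls$source_pass[i],
               if (!is.na(calls$evalue[i])) paste0(";evalue=", format(calls$evalue[i])))
      } else ""
      attr9 <- if (multi) {
        paste0("ID=", gid, ".cds", k, ";Parent=", gid, extra)
      } else {
        paste0("ID=", gid, extra)
      }
      lines <- c(lines, paste(calls$contig_id[i], "crossmask", "CDS",
                              ex[k, 1L] + 1L, ex[k, 2L],
                              if (is.na(calls$score[i])) "." else format(calls$score[i]),
                              calls$strand[i], ph[k], attr9, sep = "\t"))
    }
  }
  emit_lines(lines, file)
}
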