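SOURCE_PASSES <- c("first_pass", "second_pass", "fallback")
CATEGORIES <- c("eukaryote", "prokaryote", "virus", "unknown")

empty_calls <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             source_pass = character(), category = character(),
             score = numeric(), evalue = numeric(),
             exons = I(list()), stringsAsFactors = FALSE)
}

#' Build a table of gene calls
#'
#' Constructs the per-call table used inside a [gene_set()]. Coordinates are
#' 0-based half-open on the forward strand; exon lists are stored in ascending
#' forward-strand order regardless of strand (strand is consulted only at
#' translation time).
#'
#' @param gene_id,contig_id character vectors (recycled where scalar).
#' @param start,end half-open span coordinates (`0 <= start < end`).
#' @param strand `"+"` or `"-"`.
#' @param exons optional list of two-column integer matrices
#'   (start, end half-open); `NULL` means one exon equal to the span.
#' @param source_pass one of `"first_pass"`, `"second_pass"`, `"fallback"`.
#' @param category one of `"eukaryote"`, `"prokaryote"`, `"virus"`, `"unknown"`.
#' @param score,evalue optional numeric annotations (`NA` for absent).
#' @return A data frame of calls suitable for [gene_set()].
#' @export
gene_calls <- function(gene_id, contig_id, start, end, strand = "+",
                       exons = NULL, source_pass = "first_pass",
                       category = "unknown", score = NA_real_,
                       evalue = NA_real_) {
  n <- length(gene_id)
  df <- data.frame(gene_id = as.character(gene_id),
                   contig_id = rep_len(as.character(contig_id), n),
                   start = as.integer(rep_len(start, n)),
                   end = as.integer(rep_len(end, n)),
                   strand = rep_len(as.character(strand), n),
                   source_pass = rep_len(as.character(source_pass), n),
                   category = rep_len(as.character(category), n),
                   score = rep_len(as.numeric(score), n),
                   evalue = rep_len(as.numeric(evalue), n),
                   stringsAsFactors = FALSE)
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) cbind(df$start[i], df$end[i]))
  }
  df$exons <- I(lapply(exons, function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    m[order(m[, 1L]), , drop = FALSE]
  }))
  df
}

validate_calls <- function(calls) {
  if (!nrow(calls)) return(invisible(calls))
  dup <- calls$gene_id[duplicated(calls$gene_id)]
  if (length(dup)) stop(sprintf("duplicate gene_id: %s", dup[1]), call. = FALSE)
  if (any(!is_token(calls$gene_id)) || any(!is_token(calls$contig_id)))
    stop("gene_id and contig_id must be non-empty tokens", call. = FALSE)
  bad <- which(!(calls$start >= 0L & calls$start < calls$end))
  if (length(bad))
    stop(sprintf("invalid span for gene '%s': [%d, %d)", calls$gene_id[bad[1]],
                 calls$start[bad[1]], calls$end[bad[1]]), call. = FALSE)
  if (any(!calls$strand %in% c("+", "-")))
    stop(sprintf("unknown strand symbol '%s' for gene '%s'",
                 calls$strand[!calls$strand %in% c("+", "-")][1],
                 calls$gene_id[!calls$strand %in% c("+", "-")][1]), call. = FALSE)
  if (any(!calls$source_pass %in% SOURCE_PASSES))
    stop("source_pass must be one of: ", paste(SOURCE_PASSES, collapse = ", "), call. = FALSE)
  if (any(!calls$category %in% CATEGORIES))
    stop("category must be one of: ", paste(CATEGORIES, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(calls))) {
    ex <- calls$exons[[i]]
    gid <- calls$gene_id[i]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
      stop(sprintf("gene '%s': exons must be a two-column matrix with >= 1 row", gid), call. = FALSE)
    if (any(ex[, 1L] >= ex[, 2L]))
      stop(sprintf("gene '%s': empty or inverted exon interval", gid), call. = FALSE)
    if (is.unsorted(ex[, 1L], strictly = TRUE) && nrow(ex) > 1L)
      stop(sprintf("gene '%s': exons must be sorted ascending", gid), call. = FALSE)
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop(sprintf("gene '%s': exons must be pairwise disjoint", gid), call. = FALSE)
    if (ex[1L, 1L] < calls$start[i] || ex[nrow(ex), 2L] > calls$end[i])
      stop(sprintf("gene '%s': exon outside span", gid), call. = FALSE)
  }
  invisible(calls)
}

#' Build a gene set
#'
#' A `gene_set` is a named collection of gene calls with unique identifiers and
#' free-form provenance (tool name, parameters, counts). It is the common
#' currency between the parsers, the masking engine, the built-in ORF caller,
#' the consolidation step and the evaluation metrics.
#'
#' @param calls a calls data frame, typically from [gene_calls()].
#' @param name a label for the set.
#' @param provenance a named list of free-form provenance entries.
#' @return An object of class `gene_set`.
#' @examples
#' gs <- gene_set(gene_calls("g1", "ctg1", 100, 400))
#' n_calls(gs)
#' @export
gene_set <- function(calls = empty_calls(), name = "gene_set", provenance = list()) {
  if (!nrow(calls)) calls <- empty_calls()
  validate_calls(calls)
  rownames(calls) <- NULL
  structure(list(name = as.character(name), calls = calls,
                 provenance = provenance),
            class = "gene_set")
}

#' Number of calls in a gene set
#' @param gene_set a [gene_set()].
#' @return Integer count.
#' @export
n_calls <- function(gene_set) nrow(gene_set$calls)

#' Coding lengths of all calls
#'
#' Gene length throughout the package is coding length: the sum of exon
#' interval widths, not the span width.
#'
#' @param gene_set a [gene_set()].
#' @return Named integer vector (by `gene_id`).
#' @export
coding_lengths <- function(gene_set) {
  stats::setNames(
    vapply(gene_set$calls$exons, function(m) sum(m[, 2L] - m[, 1L]), integer(1)),
    gene_set$calls$gene_id)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> '%s': %d call(s)\n", x$name, n_calls(x)))
  if (n_calls(x)) {
    tab <- table(x$calls$category)
    cat("  by category:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    tab <- table(x$calls$source_pass)
    cat("  by pass:    ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
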