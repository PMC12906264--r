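`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
IUPAC_DNA <- "ACGTRYSWKMBDHVN"

iupac_chars <- function() {
  c(strsplit(IUPAC_DNA, "")[[1]], strsplit(tolower(IUPAC_DNA), "")[[1]])
}

# Accept either a file path or literal text; returns a character vector of lines.
input_lines <- function(file = NULL, text = NULL, what = "input") {
  if (!is.null(text)) {
    if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
    return(as.character(text))
  }
  if (is.null(file)) stop(sprintf("either 'file' or 'text' must be given for %s", what), call. = FALSE)
  if (!file.exists(file)) stop(sprintf("file not found: %s", file), call. = FALSE)
  readLines(file, warn = FALSE)
}

emit_lines <- function(lines, file = NULL) {
  if (!is.null(file)) writeLines(lines, file)
  invisible(paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else ""))
}

is_token <- function(x) {
  is.character(x) & nzchar(x) & !grepl("[[:space:]]", x)
}

# deterministic derived seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1009 * k) %% 2147483647)
}
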