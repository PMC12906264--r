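# Independent brute-force oracles used to verify the package's vectorized /
# interval-algebra implementations. These deliberately share no code with R/.

# --- masking: position-by-position boolean-array union ---------------------

mask_oracle <- function(seq, intervals, mask_char = "N") {
  v <- rep(FALSE, nchar(seq))
  if (length(intervals)) {
    m <- matrix(intervals, ncol = 2L)
    for (k in seq_len(nrow(m))) v[seq(m[k, 1] + 1L, m[k, 2])] <- TRUE
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[v] <- mask_char
  list(seq = paste(chars, collapse = ""), masked_bases = sum(v))
}

union_size_oracle <- function(intervals, max_pos) {
  v <- rep(FALSE, max_pos)
  m <- matrix(intervals, ncol = 2L)
  for (k in seq_len(nrow(m))) v[seq(m[k, 1] + 1L, m[k, 2])] <- TRUE
  sum(v)
}

# --- ORF finding: character-walk six-frame enumeration ---------------------

oracle_revcomp <- function(s) {
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- comp[chars]
  out[is.na(out)] <- "X"   # any other ambiguity code; never a codon match
  paste(out, collapse = "")
}

orf_oracle_one_strand <- function(s, min_len, starts, stops, allow_ambiguous) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  hits <- NULL
  for (f in 0:2) {
    pending <- NA_integer_
    p <- f + 1L
    while (p + 2L <= L) {
      codon <- paste(chars[p:(p + 2L)], collapse = "")
      if (is.na(pending) && codon %in% starts) pending <- p
      if (codon %in% stops) {
        if (!is.na(pending)) {
          a <- pending - 1L          # half-open
          b <- p + 2L
          ok <- (b - a) >= min_len
          if (ok && !allow_ambiguous)
            ok <- all(chars[(a + 1L):b] %in% c("A", "C", "G", "T"))
          if (ok) hits <- rbind(hits, c(a, b))
        }
        pending <- NA_integer_
      }
      p <- p + 3L
    }
  }
  hits
}

orf_oracle <- function(seq, min_len = 300L,
                       starts = c("ATG", "GTG", "TTG"),
                       stops = c("TAA", "TAG", "TGA"),
                       both_strands = TRUE, allow_ambiguous = FALSE) {
  s <- toupper(seq)
  L <- nchar(s)
  fwd <- orf_oracle_one_strand(s, min_len, starts, stops, allow_ambiguous)
  out <- if (!is.null(fwd)) cbind(fwd, 1L) else NULL
  if (both_strands) {
    rev_hits <- orf_oracle_one_strand(oracle_revcomp(s), min_len, starts, stops,
                                      allow_ambiguous)
    if (!is.null(rev_hits))
      out <- rbind(out, cbind(L - rev_hits[, 2], L - rev_hits[, 1], 2L))
  }
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  df <- data.frame(start = out[, 1], end = out[, 2],
                   strand = c("+", "-")[out[, 3]])
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

orf_calls_df <- function(gs) {
  df <- data.frame(start = gs$calls$start, end = gs$calls$end,
                   strand = gs$calls$strand)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# --- global alignment: exhaustive enumeration of achievable outcomes -------
# Enumerates, for every cell, the full set of achievable
# (score, gap_columns, matches, columns) outcomes over all global alignments,
# then applies the stated tie-break (max score, then fewest gaps).

pid_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  key <- function(i, j) paste0(i, ",", j)
  rep <- new.env()
  assign(key(0, 0), matrix(c(0, 0, 0, 0), 1), envir = rep)
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    acc <- NULL
    if (i > 0 && j > 0) {
      prev <- get(key(i - 1, j - 1), envir = rep)
      sub <- if (A[i] == B[j]) match else mismatch
      acc <- rbind(acc, prev + rep(c(sub, 0, as.numeric(A[i] == B[j]), 1),
                                   each = nrow(prev)))
    }
    if (i > 0) {
      prev <- get(key(i - 1, j), envir = rep)
      acc <- rbind(acc, prev + rep(c(gap, 1, 0, 1), each = nrow(prev)))
    }
    if (j > 0) {
      prev <- get(key(i, j - 1), envir = rep)
      acc <- rbind(acc, prev + rep(c(gap, 1, 0, 1), each = nrow(prev)))
    }
    assign(key(i, j), unique(acc), envir = rep)
  }
  fin <- get(key(n, m), envir = rep)
  fin <- fin[fin[, 1] == max(fin[, 1]), , drop = FALSE]
  fin <- fin[fin[, 2] == min(fin[, 2]), , drop = FALSE]
  100 * fin[1, 3] / fin[1, 4]
}

pid_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], match, mismatch),
                           S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

# --- reference-based detection: per-base boolean coverage ------------------

detection_oracle <- function(pred, truth, overlap_frac = 0.5, strand_aware = TRUE) {
  pt <- pred$calls
  detected <- logical(nrow(truth$calls))
  for (i in seq_along(detected)) {
    tr <- truth$calls[i, ]
    tex <- tr$exons[[1]]
    span_max <- max(tex[, 2])
    cov <- rep(FALSE, span_max)
    for (k in seq_len(nrow(pt))) {
      if (pt$contig_id[k] != tr$contig_id) next
      if (strand_aware && pt$strand[k] != tr$strand) next
      pex <- pt$exons[[k]]
      for (e in seq_len(nrow(pex))) {
        lo <- pex[e, 1]; hi <- min(pex[e, 2], span_max)
        if (lo < hi) cov[(lo + 1):hi] <- TRUE
      }
    }
    tmask <- rep(FALSE, span_max)
    for (e in seq_len(nrow(tex))) tmask[(tex[e, 1] + 1):tex[e, 2]] <- TRUE
    detected[i] <- sum(cov & tmask) >= overlap_frac * sum(tmask)
  }
  detected
}

# --- random fixture builders ----------------------------------------------

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

random_contigs <- function(n, len_range = c(50, 300), with_case = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- if (with_case) c("A", "C", "G", "T", "a", "c", "g", "t", "N")
              else c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample_range(len_range), replace = TRUE),
          collapse = "")
  }, character(1))
  contig_set(paste0("rc", seq_len(n)), seqs,
             desc = ifelse(seq_len(n) %% 2 == 0, "random fixture", NA))
}

random_gene_set <- function(n_calls, n_contigs = 3, contig_len = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- lapply(seq_len(n_calls), function(i) {
    k <- sample(1:3, 1)
    widths <- sample(30:120, k, replace = TRUE)
    gaps <- if (k > 1) sample(10:50, k - 1, replace = TRUE) else integer(0)
    s0 <- sample(0:(contig_len - sum(widths) - sum(gaps) - 1), 1)
    starts <- s0 + cumsum(c(0, head(widths, -1) + gaps))
    ex <- cbind(starts, starts + widths)
    gene_calls(sprintf("g%04d", i), sprintf("ctg%d", sample(n_contigs, 1)),
               min(ex[, 1]), max(ex[, 2]),
               strand = sample(c("+", "-"), 1), exons = list(ex),
               source_pass = sample(c("first_pass", "second_pass"), 1),
               category = sample(c("eukaryote", "prokaryote", "virus", "unknown"), 1),
               score = round(runif(1, 1, 500), 1),
               evalue = signif(10^runif(1, -40, -2), 3))
  })
  gene_set(do.call(rbind, calls), name = "random_fixture")
}

# random half-open intervals including nested / duplicate / touching cases
random_intervals <- function(n, max_pos) {
  s <- sample(0:(max_pos - 2), n, replace = TRUE)
  w <- sample(1:max(2, max_pos %/% 4), n, replace = TRUE)
  m <- cbind(s, pmin(s + w, max_pos))
  if (n >= 2) m[2, ] <- m[1, ]                       # duplicate
  if (n >= 4 && m[3, 2] - m[3, 1] > 2) {
    m[4, ] <- c(m[3, 1] + 1, m[3, 2] - 1)            # nested
  }
  if (n >= 6) m[6, ] <- c(m[5, 2], min(m[5, 2] + 3, max_pos))  # touching
  m[m[, 1] < m[, 2], , drop = FALSE]
}
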