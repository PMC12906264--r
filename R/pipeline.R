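#' Workflow configuration
#'
#' Bundles everything the staged workflow needs: the masking policy, the
#' second-pass mechanism (an external command template with `{input}` and
#' `{output}` placeholders, or the built-in ORF caller), ORF parameters for
#' the built-in path, and housekeeping flags.
#'
#' @param mask_policy a [mask_policy()].
#' @param second_pass `"builtin_orf"` or `"external_command_template"`.
#' @param orf_params an [orf_params()] (built-in path).
#' @param external_cmd command template containing `{input}` and `{output}`;
#'   required iff `second_pass = "external_command_template"`.
#' @param keep_intermediates write the masked FASTA alongside the other run
#'   outputs.
#' @param seed optional integer seed propagated to any stochastic component.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(mask_policy = crossmask::mask_policy(),
                            second_pass = c("builtin_orf", "external_command_template"),
                            orf_params = crossmask::orf_params(),
                            external_cmd = NULL, keep_intermediates = TRUE,
                            seed = NULL) {
  second_pass <- match.arg(second_pass)
  if (second_pass == "external_command_template") {
    if (is.null(external_cmd))
      stop("external_cmd is required when second_pass = 'external_command_template'",
           call. = FALSE)
    if (!grepl("{input}", external_cmd, fixed = TRUE) ||
        !grepl("{output}", external_cmd, fixed = TRUE))
      stop("external_cmd must contain both {input} and {output} placeholders",
           call. = FALSE)
  } else if (!is.null(external_cmd)) {
    stop("external_cmd must be NULL unless second_pass = 'external_command_template'",
         call. = FALSE)
  }
  structure(list(mask_policy = mask_policy, second_pass = second_pass,
                 orf_params = orf_params, external_cmd = external_cmd,
                 keep_intermediates = isTRUE(keep_intermediates),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "workflow_config")
}

#' Import first-pass predictions from a file
#'
#' @param path prediction file.
#' @param format `"metaeuk_gff"` or `"metaeuk_headers"`.
#' @param dialect a [header_dialect()] (headers format only).
#' @param contigs optional [contig_set()] for coordinate clipping.
#' @return A [gene_set()] tagged `first_pass`, with file, format and call
#'   count recorded in provenance.
#' @export
run_first_pass_import <- function(path, format = c("metaeuk_gff", "metaeuk_headers"),
                                  dialect = header_dialect(), contigs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("first-pass prediction file not found: %s", path), call. = FALSE)
  gs <- switch(format,
               metaeuk_gff = parse_metaeuk_gff(path),
               metaeuk_headers = parse_metaeuk_headers(path, dialect = dialect,
                                                       contigs = contigs))
  gs$provenance$file <- path
  gs$provenance$format <- format
  gs$provenance$n <- n_calls(gs)
  gs
}

#' Run the second prediction pass on masked contigs
#'
#' Built-in path: the six-frame ORF caller over every contig (calls tagged
#' `fallback`). External path: the masked contigs are written to a FASTA
#' file, the `{input}`/`{output}` placeholders in the command template are
#' substituted, the command is executed through the shell, and its declared
#' output is parsed as prokaryotic GFF (calls tagged `second_pass`). An empty
#' prediction set is a valid result; a non-zero exit status is an error
#' carrying the captured diagnostics.
#'
#' @param masked_contigs a [contig_set()] (already masked).
#' @param config a [workflow_config()].
#' @return A [gene_set()].
#' @export
run_second_pass <- function(masked_contigs, config = workflow_config()) {
  if (config$second_pass == "builtin_orf")
    return(find_orfs(masked_contigs, config$orf_params))
  dir <- tempfile("crossmask_sp_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  input <- file.path(dir, "masked.fa")
  output <- file.path(dir, "second_pass.gff")
  write_fasta(masked_contigs, input)
  cmd <- gsub("{output}", output, gsub("{input}", input, config$external_cmd,
                                       fixed = TRUE), fixed = TRUE)
  res <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop(sprintf("external second-pass command failed (exit %d): %s\n%s",
                 status, cmd, paste(res, collapse = "\n")), call. = FALSE)
  if (!file.exists(output))
    stop(sprintf("external second-pass command produced no output file: %s", cmd),
         call. = FALSE)
  parse_prokaryotic_gff(output)
}

#' Consolidate first- and second-pass gene sets
#'
#' Takes the union with globally unique gene ids (colliding second-pass ids
#' are prefixed `sp.`). Any second-pass call whose span overlaps a
#' first-pass call's masked region by at least one base on the same contig
#' is dropped and counted: conflicts resolve in favor of the first pass.
#' With span-mode masking and the built-in second pass no such overlap can
#' occur; the drop rule is a safety net for exon-mode masking and external
#' predictors. Output is ordered by contig, span start, then pass.
#'
#' @param first_pass,second_pass [gene_set()] objects.
#' @param policy the [mask_policy()] the masking ran with (defines the
#'   first-pass masked regions used for conflict detection).
#' @return A list with `gene_set` (the combined set) and `dropped_overlaps`.
#' @export
consolidate <- function(first_pass, second_pass, policy = mask_policy()) {
  fp <- first_pass$calls
  sp <- second_pass$calls
  dropped <- 0L
  if (nrow(sp) && nrow(fp)) {
    masked <- lapply(intervals_from_calls(first_pass, policy), merge_intervals,
                     merge_gap = policy$merge_gap)
    clash <- vapply(seq_len(nrow(sp)), function(i) {
      m <- masked[[sp$contig_id[i]]]
      !is.null(m) && any(sp$start[i] < m[, 2L] & m[, 1L] < sp$end[i])
    }, logical(1))
    dropped <- sum(clash)
    sp <- sp[!clash, , drop = FALSE]
  }
  if (nrow(sp)) {
    taken <- fp$gene_id
    clash_id <- sp$gene_id %in% taken
    while (any(clash_id)) {
      sp$gene_id[clash_id] <- paste0("sp.", sp$gene_id[clash_id])
      clash_id <- sp$gene_id %in% taken | duplicated(sp$gene_id)
    }
  }
  combined <- rbind(fp, sp)
  if (nrow(combined)) {
    pass_rank <- c(first_pass = 1L, second_pass = 2L, fallback = 2L)
    ord <- order(combined$contig_id, combined$start,
                 pass_rank[combined$source_pass], combined$gene_id)
    combined <- combined[ord, , drop = FALSE]
  }
  list(gene_set = gene_set(combined, name = "combined",
                           provenance = list(first_pass = first_pass$name,
                                             second_pass = second_pass$name,
                                             dropped_overlaps = dropped)),
       dropped_overlaps = dropped)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("workflow stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the staged gene-recovery workflow
#'
#' The four-step workflow over files: import first-pass predictions,
#' hard-mask their regions on the contigs, run the second prediction pass on
#' the masked contigs, and consolidate both gene sets. When `outdir` is
#' given, writes `combined.gff3`, `mask_report.tsv`, `summary.tsv` and
#' (with `keep_intermediates`) `masked.fa`. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param contigs_path assembled contigs (multi-FASTA).
#' @param first_pass_path first-pass prediction file.
#' @param config a [workflow_config()].
#' @param outdir optional output directory (created if needed).
#' @param first_pass_format,dialect see [run_first_pass_import()].
#' @param lenient passed to [mask_metagenome()].
#' @return An object of class `workflow_result`: `combined` ([gene_set()]),
#'   `mask_report`, `masked_contigs`, `first_pass_n`, `second_pass_n`,
#'   `dropped_overlaps`. The count identity
#'   `n_calls(combined) == first_pass_n + second_pass_n - dropped_overlaps`
#'   always holds.
#' @export
run_workflow <- function(contigs_path, first_pass_path,
                         config = workflow_config(), outdir = NULL,
                         first_pass_format = c("metaeuk_gff", "metaeuk_headers"),
                         dialect = header_dialect(), lenient = FALSE) {
  first_pass_format <- match.arg(first_pass_format)
  contigs <- run_stage("read_contigs", {
    if (!file.exists(contigs_path))
      stop(sprintf("contig FASTA not found: %s", contigs_path))
    read_fasta(contigs_path)
  })
  first <- run_stage("first_pass_import",
                     run_first_pass_import(first_pass_path, first_pass_format,
                                           dialect, contigs = contigs))
  maskres <- run_stage("mask",
                       mask_metagenome(contigs, first, config$mask_policy,
                                       lenient = lenient))
  second <- run_stage("second_pass", run_second_pass(maskres$contigs, config))
  cons <- run_stage("consolidate", consolidate(first, second, config$mask_policy))

  result <- structure(list(combined = cons$gene_set,
                           mask_report = maskres$report,
                           masked_contigs = maskres$contigs,
                           first_pass_n = n_calls(first),
                           second_pass_n = n_calls(second),
                           dropped_overlaps = cons$dropped_overlaps),
                      class = "workflow_result")
  stopifnot(n_calls(result$combined) ==
              result$first_pass_n + result$second_pass_n - result$dropped_overlaps)

  if (!is.null(outdir)) {
    run_stage("write_outputs", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_gff(result$combined, file.path(outdir, "combined.gff3"))
      write_mask_report(result$mask_report, file.path(outdir, "mask_report.tsv"))
      if (config$keep_intermediates)
        write_fasta(maskres$contigs, file.path(outdir, "masked.fa"))
      summary_df <- data.frame(
        key = c("first_pass_n", "second_pass_n", "dropped_overlaps", "combined_n",
                "total_bases", "masked_bases", "fraction_masked"),
        value = c(result$first_pass_n, result$second_pass_n,
                  result$dropped_overlaps, n_calls(result$combined),
                  maskres$report$total_bases, maskres$report$total_masked,
                  signif(maskres$report$fraction_masked, 6)))
      utils::write.table(summary_df, file.path(outdir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  result
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("<workflow_result>\n")
  cat(sprintf("  first pass : %d call(s)\n", x$first_pass_n))
  cat(sprintf("  masked     : %s bases (%.2f%%)\n",
              format(x$mask_report$total_masked, big.mark = ","),
              100 * x$mask_report$fraction_masked))
  cat(sprintf("  second pass: %d call(s), %d dropped as overlaps\n",
              x$second_pass_n, x$dropped_overlaps))
  cat(sprintf("  combined   : %d call(s)\n", n_calls(x$combined)))
  invisible(x)
}
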