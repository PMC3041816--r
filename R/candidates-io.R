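#' Write the candidate-exon table
#'
#' Writes the cascade's surviving probesets with their splice scores, event
#' types and DAS direction to a tab-delimited file with a fixed column order,
#' stably sorted by gene id and probeset start. Numeric columns are written
#' with full precision so [read_candidate_table()] reproduces the data
#' bit-exactly.
#'
#' @param candidates Data frame of candidates as produced by [run_cascade()]
#'   (columns `probeset_id`, `gene_id`, `chrom`, `start`, `si_d7`, `si_d10`,
#'   `a_value`, `as_types`, `das_direction`).
#' @param path Output path.
#' @return Invisibly, the (sorted) candidate data frame.
#' @export
write_candidate_table <- function(candidates, path) {
  cols <- c("probeset_id", "gene_id", "chrom", "start",
            "si_d7", "si_d10", "a_value", "as_types", "das_direction")
  missing <- setdiff(cols, names(candidates))
  if (length(missing) > 0L) {
    stop("candidate table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- candidates[order(candidates$gene_id, candidates$start,
                         candidates$probeset_id), cols, drop = FALSE]
  rownames(df) <- NULL
  out <- df
  for (cn in c("si_d7", "si_d10", "a_value")) {
    out[[cn]] <- sprintf("%.17g", df[[cn]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a candidate-exon table written by [write_candidate_table()]
#'
#' @param path Path to the tab-delimited candidate table.
#' @return The candidate data frame.
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  df$start <- as.integer(df$start)
  for (cn in c("si_d7", "si_d10", "a_value")) df[[cn]] <- as.numeric(df[[cn]])
  rownames(df) <- NULL
  df
}

#' Write/read the cascade audit
#'
#' The audit is the per-stage record of surviving probeset and gene counts.
#' `write_audit()` emits a tab-delimited table; `write_audit_json()` the same
#' content as JSON.
#'
#' @param audit Data frame with columns `stage`, `description`,
#'   `n_probesets`, `n_genes` (see [run_cascade()]).
#' @param path Output path.
#' @return Invisibly, `audit`.
#' @export
write_audit <- function(audit, path) {
  utils::write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(audit)
}

#' @rdname write_audit
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(audit, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(audit)
}

#' @rdname write_audit
#' @export
read_audit <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$stage <- as.integer(df$stage)
  df$n_probesets <- as.integer(df$n_probesets)
  df$n_genes <- as.integer(df$n_genes)
  df
}

#' Published per-stage audit counts of the reference exon-array screen
#'
#' Per-stage surviving probeset and gene counts from the published P19
#' neuronal-differentiation exon-array screen that this package's cascade
#' re-implements, transcribed from the study's filtering table. Useful as a
#' reference shape for audits and for derived summaries such as the
#' percentage of stage-7 survivors predicted alternative at stage 8.
#'
#' @return Audit-shaped data frame (`stage`, `description`, `n_probesets`,
#'   `n_genes`) with stages 0 (input) through 9.
#' @export
reference_audit_counts <- function() {
  path <- system.file("extdata", "published_audit_counts.tsv",
                      package = "spliceCascade", mustWork = TRUE)
  read_audit(path)
}
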