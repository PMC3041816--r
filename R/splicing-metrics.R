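#' Normalized intensity of a probeset
#'
#' The normalized intensity (NI) is the ratio of a probeset's intensity to
#' its gene's intensity, which removes gene-level expression change from the
#' exon-level signal. The ratio is formed per replicate and then averaged
#' over the biological duplicates.
#'
#' @param panel An [intensity_panel()].
#' @param probeset_id Probeset identifier.
#' @param timepoint One of `"d0"`, `"d7"`, `"d10"`.
#' @return Mean NI over replicates (nonnegative scalar).
#' @examples
#' # probeset at half its gene's level in both replicates -> NI = 0.5
#' @export
normalized_intensity <- function(panel, probeset_id, timepoint) {
  timepoint <- match.arg(timepoint, PANEL_TIMEPOINTS)
  gene_id <- panel$probeset_gene[[probeset_id]]
  if (is.null(gene_id) || is.na(gene_id)) {
    stop("unknown probeset: ", probeset_id)
  }
  cols <- tp_cols(timepoint)
  g <- panel$genes[gene_id, cols]
  if (any(g <= 0)) {
    stop("NI undefined: gene ", gene_id, " has nonpositive intensity at ",
         timepoint)
  }
  p <- panel$probesets[probeset_id, cols]
  mean(p / g)
}

#' Splicing index of a probeset
#'
#' The splicing index (SI) is the log2 ratio of the replicate-averaged NI at
#' a comparison timepoint over the reference timepoint. Large `|SI|`
#' indicates a change in exon usage beyond the gene-level expression change.
#' Swapping reference and comparison negates the value.
#'
#' @inheritParams normalized_intensity
#' @param comparison Comparison timepoint (`"d7"` or `"d10"`).
#' @param reference Reference timepoint (default `"d0"`).
#' @return SI in log2 units.
#' @export
splicing_index <- function(panel, probeset_id, comparison = c("d7", "d10"),
                           reference = "d0") {
  comparison <- match.arg(comparison, PANEL_TIMEPOINTS)
  reference <- match.arg(reference, PANEL_TIMEPOINTS)
  ni_ref <- normalized_intensity(panel, probeset_id, reference)
  ni_cmp <- normalized_intensity(panel, probeset_id, comparison)
  if (ni_ref <= 0 || ni_cmp <= 0) {
    stop("SI undefined for probeset ", probeset_id,
         ": NI is zero at ", if (ni_ref <= 0) reference else comparison)
  }
  log2(ni_cmp / ni_ref)
}

#' Convert a splicing index to a linear fold change
#'
#' @param si Splicing index in log2 units (vectorized).
#' @return `2^si`; e.g. the cascade's default SI threshold of 1.35
#'   corresponds to a 2.55-fold change of normalized intensity.
#' @examples
#' fold_from_si(1.35)  # ~2.55
#' @export
fold_from_si <- function(si) {
  stopifnot(is.numeric(si), all(is.finite(si)))
  2^si
}

#' A-value (average log2 intensity) of a probeset
#'
#' MA-plot style average intensity: the mean of `log2(probeset intensity)`
#' over the four day-0 and day-7 cells (two timepoints x two replicates).
#' Used as the x-axis of the SI-A scatter of all scored probesets.
#'
#' @inheritParams normalized_intensity
#' @return A-value in log2 intensity units.
#' @export
a_value <- function(panel, probeset_id) {
  cells <- panel$probesets[probeset_id, c(tp_cols("d0"), tp_cols("d7"))]
  if (any(cells <= 0)) {
    stop("A-value undefined for probeset ", probeset_id,
         ": nonpositive intensity at d0/d7")
  }
  mean(log2(cells))
}

#' Score every probeset in a panel
#'
#' Vectorized driver computing, per probeset: replicate-averaged NI at each
#' timepoint, `si_d7` and `si_d10` (log2 NI ratios versus day 0), their
#' absolute values, and the A-value. Probesets whose day-0/day-7 scores are
#' undefined (zero gene intensity or zero NI) are not scored; they are
#' itemized with a reason instead of raising, because the DABG-based filters
#' upstream are the pipeline's mechanism for excluding them. `si_d10` is
#' `NA` when the day-10 NI is undefined; the day-10 reversal filter removes
#' such probesets with a logged reason.
#'
#' @param panel An [intensity_panel()].
#' @return A list with `scores` (data frame: `probeset_id`, `gene_id`,
#'   `ni_d0`, `ni_d7`, `ni_d10`, `si_d7`, `si_d10`, `abs_si_d7`,
#'   `abs_si_d10`, `a_value`) and `failures` (data frame: `probeset_id`,
#'   `reason`).
#' @export
score_all <- function(panel) {
  ids <- rownames(panel$probesets)
  genes <- panel$probeset_gene[ids]
  gm <- panel$genes[genes, , drop = FALSE]
  pm <- panel$probesets

  ni_tp <- function(tp) {
    cols <- tp_cols(tp)
    g <- gm[, cols, drop = FALSE]
    r <- pm[, cols, drop = FALSE] / g
    r[g <= 0] <- NA_real_  # undefined ratio, not zero
    rowMeans(r)
  }
  ni_d0 <- ni_tp("d0"); ni_d7 <- ni_tp("d7"); ni_d10 <- ni_tp("d10")

  a_cells <- pm[, c(tp_cols("d0"), tp_cols("d7")), drop = FALSE]
  a_ok <- rowSums(a_cells <= 0) == 0L
  a_val <- ifelse(a_ok, rowMeans(log2(pmax(a_cells, .Machine$double.xmin))),
                  NA_real_)

  reason <- rep(NA_character_, length(ids))
  reason[is.na(ni_d0) | is.na(ni_d7)] <- "gene intensity nonpositive at d0/d7"
  undef <- is.na(reason) & (ni_d0 <= 0 | ni_d7 <= 0)
  reason[undef] <- "NI zero at d0/d7"
  reason[is.na(reason) & !a_ok] <- "nonpositive probeset intensity at d0/d7"
  ok <- is.na(reason)

  si_d7 <- log2(ni_d7[ok] / ni_d0[ok])
  si_d10 <- ifelse(!is.na(ni_d10[ok]) & ni_d10[ok] > 0,
                   log2(ni_d10[ok] / ni_d0[ok]), NA_real_)
  scores <- data.frame(
    probeset_id = ids[ok], gene_id = unname(genes[ok]),
    ni_d0 = unname(ni_d0[ok]), ni_d7 = unname(ni_d7[ok]),
    ni_d10 = unname(ni_d10[ok]),
    si_d7 = unname(si_d7), si_d10 = unname(si_d10),
    abs_si_d7 = abs(unname(si_d7)), abs_si_d10 = abs(unname(si_d10)),
    a_value = unname(a_val[ok]),
    stringsAsFactors = FALSE
  )
  failures <- data.frame(probeset_id = ids[!ok],
                         reason = reason[!ok],
                         stringsAsFactors = FALSE)
  rownames(scores) <- rownames(failures) <- NULL
  list(scores = scores, failures = failures)
}
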