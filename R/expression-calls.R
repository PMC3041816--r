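#' Probeset detection call at a timepoint
#'
#' A probeset counts as detected at a timepoint when its DABG p-value is at
#' or below `alpha` in both biological replicates. The both-replicates rule
#' is applied uniformly wherever detection is consulted (exon-level gate and
#' gene-expression fraction alike).
#'
#' @param panel An [intensity_panel()].
#' @param probeset_id Probeset identifier.
#' @param timepoint One of `"d0"`, `"d7"`, `"d10"`.
#' @param alpha Detection p-value cutoff (boundary inclusive; default 0.05).
#' @return Logical scalar.
#' @export
probeset_detected <- function(panel, probeset_id, timepoint, alpha = 0.05) {
  timepoint <- match.arg(timepoint, PANEL_TIMEPOINTS)
  if (!probeset_id %in% rownames(panel$dabg)) {
    stop("unknown probeset: ", probeset_id)
  }
  p <- panel$dabg[probeset_id, tp_cols(timepoint)]
  if (any(is.na(p))) stop("missing DABG replicate for probeset ", probeset_id)
  all(p <= alpha)
}

#' Detection calls for all probesets
#'
#' @inheritParams probeset_detected
#' @return Logical matrix, probesets x timepoints.
#' @export
detection_table <- function(panel, alpha = 0.05) {
  n <- nrow(panel$dabg)
  out <- matrix(NA, nrow = n, ncol = length(PANEL_TIMEPOINTS),
                dimnames = list(rownames(panel$dabg), PANEL_TIMEPOINTS))
  for (tp in PANEL_TIMEPOINTS) {
    out[, tp] <- rowSums(panel$dabg[, tp_cols(tp), drop = FALSE] <= alpha) ==
      length(PANEL_REPLICATES)
  }
  out
}

#' Gene "expressed" call at a timepoint
#'
#' A gene is expressed at a timepoint when at least `fraction` (default 50%)
#' of its annotated probesets are detected there ([probeset_detected()],
#' i.e. DABG p <= `alpha` in both replicates). The denominator is all
#' annotated probesets of the gene, independent of any cascade filtering.
#'
#' @inheritParams probeset_detected
#' @param annotation A [`probeset_annotation`][read_probeset_annotation].
#' @param gene_id Gene identifier.
#' @param fraction Minimum detected fraction (boundary inclusive).
#' @return Logical scalar.
#' @export
gene_expressed <- function(panel, annotation, gene_id, timepoint,
                           alpha = 0.05, fraction = 0.5) {
  timepoint <- match.arg(timepoint, PANEL_TIMEPOINTS)
  ps <- annotation$probeset_id[annotation$gene_id == gene_id]
  if (length(ps) == 0L) stop("gene absent from annotation: ", gene_id)
  det <- vapply(ps, probeset_detected, logical(1L),
                panel = panel, timepoint = timepoint, alpha = alpha)
  mean(det) >= fraction
}

gene_expressed_table <- function(panel, annotation, alpha = 0.05,
                                 fraction = 0.5) {
  det <- detection_table(panel, alpha)
  det <- det[annotation$probeset_id, , drop = FALSE]
  frac <- rowsum(det + 0, annotation$gene_id) /
    as.vector(table(annotation$gene_id)[sort(unique(annotation$gene_id))])
  frac >= fraction
}

#' Classify a gene's expression trajectory (DEX-up / DEX-down)
#'
#' A gene is DEX-up when its mean expression level rises between 2-fold and
#' 10-fold (both bounds inclusive) from day 0 to day 7 and then strictly
#' decreases from day 7 to day 10; DEX-down mirrors this (2- to 10-fold drop
#' to day 7, strict rise to day 10). Anything else is `"none"`. The rule is
#' purely ratio-based, so rescaling all levels leaves the class unchanged.
#'
#' @param d0,d7,d10 Positive mean gene intensity at each timepoint
#'   (vectorized).
#' @return Character vector in `c("up", "down", "none")`.
#' @examples
#' classify_dex(100, 300, 200)  # "up"
#' classify_dex(300, 100, 200)  # "down"
#' @export
classify_dex <- function(d0, d7, d10) {
  if (any(c(d0, d7, d10) <= 0)) stop("gene expression levels must be positive")
  up <- (d7 / d0 >= 2) & (d7 / d0 <= 10) & (d10 < d7)
  down <- (d0 / d7 >= 2) & (d0 / d7 <= 10) & (d10 > d7)
  out <- rep("none", length(up))
  out[up] <- "up"
  out[down] <- "down"
  out
}

#' Expression profile and DEX class for every gene in a panel
#'
#' Computes per gene the replicate-mean intensity at each timepoint, the
#' expressed calls, and the DEX class. Following the expressed-gene gate,
#' the DEX class is only assigned to genes expressed on day 0 or day 7 (or
#' both); others are `"none"`.
#'
#' @inheritParams gene_expressed
#' @return Data frame with one row per annotated gene: `gene_id`,
#'   `mean_d0`, `mean_d7`, `mean_d10`, `expressed_d0`, `expressed_d7`,
#'   `expressed_d10`, `dex_class`.
#' @export
gene_expression_profiles <- function(panel, annotation, alpha = 0.05,
                                     fraction = 0.5) {
  genes <- sort(unique(annotation$gene_id))
  gm <- panel$genes[genes, , drop = FALSE]
  means <- vapply(PANEL_TIMEPOINTS, function(tp) {
    rowMeans(gm[, tp_cols(tp), drop = FALSE])
  }, numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, PANEL_TIMEPOINTS))
  expressed <- gene_expressed_table(panel, annotation, alpha, fraction)
  expressed <- expressed[genes, , drop = FALSE]
  dex <- classify_dex(means[, "d0"], means[, "d7"], means[, "d10"])
  dex[!(expressed[, "d0"] | expressed[, "d7"])] <- "none"
  data.frame(
    gene_id = genes,
    mean_d0 = unname(means[, "d0"]), mean_d7 = unname(means[, "d7"]),
    mean_d10 = unname(means[, "d10"]),
    expressed_d0 = unname(expressed[, "d0"]),
    expressed_d7 = unname(expressed[, "d7"]),
    expressed_d10 = unname(expressed[, "d10"]),
    dex_class = dex,
    stringsAsFactors = FALSE
  )
}
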