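#' Cascade configuration
#'
#' Thresholds of the nine-stage extraction cascade. Defaults are the
#' reference screen's settings: splicing-index threshold 1.35 (2.55-fold of
#' normalized intensity), neighbor-change threshold 0.667, DABG detection
#' cutoff 0.05, probeset sequence-length bound 500 nt (exclusive: exactly
#' 500 is removed), gene-expressed probeset fraction 0.5.
#'
#' @param si_threshold Minimum `|si_d7|` to keep at stage 6 (inclusive);
#'   also the bound used by the stage-9 reversal clause.
#' @param neighbor_threshold `|si_d7|` at or above which a neighbor counts
#'   as "changed" at stage 7.
#' @param dabg_alpha DABG p-value cutoff for detection (inclusive).
#' @param max_seq_length Probesets with `seq_length >= max_seq_length` are
#'   removed at stage 2 (long probesets mostly indicate UTRs).
#' @param expressed_fraction Minimum fraction of a gene's probesets that
#'   must be detected for the gene to count as expressed.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(si_threshold = 1.35, neighbor_threshold = 0.667,
                           dabg_alpha = 0.05, max_seq_length = 500,
                           expressed_fraction = 0.5) {
  cfg <- list(si_threshold = si_threshold,
              neighbor_threshold = neighbor_threshold,
              dabg_alpha = dabg_alpha,
              max_seq_length = max_seq_length,
              expressed_fraction = expressed_fraction)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1L)))) {
    stop("all cascade thresholds must be positive scalars")
  }
  class(cfg) <- "cascade_config"
  cfg
}

#' Stage 1: remove terminal probesets
#'
#' Within each gene, removes every probeset whose start equals the gene's
#' minimum or maximum probeset start (outermost probesets often sit on
#' potential exons outside the gene body). All probesets tied at an extreme
#' start are removed. The extremes are computed from the full annotation,
#' so the filter is idempotent on any survivor set; genes with two or fewer
#' probesets lose all of them.
#'
#' @param ids Character vector of surviving probeset ids.
#' @param annotation A [`probeset_annotation`][read_probeset_annotation].
#' @return Surviving ids (subset of `ids`, input order preserved).
#' @export
filter_terminal_probesets <- function(ids, annotation) {
  minstart <- stats::ave(annotation$start, annotation$gene_id, FUN = min)
  maxstart <- stats::ave(annotation$start, annotation$gene_id, FUN = max)
  terminal <- annotation$probeset_id[annotation$start == minstart |
                                       annotation$start == maxstart]
  setdiff(ids, terminal)
}

#' Stage 2: remove long probesets
#'
#' Keeps probesets whose target-sequence length is strictly below the bound
#' (default 500 nt); long probesets mostly indicate untranslated regions.
#'
#' @inheritParams filter_terminal_probesets
#' @param max_seq_length Exclusive length bound.
#' @return Surviving ids.
#' @export
filter_long_probesets <- function(ids, annotation, max_seq_length = 500) {
  len <- stats::setNames(annotation$seq_length, annotation$probeset_id)
  ids[len[ids] < max_seq_length]
}

#' Stage 3: remove cross-hybridizing probesets
#'
#' @inheritParams filter_terminal_probesets
#' @return Ids whose `xhyb` flag is `FALSE`.
#' @export
filter_xhyb_probesets <- function(ids, annotation) {
  xh <- stats::setNames(annotation$xhyb, annotation$probeset_id)
  ids[!xh[ids]]
}

#' Stage 4: keep probesets of genes expressed on both day 0 and day 7
#'
#' @inheritParams filter_terminal_probesets
#' @param panel An [intensity_panel()].
#' @param alpha,fraction Detection cutoff and expressed fraction (see
#'   [gene_expressed()]).
#' @return Surviving ids.
#' @export
filter_expressed_genes <- function(ids, panel, annotation, alpha = 0.05,
                                   fraction = 0.5) {
  expressed <- gene_expressed_table(panel, annotation, alpha, fraction)
  ok_genes <- rownames(expressed)[expressed[, "d0"] & expressed[, "d7"]]
  gene_of <- stats::setNames(annotation$gene_id, annotation$probeset_id)
  ids[gene_of[ids] %in% ok_genes]
}

#' Stage 5: keep probesets detected on day 0 or day 7
#'
#' Detection requires DABG p at or below `alpha` in both replicates of the
#' timepoint; day 10 is not consulted.
#'
#' @inheritParams filter_expressed_genes
#' @return Surviving ids.
#' @export
filter_detected_probesets <- function(ids, panel, alpha = 0.05) {
  det <- detection_table(panel, alpha)
  ids[det[ids, "d0"] | det[ids, "d7"]]
}

#' Stage 6: keep probesets with a large day-7 splicing index
#'
#' @inheritParams filter_terminal_probesets
#' @param scores Scores data frame from [score_all()].
#' @param si_threshold Inclusive `|si_d7|` threshold.
#' @return Surviving ids.
#' @export
filter_splicing_index <- function(ids, scores, si_threshold = 1.35) {
  si <- stats::setNames(scores$si_d7, scores$probeset_id)
  missing <- setdiff(ids, names(si))
  if (length(missing) > 0L) {
    stop("splicing index undefined for survivor(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  ids[abs(si[ids]) >= si_threshold]
}

# Nearest detectable neighbors (by probeset start) of each id within the
# neighbor search space. Returns per id a list with up/down neighbor ids
# (NA when none exists on that side).
neighbor_map <- function(ids, search_space, annotation) {
  ann <- annotation[match(search_space, annotation$probeset_id), ,
                    drop = FALSE]
  start_of <- stats::setNames(annotation$start, annotation$probeset_id)
  gene_of <- stats::setNames(annotation$gene_id, annotation$probeset_id)
  ann <- ann[order(ann$start, ann$probeset_id), , drop = FALSE]
  by_gene <- split(ann, ann$gene_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    g <- gene_of[[id]]
    s <- start_of[[id]]
    space <- by_gene[[g]]
    up <- down <- NA_character_
    if (!is.null(space)) {
      before <- space[space$start < s & space$probeset_id != id, ]
      after <- space[space$start > s & space$probeset_id != id, ]
      if (nrow(before) > 0L) up <- before$probeset_id[nrow(before)]
      if (nrow(after) > 0L) down <- after$probeset_id[1L]
    }
    out[[id]] <- c(up = up, down = down)
  }
  out
}

#' Stage 7: neighbor-change rule
#'
#' For each candidate, the nearest detectable upstream and downstream
#' probesets of the same gene are located (by probeset start, within the
#' probesets surviving stages 1-3 and detected on day 0 or day 7). A
#' neighbor counts as "changed" when its `|si_d7|` is at or above
#' `neighbor_threshold`. The candidate is removed when both neighbors exist
#' and both changed, or when exactly one neighbor exists and it changed; a
#' candidate with no detectable neighbor is kept. A surviving candidate
#' therefore marks a border between alternative and constitutive exons.
#'
#' @inheritParams filter_splicing_index
#' @param panel An [intensity_panel()].
#' @param annotation A [`probeset_annotation`][read_probeset_annotation].
#' @param neighbor_threshold `|si_d7|` at or above which a neighbor counts
#'   as changed.
#' @param alpha DABG detection cutoff.
#' @param search_space Probeset ids eligible as neighbors. Defaults to the
#'   stage-1..3 survivors of `annotation` that are detected on day 0 or 7;
#'   pass explicitly inside a cascade run to avoid recomputation.
#' @param max_seq_length Stage-2 bound used when deriving the default
#'   search space.
#' @return Surviving ids.
#' @export
filter_neighbor_change <- function(ids, scores, panel, annotation,
                                   neighbor_threshold = 0.667, alpha = 0.05,
                                   search_space = NULL,
                                   max_seq_length = 500) {
  if (is.null(search_space)) {
    sp <- filter_terminal_probesets(annotation$probeset_id, annotation)
    sp <- filter_long_probesets(sp, annotation, max_seq_length)
    sp <- filter_xhyb_probesets(sp, annotation)
    search_space <- filter_detected_probesets(sp, panel, alpha)
  }
  si <- stats::setNames(scores$si_d7, scores$probeset_id)
  changed <- function(nb) {
    if (is.na(nb)) return(NA)  # no neighbor on this side
    s <- si[nb]
    !is.na(s) && abs(s) >= neighbor_threshold  # undefined SI: no evidence
  }
  nbs <- neighbor_map(ids, search_space, annotation)
  keep <- vapply(ids, function(id) {
    ch <- c(changed(nbs[[id]][["up"]]), changed(nbs[[id]][["down"]]))
    ch <- ch[!is.na(ch)]
    if (length(ch) == 0L) TRUE else !all(ch)
  }, logical(1L))
  ids[keep]
}

#' Stage 8: keep probesets predicted alternative against transcript models
#'
#' Runs [classify_probeset_splicing()] for each survivor against its gene's
#' transcript models and keeps those called alternative. Probesets of genes
#' without any transcript model cannot be predicted and are removed with a
#' logged reason.
#'
#' @inheritParams filter_terminal_probesets
#' @param gene_models A [gene_model_set()].
#' @return A list: `ids` (survivors), `calls` (data frame `probeset_id`,
#'   `as_types` comma-joined), `failures` (data frame `probeset_id`,
#'   `reason`).
#' @export
filter_alternative_exons <- function(ids, annotation, gene_models) {
  ann <- annotation[match(ids, annotation$probeset_id), , drop = FALSE]
  keep <- character(0L)
  types <- character(0L)
  fail_id <- character(0L)
  fail_reason <- character(0L)
  for (k in seq_along(ids)) {
    ps <- ann[k, ]
    txs <- gene_models[[ps$gene_id]]
    if (is.null(txs)) {
      fail_id <- c(fail_id, ps$probeset_id)
      fail_reason <- c(fail_reason, "no transcript model for gene")
      next
    }
    call <- classify_probeset_splicing(ps, txs)
    if (call$is_alternative) {
      keep <- c(keep, ps$probeset_id)
      types <- c(types, paste(call$event_types, collapse = ","))
    }
  }
  list(ids = keep,
       calls = data.frame(probeset_id = keep, as_types = types,
                          stringsAsFactors = FALSE),
       failures = data.frame(probeset_id = fail_id, reason = fail_reason,
                             stringsAsFactors = FALSE))
}

#' Stage 9: day-10 reversal rule
#'
#' Keeps a probeset when its day-7 effect exceeds its day-10 effect in
#' magnitude (`|si_d7| > |si_d10|`), or when the sign reverses strongly
#' between day 7 and day 10 (`si_d7 < 0` with `si_d10 >= si_threshold`, or
#' `si_d7 > 0` with `si_d10 <= -si_threshold`). Probesets whose day-10
#' splicing index is undefined are removed with a logged reason.
#'
#' @inheritParams filter_splicing_index
#' @param si_threshold Bound used by the sign-reversal clause.
#' @return A list: `ids` (survivors), `failures` (data frame).
#' @export
filter_d10_reversal <- function(ids, scores, si_threshold = 1.35) {
  s7 <- stats::setNames(scores$si_d7, scores$probeset_id)[ids]
  s10 <- stats::setNames(scores$si_d10, scores$probeset_id)[ids]
  undef <- is.na(s10)
  keep <- !undef & (abs(s7) > abs(s10) |
                      (s7 < 0 & s10 >= si_threshold) |
                      (s7 > 0 & s10 <= -si_threshold))
  list(ids = ids[keep],
       failures = data.frame(
         probeset_id = ids[undef],
         reason = rep("si_d10 undefined", sum(undef)),
         stringsAsFactors = FALSE))
}

#' Run the nine-stage DAS extraction cascade
#'
#' Applies the nine filters in order to every annotated probeset and audits
#' the surviving probeset and gene counts after each stage (stage 0 is the
#' input). Surviving candidates are labeled DAS-up (`si_d7 >= si_threshold`)
#' or DAS-down (`si_d7 <= -si_threshold`) and carry their splice scores and
#' predicted event types, sorted by gene id and probeset start.
#'
#' @param annotation A [`probeset_annotation`][read_probeset_annotation].
#' @param panel An [intensity_panel()] covering every annotated probeset.
#' @param gene_models A [gene_model_set()] for the annotated genes.
#' @param config A [cascade_config()].
#' @return A list of class `cascade_result`: `candidates` (data frame),
#'   `audit` (data frame `stage`, `description`, `n_probesets`, `n_genes`),
#'   `failures` (itemized removals with stage and reason), `stages`
#'   (named list of per-stage survivor id vectors), `scores`, `config`.
#' @export
run_cascade <- function(annotation, panel, gene_models,
                        config = cascade_config()) {
  not_in_panel <- setdiff(annotation$probeset_id, rownames(panel$probesets))
  if (length(not_in_panel) > 0L) {
    stop("annotation probeset(s) missing from panel: ",
         paste(utils::head(not_in_panel, 5L), collapse = ", "))
  }
  gene_of <- stats::setNames(annotation$gene_id, annotation$probeset_id)
  start_of <- stats::setNames(annotation$start, annotation$probeset_id)

  descriptions <- c(
    "input probesets",
    "remove first/last probeset of each gene",
    paste0("remove probesets with sequence length >= ",
           config$max_seq_length, " nt"),
    "remove cross-hybridizing probesets",
    "keep genes expressed on both day 0 and day 7",
    "keep probesets detected on day 0 or day 7",
    paste0("keep |si_d7| >= ", config$si_threshold),
    paste0("remove probesets whose detectable neighbors all changed ",
           "(|si_d7| >= ", config$neighbor_threshold, ")"),
    "keep probesets predicted alternative against transcript models",
    "keep probesets whose day-7 effect exceeds day 10"
  )

  stages <- vector("list", 10L)
  names(stages) <- paste0("stage", 0:9)
  stages[[1L]] <- annotation$probeset_id

  s <- stages[[1L]]
  s <- filter_terminal_probesets(s, annotation); stages[[2L]] <- s
  s <- filter_long_probesets(s, annotation, config$max_seq_length)
  stages[[3L]] <- s
  s <- filter_xhyb_probesets(s, annotation); stages[[4L]] <- s
  s <- filter_expressed_genes(s, panel, annotation, config$dabg_alpha,
                              config$expressed_fraction)
  stages[[5L]] <- s
  s <- filter_detected_probesets(s, panel, config$dabg_alpha)
  stages[[6L]] <- s

  scored <- score_all(panel)
  scores <- scored$scores
  failures <- data.frame(stage = integer(0L), probeset_id = character(0L),
                         reason = character(0L), stringsAsFactors = FALSE)

  s <- filter_splicing_index(s, scores, config$si_threshold)
  stages[[7L]] <- s

  search_space <- filter_detected_probesets(stages[[4L]], panel,
                                            config$dabg_alpha)
  s <- filter_neighbor_change(s, scores, panel, annotation,
                              config$neighbor_threshold, config$dabg_alpha,
                              search_space = search_space)
  stages[[8L]] <- s

  f8 <- filter_alternative_exons(s, annotation, gene_models)
  s <- f8$ids
  stages[[9L]] <- s
  if (nrow(f8$failures) > 0L) {
    failures <- rbind(failures,
                      cbind(stage = 8L, f8$failures))
  }

  f9 <- filter_d10_reversal(s, scores, config$si_threshold)
  s <- f9$ids
  stages[[10L]] <- s
  if (nrow(f9$failures) > 0L) {
    failures <- rbind(failures, cbind(stage = 9L, f9$failures))
  }

  audit <- data.frame(
    stage = 0:9,
    description = descriptions,
    n_probesets = vapply(stages, length, integer(1L)),
    n_genes = vapply(stages, function(ids) {
      length(unique(gene_of[ids]))
    }, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(audit) <- NULL

  sc <- scores[match(s, scores$probeset_id), , drop = FALSE]
  as_types <- stats::setNames(f8$calls$as_types, f8$calls$probeset_id)
  candidates <- data.frame(
    probeset_id = s,
    gene_id = unname(gene_of[s]),
    chrom = annotation$chrom[match(s, annotation$probeset_id)],
    start = unname(start_of[s]),
    si_d7 = sc$si_d7, si_d10 = sc$si_d10, a_value = sc$a_value,
    as_types = unname(as_types[s]),
    das_direction = ifelse(sc$si_d7 >= config$si_threshold, "up", "down"),
    stringsAsFactors = FALSE
  )
  candidates <- candidates[order(candidates$gene_id, candidates$start,
                                 candidates$probeset_id), , drop = FALSE]
  rownames(candidates) <- NULL

  structure(
    list(candidates = candidates, audit = audit, failures = failures,
         stages = stages, scores = scored, config = config),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("DAS extraction cascade:",
      x$audit$n_probesets[1L], "probesets ->",
      nrow(x$candidates), "candidates in",
      x$audit$n_genes[10L], "genes\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
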