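AS_EVENT_TYPES <- c("exon_skip", "alt_5ss", "alt_3ss", "retained_intron",
                    "mutually_exclusive", "alt_promoter", "alt_terminator")

#' Presence of an interval in a transcript's exons
#'
#' @param start,stop 1-based inclusive interval (e.g. a probeset's genomic
#'   span).
#' @param transcript A [transcript_model()].
#' @return `"contained"` if the interval lies within a single exon,
#'   `"partial"` if it overlaps at least one exon without being contained,
#'   `"absent"` otherwise.
#' @export
exon_presence <- function(start, stop, transcript) {
  ex <- transcript$exons
  contained <- any(ex$start <= start & stop <= ex$end)
  if (contained) return("contained")
  overlap <- any(ex$start <= stop & start <= ex$end)
  if (overlap) "partial" else "absent"
}

# First exon of a transcript in transcription order.
first_exon_idx <- function(transcript) {
  if (transcript$strand == "+") 1L else nrow(transcript$exons)
}
last_exon_idx <- function(transcript) {
  if (transcript$strand == "+") nrow(transcript$exons) else 1L
}

exon_identical_in <- function(exon, other_exons) {
  any(other_exons$start == exon$start & other_exons$end == exon$end)
}

overlaps_any <- function(exon, other_exons) {
  any(other_exons$start <= exon$end & exon$start <= other_exons$end)
}

# Is exon `i` of transcript `ts` skipped in transcript `te`? True when the
# exon overlaps no exon of `te` while its flanking exons in `ts` (where they
# exist) are present in `te` with identical coordinates.
exon_skipped_in <- function(ts, i, te) {
  e <- ts$exons[i, ]
  if (overlaps_any(e, te$exons)) return(FALSE)
  ok <- TRUE
  if (i > 1L) ok <- ok && exon_identical_in(ts$exons[i - 1L, ], te$exons)
  if (i < nrow(ts$exons)) {
    ok <- ok && exon_identical_in(ts$exons[i + 1L, ], te$exons)
  }
  ok
}

# Event types for containing exon `i` of transcript `ts` against excluding
# transcript `te`. Strand-aware 5'/3' naming: on '+' the genomic-right edge
# of an exon is its 5' splice-site (donor) side, on '-' the genomic-left.
event_types_pair <- function(ts, i, te) {
  types <- character(0L)
  e <- ts$exons[i, ]
  strand <- ts$strand

  skipped <- exon_skipped_in(ts, i, te)
  if (skipped) types <- c(types, "exon_skip")

  # mutually exclusive: skip holds in both directions for a non-overlapping
  # exon pair between the two transcripts
  if (skipped) {
    for (j in seq_len(nrow(te$exons))) {
      ej <- te$exons[j, ]
      if (ej$start <= e$end && e$start <= ej$end) next
      if (exon_skipped_in(te, j, ts)) {
        types <- c(types, "mutually_exclusive")
        break
      }
    }
  }

  # alternative donor/acceptor: an exon of `te` shares exactly one boundary
  share_start <- te$exons$start == e$start & te$exons$end != e$end
  share_end <- te$exons$end == e$end & te$exons$start != e$start
  if (any(share_start)) {
    # genomic-right edge shifts
    types <- c(types, if (strand == "+") "alt_5ss" else "alt_3ss")
  }
  if (any(share_end)) {
    # genomic-left edge shifts
    types <- c(types, if (strand == "+") "alt_3ss" else "alt_5ss")
  }

  # retained intron: the containing exon spans an intron of `te`, i.e. both
  # exons flanking that intron fall within the containing exon's span
  if (nrow(te$exons) > 1L) {
    for (j in seq_len(nrow(te$exons) - 1L)) {
      a <- te$exons[j, ]; b <- te$exons[j + 1L, ]
      if (e$start <= a$start && a$end <= e$end &&
          e$start <= b$start && b$end <= e$end) {
        types <- c(types, "retained_intron")
        break
      }
    }
  }

  # differential first/last exon usage
  if (i == first_exon_idx(ts)) {
    fe <- te$exons[first_exon_idx(te), ]
    if (!(fe$start <= e$end && e$start <= fe$end)) {
      types <- c(types, "alt_promoter")
    }
  }
  if (i == last_exon_idx(ts)) {
    le <- te$exons[last_exon_idx(te), ]
    if (!(le$start <= e$end && e$start <= le$end)) {
      types <- c(types, "alt_terminator")
    }
  }

  unique(types)
}

#' Classify a probeset as alternative or constitutive
#'
#' Annotation-based alternative-exon prediction: a probeset is alternative
#' when its interval is contained in an exon of at least one of its gene's
#' transcripts and absent from (or only partially overlapping the exons of)
#' at least one other. Event types are assigned by comparing the containing
#' exon against each excluding transcript: cassette exon (`exon_skip`),
#' alternative 5'/3' splice site (one shared exon boundary; strand-aware
#' naming), retained intron, mutually exclusive exons, and alternative
#' promoter/terminator (differential strand-aware first/last exon). Complex
#' patterns that satisfy the presence rule without matching a named
#' geometry fall back to `exon_skip`, the coarsest inclusion/exclusion
#' label, so an alternative call always carries at least one type.
#'
#' @param probeset One-row slice of a
#'   [`probeset_annotation`][read_probeset_annotation] (or any list with
#'   `probeset_id`, `gene_id`, `start`, `stop`).
#' @param transcripts List of [transcript_model()] objects, all from the
#'   probeset's gene.
#' @return A list of class `as_call`: `probeset_id`, `is_alternative`,
#'   `event_types`, `supporting_transcripts`, `excluding_transcripts`.
#' @export
classify_probeset_splicing <- function(probeset, transcripts) {
  if (length(transcripts) < 1L) stop("at least one transcript is required")
  tx_genes <- vapply(transcripts, function(t) t$gene_id, character(1L))
  if (any(tx_genes != probeset$gene_id)) {
    stop("transcript(s) from a different gene than probeset ",
         probeset$probeset_id)
  }
  presence <- vapply(transcripts, function(t) {
    exon_presence(probeset$start, probeset$stop, t)
  }, character(1L))
  sup <- which(presence == "contained")
  exc <- which(presence != "contained")
  is_alt <- length(sup) > 0L && length(exc) > 0L
  types <- character(0L)
  if (is_alt) {
    for (si in sup) {
      ts <- transcripts[[si]]
      i <- which(ts$exons$start <= probeset$start &
                   probeset$stop <= ts$exons$end)[1L]
      for (ei in exc) {
        types <- union(types, event_types_pair(ts, i, transcripts[[ei]]))
      }
    }
    if (length(types) == 0L) types <- "exon_skip"  # coarse fallback
  }
  structure(
    list(
      probeset_id = probeset$probeset_id,
      is_alternative = is_alt,
      event_types = intersect(AS_EVENT_TYPES, types),
      supporting_transcripts =
        vapply(transcripts[sup], function(t) t$transcript_id, character(1L)),
      excluding_transcripts =
        vapply(transcripts[exc], function(t) t$transcript_id, character(1L))
    ),
    class = "as_call"
  )
}

#' Summarize event-type composition over a set of calls
#'
#' Percentage breakdown of event types among alternative calls. A probeset
#' carrying `k` types contributes `1/k` to each (fractional attribution),
#' so the percentages sum to 100 whenever any alternative call exists.
#'
#' @param calls List of `as_call` objects (see
#'   [classify_probeset_splicing()]).
#' @return Data frame `event_type`, `weight`, `percent`, sorted by
#'   decreasing percentage; zero rows when no call is alternative.
#' @export
summarize_as_types <- function(calls) {
  alt <- Filter(function(cl) isTRUE(cl$is_alternative), calls)
  if (length(alt) == 0L) {
    return(data.frame(event_type = character(0L), weight = numeric(0L),
                      percent = numeric(0L), stringsAsFactors = FALSE))
  }
  w <- stats::setNames(numeric(length(AS_EVENT_TYPES)), AS_EVENT_TYPES)
  for (cl in alt) {
    k <- length(cl$event_types)
    w[cl$event_types] <- w[cl$event_types] + 1 / k
  }
  w <- w[w > 0]
  out <- data.frame(event_type = names(w), weight = unname(w),
                    percent = 100 * unname(w) / length(alt),
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$event_type), , drop = FALSE]
}
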