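#' Read a probeset annotation table
#'
#' Reads the static probeset annotation: one row per probeset with its gene
#' membership, genomic interval, the length of the probeset target sequence
#' (which may differ from the genomic span and is the quantity the length
#' filter uses), and the cross-hybridization flag. The delimiter (comma or
#' tab) is sniffed from the header line. Coordinates are 1-based inclusive,
#' the convention used throughout the package.
#'
#' @param path Path to a delimited text file with header columns
#'   `probeset_id`, `gene_id`, `chrom`, `start`, `stop`, `strand`,
#'   `seq_length`, `xhyb`.
#' @return A `data.frame` of class `probeset_annotation` with one row per
#'   probeset; `xhyb` is logical, coordinates are integer.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("probeset_id,gene_id,chrom,start,stop,strand,seq_length,xhyb",
#'              "ps1,g1,chr1,101,200,+,100,false"), tf)
#' read_probeset_annotation(tf)
#' @export
read_probeset_annotation <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("annotation file is empty: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", colClasses = "character")
  required <- c("probeset_id", "gene_id", "chrom", "start", "stop",
                "strand", "seq_length", "xhyb")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("annotation file missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$start <- as.integer(df$start)
  df$stop <- as.integer(df$stop)
  df$seq_length <- as.integer(df$seq_length)
  df$xhyb <- parse_logical_tokens(df$xhyb, "xhyb")
  as_probeset_annotation(df)
}

parse_logical_tokens <- function(x, column) {
  tok <- tolower(trimws(x))
  out <- rep(NA, length(tok))
  out[tok %in% c("true", "t", "1", "yes")] <- TRUE
  out[tok %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("non-boolean ", column, " token '", x[bad[1L]],
         "' at data row ", bad[1L])
  }
  out
}

#' Construct/validate a probeset annotation
#'
#' Validates the annotation invariants: unique probeset ids, positive
#' sequence lengths, `start <= stop` (1-based inclusive intervals), strand in
#' `+`/`-`. Each probeset belongs to exactly one gene because the table has
#' one row per probeset.
#'
#' @param df A data.frame with the annotation columns (see
#'   [read_probeset_annotation()]).
#' @return The validated data.frame with class `probeset_annotation`.
#' @export
as_probeset_annotation <- function(df) {
  dup <- duplicated(df$probeset_id)
  if (any(dup)) {
    stop("duplicate probeset_id in annotation: ",
         paste(unique(df$probeset_id[dup]), collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(is.na(df$start)) || any(is.na(df$stop))) {
      stop("non-numeric start/stop coordinate in annotation")
    }
    if (any(df$start > df$stop)) {
      stop("annotation interval with start > stop for probeset: ",
           df$probeset_id[which(df$start > df$stop)[1L]])
    }
    if (any(is.na(df$seq_length)) || any(df$seq_length <= 0L)) {
      stop("seq_length must be a positive integer for every probeset")
    }
    if (!all(df$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-' for every probeset")
    }
    if (!is.logical(df$xhyb) || any(is.na(df$xhyb))) {
      stop("xhyb must be TRUE/FALSE for every probeset")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("probeset_annotation", "data.frame")
  df
}
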