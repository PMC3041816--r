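#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start` and `end` columns, 1-based inclusive.
#'   Exons are sorted by start and must not overlap.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[c("start", "end")]
  if (nrow(exons) < 1L) stop("transcript must have at least one exon")
  if (any(exons$start > exons$end)) {
    stop("exon with start > end in transcript ", transcript_id)
  }
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("overlapping exons within transcript ", transcript_id)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "transcript_model"
  )
}

#' Group transcript models by gene
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return Named list (by gene id) of transcript lists, class
#'   `gene_model_set`.
#' @export
gene_model_set <- function(transcripts) {
  genes <- vapply(transcripts, function(t) t$gene_id, character(1L))
  out <- split(transcripts, genes)
  for (g in names(out)) {
    strands <- unique(vapply(out[[g]], function(t) t$strand, character(1L)))
    chroms <- unique(vapply(out[[g]], function(t) t$chrom, character(1L)))
    if (length(strands) > 1L || length(chroms) > 1L) {
      stop("transcripts of gene ", g, " disagree on strand or chromosome")
    }
  }
  structure(out, class = "gene_model_set")
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are consulted; each must carry `gene_id` and
#' `transcript_id` attributes. Exons are grouped per transcript and sorted
#' in genomic order. A transcript id that appears in the file without any
#' exon feature is skipped with a warning; overlapping exons within one
#' transcript are an error.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return A [gene_model_set()].
#' @export
read_transcript_models <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ",
                             conditionMessage(e))
  )
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% colnames(meta))) {
    stop("GTF must carry type, gene_id and transcript_id attributes")
  }
  is_exon <- as.character(meta$type) == "exon"
  all_tx <- unique(stats::na.omit(as.character(meta$transcript_id)))
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  no_exon <- setdiff(all_tx, unique(as.character(exm$transcript_id)))
  if (length(no_exon) > 0L) {
    warning("skipping transcript(s) with no exon features: ",
            paste(no_exon, collapse = ", "))
  }
  if (length(ex) == 0L) stop("GTF contains no exon features")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(exm$gene_id),
    transcript_id = as.character(exm$transcript_id),
    stringsAsFactors = FALSE
  )
  txs <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], d[c("start", "end")])
  })
  gene_model_set(unname(txs))
}

#' Write transcript models to a GTF file
#'
#' @param models A [gene_model_set()].
#' @param path Output GTF path.
#' @return Invisibly, `models`.
#' @export
write_transcript_models <- function(models, path) {
  rows <- do.call(rbind, lapply(unlist(unname(models), recursive = FALSE),
    function(t) {
      data.frame(chrom = t$chrom, start = t$exons$start, end = t$exons$end,
                 strand = t$strand, gene_id = t$gene_id,
                 transcript_id = t$transcript_id, stringsAsFactors = FALSE)
    }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "spliceCascade"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(models)
}
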