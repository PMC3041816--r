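#' Assemble an intensity panel
#'
#' An intensity panel bundles the three matrices the pipeline consumes:
#' probeset-level intensities, gene-level intensities and DABG (detection
#' above background) p-values, all over the fixed grid of three timepoints
#' (`d0`, `d7`, `d10`) with two biological replicates (`r1`, `r2`), plus the
#' probeset-to-gene map. Column order is `d0_r1, d0_r2, d7_r1, d7_r2,
#' d10_r1, d10_r2` in every matrix.
#'
#' Intensities must be nonnegative and DABG p-values in `[0, 1]`. In normal
#' operation gene intensities are strictly positive (they are summarized
#' over many probes); zero gene intensities are tolerated at construction so
#' that downstream scoring can itemize the resulting undefined ratios
#' instead of the constructor masking them.
#'
#' @param probesets Numeric matrix, probesets x 6 panel columns, rownames =
#'   probeset ids.
#' @param genes Numeric matrix, genes x 6 panel columns, rownames = gene ids.
#' @param dabg Numeric matrix of DABG p-values, same shape/rownames as
#'   `probesets`.
#' @param probeset_gene Named character vector mapping probeset id -> gene id.
#' @return An object of class `intensity_panel`.
#' @export
intensity_panel <- function(probesets, genes, dabg, probeset_gene) {
  probesets <- as.matrix(probesets)
  genes <- as.matrix(genes)
  dabg <- as.matrix(dabg)
  cols <- panel_columns()
  for (nm in list(c("probeset intensity", "probesets"),
                  c("gene intensity", "genes"),
                  c("dabg", "dabg"))) {
    m <- get(nm[2L])
    if (!all(cols %in% colnames(m))) {
      stop(nm[1L], " table must have columns ", paste(cols, collapse = ", "))
    }
  }
  probesets <- probesets[, cols, drop = FALSE]
  genes <- genes[, cols, drop = FALSE]
  dabg <- dabg[, cols, drop = FALSE]
  if (any(probesets < 0)) stop("negative probeset intensity")
  if (any(genes < 0)) stop("negative gene intensity")
  if (any(dabg < 0 | dabg > 1)) stop("DABG p-value outside [0, 1]")
  if (!identical(sort(rownames(probesets)), sort(rownames(dabg)))) {
    stop("probeset intensity and DABG tables list different probesets")
  }
  dabg <- dabg[rownames(probesets), , drop = FALSE]
  missing_map <- setdiff(rownames(probesets), names(probeset_gene))
  if (length(missing_map) > 0L) {
    stop("no gene mapping for probeset(s): ",
         paste(utils::head(missing_map, 5L), collapse = ", "))
  }
  probeset_gene <- probeset_gene[rownames(probesets)]
  missing_gene <- setdiff(unique(probeset_gene), rownames(genes))
  if (length(missing_gene) > 0L) {
    stop("gene intensity table missing gene(s) of listed probesets: ",
         paste(utils::head(missing_gene, 5L), collapse = ", "))
  }
  structure(
    list(probesets = probesets, genes = genes, dabg = dabg,
         probeset_gene = probeset_gene,
         timepoints = PANEL_TIMEPOINTS, replicates = PANEL_REPLICATES),
    class = "intensity_panel"
  )
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat("intensity_panel:", nrow(x$probesets), "probesets,",
      nrow(x$genes), "genes,",
      length(x$timepoints), "timepoints x",
      length(x$replicates), "replicates\n")
  invisible(x)
}

#' Read an intensity panel from three wide tables
#'
#' Each table is tab-delimited with an id first column and then the six
#' panel columns `d0_r1 ... d10_r2`. The annotation supplies the
#' probeset-to-gene map and drives the consistency check that every listed
#' probeset's gene is present in the gene-level table.
#'
#' @param probeset_path,gene_path,dabg_path Paths to the probeset-intensity,
#'   gene-intensity and DABG p-value tables.
#' @param annotation A [`probeset_annotation`][read_probeset_annotation]
#'   covering every probeset in the tables.
#' @return An [intensity_panel()].
#' @export
read_intensity_panel <- function(probeset_path, gene_path, dabg_path,
                                 annotation) {
  read_wide <- function(path, what) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    cols <- panel_columns()
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L) {
      stop(what, " table missing column(s): ", paste(missing, collapse = ", "))
    }
    ids <- df[[1L]]
    if (anyDuplicated(ids)) stop("duplicate id in ", what, " table")
    m <- as.matrix(df[cols])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  probesets <- read_wide(probeset_path, "probeset intensity")
  genes <- read_wide(gene_path, "gene intensity")
  dabg <- read_wide(dabg_path, "DABG")
  if (any(genes <= 0)) stop("gene intensity table contains nonpositive values")
  unknown <- setdiff(rownames(probesets), annotation$probeset_id)
  if (length(unknown) > 0L) {
    stop("probeset(s) absent from annotation: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  map <- stats::setNames(annotation$gene_id, annotation$probeset_id)
  intensity_panel(probesets, genes, dabg, map[rownames(probesets)])
}

#' Write the three panel tables of an intensity panel
#'
#' Inverse of [read_intensity_panel()]; numeric cells are written with full
#' precision so a write/read round trip reproduces the panel bit-exactly.
#'
#' @param panel An [intensity_panel()].
#' @param probeset_path,gene_path,dabg_path Output paths.
#' @return Invisibly, `panel`.
#' @export
write_intensity_panel <- function(panel, probeset_path, gene_path, dabg_path) {
  write_wide <- function(m, id_name, path) {
    df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
    names(df) <- id_name
    for (cn in colnames(m)) df[[cn]] <- sprintf("%.17g", m[, cn])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_wide(panel$probesets, "probeset_id", probeset_path)
  write_wide(panel$genes, "gene_id", gene_path)
  write_wide(panel$dabg, "probeset_id", dabg_path)
  invisible(panel)
}
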