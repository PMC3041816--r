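#' Simulation configuration
#'
#' Parameters of the synthetic exon-array generator. Defaults define the
#' standard evaluation regime: 500 genes, 10% carrying one true DAS
#' (cassette) exon with a day-7 normalized-intensity effect of 2 log2
#' units, 30% of which is retained at day 10, multiplicative log-normal
#' noise with a 10% coefficient of variation, and small fractions of
#' cross-hybridizing and long (>= 500 nt) probesets so the annotation
#' filters have work to do.
#'
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Integer range (length 2) of transcripts for
#'   constitutive genes; when 2, the second transcript has identical
#'   structure. DAS genes always get a full transcript plus one skipping
#'   the alternative exon.
#' @param exons_per_transcript Integer range of exon counts (DAS genes are
#'   given at least 3 so the alternative exon can be internal).
#' @param probesets_per_exon Integer range of probesets per exon.
#' @param das_fraction Fraction of genes given a true DAS exon.
#' @param delta_si True day-7 splicing-index effect in log2 units (sign is
#'   drawn per event); must be nonzero when `das_fraction > 0`.
#' @param d10_relaxation Fraction of the day-7 effect retained at day 10,
#'   in `[0, 1)`.
#' @param dex_up_fraction,dex_down_fraction Fractions of genes given
#'   DEX-up / DEX-down expression trajectories (disjoint from DAS genes).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied independently to every intensity cell.
#' @param detect_floor Noise-free signal below which a DABG p-value is
#'   drawn from the non-significant regime (`Uniform(0.1, 1)`), otherwise
#'   from the detected regime (`Uniform(0, 0.01)`).
#' @param xhyb_fraction Fraction of non-DAS probesets flagged
#'   cross-hybridizing.
#' @param long_probeset_fraction Fraction of non-DAS probesets given a
#'   target-sequence length of at least 500 nt.
#' @param seed Integer random seed; identical configurations (including the
#'   seed) generate bit-identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       transcripts_per_gene = c(1L, 2L),
                       exons_per_transcript = c(4L, 8L),
                       probesets_per_exon = c(1L, 2L),
                       das_fraction = 0.1,
                       delta_si = 2.0,
                       d10_relaxation = 0.3,
                       dex_up_fraction = 0.1,
                       dex_down_fraction = 0.05,
                       noise_cv = 0.1,
                       detect_floor = 10,
                       xhyb_fraction = 0.05,
                       long_probeset_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              probesets_per_exon = as.integer(probesets_per_exon),
              das_fraction = das_fraction, delta_si = delta_si,
              d10_relaxation = d10_relaxation,
              dex_up_fraction = dex_up_fraction,
              dex_down_fraction = dex_down_fraction,
              noise_cv = noise_cv, detect_floor = detect_floor,
              xhyb_fraction = xhyb_fraction,
              long_probeset_fraction = long_probeset_fraction,
              seed = as.integer(seed))
  fracs <- c(cfg$das_fraction, cfg$dex_up_fraction, cfg$dex_down_fraction,
             cfg$xhyb_fraction, cfg$long_probeset_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$das_fraction + cfg$dex_up_fraction + cfg$dex_down_fraction > 1) {
    stop("das_fraction + dex_up_fraction + dex_down_fraction must be <= 1")
  }
  if (cfg$das_fraction > 0 && cfg$delta_si == 0) {
    stop("delta_si must be nonzero when das_fraction > 0")
  }
  if (cfg$d10_relaxation < 0 || cfg$d10_relaxation >= 1) {
    stop("d10_relaxation must lie in [0, 1)")
  }
  if (cfg$n_genes < 0) stop("n_genes must be nonnegative")
  for (r in c("transcripts_per_gene", "exons_per_transcript",
              "probesets_per_exon")) {
    if (length(cfg[[r]]) != 2L || any(cfg[[r]] < 1L) ||
        cfg[[r]][1L] > cfg[[r]][2L]) {
      stop(r, " must be an increasing integer range of length 2")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

sample_range <- function(r) {
  if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
}

# log-normal noise factors with unit mean and the requested CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a complete synthetic exon-array dataset
#'
#' Generates annotation, transcript models, an intensity panel and the
#' ground truth behind them. Gene intensities are baseline x trajectory x
#' log-normal noise; probeset intensities are gene intensity x probeset
#' affinity x NI(t) x log-normal noise, where the normalized-intensity
#' multiplier NI(t) is 1 everywhere for constitutive probesets and shifts
#' by `2^delta_si` at day 7 (partially retained at day 10 per
#' `d10_relaxation`, direction drawn per event) for probesets on a true DAS
#' exon. Every DAS exon is realized as a cassette exon: the gene carries a
#' full-length transcript and a second transcript skipping that exon, so
#' the alternative-exon filter can rediscover it. DABG p-values follow a
#' two-regime uniform model around `detect_floor`. Terminal probesets
#' exist by construction (every gene's outermost probesets), and the
#' configured fractions of long and cross-hybridizing probesets are
#' assigned among non-DAS probesets.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `annotation`
#'   ([`probeset_annotation`][as_probeset_annotation]), `models`
#'   ([gene_model_set()]), `panel` ([intensity_panel()]), `truth` (list
#'   with `das` data frame of `probeset_id`, `gene_id`, `direction`;
#'   `dex_up`/`dex_down` gene id vectors; `ni` data frame of true NI
#'   multipliers per timepoint), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes

  if (ng == 0L) {
    empty_mat <- matrix(numeric(0L), nrow = 0L, ncol = 6L,
                        dimnames = list(character(0L), panel_columns()))
    return(structure(list(
      annotation = as_probeset_annotation(data.frame(
        probeset_id = character(0L), gene_id = character(0L),
        chrom = character(0L), start = integer(0L), stop = integer(0L),
        strand = character(0L), seq_length = integer(0L),
        xhyb = logical(0L), stringsAsFactors = FALSE)),
      models = structure(list(), class = "gene_model_set"),
      panel = intensity_panel(empty_mat, empty_mat, empty_mat,
                              stats::setNames(character(0L), character(0L))),
      truth = list(das = data.frame(probeset_id = character(0L),
                                    gene_id = character(0L),
                                    direction = integer(0L),
                                    stringsAsFactors = FALSE),
                   dex_up = character(0L), dex_down = character(0L),
                   ni = data.frame(probeset_id = character(0L),
                                   ni_d0 = numeric(0L), ni_d7 = numeric(0L),
                                   ni_d10 = numeric(0L),
                                   stringsAsFactors = FALSE)),
      config = config), class = "sim_dataset"))
  }

  n_das <- round(ng * config$das_fraction)
  n_up <- round(ng * config$dex_up_fraction)
  n_down <- round(ng * config$dex_down_fraction)
  if (n_das + n_up + n_down > ng) {
    stop("configuration demands more special genes than genes")
  }
  role <- rep("none", ng)
  ord <- sample.int(ng)
  role[ord[seq_len(n_das)]] <- "das"
  if (n_up > 0L) role[ord[n_das + seq_len(n_up)]] <- "dex_up"
  if (n_down > 0L) role[ord[n_das + n_up + seq_len(n_down)]] <- "dex_down"

  gene_ids <- sprintf("g%05d", seq_len(ng))
  chroms <- paste0("chr", (seq_len(ng) - 1L) %% 19L + 1L)

  ann_list <- vector("list", ng)
  tx_list <- list()
  truth_das <- list()
  ni_mult <- list()  # per gene: probesets x 3 true NI multipliers
  affin <- list()
  traj <- matrix(1, nrow = ng, ncol = 3L,
                 dimnames = list(gene_ids, PANEL_TIMEPOINTS))

  for (g in seq_len(ng)) {
    gid <- gene_ids[g]
    n_ex <- sample_range(config$exons_per_transcript)
    is_das <- role[g] == "das"
    if (is_das) n_ex <- max(n_ex, 3L)
    offset <- ((g - 1L) %/% 19L) * 1000000L + 1L
    widths <- sample(80:300, n_ex, replace = TRUE)
    starts <- offset + (seq_len(n_ex) - 1L) * 1000L
    ends <- starts + widths - 1L
    strand <- sample(c("+", "-"), 1L)
    exons <- data.frame(start = starts, end = ends)

    # probesets tile each exon left to right without overlap
    ps_rows <- list()
    for (e in seq_len(n_ex)) {
      k <- sample_range(config$probesets_per_exon)
      w <- widths[e] %/% k
      for (j in seq_len(k)) {
        ps_start <- starts[e] + (j - 1L) * w
        ps_stop <- if (j == k) ends[e] else ps_start + w - 1L
        ps_rows[[length(ps_rows) + 1L]] <-
          data.frame(exon = e, start = ps_start, stop = ps_stop)
      }
    }
    ps <- do.call(rbind, ps_rows)
    ps$probeset_id <- sprintf("%s_ps%02d", gid, seq_len(nrow(ps)))
    ps$seq_length <- sample(60:400, nrow(ps), replace = TRUE)
    ps$xhyb <- FALSE

    # transcript structure
    alt_exon <- NA_integer_
    if (is_das) {
      alt_exon <- sample(2:(n_ex - 1L), 1L)
      tx_list[[length(tx_list) + 1L]] <- transcript_model(
        paste0(gid, "_t1"), gid, chroms[g], strand, exons)
      tx_list[[length(tx_list) + 1L]] <- transcript_model(
        paste0(gid, "_t2"), gid, chroms[g], strand,
        exons[-alt_exon, , drop = FALSE])
    } else {
      n_tx <- sample_range(config$transcripts_per_gene)
      for (t in seq_len(n_tx)) {
        tx_list[[length(tx_list) + 1L]] <- transcript_model(
          sprintf("%s_t%d", gid, t), gid, chroms[g], strand, exons)
      }
    }

    # true NI multipliers
    m <- matrix(1, nrow = nrow(ps), ncol = 3L)
    if (is_das) {
      dir <- sample(c(-1L, 1L), 1L)
      on_alt <- ps$exon == alt_exon
      m[on_alt, 2L] <- 2^(dir * config$delta_si)
      m[on_alt, 3L] <- 2^(dir * config$delta_si * config$d10_relaxation)
      truth_das[[length(truth_das) + 1L]] <- data.frame(
        probeset_id = ps$probeset_id[on_alt], gene_id = gid,
        direction = dir, stringsAsFactors = FALSE)
    }
    ni_mult[[g]] <- m
    affin[[g]] <- exp(stats::rnorm(nrow(ps), 0, 0.25))

    # expression trajectory
    if (role[g] == "dex_up") {
      f <- stats::runif(1L, 2.5, 8)
      traj[g, ] <- c(1, f, f * stats::runif(1L, 0.3, 0.8))
    } else if (role[g] == "dex_down") {
      f <- stats::runif(1L, 2.5, 8)
      traj[g, ] <- c(1, 1 / f, (1 / f) * stats::runif(1L, 1.5, 2.5))
    }

    ann_list[[g]] <- data.frame(
      probeset_id = ps$probeset_id, gene_id = gid, chrom = chroms[g],
      start = ps$start, stop = ps$stop, strand = strand,
      seq_length = ps$seq_length, xhyb = ps$xhyb, stringsAsFactors = FALSE)
  }

  annotation <- do.call(rbind, ann_list)

  # baselines: wide log-normal dynamic range; DAS/DEX genes floored well
  # above the detection floor so their gates hold by construction
  baseline <- exp(stats::rnorm(ng, log(100), 1.5))
  special <- role != "none"
  baseline[special] <- pmax(baseline[special], 20 * config$detect_floor)

  # assign long / cross-hybridizing flags among non-DAS probesets
  das_ps <- if (length(truth_das) > 0L) {
    do.call(rbind, truth_das)$probeset_id
  } else character(0L)
  eligible <- setdiff(annotation$probeset_id, das_ps)
  n_long <- round(length(eligible) * config$long_probeset_fraction)
  n_xh <- round(length(eligible) * config$xhyb_fraction)
  pick <- sample(eligible, min(length(eligible), n_long + n_xh))
  long_ids <- pick[seq_len(n_long)]
  xh_ids <- setdiff(pick, long_ids)
  annotation$seq_length[annotation$probeset_id %in% long_ids] <-
    sample(500:2000, length(long_ids), replace = TRUE)
  annotation$xhyb[annotation$probeset_id %in% xh_ids] <- TRUE

  # intensities
  gene_mat <- matrix(0, nrow = ng, ncol = 6L,
                     dimnames = list(gene_ids, panel_columns()))
  for (t in 1:3) {
    for (r in 1:2) {
      gene_mat[, (t - 1L) * 2L + r] <-
        baseline * traj[, t] * lnoise(ng, config$noise_cv)
    }
  }

  n_ps <- nrow(annotation)
  ps_gene_idx <- match(annotation$gene_id, gene_ids)
  aff_vec <- unlist(affin)
  ni_all <- do.call(rbind, ni_mult)
  ps_mat <- matrix(0, nrow = n_ps, ncol = 6L,
                   dimnames = list(annotation$probeset_id, panel_columns()))
  dabg_mat <- ps_mat
  for (t in 1:3) {
    underlying <- baseline[ps_gene_idx] * traj[ps_gene_idx, t] *
      aff_vec * ni_all[, t]
    for (r in 1:2) {
      col <- (t - 1L) * 2L + r
      ps_mat[, col] <- gene_mat[ps_gene_idx, col] * aff_vec * ni_all[, t] *
        lnoise(n_ps, config$noise_cv)
      detected <- underlying >= config$detect_floor
      p <- numeric(n_ps)
      p[detected] <- stats::runif(sum(detected), 0, 0.01)
      p[!detected] <- stats::runif(sum(!detected), 0.1, 1)
      dabg_mat[, col] <- p
    }
  }

  panel <- intensity_panel(
    ps_mat, gene_mat, dabg_mat,
    stats::setNames(annotation$gene_id, annotation$probeset_id))

  truth <- list(
    das = if (length(truth_das) > 0L) {
      do.call(rbind, truth_das)
    } else {
      data.frame(probeset_id = character(0L), gene_id = character(0L),
                 direction = integer(0L), stringsAsFactors = FALSE)
    },
    dex_up = gene_ids[role == "dex_up"],
    dex_down = gene_ids[role == "dex_down"],
    ni = data.frame(probeset_id = annotation$probeset_id,
                    ni_d0 = aff_vec * ni_all[, 1L],
                    ni_d7 = aff_vec * ni_all[, 2L],
                    ni_d10 = aff_vec * ni_all[, 3L],
                    stringsAsFactors = FALSE)
  )

  structure(list(annotation = as_probeset_annotation(annotation),
                 models = gene_model_set(tx_list),
                 panel = panel, truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$annotation), "probesets,",
      x$config$n_genes, "genes,",
      nrow(x$truth$das), "true DAS probesets\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `annotation.tsv`, `probeset_intensity.tsv`, `gene_intensity.tsv`,
#' `dabg.tsv`, `models.gtf` and `truth.tsv` in the package's standard
#' formats. Output is deterministic: the same dataset always produces
#' byte-identical files.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("annotation.tsv", "probeset_intensity.tsv",
                            "gene_intensity.tsv", "dabg.tsv", "models.gtf",
                            "truth.tsv"))
  ann <- dataset$annotation
  ann$xhyb <- ifelse(ann$xhyb, "true", "false")
  utils::write.table(ann, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_intensity_panel(dataset$panel, paths[2L], paths[3L], paths[4L])
  write_transcript_models(dataset$models, paths[5L])
  truth <- dataset$truth$das
  utils::write.table(truth, paths[6L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Recovery of known DAS probesets by a candidate set
#'
#' @param candidates Character vector of candidate probeset ids (e.g.
#'   `run_cascade(...)$candidates$probeset_id`).
#' @param truth Truth list from [simulate_dataset()] (`$truth`).
#' @param probeset_ids Optional universe of valid probeset ids; when given,
#'   a candidate outside it raises a consistency error.
#' @return List with `sensitivity` (recovered fraction of true DAS
#'   probesets), `precision` (true fraction of candidates; 1 when there are
#'   no candidates), `fdr` (`1 - precision`), and the counts `n_true`,
#'   `n_candidates`, `n_hit`.
#' @export
evaluate_recovery <- function(candidates, truth, probeset_ids = NULL) {
  if (!is.null(probeset_ids)) {
    alien <- setdiff(candidates, probeset_ids)
    if (length(alien) > 0L) {
      stop("candidate probeset(s) absent from dataset: ",
           paste(utils::head(alien, 5L), collapse = ", "))
    }
  }
  true_das <- truth$das$probeset_id
  hit <- length(intersect(candidates, true_das))
  sensitivity <- if (length(true_das) == 0L) 1 else hit / length(true_das)
  precision <- if (length(candidates) == 0L) 1 else hit / length(candidates)
  list(sensitivity = sensitivity, precision = precision,
       fdr = 1 - precision, n_true = length(true_das),
       n_candidates = length(candidates), n_hit = hit)
}
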