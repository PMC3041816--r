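# Shared fixture builders and independent oracles. The oracles deliberately
# re-evaluate the rules with plain loops, without the package's pipeline
# machinery, so that tests compare two independent routes.

panel_cols <- c("d0_r1", "d0_r2", "d7_r1", "d7_r2", "d10_r1", "d10_r2")

# Build a panel from per-probeset/per-gene named lists of 6-vectors.
make_panel <- function(probesets, genes, map, dabg = NULL) {
  pm <- do.call(rbind, probesets)
  rownames(pm) <- names(probesets)
  colnames(pm) <- panel_cols
  gm <- do.call(rbind, genes)
  rownames(gm) <- names(genes)
  colnames(gm) <- panel_cols
  if (is.null(dabg)) {
    dm <- matrix(0.01, nrow = nrow(pm), ncol = 6L,
                 dimnames = list(rownames(pm), panel_cols))
  } else {
    dm <- do.call(rbind, dabg)
    rownames(dm) <- names(dabg)
    colnames(dm) <- panel_cols
  }
  intensity_panel(pm, gm, dm, map)
}

make_annotation <- function(probeset_id, gene_id, start,
                            stop = start + 49L, chrom = "chr1",
                            strand = "+", seq_length = 100L, xhyb = FALSE) {
  as_probeset_annotation(data.frame(
    probeset_id = probeset_id, gene_id = gene_id, chrom = chrom,
    start = as.integer(start), stop = as.integer(stop), strand = strand,
    seq_length = as.integer(seq_length), xhyb = xhyb,
    stringsAsFactors = FALSE))
}

# Random panel of constitutive-style probesets for metric property tests.
random_panel <- function(n_ps = 8L, n_genes = 3L, seed = 1L) {
  set.seed(seed)
  gids <- sprintf("g%d", seq_len(n_genes))
  pids <- sprintf("p%d", seq_len(n_ps))
  map <- setNames(sample(gids, n_ps, replace = TRUE), pids)
  probesets <- setNames(lapply(pids, function(i) runif(6, 10, 500)), pids)
  genes <- setNames(lapply(gids, function(i) runif(6, 100, 1000)), gids)
  make_panel(probesets, genes, map)
}

# Random small gene models for classifier oracle tests: a pool of
# non-overlapping exons; each transcript takes a random nonempty subset and
# may jitter one boundary into the flanking intron gap.
random_gene_models <- function(seed, gene_id = "g1", max_tx = 4L,
                               max_exons = 8L) {
  set.seed(seed)
  n_ex <- sample(2:max_exons, 1L)
  starts <- cumsum(sample(200:400, n_ex, replace = TRUE))
  widths <- sample(50:150, n_ex, replace = TRUE)
  pool <- data.frame(start = starts, end = starts + widths - 1L)
  strand <- sample(c("+", "-"), 1L)
  n_tx <- sample(1:max_tx, 1L)
  txs <- lapply(seq_len(n_tx), function(t) {
    idx <- sort(sample(seq_len(n_ex), sample(seq_len(n_ex), 1L)))
    ex <- pool[idx, , drop = FALSE]
    if (nrow(ex) > 0L && runif(1) < 0.5) {
      j <- sample(nrow(ex), 1L)
      if (runif(1) < 0.5) {
        ex$start[j] <- ex$start[j] + sample(-40:40, 1L)
      } else {
        ex$end[j] <- ex$end[j] + sample(-40:40, 1L)
      }
      ex$start[j] <- max(1L, ex$start[j])
      if (ex$start[j] > ex$end[j]) ex$end[j] <- ex$start[j] + 10L
      ord <- order(ex$start)
      ex <- ex[ord, , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        ex <- pool[idx, , drop = FALSE]  # jitter created overlap: revert
      }
    }
    transcript_model(sprintf("t%d", t), gene_id, "chr1", strand, ex)
  })
  probeset_exon <- pool[sample(n_ex, 1L), ]
  ps_start <- probeset_exon$start + 5L
  ps_stop <- max(ps_start, probeset_exon$end - 5L)
  list(transcripts = txs,
       probeset = list(probeset_id = "psX", gene_id = gene_id,
                       start = ps_start, stop = ps_stop))
}

# Brute-force presence verdict: contained in >=1 transcript and not
# contained in >=1 other.
oracle_is_alternative <- function(probeset, transcripts) {
  presence <- character(0L)
  for (t in transcripts) {
    cont <- FALSE; over <- FALSE
    for (i in seq_len(nrow(t$exons))) {
      s <- t$exons$start[i]; e <- t$exons$end[i]
      if (s <= probeset$start && probeset$stop <= e) cont <- TRUE
      if (s <= probeset$stop && probeset$start <= e) over <- TRUE
    }
    presence <- c(presence,
                  if (cont) "contained" else if (over) "partial" else "absent")
  }
  any(presence == "contained") && any(presence != "contained")
}

# Straight-line re-evaluation of the nine cascade predicates with plain
# loops over one probeset at a time.
oracle_cascade_survivors <- function(annotation, panel, models,
                                     si_threshold = 1.35,
                                     neighbor_threshold = 0.667,
                                     alpha = 0.05, max_len = 500,
                                     fraction = 0.5) {
  ids <- annotation$probeset_id
  ann <- as.data.frame(annotation)
  rownames(ann) <- ann$probeset_id

  detected <- function(id, tp) {
    all(panel$dabg[id, paste0(tp, c("_r1", "_r2"))] <= alpha)
  }
  ni <- function(id, tp) {
    g <- ann[id, "gene_id"]
    cols <- paste0(tp, c("_r1", "_r2"))
    mean(panel$probesets[id, cols] / panel$genes[g, cols])
  }
  si <- function(id, tp) log2(ni(id, tp) / ni(id, "d0"))

  gene_expr <- function(g, tp) {
    ps <- ann$probeset_id[ann$gene_id == g]
    mean(sapply(ps, detected, tp = tp)) >= fraction
  }

  # static context
  f13 <- character(0L)
  for (id in ids) {
    g <- ann[id, "gene_id"]
    starts <- ann$start[ann$gene_id == g]
    if (ann[id, "start"] == min(starts)) next
    if (ann[id, "start"] == max(starts)) next
    if (ann[id, "seq_length"] >= max_len) next
    if (ann[id, "xhyb"]) next
    f13 <- c(f13, id)
  }
  space <- f13[sapply(f13, function(id) detected(id, "d0") ||
                        detected(id, "d7"))]

  survivors <- character(0L)
  for (id in f13) {
    g <- ann[id, "gene_id"]
    if (!(gene_expr(g, "d0") && gene_expr(g, "d7"))) next
    if (!(detected(id, "d0") || detected(id, "d7"))) next
    s7 <- si(id, "d7")
    if (abs(s7) < si_threshold) next
    # neighbor rule
    sp <- space[ann[space, "gene_id"] == g & space != id]
    up <- sp[ann[sp, "start"] < ann[id, "start"]]
    down <- sp[ann[sp, "start"] > ann[id, "start"]]
    changed <- function(nbs, pickmax) {
      if (length(nbs) == 0L) return(NA)
      st <- ann[nbs, "start"]
      # nearest by start; ties broken by probeset id, matching the
      # pipeline's (start, id) ordering
      cand <- if (pickmax) nbs[st == max(st)] else nbs[st == min(st)]
      nb <- if (pickmax) max(cand) else min(cand)
      abs(si(nb, "d7")) >= neighbor_threshold
    }
    ch <- c(changed(up, TRUE), changed(down, FALSE))
    ch <- ch[!is.na(ch)]
    if (length(ch) > 0L && all(ch)) next
    # alternative-exon prediction via presence oracle
    txs <- models[[g]]
    if (is.null(txs)) next
    ps <- list(probeset_id = id, gene_id = g,
               start = ann[id, "start"], stop = ann[id, "stop"])
    if (!oracle_is_alternative(ps, txs)) next
    # day-10 reversal
    s10 <- si(id, "d10")
    keep <- (abs(s7) > abs(s10)) ||
      (s7 < 0 && s10 >= si_threshold) || (s7 > 0 && s10 <= -si_threshold)
    if (!keep) next
    survivors <- c(survivors, id)
  }
  survivors
}
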