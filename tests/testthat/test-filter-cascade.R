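test_that("terminal-probeset filter removes extreme starts including ties", {
  ann <- make_annotation(c("a", "b", "c"), rep("g1", 3), c(10L, 50L, 90L))
  expect_equal(filter_terminal_probesets(ann$probeset_id, ann), "b")
  # two probesets: zero survive
  ann2 <- make_annotation(c("a", "b"), rep("g1", 2), c(10L, 50L))
  expect_equal(filter_terminal_probesets(ann2$probeset_id, ann2),
               character(0L))
  # all probesets tied at an extreme start are removed
  ann3 <- make_annotation(c("a1", "a2", "b", "c"), rep("g1", 4),
                          c(10L, 10L, 50L, 90L))
  expect_equal(filter_terminal_probesets(ann3$probeset_id, ann3), "b")
  # extremes come from the full annotation: the filter is idempotent
  s1 <- filter_terminal_probesets(ann$probeset_id, ann)
  expect_equal(filter_terminal_probesets(s1, ann), s1)
})

test_that("length filter removes probesets at or above 500 nt", {
  ann <- make_annotation(c("a", "b", "c"), rep("g1", 3), c(10L, 50L, 90L),
                         seq_length = c(499L, 500L, 501L))
  expect_equal(filter_long_probesets(ann$probeset_id, ann), "a")
})

test_that("cross-hybridization filter keeps only xhyb = FALSE", {
  ann <- make_annotation(sprintf("p%d", 1:10), rep("g1", 10), (1:10) * 10L,
                         xhyb = c(rep(FALSE, 7), rep(TRUE, 3)))
  expect_length(filter_xhyb_probesets(ann$probeset_id, ann), 7L)
})

test_that("detection filter keeps probesets detected on day 0 or day 7 only", {
  dabg <- list(p1 = c(0.01, 0.01, 0.9, 0.9, 0.9, 0.9),  # d0 only
               p2 = rep(0.9, 6),                         # never
               p3 = c(0.9, 0.9, 0.9, 0.9, 0.01, 0.01))  # d10 only
  panel <- make_panel(
    probesets = setNames(rep(list(rep(50, 6)), 3), names(dabg)),
    genes = list(g1 = rep(100, 6)),
    map = setNames(rep("g1", 3), names(dabg)), dabg = dabg)
  expect_equal(filter_detected_probesets(names(dabg), panel), "p1")
})

test_that("splicing-index filter is inclusive at the threshold", {
  scores <- data.frame(probeset_id = c("a", "b", "c"),
                       si_d7 = c(1.35, -1.36, 1.34),
                       stringsAsFactors = FALSE)
  expect_equal(filter_splicing_index(c("a", "b", "c"), scores), c("a", "b"))
  expect_error(filter_splicing_index("missing", scores), "undefined")
})

test_that("neighbor rule removes a probeset only when all its neighbors changed", {
  # gene with 5 probesets; candidate is p3, neighbors p2/p4 in the space
  neighbor_case <- function(si2, si4) {
    ann <- make_annotation(sprintf("p%d", 1:5), rep("g1", 5), (1:5) * 100L)
    scores <- data.frame(probeset_id = sprintf("p%d", 1:5),
                         si_d7 = c(0, si2, 2, si4, 0),
                         stringsAsFactors = FALSE)
    panel <- make_panel(
      probesets = setNames(rep(list(rep(50, 6)), 5), sprintf("p%d", 1:5)),
      genes = list(g1 = rep(100, 6)),
      map = setNames(rep("g1", 5), sprintf("p%d", 1:5)))
    filter_neighbor_change("p3", scores, panel, ann,
                           search_space = sprintf("p%d", 2:4))
  }
  expect_equal(neighbor_case(0.2, 2.0), "p3")          # one unchanged
  expect_equal(neighbor_case(1.0, 2.0), character(0L)) # both changed
  expect_equal(neighbor_case(0.666, 0.666), "p3")      # below threshold
  expect_equal(neighbor_case(0.667, 0.667), character(0L))  # at threshold

  # single neighbor: removed iff it changed
  single_case <- function(si2) {
    ann <- make_annotation(c("p2", "p3"), rep("g1", 2), c(200L, 300L))
    scores <- data.frame(probeset_id = c("p2", "p3"), si_d7 = c(si2, 2),
                         stringsAsFactors = FALSE)
    panel <- make_panel(
      probesets = list(p2 = rep(50, 6), p3 = rep(50, 6)),
      genes = list(g1 = rep(100, 6)), map = c(p2 = "g1", p3 = "g1"))
    filter_neighbor_change("p3", scores, panel, ann,
                           search_space = c("p2", "p3"))
  }
  expect_equal(single_case(0.5), "p3")
  expect_equal(single_case(1.0), character(0L))

  # no detectable neighbor at all: keep
  ann <- make_annotation("p3", "g1", 300L)
  scores <- data.frame(probeset_id = "p3", si_d7 = 2,
                       stringsAsFactors = FALSE)
  panel <- make_panel(probesets = list(p3 = rep(50, 6)),
                      genes = list(g1 = rep(100, 6)), map = c(p3 = "g1"))
  expect_equal(filter_neighbor_change("p3", scores, panel, ann,
                                      search_space = "p3"), "p3")
})

test_that("day-10 reversal rule compares effect sizes and strong reversals", {
  scores <- data.frame(
    probeset_id = c("a", "b", "c", "d", "e"),
    si_d7 = c(2.0, 1.5, 1.0, -2.0, 1.5),
    si_d10 = c(1.0, -1.5, 1.2, 1.35, NA),
    stringsAsFactors = FALSE)
  out <- filter_d10_reversal(scores$probeset_id, scores)
  expect_equal(out$ids, c("a", "b", "d"))
  # b: positive d7 with d10 <= -1.35 (strong reversal) is kept
  # d: negative d7 with d10 >= 1.35 is kept
  # e: undefined si_d10 is removed with a logged reason
  expect_equal(out$failures$probeset_id, "e")
})

# Hand-built three-gene dataset in which exactly one probeset survives all
# nine stages; every audit count below was derived by evaluating the nine
# rules manually.
hand_dataset <- function() {
  ann <- as_probeset_annotation(data.frame(
    probeset_id = c(sprintf("a%d", 1:5), sprintf("b%d", 1:3),
                    sprintf("c%d", 1:3)),
    gene_id = c(rep("gA", 5), rep("gB", 3), rep("gC", 3)),
    chrom = "chr1",
    start = c(100L, 200L, 300L, 400L, 500L, 100L, 200L, 300L,
              100L, 200L, 300L),
    stop = c(100L, 200L, 300L, 400L, 500L, 100L, 200L, 300L,
             100L, 200L, 300L) + 49L,
    strand = "+", seq_length = 120L, xhyb = FALSE,
    stringsAsFactors = FALSE))

  flat <- rep(100, 6)
  probesets <- list(
    a1 = flat, a2 = flat,
    a3 = c(100, 100, 400, 400, 150, 150),  # si_d7 = 2, si_d10 ~ 0.585
    a4 = flat, a5 = flat,
    b1 = flat, b2 = flat, b3 = flat,
    c1 = flat,
    c2 = c(100, 100, 100 * 2^1.5, 100 * 2^1.5, 100 * 2^1.8, 100 * 2^1.8),
    c3 = flat)
  genes <- list(gA = rep(1000, 6), gB = rep(1000, 6), gC = rep(1000, 6))
  dabg <- setNames(rep(list(rep(0.01, 6)), 11), names(probesets))
  # gene gB is not expressed on day 7: all its probesets undetected there
  for (id in c("b1", "b2", "b3")) dabg[[id]][3:4] <- 0.5
  panel <- make_panel(probesets, genes,
                      setNames(ann$gene_id, ann$probeset_id), dabg)

  exons <- function(starts) data.frame(start = starts, end = starts + 89L)
  models <- gene_model_set(list(
    transcript_model("gA_t1", "gA", "chr1", "+",
                     exons(c(95L, 195L, 295L, 395L, 495L))),
    transcript_model("gA_t2", "gA", "chr1", "+",
                     exons(c(95L, 195L, 395L, 495L))),   # skips a3's exon
    transcript_model("gB_t1", "gB", "chr1", "+", exons(c(95L, 195L, 295L))),
    transcript_model("gB_t2", "gB", "chr1", "+", exons(c(95L, 295L))),
    transcript_model("gC_t1", "gC", "chr1", "+", exons(c(95L, 195L, 295L))),
    transcript_model("gC_t2", "gC", "chr1", "+", exons(c(95L, 295L)))))
  list(annotation = ann, panel = panel, models = models)
}

test_that("the cascade reproduces hand-derived audit counts on a fixture", {
  d <- hand_dataset()
  res <- run_cascade(d$annotation, d$panel, d$models)
  expect_equal(res$audit$n_probesets,
               c(11L, 5L, 5L, 5L, 4L, 4L, 2L, 2L, 2L, 1L))
  expect_equal(res$audit$n_genes,
               c(3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 1L))
  expect_equal(res$candidates$probeset_id, "a3")
  expect_equal(res$candidates$das_direction, "up")
  expect_equal(res$candidates$as_types, "exon_skip")
  expect_equal(res$candidates$si_d7, 2)
  # c2 fell at the final stage: |si_d7| = 1.5 < |si_d10| = 1.8
  expect_false("c2" %in% res$candidates$probeset_id)
})

test_that("an empty annotation yields an all-zero audit", {
  ds <- simulate_dataset(sim_config(n_genes = 0))
  res <- run_cascade(ds$annotation, ds$panel, ds$models)
  expect_equal(res$audit$n_probesets, rep(0L, 10L))
  expect_equal(nrow(res$candidates), 0L)
})

test_that("audit counts never increase and filters are idempotent", {
  for (seed in 1:3) {
    ds <- simulate_dataset(sim_config(n_genes = 40, seed = seed))
    res <- run_cascade(ds$annotation, ds$panel, ds$models)
    expect_true(all(diff(res$audit$n_probesets) <= 0))
    expect_true(all(diff(res$audit$n_genes) <= 0))
    # survivor sets are nested
    for (k in 2:10) {
      expect_true(all(res$stages[[k]] %in% res$stages[[k - 1L]]))
    }
    # each annotation-level filter applied twice equals once
    ann <- ds$annotation
    s <- filter_terminal_probesets(ann$probeset_id, ann)
    expect_equal(filter_terminal_probesets(s, ann), s)
    s <- filter_long_probesets(s, ann)
    expect_equal(filter_long_probesets(s, ann), s)
    s <- filter_xhyb_probesets(s, ann)
    expect_equal(filter_xhyb_probesets(s, ann), s)
    s <- filter_detected_probesets(s, ds$panel)
    expect_equal(filter_detected_probesets(s, ds$panel), s)
    scores <- res$scores$scores
    s6 <- filter_splicing_index(intersect(s, scores$probeset_id), scores)
    expect_equal(filter_splicing_index(s6, scores), s6)
    space <- filter_detected_probesets(
      filter_xhyb_probesets(
        filter_long_probesets(
          filter_terminal_probesets(ann$probeset_id, ann), ann), ann),
      ds$panel)
    s7 <- filter_neighbor_change(s6, scores, ds$panel, ann,
                                 search_space = space)
    expect_equal(filter_neighbor_change(s7, scores, ds$panel, ann,
                                        search_space = space), s7)
  }
})

test_that("cascade survivors equal a straight-line oracle on small datasets", {
  for (seed in 4:6) {
    ds <- simulate_dataset(sim_config(n_genes = 15, seed = seed))
    res <- run_cascade(ds$annotation, ds$panel, ds$models)
    oracle <- oracle_cascade_survivors(ds$annotation, ds$panel, ds$models)
    expect_setequal(res$candidates$probeset_id, oracle)
  }
})

test_that("candidates are invariant under gene relabeling and translation", {
  ds <- simulate_dataset(sim_config(n_genes = 20, seed = 9))
  res <- run_cascade(ds$annotation, ds$panel, ds$models)

  # relabel genes bijectively everywhere
  relabel <- function(g) paste0("X", g)
  ann2 <- ds$annotation
  ann2$gene_id <- relabel(ann2$gene_id)
  ann2 <- as_probeset_annotation(as.data.frame(ann2))
  panel2 <- ds$panel
  rownames(panel2$genes) <- relabel(rownames(panel2$genes))
  panel2$probeset_gene <- setNames(relabel(panel2$probeset_gene),
                                   names(panel2$probeset_gene))
  models2 <- lapply(unlist(unname(ds$models), recursive = FALSE),
                    function(t) {
                      t$gene_id <- relabel(t$gene_id)
                      t$transcript_id <- paste0("X", t$transcript_id)
                      t
                    })
  models2 <- gene_model_set(models2)
  res2 <- run_cascade(ann2, panel2, models2)
  expect_setequal(res2$candidates$probeset_id, res$candidates$probeset_id)

  # translate all coordinates by a constant
  shift <- 5000L
  ann3 <- ds$annotation
  ann3$start <- ann3$start + shift
  ann3$stop <- ann3$stop + shift
  ann3 <- as_probeset_annotation(as.data.frame(ann3))
  models3 <- lapply(unlist(unname(ds$models), recursive = FALSE),
                    function(t) {
                      t$exons$start <- t$exons$start + shift
                      t$exons$end <- t$exons$end + shift
                      t
                    })
  models3 <- gene_model_set(models3)
  res3 <- run_cascade(ann3, ds$panel, models3)
  expect_setequal(res3$candidates$probeset_id, res$candidates$probeset_id)
})

test_that("probesets of genes without transcript models are removed with a reason", {
  d <- hand_dataset()
  models <- d$models
  models[["gA"]] <- NULL
  res <- run_cascade(d$annotation, d$panel, models)
  expect_equal(nrow(res$candidates), 0L)
  expect_true("a3" %in% res$failures$probeset_id)
  expect_match(res$failures$reason[res$failures$probeset_id == "a3"],
               "no transcript model")
})
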