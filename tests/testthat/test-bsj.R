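test_that("Blat score is matches minus mismatches minus gap openings", {
  expect_equal(blatScore(mk_hit(matches = 40L)), 40L)
  expect_equal(blatScore(mk_hit(matches = 35L, mismatches = 3L,
                                q_gap_count = 1L, t_gap_count = 1L)), 30L)
  # 29 sits just below the calling threshold
  expect_equal(blatScore(mk_hit(matches = 29L)), 29L)
})

test_that("hit pairing enforces each back-splice criterion at its boundary", {
  # read-earlier hit maps genomically downstream: a valid BSJ on +
  a <- mk_hit("r", q_start = 0L, t_start = 10000L, t_end = 10100L)
  b <- mk_hit("r", q_start = 100L, t_start = 500L, t_end = 600L)
  p <- pairHits(a, b)
  expect_true(p$accepted)
  expect_equal(p$candidate$circ_start, 500L)
  expect_equal(p$candidate$circ_end, 10100L)
  # argument order does not change the decision
  expect_true(pairHits(b, a)$accepted)
  expect_error(pairHits(a, mk_hit("other", q_start = 100L)),
               "different reads")

  # opposite strands
  b2 <- b; b2$strand <- "-"
  expect_equal(pairHits(a, b2)$reason, "strand")
  # different chromosome
  b3 <- b; b3$t_chrom <- "chr2"
  expect_equal(pairHits(a, b3)$reason, "chrom")
  # span: 1 Mb inclusive, 1 Mb + 1 rejected
  a3 <- mk_hit("r", q_start = 0L, t_start = 500L + 1e6L - 100L,
               t_end = 500L + 1e6L)
  expect_true(pairHits(a3, b)$accepted)       # span exactly 1 Mb
  a4 <- mk_hit("r", q_start = 0L, t_start = 500L + 1e6L - 99L,
               t_end = 500L + 1e6L + 1L)
  expect_equal(pairHits(a4, b)$reason, "distance")
  # overlap: 49 bp tolerated, 50 bp rejected
  b49 <- mk_hit("r", q_start = 100L, t_start = 9951L, t_end = 10051L)
  a49 <- mk_hit("r", q_start = 0L, t_start = 10002L, t_end = 10102L)
  expect_true(pairHits(a49, b49)$accepted)    # overlap 49
  a50 <- mk_hit("r", q_start = 0L, t_start = 10001L, t_end = 10101L)
  expect_equal(pairHits(a50, b49)$reason, "overlap")
  # order: read-earlier hit upstream is a linear split, not a BSJ
  expect_equal(pairHits(b, a, maxSpan = 1e6)$accepted, TRUE)
  lin_a <- mk_hit("r", q_start = 0L, t_start = 500L, t_end = 600L)
  lin_b <- mk_hit("r", q_start = 100L, t_start = 10000L, t_end = 10100L)
  expect_equal(pairHits(lin_a, lin_b)$reason, "order")
  # score threshold 30 reached / missed by one
  a30 <- mk_hit("r", q_start = 0L, t_start = 10000L, t_end = 10030L)
  b30 <- mk_hit("r", q_start = 100L, t_start = 500L, t_end = 530L)
  expect_true(pairHits(a30, b30)$accepted)
  a29 <- mk_hit("r", q_start = 0L, t_start = 10000L, t_end = 10029L)
  expect_equal(pairHits(a29, b30)$reason, "score")
})

test_that("minus-strand pairing reverses the downstream test", {
  # on -, the read-earlier hit must map at smaller coordinates
  a <- mk_hit("r", q_start = 0L, t_start = 500L, t_end = 600L,
              strand = "-")
  b <- mk_hit("r", q_start = 100L, t_start = 10000L, t_end = 10100L,
              strand = "-")
  expect_true(pairHits(a, b)$accepted)
  expect_equal(pairHits(b, a, maxSpan = 1e6)$accepted, TRUE)
  expect_equal(pairHits(mk_hit("r", q_start = 0L, t_start = 10000L,
                               t_end = 10100L, strand = "-"),
                        mk_hit("r", q_start = 100L, t_start = 500L,
                               t_end = 600L, strand = "-"))$reason,
               "order")
})

test_that("read classification separates BSJ, multi-round and linear reads", {
  a <- mk_hit("r", q_start = 0L, t_start = 10000L, t_end = 10100L)
  b <- mk_hit("r", q_start = 100L, t_start = 500L, t_end = 600L)
  expect_equal(classifyReadHits(bind_rows_df(a, b))$class, "bsj_two_hit")
  # four hits alternating over the same two exonic segments: two circles
  segA <- function(q) mk_hit("r", q_start = q, t_start = 500L,
                             t_end = 700L)
  segB <- function(q) mk_hit("r", q_start = q, t_start = 900L,
                             t_end = 1100L)
  hits4 <- bind_rows_df(segB(0L), segA(200L), segB(400L), segA(600L))
  expect_equal(classifyReadHits(hits4)$class, "multi_round")
  expect_equal(classifyReadHits(mk_hit("r"))$class, "linear_like")
  expect_equal(classifyReadHits(mk_hit("r", t_end = 10L))$class,
               "unmapped_for_circ")
  expect_error(classifyReadHits(mk_hit("r")[0, ]), "empty")
})

test_that("annotation overlap sums bp per layer over hit blocks", {
  models <- mk_models()
  layers <- prepareAnnotation(models)
  # fully inside exon 1 of geneA (1000..1200 0-based)
  h <- mk_hit("r", t_start = 1020L, t_end = 1100L)
  bp <- annotateHit(h, layers)
  expect_equal(unname(bp), c(80L, 80L, 0L, 0L))
  # 60 bp exon + 40 bp intron
  h2 <- mk_hit("r", t_start = 1140L, t_end = 1240L)
  bp2 <- annotateHit(h2, layers)
  expect_equal(bp2[["bp_gene"]], 100L)
  expect_equal(bp2[["bp_exon"]], 60L)
  expect_equal(bp2[["bp_intron"]], 40L)
  # unannotated contig
  h3 <- mk_hit("r", t_chrom = "chrUn", t_start = 0L, t_end = 100L)
  expect_equal(unname(annotateHit(h3, layers)), c(0L, 0L, 0L, 0L))
})

test_that("end correction snaps to exon boundaries within 30 bp", {
  models <- mk_models()
  # geneA exon boundaries (0-based): starts 1000/1500/2000, ends
  # 1200/1700/2200
  cand <- list(read_id = "r", t_chrom = "chr1", strand = "+",
               circ_start = 1012L, circ_end = 2200L,
               score_left = 40L, score_right = 40L,
               bp_gene = 0L, bp_exon = 0L, bp_intron = 0L, bp_est = 0L,
               block_t_starts = c(1012L), block_sizes = c(100L))
  r <- correctEnds(cand, models)
  expect_true(r$accepted)
  expect_equal(r$candidate$corr_start, 1000L)
  expect_equal(r$candidate$corr_end, 2200L)
  expect_equal(r$candidate$adjust_start, 12L)
  expect_equal(r$candidate$adjust_end, 0L)
  expect_equal(r$candidate$snap_mode, "exon")
  # 30 bp away still snaps; 31 bp does not
  c30 <- cand; c30$circ_start <- 1030L
  expect_true(correctEnds(c30, models)$accepted)
  c31 <- cand; c31$circ_start <- 1031L
  expect_false(correctEnds(c31, models)$accepted)
})

test_that("known-circRNA fallback requires 95% span Jaccard", {
  models <- mk_models()
  known <- GRanges("chr1", IRanges(20001L, 21000L), strand = "+")
  mcols(known)$circ_id <- "hsa_circ_X"
  mcols(known)$db_name <- "circBase"
  base <- list(read_id = "r", t_chrom = "chr1", strand = "+",
               score_left = 40L, score_right = 40L,
               bp_gene = 0L, bp_exon = 0L, bp_intron = 0L, bp_est = 0L,
               block_t_starts = c(20040L), block_sizes = c(100L))
  # ends far from any exon; Jaccard 960/1000 = 0.96 -> snapped to record
  c96 <- c(base, list(circ_start = 20040L, circ_end = 21000L))
  r <- correctEnds(c96, models, known)
  expect_true(r$accepted)
  expect_equal(r$candidate$corr_start, 20000L)
  expect_equal(r$candidate$corr_end, 21000L)
  expect_equal(r$candidate$snap_mode, "known")
  expect_equal(r$candidate$circBase_id, "hsa_circ_X")
  # Jaccard 900/1000 = 0.90 -> rejected (brute-force check inline)
  c90 <- c(base, list(circ_start = 20100L, circ_end = 21000L))
  jac <- (21000 - 20100) / (21000 - 20000)
  expect_equal(jac, 0.90)
  expect_false(correctEnds(c90, models, known)$accepted)
  # boundary: exactly 0.95 accepted
  c95 <- c(base, list(circ_start = 20050L, circ_end = 21000L))
  expect_true(correctEnds(c95, models, known)$accepted)
})

test_that("collapsing groups identical regions and filters chrM/rRNA", {
  models <- mk_models()
  # add an rRNA gene at chr1:30000-31000
  genes <- c(geneRanges(models),
             GRanges("chr1", IRanges(30001, 31000), strand = "+",
                     gene_id = "rna5S", is_rRNA = TRUE))
  ex <- c(unname(exonsByGene(models)),
          GRangesList(GRanges("chr1", IRanges(30001, 31000), strand = "+",
                              phase = NA_integer_)))
  models2 <- GeneModelSet(genes, ex)
  cand <- function(id, chrom = "chr1", s = 1000L, e = 2200L,
                   adj_s = 0L, adj_e = 0L)
    list(read_id = id, t_chrom = chrom, strand = "+", circ_start = s,
         circ_end = e, score_left = 40L, score_right = 40L,
         bp_gene = 100L, bp_exon = 80L, bp_intron = 20L, bp_est = 0L,
         corr_start = s, corr_end = e, adjust_start = adj_s,
         adjust_end = adj_e, snap_mode = "exon",
         circBase_id = NA_character_, circAtlas_id = NA_character_,
         CIRCpedia_id = NA_character_,
         block_t_starts = s, block_sizes = e - s)
  corrected <- longcirc:::.cand_df(list(
    cand("r1"), cand("r2", adj_s = 12L), cand("r3"),
    cand("rM", chrom = "chrM"),
    cand("rR", s = 30000L, e = 31000L)))
  circs <- collapseCircRNAs(corrected, models2)
  df <- as.data.frame(circs)
  expect_equal(nrow(df), 1L)           # chrM and rRNA removed
  expect_equal(df$n_reads, 3L)
  expect_equal(df$host_gene, "geneA")
  expect_equal(df$adjust_min, 0)
  expect_equal(df$adjust_max, 12)
  expect_equal(df$adjust_mean, 4)
  expect_true(df$is_novel)
  # empty input
  expect_equal(length(collapseCircRNAs(NULL, models2)), 0L)
})

test_that("run summary reports fractions of filtered reads", {
  circs <- mk_circset("chr1", 0L, 100L)
  classes <- DataFrame(read_id = c("a", "b", "c"),
                       class = c("bsj_two_hit", "bsj_two_hit",
                                 "linear_like"))
  s <- summarizeRun(classes, circs, nFiltered = 40L)
  expect_equal(s$bsj_reads, 2L)
  expect_equal(s$bsj_reads_pct, 5)
  expect_warning(summarizeRun(classes, circs, nFiltered = 0L),
                 "undefined")
})

test_that("call thresholds are monotone and reads are conserved", {
  sh <- shared_sim()
  base <- sh$call
  n_base <- length(base$circs)
  # conservation of reads: support sums to accepted candidates
  expect_equal(sum(mcols(circRanges(base$circs))$n_reads),
               nrow(base$candidates))
  # raising the score threshold never increases the number of circRNAs
  strict <- callCircRNAs(sh$sim$hits, sh$ref$models, sh$ref$known,
                         minScore = 120)
  expect_lte(length(strict$circs), n_base)
  # lowering the snap window never increases the number of circRNAs
  snap0 <- callCircRNAs(sh$sim$hits, sh$ref$models, sh$ref$known,
                        snapBp = 0)
  expect_lte(length(snap0$circs), n_base)
})
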