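test_that("microexon classes follow the 3-15/16-29 nt bounds", {
  expect_equal(classifyMicroexon(c(2, 3, 12, 15, 16, 29, 30)),
               c("none", "me_3_15", "me_3_15", "me_3_15", "me_16_29",
                 "me_16_29", "none"))
  expect_error(classifyMicroexon(0))
})

test_that("interval similarity is a symmetric Jaccard", {
  expect_equal(intervalSimilarity(0, 100, 0, 100), 1.0)
  expect_equal(intervalSimilarity(0, 100, 0, 95), 0.95)
  expect_equal(intervalSimilarity(0, 100, 200, 300), 0.0)
  set.seed(5)
  for (i in 1:40) {
    a <- sort(sample(0:100, 2)); b <- sort(sample(0:100, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    expect_equal(intervalSimilarity(a[1], a[2], b[1], b[2]),
                 intervalSimilarity(b[1], b[2], a[1], a[2]))
  }
  # 1 iff identical
  expect_lt(intervalSimilarity(0, 100, 0, 101), 1)
})

test_that("reading-frame analysis scans codons in the dictated phase", {
  # 13 nt cannot be in frame
  r <- exonFrameAnalysis(strrep("C", 13), 0)
  expect_equal(r$frame_class, "out_frame_no_stop")
  expect_equal(exonFrameAnalysis("ATGTAAGGC", 0)$frame_class,
               "in_frame_stop")
  expect_equal(exonFrameAnalysis("ATGGCCGGC", 0)$frame_class,
               "in_frame_no_stop")
  # the same sequence read in phase 1 has no full stop codon
  expect_equal(exonFrameAnalysis("ATGTAAGGC", 1)$frame_class,
               "in_frame_no_stop")
  # unknown phase scans all three frames and flags it
  r2 <- exonFrameAnalysis("ATGTAAGGC", NA)
  expect_equal(r2$frame_class, "in_frame_stop")
  expect_false(r2$phase_known)
})

test_that("exon usage is reads-using over reads-spanning", {
  ex <- GRanges("chr1", IRanges(501, 560))    # 0-based 500..560
  # 4 of 5 spanning reads carry the exon: usage 0.80
  with_exon <- lapply(1:4, function(i)
    mk_cand(paste0("u", i), corr_start = 0L, corr_end = 1000L,
            t_starts = c(0L, 500L, 900L), sizes = c(100L, 60L, 100L)))
  without <- mk_cand("s1", corr_start = 0L, corr_end = 1000L,
                     t_starts = c(0L, 900L), sizes = c(100L, 100L))
  cands <- do.call(rbind, c(with_exon, list(without)))
  u <- exonUsage(cands, ex, minReads = 1)
  expect_equal(u$n_reads_spanning, 5L)
  expect_equal(u$n_reads_using, 4L)
  expect_equal(u$usage_level, 0.80)
  expect_false(u$suppressed)
  # the 10-read circNick gate suppresses the same record
  u10 <- exonUsage(cands, ex, mode = "nick")
  expect_true(u10$suppressed)
  # 16 of 50: usage 0.32 (panel-scale example)
  cands50 <- do.call(rbind, c(
    lapply(1:16, function(i)
      mk_cand(paste0("u", i), corr_start = 0L, corr_end = 1000L,
              t_starts = c(0L, 500L, 900L), sizes = c(100L, 60L, 100L))),
    lapply(1:34, function(i)
      mk_cand(paste0("s", i), corr_start = 0L, corr_end = 1000L,
              t_starts = c(0L, 900L), sizes = c(100L, 100L)))))
  u50 <- exonUsage(cands50, ex, minReads = 1)
  expect_equal(u50$usage_level, 0.32)
  # reads not spanning the exon position cannot witness exclusion
  part <- mk_cand("p1", corr_start = 600L, corr_end = 1000L,
                  t_starts = 600L, sizes = 400L)
  u2 <- exonUsage(rbind(cands, part), ex, minReads = 1)
  expect_equal(u2$n_reads_spanning, 5L)
})

test_that("linear inclusion reproduces the circ-vs-linear comparisons", {
  expect_equal(round(linearInclusion(4, 116), 4), 0.0345)
  expect_equal(round(linearInclusion(7, 30), 2), 0.23)
  expect_equal(linearInclusion(0, 50), 0)
  expect_warning(out <- linearInclusion(0, 0), "no spanning reads")
  expect_true(is.na(out))
})

test_that("intron coverage matches brute-force per-base accounting", {
  intron <- GRanges("chr1", IRanges(201, 300))  # 0-based 200..300
  # all reads retain the 100-bp intron inside a 400-bp gene-mapped span
  retain <- lapply(1:20, function(i)
    mk_cand(paste0("r", i), corr_start = 0L, corr_end = 400L,
            t_starts = 0L, sizes = 400L, bp_gene = 400L, bp_intron = 100L))
  st <- intronCoverage(do.call(rbind, retain), intron)
  expect_equal(st$n_bsj_reads_spanning, 20L)
  expect_equal(st$intron_coverage_fraction, 1.0)
  expect_equal(st$intronic_fraction, 0.25)
  # all reads splice it out
  splice <- lapply(1:20, function(i)
    mk_cand(paste0("s", i), corr_start = 0L, corr_end = 400L,
            t_starts = c(0L, 300L), sizes = c(200L, 100L),
            bp_gene = 300L, bp_intron = 0L))
  st0 <- intronCoverage(do.call(rbind, splice), intron)
  expect_equal(st0$intron_coverage_fraction, 0)
  expect_equal(st0$intronic_fraction, 0)
  # half retain: union coverage stays 1, intronic fraction halves
  mixed <- do.call(rbind, c(retain[1:10], splice[1:10]))
  stm <- intronCoverage(mixed, intron)
  brute_cov <- local({
    covered <- logical(100)
    for (i in seq_len(nrow(mixed))) {
      bs <- mixed$block_t_starts[[i]]; be <- bs + mixed$block_sizes[[i]]
      for (k in seq_along(bs)) {
        lo <- max(bs[k], 200L); hi <- min(be[k], 300L)
        if (hi > lo) covered[(lo - 199L):(hi - 200L)] <- TRUE
      }
    }
    mean(covered)
  })
  expect_equal(stm$intron_coverage_fraction, brute_cov)
  expect_equal(stm$intron_coverage_fraction, 1.0)
  expect_equal(stm$intronic_fraction,
               mean(mixed$bp_intron) / mean(mixed$bp_gene))
  expect_equal(stm$intronic_fraction, st$intronic_fraction * 50 / 87.5)
})

test_that("retained-intron gates fire exactly at their thresholds", {
  mk_stats <- function(n, cov, frac, ne = FALSE)
    DataFrame(chrom = "chr1", intron_start = 200L, intron_end = 300L,
              n_bsj_reads_spanning = n, intron_coverage_fraction = cov,
              intronic_fraction = frac, has_novel_exon_inside = ne)
  expect_equal(nrow(callRetainedIntrons(mk_stats(25, 0.95, 0.05))), 1L)
  expect_equal(nrow(callRetainedIntrons(mk_stats(20, 0.90, 0.031))), 1L)
  expect_equal(nrow(callRetainedIntrons(mk_stats(19, 0.95, 0.05))), 0L)
  expect_equal(nrow(callRetainedIntrons(mk_stats(25, 0.89, 0.05))), 0L)
  # the 3% intronic gate is strict
  expect_equal(nrow(callRetainedIntrons(mk_stats(25, 0.95, 0.03))), 0L)
  expect_equal(nrow(callRetainedIntrons(mk_stats(25, 0.95, 0.05, TRUE))),
               0L)
  # monotone: stricter thresholds call a subset
  st <- rbind(mk_stats(25, 0.95, 0.05), mk_stats(21, 0.92, 0.05),
              mk_stats(40, 0.99, 0.05))
  loose <- callRetainedIntrons(st, minReads = 20, minCov = 0.90)
  strict <- callRetainedIntrons(st, minReads = 24, minCov = 0.94)
  expect_true(all(strict$n_bsj_reads_spanning %in%
                    loose$n_bsj_reads_spanning))
  expect_lte(nrow(strict), nrow(loose))
})

test_that("novel-exon detection needs AG/GT flanks and 2-read support", {
  # toy genome: gene with 2 exons at 100..200 and 400..500 (0-based),
  # candidate segment 260..320 inside the intron
  set.seed(99)
  seqc <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  seqc[201:202] <- c("G", "T"); seqc[399:400] <- c("A", "G")
  seqc[259:260] <- c("A", "G"); seqc[321:322] <- c("G", "T")
  genome <- DNAStringSet(paste(seqc, collapse = ""))
  names(genome) <- "chr1"
  ex <- GRanges("chr1", IRanges(c(101, 401), c(200, 500)), strand = "+")
  mcols(ex)$phase <- c(0L, 2L)
  genes <- GRanges("chr1", IRanges(101, 500), strand = "+",
                   gene_id = "g", is_rRNA = FALSE)
  models <- GeneModelSet(genes, GRangesList(ex))
  cand2 <- function(ids, starts, sizes) do.call(rbind, lapply(ids, function(i)
    mk_cand(i, corr_start = 100L, corr_end = 500L, t_starts = starts,
            sizes = sizes)))
  with_ne <- cand2(c("a", "b"), c(100L, 260L, 400L), c(100L, 60L, 100L))
  ne <- detectNovelExons(with_ne, genome, models)
  novel <- ne[ne$category != "known", , drop = FALSE]
  expect_equal(nrow(novel), 1L)
  expect_equal(novel$start, 260L)
  expect_equal(novel$end, 320L)
  expect_equal(novel$category, "unique_novel")
  expect_equal(novel$n_supporting_reads, 2L)
  # a single corroborating read is not enough
  one <- cand2("a", c(100L, 260L, 400L), c(100L, 60L, 100L))
  ne1 <- detectNovelExons(one, genome, models)
  expect_equal(nrow(ne1[ne1$category != "known", ]), 0L)
  # without the AG (AC..GT instead): no exon
  seqc2 <- seqc; seqc2[259:260] <- c("A", "C")
  genome2 <- DNAStringSet(paste(seqc2, collapse = "")); names(genome2) <- "chr1"
  ne2 <- detectNovelExons(with_ne, genome2, models)
  expect_equal(nrow(ne2[ne2$category != "known", ]), 0L)
  # blocks split by a <=10 bp internal deletion merge back into one exon
  split_reads <- cand2(c("a", "b"), c(100L, 260L, 290L, 400L),
                       c(100L, 20L, 30L, 100L))
  ne3 <- detectNovelExons(split_reads, genome, models)
  nov3 <- ne3[ne3$category != "known", , drop = FALSE]
  expect_equal(nrow(nov3), 1L)
  expect_equal(c(nov3$start, nov3$end), c(260L, 320L))
  # an 11-bp gap stays split and neither part is AG/GT flanked
  split11 <- cand2(c("a", "b"), c(100L, 260L, 291L, 400L),
                   c(100L, 20L, 29L, 100L))
  ne4 <- detectNovelExons(split11, genome, models)
  expect_equal(nrow(ne4[ne4$category != "known", ]), 0L)
})

test_that("minus-strand flanks use the reverse-complement signature", {
  # exon on -: needs genomic AC immediately 5' (left) and CT 3' (right)
  set.seed(1)
  seqc <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  seqc[259:260] <- c("A", "C"); seqc[321:322] <- c("C", "T")
  # annotated intron flanks for the minus-strand gene: CT..AC
  seqc[201:202] <- c("C", "T"); seqc[399:400] <- c("A", "C")
  genome <- DNAStringSet(paste(seqc, collapse = "")); names(genome) <- "chr1"
  ex <- GRanges("chr1", IRanges(c(101, 401), c(200, 500)), strand = "-")
  mcols(ex)$phase <- c(2L, 0L)
  genes <- GRanges("chr1", IRanges(101, 500), strand = "-",
                   gene_id = "g", is_rRNA = FALSE)
  models <- GeneModelSet(genes, GRangesList(ex))
  cands <- do.call(rbind, lapply(c("a", "b"), function(i)
    mk_cand(i, strand = "-", corr_start = 100L, corr_end = 500L,
            t_starts = c(100L, 260L, 400L), sizes = c(100L, 60L, 100L))))
  ne <- detectNovelExons(cands, genome, models)
  novel <- ne[ne$category != "known", , drop = FALSE]
  expect_equal(nrow(novel), 1L)
  expect_equal(novel$strand, "-")
  expect_equal(novel$category, "unique_novel")
})

test_that("planted splicing phenomena are recovered with correct labels", {
  sh <- shared_sim()
  truth <- sh$ref$features
  ne <- as.data.frame(sh$feats$novel_exons)
  ri <- as.data.frame(sh$feats$retained_introns)
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (tr$type %in% c("retained_intron_full", "retained_intron_partial")) {
      hit <- ri[ri$intron_start == tr$start & ri$intron_end == tr$end, ]
      expect_equal(nrow(hit), 1L, label = tr$type)
      expect_gte(hit$n_bsj_reads_spanning, 20L)
      expect_gte(hit$intron_coverage_fraction, 0.9)
    } else {
      hit <- ne[ne$start == tr$start & ne$end == tr$end, ]
      expect_equal(nrow(hit), 1L, label = tr$type)
      expect_gte(hit$n_supporting_reads, 2L)
      lab <- switch(tr$type,
                    unique_novel_exon = hit$category,
                    cryptic_exon = hit$category,
                    microexon_12 = hit$microexon_class,
                    microexon_20 = hit$microexon_class,
                    stop_exon = hit$frame_class)
      expect_equal(lab, tr$expected, label = tr$type)
    }
  }
  # no exon lacking AG/GT flanks is ever reported: verify on the genome
  gseq <- sh$ref$genome
  for (i in seq_len(nrow(ne))) {
    left <- as.character(subseq(gseq[[ne$chrom[i]]], ne$start[i] - 1L,
                                ne$start[i]))
    right <- as.character(subseq(gseq[[ne$chrom[i]]], ne$end[i] + 1L,
                                 ne$end[i] + 2L))
    expect_equal(paste0(left, right), "AGGT")
  }
  # the cryptic exon shares exactly one splice site
  cr <- ne[ne$category == "cryptic_novel", ]
  expect_true(all(xor(cr$shares_5prime, cr$shares_3prime)))
})

test_that("constitutive exons of single-isoform circRNAs have usage 1", {
  sh <- shared_sim()
  us <- as.data.frame(sh$feats$exon_usage)
  # genes 8..12 have a single isoform: every exon constitutive
  plain <- sh$ref$circs$gene_id[8:12]
  keys <- vapply(seq_len(nrow(sh$ref$circs))[8:12], function(i)
    paste(sh$ref$circs$chrom[i], "+", sh$ref$circs$start[i],
          sh$ref$circs$end[i], sep = ":"), character(1))
  sub <- us[us$circ_key %in% keys, ]
  expect_gt(nrow(sub), 0L)
  expect_true(all(sub$usage_level == 1))
  expect_true(all(us$usage_level >= 0 & us$usage_level <= 1))
})
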