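# Shared fixtures, all built in code.

library(GenomicRanges)
library(S4Vectors)
library(Biostrings)

# one alignment hit in the plain-table form every caller-facing function
# accepts (single block spanning the hit unless blocks are given)
mk_hit <- function(read_id = "r1", q_start = 0L, q_end = NULL,
                   t_chrom = "chr1", t_start = 0L, t_end = 100L,
                   strand = "+", matches = NULL, mismatches = 0L,
                   q_gap_count = 0L, t_gap_count = 0L, sizes = NULL,
                   t_starts = NULL, q_starts = NULL, q_size = 1000L,
                   t_size = 100000L) {
  if (is.null(sizes)) { sizes <- t_end - t_start; t_starts <- t_start }
  if (is.null(t_starts)) t_starts <- t_start
  if (is.null(matches)) matches <- sum(sizes) - mismatches
  if (is.null(q_end)) q_end <- q_start + sum(sizes)
  if (is.null(q_starts)) q_starts <- q_start + cumsum(c(0L, sizes))[
    seq_along(sizes)]
  data.frame(read_id = read_id, q_size = q_size,
             q_start = q_start, q_end = q_end, t_chrom = t_chrom,
             t_size = t_size, t_start = t_start, t_end = t_end,
             strand = strand, matches = matches, mismatches = mismatches,
             rep_matches = 0L, n_count = 0L,
             q_gap_count = q_gap_count, t_gap_count = t_gap_count,
             block_sizes = I(list(as.integer(sizes))),
             block_q_starts = I(list(as.integer(q_starts))),
             block_t_starts = I(list(as.integer(t_starts))),
             stringsAsFactors = FALSE)
}

# an end-corrected BSJ-candidate row (plain table) for the splice-feature
# functions
mk_cand <- function(read_id, chrom = "chr1", strand = "+",
                    corr_start, corr_end, t_starts, sizes,
                    bp_gene = 0L, bp_exon = 0L, bp_intron = 0L,
                    bp_est = 0L) {
  data.frame(read_id = read_id, t_chrom = chrom, strand = strand,
             circ_start = corr_start, circ_end = corr_end,
             corr_start = corr_start, corr_end = corr_end,
             adjust_start = 0L, adjust_end = 0L,
             bp_gene = bp_gene, bp_exon = bp_exon, bp_intron = bp_intron,
             bp_est = bp_est,
             block_t_starts = I(list(as.integer(t_starts))),
             block_sizes = I(list(as.integer(sizes))),
             stringsAsFactors = FALSE)
}

bind_rows_df <- function(...) do.call(rbind, list(...))

# tiny two-gene annotation: gene A (+, 3 exons) and gene B (-, 2 exons)
mk_models <- function() {
  exA <- GRanges("chr1", IRanges(c(1001, 1501, 2001), c(1200, 1700, 2200)),
                 strand = "+")
  mcols(exA)$phase <- c(0L, 2L, 1L)
  exB <- GRanges("chr1", IRanges(c(5001, 5501), c(5200, 5700)),
                 strand = "-")
  mcols(exB)$phase <- c(NA_integer_, NA_integer_)
  genes <- GRanges("chr1", IRanges(c(1001, 5001), c(2200, 5700)),
                   strand = c("+", "-"))
  mcols(genes)$gene_id <- c("geneA", "geneB")
  mcols(genes)$is_rRNA <- c(FALSE, FALSE)
  GeneModelSet(genes, GRangesList(exA, exB))
}

# CircRNASet from bare coordinates (0-based half-open)
mk_circset <- function(chrom, start0, end0, strand = "+") {
  n <- length(start0)
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  mcols(gr) <- DataFrame(
    n_reads = rep(1L, n), host_gene = rep(NA_character_, n),
    circBase_id = rep(NA_character_, n),
    circAtlas_id = rep(NA_character_, n),
    CIRCpedia_id = rep(NA_character_, n),
    mean_bp_gene = numeric(n), mean_bp_exon = numeric(n),
    mean_bp_intron = numeric(n), mean_bp_est = numeric(n),
    adjust_min = numeric(n), adjust_max = numeric(n),
    adjust_mean = numeric(n), is_novel = rep(TRUE, n))
  CircRNASet(gr)
}

# single-chain ChainMap built from a block table (0-based)
mk_chain <- function(t_name = "chr1", t_size = 100000L, q_name = "chr1",
                     q_size = 100000L, q_strand = "+", blocks,
                     score = 1000) {
  blocks <- as.data.frame(blocks)
  names(blocks) <- c("t_start", "q_start", "size")
  ch <- list(score = score, t_name = t_name, t_size = t_size,
             t_start = min(blocks$t_start),
             t_end = max(blocks$t_start + blocks$size),
             q_name = q_name, q_size = q_size, q_strand = q_strand,
             q_start = min(blocks$q_start),
             q_end = max(blocks$q_start + blocks$size),
             id = "1", blocks = blocks)
  new("ChainMap", chains = list(ch))
}

# identity ChainMap over the given chromosome sizes
mk_identity_chain <- function(sizes) {
  chains <- lapply(names(sizes), function(ch)
    list(score = 1000, t_name = ch, t_size = sizes[[ch]], t_start = 0L,
         t_end = sizes[[ch]], q_name = ch, q_size = sizes[[ch]],
         q_strand = "+", q_start = 0L, q_end = sizes[[ch]], id = "1",
         blocks = data.frame(t_start = 0L, q_start = 0L,
                             size = sizes[[ch]])))
  new("ChainMap", chains = chains)
}

# the standard simulated dataset, built once per test run
shared_sim <- local({
  env <- new.env()
  function() {
    if (is.null(env$x)) {
      ref <- makeReference(simConfig(seed = 1))
      sim <- simulateCircReads(ref)
      call <- callCircRNAs(sim$hits, ref$models, ref$known)
      feats <- circFeatures(call, ref$models, ref$genome)
      env$x <- list(ref = ref, sim = sim, call = call, feats = feats)
    }
    env$x
  }
})
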