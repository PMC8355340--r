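# End-to-end orchestration: filter -> call -> features -> conserve ->
# report, with a resolved config, per-stage accounting and idempotent
# output.

#' Pipeline configuration
#'
#' All thresholds default to the calling criteria the pipeline is built
#' around: per-side Blat score 30, 1 Mb span, < 50 bp hit overlap, 30 bp
#' end snap, 95% known-circRNA Jaccard, intron-retention gates 20 reads /
#' 90% coverage / 3% intronic fraction, novel-exon gates 2 reads / 10 bp
#' internal deletion, exon-usage gates 10 (nick mode) or 50 (panel mode)
#' reads, microexon bounds 3-15/16-29 nt, poly(A) run length 7.
#'
#' @param fastq,psl,genome,genes input files (FASTQ, PSL, FASTA, gene-model
#'   TSV)
#' @param known character vector of known-circRNA catalog files (optional)
#' @param out_dir output directory
#' @param mode "nick" or "panel" (switches the exon-usage read gate)
#' @param min_qual,min_len read filters (Phred, bp)
#' @param min_score,max_span,max_overlap BSJ pairing criteria
#' @param snap_bp,known_jaccard end-correction criteria
#' @param ir_min_reads,ir_min_cov,ir_min_fraction retained-intron gates
#' @param ne_min_reads,ne_merge_gap,ne_known_sim novel-exon gates
#' @param usage_min_reads exon-usage gate; NULL = 10/50 by mode
#' @param polya_k poly(A) stretch length
#' @param mito_chroms mitochondrial chromosome names
#' @param force rerun even when outputs for the same config exist
#' @return config list
#' @export
pipelineConfig <- function(fastq, psl, genome, genes, known = character(),
                           out_dir = "longcirc_out",
                           mode = c("nick", "panel"),
                           min_qual = 7, min_len = 250, min_score = 30,
                           max_span = 1e6, max_overlap = 50, snap_bp = 30,
                           known_jaccard = 0.95, ir_min_reads = 20,
                           ir_min_cov = 0.90, ir_min_fraction = 0.03,
                           ne_min_reads = 2, ne_merge_gap = 10,
                           ne_known_sim = 0.95, usage_min_reads = NULL,
                           polya_k = 7,
                           mito_chroms = c("chrM", "MT", "chrMT"),
                           force = FALSE) {
  mode <- match.arg(mode)
  if (is.null(usage_min_reads))
    usage_min_reads <- if (mode == "nick") 10L else 50L
  as.list(environment())
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds any subset of [pipelineConfig()]'s arguments; unset keys
#' take the defaults.
#'
#' @param path YAML file
#' @return config list (see [pipelineConfig()])
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown config keys in '", path, "': ",
         paste(extra, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("force", "out_dir"))]
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  as.character(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647)
}

.write_df <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the circRNA pipeline end to end
#'
#' Filters reads, pairs split alignments into BSJ candidates, end-corrects
#' and collapses them into a unique circRNA table, characterizes
#' circRNA-internal splicing (novel/cryptic exons, microexons, intron
#' retention, exon usage) for every multi-exon circRNA, and writes the
#' result tables, a per-read BED12 isoform file, a run summary (text +
#' JSON) and a log into `out_dir`. Deterministic given inputs and config;
#' rerunning with an unchanged config is a no-op unless `force`.
#'
#' @param config a [pipelineConfig()]
#' @return list: `circs` ([CircRNASet]), `summary`, `novel_exons`,
#'   `introns`, `retained_introns`, `exon_usage`, `classes`
#' @export
runPipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash_file <- file.path(config$out_dir, "config.hash")
  hash <- .config_hash(config)
  summary_file <- file.path(config$out_dir, "summary.json")
  if (!isTRUE(config$force) && file.exists(hash_file) &&
      file.exists(summary_file) &&
      identical(readLines(hash_file, warn = FALSE)[1], hash)) {
    message("outputs up to date for this config; skipping (use force)")
    return(invisible(NULL))
  }
  unlink(c(summary_file, hash_file))
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  for (f in c("fastq", "psl", "genome", "genes"))
    if (!file.exists(config[[f]]))
      stop("input ", f, " file not found: ", config[[f]])

  reads <- readLongReads(config$fastq)
  filtered <- filterReads(reads, config$min_qual, config$min_len)
  say("reads: ", length(reads), " total, ", length(filtered),
      " pass Q>=", config$min_qual, " and length>=", config$min_len)

  hits <- parsePsl(config$psl)
  hits <- hits[hits$read_id %in% names(filtered), , drop = FALSE]
  say("alignments: ", nrow(hits), " hits from ",
      length(unique(hits$read_id)), " filtered reads")

  models <- readGeneModels(config$genes)
  known <- NULL
  if (length(config$known)) {
    kn <- lapply(config$known, readKnownCircs)
    known <- do.call(c, kn)
  }
  genome <- readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  call <- callCircRNAs(hits, models, known,
                       minScore = config$min_score,
                       maxSpan = config$max_span,
                       maxOverlap = config$max_overlap,
                       snapBp = config$snap_bp,
                       knownJaccard = config$known_jaccard,
                       mitoChroms = config$mito_chroms)
  say("called ", length(call$circs), " unique circRNAs (",
      call$n_rejected_ends, " candidate reads without end anchor)")

  feats <- circFeatures(call, models, genome,
                        ne_min_reads = config$ne_min_reads,
                        ne_merge_gap = config$ne_merge_gap,
                        ne_known_sim = config$ne_known_sim,
                        ir_min_reads = config$ir_min_reads,
                        ir_min_cov = config$ir_min_cov,
                        ir_min_fraction = config$ir_min_fraction,
                        usage_min_reads = config$usage_min_reads)
  say("features: ", nrow(feats$novel_exons), " novel-exon candidates, ",
      nrow(feats$retained_introns), " retained introns")

  smry <- summarizeRun(call$classes, call$circs, length(filtered))
  circ_df <- as.data.frame(call$circs)
  circ_df$has_polyA_stretch <- vapply(seq_len(nrow(circ_df)), function(i) {
    s <- .seq0(genome, circ_df$chrom[i], circ_df$start[i], circ_df$end[i])
    if (is.na(s)) NA else polyAStretch(s, config$polya_k)
  }, logical(1))

  .write_df(circ_df, file.path(config$out_dir, "circs.tsv"))
  .write_df(feats$novel_exons, file.path(config$out_dir,
                                         "novel_exons.tsv"))
  .write_df(feats$introns, file.path(config$out_dir, "introns.tsv"))
  .write_df(feats$retained_introns,
            file.path(config$out_dir, "retained_introns.tsv"))
  .write_df(feats$exon_usage, file.path(config$out_dir, "exon_usage.tsv"))
  .write_df(as.data.frame(call$classes),
            file.path(config$out_dir, "read_classes.tsv"))
  .write_read_bed12(call$candidates, config$ne_merge_gap,
                    file.path(config$out_dir, "read_isoforms.bed"))
  jsonlite::write_json(smry, summary_file, auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(config$out_dir, "run.log"))
  writeLines(hash, hash_file)
  invisible(list(circs = call$circs, summary = smry,
                 novel_exons = feats$novel_exons, introns = feats$introns,
                 retained_introns = feats$retained_introns,
                 exon_usage = feats$exon_usage, classes = call$classes))
}

# per-read BED12: merged block structure clamped to the corrected span
.write_read_bed12 <- function(cands, mergeGap, path) {
  if (is.null(cands) || nrow(cands) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  blocks <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    segs <- .merge_blocks(cands$block_t_starts[[i]],
                          cands$block_sizes[[i]], mergeGap)
    s0 <- cands$corr_start[i]; e0 <- cands$corr_end[i]
    segs[, 1] <- pmax(segs[, 1], s0); segs[, 2] <- pmin(segs[, 2], e0)
    segs <- segs[segs[, 2] > segs[, 1], , drop = FALSE]
    segs[1, 1] <- s0; segs[nrow(segs), 2] <- e0
    blocks[[i]] <- IRanges(segs[, 1] - s0 + 1L, segs[, 2] - s0)
  }
  gr <- .gr1(cands$t_chrom, cands$corr_start, cands$corr_end,
             cands$strand)
  mcols(gr)$name <- cands$read_id
  mcols(gr)$score <- 0L
  mcols(gr)$blocks <- IRangesList(blocks)
  writeBed12(gr, path)
}

#' Splicing features for every called circRNA
#'
#' Runs novel-exon detection, intron coverage/retention and exon usage per
#' circRNA (single-exon circRNAs, whose reads carry no internal splice
#' evidence, are skipped in the novel-exon scan).
#'
#' @param call output of [callCircRNAs()]
#' @param models a [GeneModelSet]
#' @param genome DNAStringSet
#' @param ne_min_reads,ne_merge_gap,ne_known_sim novel-exon gates
#' @param ir_min_reads,ir_min_cov,ir_min_fraction retained-intron gates
#' @param usage_min_reads exon-usage suppression gate
#' @return list of DataFrames: `novel_exons`, `introns`,
#'   `retained_introns`, `exon_usage`, each keyed by `circ_key`
#' @export
circFeatures <- function(call, models, genome, ne_min_reads = 2,
                         ne_merge_gap = 10, ne_known_sim = 0.95,
                         ir_min_reads = 20, ir_min_cov = 0.90,
                         ir_min_fraction = 0.03, usage_min_reads = 10) {
  add_key <- function(df, key) {
    if (nrow(df)) df$circ_key <- key
    else df$circ_key <- character(0)
    df
  }
  ne_all <- list(); ir_all <- list(); us_all <- list()
  cands <- call$candidates
  gr <- circRanges(call$circs)
  exons_bg <- exonsByGene(models)
  introns_bg <- intronsByGene(models)
  for (i in seq_along(gr)) {
    key <- paste(as.character(seqnames(gr))[i],
                 as.character(strand(gr))[i],
                 start(gr)[i] - 1L, end(gr)[i], sep = ":")
    cc <- cands[cands$circ_key == key, , drop = FALSE]
    host <- mcols(gr)$host_gene[i]
    if (is.na(host)) next
    host_ex <- exons_bg[[host]]
    in_span <- start(host_ex) >= start(gr)[i] & end(host_ex) <= end(gr)[i]
    host_ex <- host_ex[in_span]
    host_in <- introns_bg[[host]]
    host_in <- host_in[start(host_in) >= start(gr)[i] &
                         end(host_in) <= end(gr)[i]]
    ne <- if (length(host_ex) >= 2L)
      detectNovelExons(cc, genome, models, minReads = ne_min_reads,
                       mergeGap = ne_merge_gap, knownSim = ne_known_sim)
    else detectNovelExons(cc[0, ], genome, models)
    ic <- intronCoverage(cc, host_in, ne)
    us <- exonUsage(cc, host_ex, minReads = usage_min_reads)
    ne_all[[key]] <- add_key(ne[ne$category != "known", , drop = FALSE],
                             key)
    ir_all[[key]] <- add_key(ic, key)
    us_all[[key]] <- add_key(us, key)
  }
  bind <- function(lst, empty) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst)) do.call(rbind, lst) else add_key(empty, character(0))
  }
  ne <- bind(ne_all, detectNovelExons(NULL, genome, models))
  ic <- bind(ir_all, intronCoverage(NULL, GRanges()))
  us <- bind(us_all, exonUsage(NULL, GRanges()))
  ri <- callRetainedIntrons(ic, minReads = ir_min_reads,
                            minCov = ir_min_cov,
                            minIntronicFraction = ir_min_fraction)
  list(novel_exons = ne, introns = ic, retained_introns = ri,
       exon_usage = us)
}
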