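# Deterministic simulator: toy genome, gene models, circRNA isoforms,
# once-nicked and concatemeric long reads, ideal-aligner PSL and ground
# truth. The simulator emulates the two library designs the pipeline
# targets: molecules of a circular template opened by exactly one nick at a
# uniform position (once-nicked fragments), and strand-displacing
# reverse-transcription products that run several times around the circle
# (concatemers). The alignments an ideal split aligner would report are
# emitted directly as PSL, which keeps the testbed offline and isolates the
# calling logic from aligner behavior.

#' Simulator configuration
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: a dozen multi-exon genes on two toy chromosomes, one circRNA per
#' gene, depth 30 per circRNA, error-free reads with mean quality ~12, no
#' concatemers, and one planted instance of each splicing phenomenon.
#'
#' @param seed integer seed; fully determines all outputs
#' @param n_genes number of genes (and circRNA loci); >= 8 when
#'   `plant_features`
#' @param depth reads per circRNA (split over its isoforms by frequency)
#' @param mismatch_rate,insertion_rate,deletion_rate per-base error rates
#' @param mean_q,sd_q per-base quality model (Phred), truncated to \[2, 40\]
#' @param concatemer_fraction fraction of molecules sequenced as multi-round
#'   concatemers
#' @param rounds_range range of rounds for concatemers (continuous)
#' @param known_fraction fraction of circRNAs entered into the known
#'   catalogs (cycled over circBase/circAtlas/CIRCpedia)
#' @param shift coordinate shift of the second toy assembly
#' @param end_noise max bp trimmed from the BSJ-adjacent hit ends (exercises
#'   the 30-bp snap); 0 = exact ends
#' @param n_junk_short,n_junk_lowq unmappable reads failing the length /
#'   quality filter, to exercise read filtering
#' @param plant_features plant one instance of each splicing phenomenon
#' @return a validated config list
#' @export
simConfig <- function(seed = 1L, n_genes = 12L, depth = 30L,
                      mismatch_rate = 0, insertion_rate = 0,
                      deletion_rate = 0, mean_q = 12, sd_q = 2,
                      concatemer_fraction = 0, rounds_range = c(2, 3),
                      known_fraction = 0.5, shift = 1000L, end_noise = 0L,
                      n_junk_short = 2L, n_junk_lowq = 2L,
                      plant_features = TRUE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              depth = as.integer(depth), mismatch_rate = mismatch_rate,
              insertion_rate = insertion_rate,
              deletion_rate = deletion_rate, mean_q = mean_q, sd_q = sd_q,
              concatemer_fraction = concatemer_fraction,
              rounds_range = rounds_range,
              known_fraction = known_fraction, shift = as.integer(shift),
              end_noise = as.integer(end_noise),
              n_junk_short = as.integer(n_junk_short),
              n_junk_lowq = as.integer(n_junk_lowq),
              plant_features = plant_features)
  probs <- c(cfg$mismatch_rate, cfg$insertion_rate, cfg$deletion_rate,
             cfg$concatemer_fraction, cfg$known_fraction)
  if (any(probs < 0 | probs > 1))
    stop("simConfig: probabilities must be in [0, 1]")
  if (cfg$plant_features && cfg$n_genes < 8L)
    stop("simConfig: plant_features needs n_genes >= 8")
  if (cfg$end_noise > 15L)
    stop("simConfig: end_noise must stay below half the snap window")
  cfg
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.plant <- function(seqs, chrom, s0, bases) {
  # overwrite genome bases at 0-based position s0
  substr(seqs[[chrom]], s0 + 1L, s0 + nchar(bases)) <- bases
  seqs
}

#' Build the toy reference for a simulation
#'
#' Genes are laid out with canonical GT..AG introns (so planted exons carry
#' correct splice flanks), per-exon coding phases, and one circRNA per gene
#' spanning all of its exons. When `plant_features` is set, genes 1-7 carry
#' one instance each of: a fully retained intron, a partially retained
#' intron, a unique novel exon, a cryptic exon sharing its 3' splice site,
#' microexons of 12 and 20 nt, and a novel exon introducing an in-frame
#' stop codon. A fraction of the circRNAs is entered into the known
#' catalogs, and a coordinate-shifted second assembly with chains in both
#' directions supports conservation tests.
#'
#' @param config a [simConfig()]
#' @return list: `genome` (DNAStringSet), `models` ([GeneModelSet]),
#'   `known` (GRanges), `chainsAB`/`chainsBA` ([ChainMap]s), `circs`
#'   (truth data.frame), `isoforms` (per-circ isoform plans), `features`
#'   (planted-feature truth data.frame), `config`
#' @export
makeReference <- function(config = simConfig()) {
  set.seed(config$seed)
  n <- config$n_genes
  genes <- vector("list", n)
  cursor <- c(chr1 = 500L, chr2 = 500L)
  for (i in seq_len(n)) {
    chrom <- if (i <= ceiling(n * 2 / 3)) "chr1" else "chr2"
    k <- 3L + (i %% 3L)                       # 3..5 exons
    exon_len <- 120L + 20L * ((i + seq_len(k)) %% 4L)
    intron_len <- 150L + 30L * (seq_len(k - 1L) %% 3L)
    starts <- integer(k)
    pos <- cursor[[chrom]]
    for (j in seq_len(k)) {
      starts[j] <- pos
      pos <- pos + exon_len[j] + if (j < k) intron_len[j] else 0L
    }
    cursor[[chrom]] <- pos + 300L + (i * 37L) %% 200L
    phases <- integer(k)
    for (j in seq_len(k)[-1])
      phases[j] <- .next_phase(phases[j - 1L], exon_len[j - 1L])
    genes[[i]] <- list(gene_id = sprintf("g%02d", i), chrom = chrom,
                       strand = "+", starts0 = starts,
                       ends0 = starts + exon_len, phases = phases)
  }
  sizes <- cursor + 500L
  seqs <- lapply(sizes, .rand_dna)
  # canonical splice flanks for every annotated intron
  for (g in genes) {
    k <- length(g$starts0)
    if (k < 2L) next
    for (j in seq_len(k - 1L)) {
      seqs <- .plant(seqs, g$chrom, g$ends0[j], "GT")
      seqs <- .plant(seqs, g$chrom, g$starts0[j + 1L] - 2L, "AG")
    }
  }

  # isoform plans: list of isoforms, each a list(intervals = 2-col matrix
  # of 0-based [s, e), freq, features = character vector)
  isoforms <- vector("list", n)
  feat_rows <- list()
  add_feat <- function(type, gene, s0, e0, extra = NA_character_) {
    feat_rows[[length(feat_rows) + 1L]] <<- data.frame(
      type = type, gene_id = gene$gene_id,
      circ_id = paste0("circ_", gene$gene_id), chrom = gene$chrom,
      start = s0, end = e0, expected = extra, stringsAsFactors = FALSE)
  }
  base_iso <- function(g) list(
    intervals = cbind(g$starts0, g$ends0), freq = 1, features = character())
  retained_iso <- function(g, j) {
    # intron j merged with its flanking exons
    s <- g$starts0; e <- g$ends0
    iv <- cbind(s[-(j + 1L)], e[-j])
    list(intervals = iv, freq = 1, features = "retained_intron")
  }
  insert_exon_iso <- function(g, s0, e0, feat) {
    iv <- rbind(cbind(g$starts0, g$ends0), c(s0, e0))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    list(intervals = iv, freq = 1, features = feat)
  }
  plant_novel <- function(g, len, offset = 40L) {
    # inside intron 2 (after exon 2), with AG/GT flanks
    s0 <- g$ends0[2L] + offset
    e0 <- s0 + len
    seqs <<- .plant(seqs, g$chrom, s0 - 2L, "AG")
    seqs <<- .plant(seqs, g$chrom, e0, "GT")
    c(s0, e0)
  }

  for (i in seq_len(n)) {
    g <- genes[[i]]
    isoforms[[i]] <- list(base_iso(g))
  }
  if (config$plant_features) {
    g <- genes[[1]]                           # fully retained intron 2
    iso <- retained_iso(g, 2L); iso$freq <- 1
    isoforms[[1]] <- list(iso)
    add_feat("retained_intron_full", g, g$ends0[2L], g$starts0[3L],
             "retained")
    g <- genes[[2]]                           # partially retained intron 2
    iso_a <- base_iso(g); iso_a$freq <- 0.6
    iso_b <- retained_iso(g, 2L); iso_b$freq <- 0.4
    isoforms[[2]] <- list(iso_a, iso_b)
    add_feat("retained_intron_partial", g, g$ends0[2L], g$starts0[3L],
             "retained")
    g <- genes[[3]]                           # unique novel exon, 60 nt
    se <- plant_novel(g, 60L)
    iso_a <- base_iso(g); iso_a$freq <- 0.5
    iso_b <- insert_exon_iso(g, se[1], se[2], "novel_exon")
    iso_b$freq <- 0.5
    isoforms[[3]] <- list(iso_a, iso_b)
    add_feat("unique_novel_exon", g, se[1], se[2], "unique_novel")
    g <- genes[[4]]                           # cryptic exon: exon 2
    ext <- 25L                                # extended 25 nt at its 5' side
    s0 <- g$starts0[2L] - ext
    seqs <- .plant(seqs, g$chrom, s0 - 2L, "AG")
    iv <- cbind(g$starts0, g$ends0); iv[2L, 1L] <- s0
    iso_a <- base_iso(g); iso_a$freq <- 0.5
    iso_b <- list(intervals = iv, freq = 0.5, features = "cryptic_exon")
    isoforms[[4]] <- list(iso_a, iso_b)
    add_feat("cryptic_exon", g, s0, g$ends0[2L], "cryptic_novel")
    g <- genes[[5]]                           # microexon 12 nt
    se <- plant_novel(g, 12L)
    iso_a <- base_iso(g); iso_a$freq <- 0.5
    iso_b <- insert_exon_iso(g, se[1], se[2], "microexon_12")
    iso_b$freq <- 0.5
    isoforms[[5]] <- list(iso_a, iso_b)
    add_feat("microexon_12", g, se[1], se[2], "me_3_15")
    g <- genes[[6]]                           # microexon 20 nt
    se <- plant_novel(g, 20L)
    iso_a <- base_iso(g); iso_a$freq <- 0.5
    iso_b <- insert_exon_iso(g, se[1], se[2], "microexon_20")
    iso_b$freq <- 0.5
    isoforms[[6]] <- list(iso_a, iso_b)
    add_feat("microexon_20", g, se[1], se[2], "me_16_29")
    g <- genes[[7]]                           # 9-nt exon with in-frame stop
    se <- plant_novel(g, 9L)
    ph <- .next_phase(g$phases[2L], g$ends0[2L] - g$starts0[2L])
    body <- rep("C", 9L)
    body[(ph + 1L):(ph + 3L)] <- c("T", "A", "A")
    seqs <- .plant(seqs, g$chrom, se[1], paste(body, collapse = ""))
    iso_a <- base_iso(g); iso_a$freq <- 0.5
    iso_b <- insert_exon_iso(g, se[1], se[2], "stop_exon")
    iso_b$freq <- 0.5
    isoforms[[7]] <- list(iso_a, iso_b)
    add_feat("stop_exon", g, se[1], se[2], "in_frame_stop")
  }
  # normalize isoform frequencies and fix per-isoform depths
  for (i in seq_len(n)) {
    fr <- vapply(isoforms[[i]], `[[`, numeric(1), "freq")
    fr <- fr / sum(fr)
    d <- floor(config$depth * fr)
    d[1] <- d[1] + config$depth - sum(d)
    for (j in seq_along(isoforms[[i]])) {
      isoforms[[i]][[j]]$freq <- fr[j]
      isoforms[[i]][[j]]$depth <- d[j]
      isoforms[[i]][[j]]$isoform_id <-
        sprintf("circ_%s.iso%d", genes[[i]]$gene_id, j)
    }
  }

  genome <- DNAStringSet(unlist(seqs))
  names(genome) <- names(seqs)
  exon_list <- lapply(genes, function(g) {
    ex <- GRanges(g$chrom, IRanges(g$starts0 + 1L, g$ends0),
                  strand = g$strand)
    mcols(ex)$phase <- g$phases
    ex
  })
  gene_gr <- GRanges(
    vapply(genes, `[[`, character(1), "chrom"),
    IRanges(vapply(genes, function(g) min(g$starts0), integer(1)) + 1L,
            vapply(genes, function(g) max(g$ends0), integer(1))),
    strand = vapply(genes, `[[`, character(1), "strand"))
  mcols(gene_gr)$gene_id <- vapply(genes, `[[`, character(1), "gene_id")
  mcols(gene_gr)$is_rRNA <- FALSE
  models <- GeneModelSet(gene_gr, GRangesList(exon_list))

  circs <- data.frame(
    circ_id = paste0("circ_", mcols(gene_gr)$gene_id),
    gene_id = mcols(gene_gr)$gene_id,
    chrom = as.character(seqnames(gene_gr)),
    strand = as.character(strand(gene_gr)),
    start = start(gene_gr) - 1L, end = end(gene_gr),
    stringsAsFactors = FALSE)

  n_known <- round(config$known_fraction * n)
  dbs <- c("circBase", "circAtlas", "CIRCpedia")
  known <- GRanges()
  if (n_known > 0) {
    idx <- seq_len(n_known)
    known <- GRanges(circs$chrom[idx],
                     IRanges(circs$start[idx] + 1L, circs$end[idx]),
                     strand = circs$strand[idx])
    mcols(known)$circ_id <- paste0("db_", circs$circ_id[idx])
    mcols(known)$db_name <- dbs[(idx - 1L) %% 3L + 1L]
  }

  mk_chain <- function(forward) {
    chains <- lapply(names(sizes), function(ch) {
      L <- sizes[[ch]]
      if (forward)
        list(score = 1000, t_name = ch, t_size = L, t_start = 0L,
             t_end = L, q_name = ch, q_size = L + config$shift,
             q_strand = "+", q_start = config$shift,
             q_end = L + config$shift, id = "1",
             blocks = data.frame(t_start = 0L, q_start = config$shift,
                                 size = L))
      else
        list(score = 1000, t_name = ch, t_size = L + config$shift,
             t_start = config$shift, t_end = L + config$shift,
             q_name = ch, q_size = L, q_strand = "+", q_start = 0L,
             q_end = L, id = "1",
             blocks = data.frame(t_start = config$shift, q_start = 0L,
                                 size = L))
    })
    new("ChainMap", chains = chains)
  }

  features <- if (length(feat_rows)) do.call(rbind, feat_rows)
    else data.frame(type = character(), gene_id = character(),
                    circ_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    expected = character(), stringsAsFactors = FALSE)
  list(genome = genome, models = models, known = known,
       chainsAB = mk_chain(TRUE), chainsBA = mk_chain(FALSE),
       circs = circs, isoforms = isoforms, features = features,
       config = config)
}

# transcript interval [a, b) of an isoform -> genomic blocks (0-based),
# ascending
.txt_to_blocks <- function(iv, a, b) {
  lens <- iv[, 2] - iv[, 1]
  cum <- c(0L, cumsum(lens))
  out <- list()
  for (j in seq_len(nrow(iv))) {
    lo <- max(a, cum[j]); hi <- min(b, cum[j + 1L])
    if (hi > lo)
      out[[length(out) + 1L]] <- c(t_start = iv[j, 1] + (lo - cum[j]),
                                   size = hi - lo, q_off = lo - a)
  }
  do.call(rbind, out)
}

# apply the per-base error model to one block of aligned sequence.
# sub_blocks: matrix (t_start, size, q_extra), q_extra = unaligned read
# bases (insertions) immediately after the sub-block.
.mutate_block <- function(tmpl, t_start, mm, ins, del) {
  if (mm == 0 && ins == 0 && del == 0)      # error-free fast path
    return(list(seq = tmpl,
                sub_blocks = matrix(c(t_start, nchar(tmpl), 0L), nrow = 1),
                n_mm = 0L, n_ins = 0L, n_del = 0L))
  bases <- strsplit(tmpl, "")[[1]]
  w <- length(bases)
  out <- character(0)
  subs <- list(); cur_s <- t_start; cur_len <- 0L
  n_mm <- 0L; n_ins <- 0L; n_del <- 0L
  alt <- c("A", "C", "G", "T")
  close_sub <- function(q_extra) {
    if (cur_len > 0L)
      subs[[length(subs) + 1L]] <<- c(cur_s, cur_len, q_extra)
    else if (q_extra > 0L && length(subs))
      subs[[length(subs)]][3] <<- subs[[length(subs)]][3] + q_extra
  }
  for (p in seq_len(w)) {
    if (del > 0 && runif(1) < del) {          # genome base absent from read
      close_sub(0L)
      cur_s <- t_start + p; cur_len <- 0L
      n_del <- n_del + 1L
      next
    }
    b <- bases[p]
    if (mm > 0 && runif(1) < mm) {
      b <- sample(setdiff(alt, bases[p]), 1L)
      n_mm <- n_mm + 1L
    }
    out <- c(out, b)
    cur_len <- cur_len + 1L
    if (ins > 0 && runif(1) < ins && p < w) { # extra read base
      out <- c(out, sample(alt, 1L))
      close_sub(1L)
      cur_s <- t_start + p; cur_len <- 0L
      n_ins <- n_ins + 1L
    }
  }
  close_sub(0L)
  list(seq = paste(out, collapse = ""),
       sub_blocks = do.call(rbind, subs),
       n_mm = n_mm, n_ins = n_ins, n_del = n_del)
}

.phred_string <- function(q) intToUtf8(pmin(93L, q) + 33L)

#' Simulate long reads from the circRNA isoforms of a reference
#'
#' Each molecule picks an isoform, is opened at a uniformly drawn nick
#' position (exactly one nick per molecule), optionally runs several rounds
#' around the circle (concatemer), receives per-base errors and qualities,
#' and is emitted together with the PSL hits an ideal split aligner would
#' report (two hits for a once-nicked molecule, three or more block groups
#' for a concatemer) and a ground-truth record.
#'
#' @param reference output of [makeReference()]
#' @param config a [simConfig()]; defaults to the reference's own config
#' @return list: `reads` (QualityScaledDNAStringSet), `hits` (truth
#'   alignment table, [parsePsl()] schema), `truth` (data.frame: read_id,
#'   circ_id, isoform_id, gene_id, nick, rounds, n_hits, start, end,
#'   features)
#' @export
simulateCircReads <- function(reference, config = reference$config) {
  set.seed(config$seed + 1L)
  genome <- reference$genome
  seq_cache <- lapply(genome, as.character)
  reads <- character(0); quals <- character(0); read_ids <- character(0)
  hit_rows <- list(); truth_rows <- list()
  for (i in seq_along(reference$isoforms)) {
    ci <- reference$circs[i, ]
    for (iso in reference$isoforms[[i]]) {
      iv <- iso$intervals
      tseq <- paste(vapply(seq_len(nrow(iv)), function(j)
        substr(seq_cache[[ci$chrom]], iv[j, 1] + 1L, iv[j, 2]),
        character(1)), collapse = "")
      L <- nchar(tseq)
      for (m in seq_len(iso$depth)) {
        rid <- sprintf("%s_r%03d", iso$isoform_id, m)
        rounds <- 1
        if (config$concatemer_fraction > 0 &&
            runif(1) < config$concatemer_fraction)
          rounds <- runif(1, config$rounds_range[1], config$rounds_range[2])
        nick <- sample.int(L - 1L, 1L)        # never exactly at the BSJ
        total <- round(rounds * L)
        # maximal runs of contiguous transcript positions
        runs <- list(); a <- nick; left <- total
        repeat {
          b <- min(L, a + left)
          runs[[length(runs) + 1L]] <- c(a, b)
          left <- left - (b - a)
          if (left <= 0L) break
          a <- 0L
        }
        # optional trimming of the BSJ-adjacent alignment ends
        d_end <- d_start <- 0L
        if (config$end_noise > 0L && length(runs) == 2L) {
          d_end <- sample.int(config$end_noise + 1L, 1L) - 1L
          d_start <- sample.int(config$end_noise + 1L, 1L) - 1L
        }
        read_seq <- character(0)
        q_cursor <- 0L
        read_hits <- list()
        for (r in seq_along(runs)) {
          blocks <- .txt_to_blocks(iv, runs[[r]][1], runs[[r]][2])
          sub_all <- list(); mm_tot <- 0L; ins_tot <- 0L; del_tot <- 0L
          hseq <- character(0)
          for (k in seq_len(nrow(blocks))) {
            bs <- blocks[k, "t_start"]; bw <- blocks[k, "size"]
            tmpl <- substr(seq_cache[[ci$chrom]], bs + 1L, bs + bw)
            mut <- .mutate_block(tmpl, bs, config$mismatch_rate,
                                 config$insertion_rate,
                                 config$deletion_rate)
            hseq <- c(hseq, mut$seq)
            sub_all[[k]] <- mut$sub_blocks
            mm_tot <- mm_tot + mut$n_mm; ins_tot <- ins_tot + mut$n_ins
            del_tot <- del_tot + mut$n_del
          }
          hseq <- paste(hseq, collapse = "")
          sub <- do.call(rbind, sub_all)
          sub <- sub[sub[, 2] > 0, , drop = FALSE]
          # trim BSJ-adjacent ends of the once-nicked alignments; the
          # trimmed bases stay in the read but unaligned
          trim_hi <- if (r == 1L && length(runs) == 2L) d_end else 0L
          trim_lo <- if (r == 2L && length(runs) == 2L) d_start else 0L
          q_start <- q_cursor; q_len <- nchar(hseq)
          read_seq <- c(read_seq, hseq)
          q_cursor <- q_cursor + q_len
          # never trim a terminal block away entirely (short blocks arise
          # when the nick falls near an exon boundary)
          if (trim_hi > 0L) {
            last <- nrow(sub)
            trim_hi <- min(trim_hi, sub[last, 2] - 1L)
            sub[last, 2] <- sub[last, 2] - trim_hi
          }
          if (trim_lo > 0L) {
            trim_lo <- min(trim_lo, sub[1, 2] - 1L)
            sub[1, 1] <- sub[1, 1] + trim_lo
            sub[1, 2] <- sub[1, 2] - trim_lo
          }
          aligned <- sum(sub[, 2])
          # q offsets: aligned bases are consecutive in the read except for
          # the q_extra inserted bases after a sub-block
          q_starts <- (q_start + trim_lo) +
            cumsum(c(0L, (sub[, 2] + sub[, 3])[-nrow(sub)]))
          read_hits[[length(read_hits) + 1L]] <- list(
            read_id = rid, q_start = q_start + trim_lo,
            q_end = q_start + q_len - trim_hi,
            t_chrom = ci$chrom,
            t_size = nchar(seq_cache[[ci$chrom]]),
            t_start = sub[1, 1], t_end = sub[nrow(sub), 1] +
              sub[nrow(sub), 2],
            strand = "+",
            matches = aligned - mm_tot, mismatches = mm_tot,
            rep_matches = 0L, n_count = 0L,
            q_gap_count = ins_tot, t_gap_count = del_tot,
            block_sizes = unname(sub[, 2]),
            block_q_starts = unname(q_starts),
            block_t_starts = unname(sub[, 1]))
        }
        read_seq <- paste(read_seq, collapse = "")
        rl <- nchar(read_seq)
        for (h in read_hits) { h$q_size <- rl
          hit_rows[[length(hit_rows) + 1L]] <- h }
        q <- pmin(40L, pmax(2L, round(rnorm(rl, config$mean_q,
                                            config$sd_q))))
        reads <- c(reads, read_seq)
        quals <- c(quals, .phred_string(q))
        read_ids <- c(read_ids, rid)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          read_id = rid, circ_id = ci$circ_id,
          isoform_id = iso$isoform_id, gene_id = ci$gene_id,
          nick = nick, rounds = rounds, n_hits = length(read_hits),
          start = ci$start, end = ci$end,
          features = paste(iso$features, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  # junk reads: too short or too low-quality; no alignments
  junk <- function(len, q_mean, tag, k) {
    for (m in seq_len(k)) {
      rid <- sprintf("junk_%s_%02d", tag, m)
      s <- .rand_dna(len)
      q <- pmin(40L, pmax(1L, round(rnorm(len, q_mean, 1))))
      reads <<- c(reads, s); quals <<- c(quals, .phred_string(q))
      read_ids <<- c(read_ids, rid)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        read_id = rid, circ_id = NA_character_,
        isoform_id = NA_character_, gene_id = NA_character_,
        nick = NA_integer_, rounds = NA_real_, n_hits = 0L,
        start = NA_integer_, end = NA_integer_, features = tag,
        stringsAsFactors = FALSE)
    }
  }
  if (config$n_junk_short > 0L) junk(100L, 20, "short", config$n_junk_short)
  if (config$n_junk_lowq > 0L) junk(400L, 4, "lowq", config$n_junk_lowq)

  dna <- DNAStringSet(reads)
  qual <- PhredQuality(quals)
  qsd <- QualityScaledDNAStringSet(dna, qual)
  names(qsd) <- read_ids
  for (k in seq_along(hit_rows)) {
    h <- hit_rows[[k]]
    hit_rows[[k]] <- h[c("read_id", "q_size", "q_start", "q_end",
                         "t_chrom", "t_size", "t_start", "t_end", "strand",
                         "matches", "mismatches", "rep_matches", "n_count",
                         "q_gap_count", "t_gap_count", "block_sizes",
                         "block_q_starts", "block_t_starts")]
  }
  list(reads = qsd, hits = .hits_df(hit_rows),
       truth = do.call(rbind, truth_rows))
}

#' Write a simulation to disk
#'
#' Writes genome.fa, genes.tsv, known.tsv, reads.fastq, truth.psl,
#' truth.tsv and chains/ under `dir`.
#'
#' @param reference output of [makeReference()]
#' @param sim output of [simulateCircReads()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
writeSimulation <- function(reference, sim, dir) {
  dir.create(file.path(dir, "chains"), recursive = TRUE,
             showWarnings = FALSE)
  writeXStringSet(reference$genome, file.path(dir, "genome.fa"))
  writeGeneModels(reference$models, file.path(dir, "genes.tsv"))
  if (length(reference$known))
    writeKnownCircs(reference$known, file.path(dir, "known.tsv"))
  writeLongReads(sim$reads, file.path(dir, "reads.fastq"))
  writePsl(sim$hits, file.path(dir, "truth.psl"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeChain(reference$chainsAB, file.path(dir, "chains", "a_to_b.chain"))
  writeChain(reference$chainsBA, file.path(dir, "chains", "b_to_a.chain"))
  invisible(dir)
}
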