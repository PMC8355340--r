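# circRNA-internal splicing: intron retention, novel/cryptic exon and
# microexon discovery, exon usage, reading-frame consequences.

.seq0 <- function(genome, chrom, s0, e0) {
  if (!chrom %in% names(genome)) return(NA_character_)
  L <- length(genome[[chrom]])
  if (s0 < 0 || e0 > L || e0 <= s0) return(NA_character_)
  as.character(subseq(genome[[chrom]], s0 + 1L, e0))
}

#' Classify an exon length as a microexon class
#'
#' Microexons are 3-29 nt, split into a 3-15 nt and a 16-29 nt group.
#'
#' @param length integer vector of exon lengths (>= 1)
#' @return character vector: "me_3_15", "me_16_29" or "none"
#' @export
classifyMicroexon <- function(length) {
  stopifnot(all(length >= 1))
  ifelse(length >= 3 & length <= 15, "me_3_15",
         ifelse(length >= 16 & length <= 29, "me_16_29", "none"))
}

#' Reading-frame consequence of inserting an exon
#'
#' An exon is in frame iff its length is a multiple of 3. Stop codons
#' (TAA/TAG/TGA) are scanned only over codons lying fully inside the exon,
#' in the single reading frame dictated by the phase handed down from the
#' immediate upstream exon (`phase` = bases at the exon 5' end completing
#' the upstream codon, 0/1/2). With `phase = NA` (no coding upstream exon)
#' all three phases are scanned and the stop flag is set if any phase
#' contains a stop; the returned `phase_known` marker records this.
#'
#' @param sequence exon sequence in transcript orientation (character)
#' @param phase 0, 1, 2 or NA
#' @return list: `frame_class` in in_frame_no_stop / in_frame_stop /
#'   out_frame_no_stop / out_frame_stop, and `phase_known`
#' @export
exonFrameAnalysis <- function(sequence, phase) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  has_stop_in <- function(ph) {
    n_codon <- (len - ph) %/% 3
    if (n_codon <= 0) return(FALSE)
    starts <- ph + 3 * (seq_len(n_codon) - 1) + 1
    any(substring(sequence, starts, starts + 2) %in% stops)
  }
  phase_known <- !is.na(phase)
  stop_found <- if (phase_known) has_stop_in(phase)
                else any(vapply(0:2, has_stop_in, logical(1)))
  in_frame <- len %% 3 == 0
  cls <- paste0(if (in_frame) "in_frame" else "out_frame",
                if (stop_found) "_stop" else "_no_stop")
  list(frame_class = cls, phase_known = phase_known)
}

# Phase handed to an exon inserted right after an upstream exon with entry
# phase p and width w (GFF3 CDS phase arithmetic).
.next_phase <- function(p, w) (3L - ((w - p) %% 3L)) %% 3L

# Immediate upstream (transcript sense) annotated exon with known phase.
.upstream_phase <- function(models, chrom, strand, s0, e0) {
  ex <- unlist(exonsByGene(models), use.names = FALSE)
  ex <- ex[as.character(seqnames(ex)) == chrom &
             as.character(strand(ex)) == strand &
             !is.na(mcols(ex)$phase)]
  if (!length(ex)) return(NA_integer_)
  if (strand == "+") {
    ex <- ex[end(ex) <= s0]
    if (!length(ex)) return(NA_integer_)
    i <- which.max(end(ex))
  } else {
    ex <- ex[start(ex) - 1L >= e0]
    if (!length(ex)) return(NA_integer_)
    i <- which.min(start(ex))
  }
  .next_phase(mcols(ex)$phase[i], width(ex)[i])
}

# Merge a read's sorted genomic blocks, closing gaps <= mergeGap.
.merge_blocks <- function(starts0, sizes, mergeGap) {
  ord <- order(starts0)
  s <- starts0[ord]; e <- starts0[ord] + sizes[ord]
  out_s <- s[1]; out_e <- e[1]
  segs <- list()
  for (k in seq_along(s)[-1]) {
    if (s[k] - out_e <= mergeGap) out_e <- max(out_e, e[k])
    else { segs[[length(segs) + 1L]] <- c(out_s, out_e)
           out_s <- s[k]; out_e <- e[k] }
  }
  segs[[length(segs) + 1L]] <- c(out_s, out_e)
  do.call(rbind, segs)
}

# Splice-signature check, strand aware: transcript-sense AG immediately 5'
# of the exon and GT immediately 3' of it. On the minus strand that is
# genomic AC in [s-2,s) and CT in [e,e+2).
.flanks_ok <- function(genome, chrom, strand, s0, e0) {
  left <- .seq0(genome, chrom, s0 - 2L, s0)
  right <- .seq0(genome, chrom, e0, e0 + 2L)
  if (is.na(left) || is.na(right)) return(NA)
  if (strand == "+") left == "AG" && right == "GT"
  else left == "AC" && right == "CT"
}

#' Detect novel and cryptic exons in the reads of one circRNA
#'
#' Each supporting read's raw mapped blocks (no end processing) are merged
#' across internal deletions of up to `mergeGap` (10) bp into segments; a
#' segment is an exon candidate iff the genome carries the AG-GT splicing
#' signature immediately around it (strand aware). Identical (start, end)
#' segments corroborated by at least `minReads` (2) reads are kept and
#' compared with annotated exons: Jaccard similarity of at least
#' `knownSim` (0.95) with some exon means "known"; no overlap with any
#' exon, "unique_novel"; partial overlap (typically sharing one splice
#' site), "cryptic_novel". Single-exon circRNAs should not be passed here:
#' their two mapped segments assemble one exon across the BSJ and carry no
#' internal splice evidence.
#'
#' @param cands end-corrected candidate DataFrame for one circRNA (its
#'   supporting reads)
#' @param genome a DNAStringSet (chromosome sequences)
#' @param models a [GeneModelSet]
#' @param minReads corroborating reads required (default 2)
#' @param mergeGap internal deletion allowance in bp (default 10)
#' @param knownSim Jaccard above which a segment is a known exon
#' @return DataFrame: chrom, start, end (0-based half-open), strand,
#'   n_supporting_reads, category, shares_5prime, shares_3prime, length,
#'   microexon_class, frame_class, phase_known
#' @export
detectNovelExons <- function(cands, genome, models, minReads = 2,
                             mergeGap = 10, knownSim = 0.95) {
  empty <- DataFrame(chrom = character(), start = integer(),
                     end = integer(), strand = character(),
                     n_supporting_reads = integer(), category = character(),
                     shares_5prime = logical(), shares_3prime = logical(),
                     length = integer(), microexon_class = character(),
                     frame_class = character(), phase_known = logical())
  if (is.null(cands) || nrow(cands) == 0L) return(empty)
  chrom <- cands$t_chrom[1]; strand <- cands$strand[1]
  seen <- list()
  for (i in seq_len(nrow(cands))) {
    segs <- .merge_blocks(cands$block_t_starts[[i]],
                          cands$block_sizes[[i]], mergeGap)
    for (k in seq_len(nrow(segs))) {
      key <- paste(segs[k, 1], segs[k, 2], sep = ":")
      seen[[key]] <- union(seen[[key]], cands$read_id[i])
    }
  }
  counts <- vapply(seen, length, integer(1))
  keys <- names(counts)[counts >= minReads]
  if (!length(keys)) return(empty)
  ex_all <- unlist(exonsByGene(models), use.names = FALSE)
  ex_str <- ex_all[as.character(seqnames(ex_all)) == chrom &
                     as.character(strand(ex_all)) == strand]
  intr_all <- unlist(intronsByGene(models), use.names = FALSE)
  intr_str <- intr_all[as.character(seqnames(intr_all)) == chrom &
                         as.character(strand(intr_all)) == strand]
  rows <- list()
  for (key in keys) {
    se <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    s0 <- se[1]; e0 <- se[2]
    # a segment that spans a whole annotated intron is intron-retention
    # evidence, not an exon candidate
    if (length(intr_str) &&
        any(s0 <= start(intr_str) - 1L & e0 >= end(intr_str))) next
    fl <- .flanks_ok(genome, chrom, strand, s0, e0)
    if (is.na(fl)) {
      warning("genome sequence unavailable around ", chrom, ":", s0, "-",
              e0, "; candidate skipped")
      next
    }
    if (!fl) next
    cat_ <- "unique_novel"; sh5 <- FALSE; sh3 <- FALSE
    if (length(ex_str)) {
      es0 <- start(ex_str) - 1L; ee0 <- end(ex_str)
      jac <- intervalSimilarity(s0, e0, es0, ee0)
      ov <- pmin(e0, ee0) - pmax(s0, es0) > 0
      if (any(jac >= knownSim)) cat_ <- "known"
      else if (any(ov)) {
        cat_ <- "cryptic_novel"
        b <- which(ov)[which.max(jac[ov])]
        if (strand == "+") { sh5 <- es0[b] == s0; sh3 <- ee0[b] == e0 }
        else { sh5 <- ee0[b] == e0; sh3 <- es0[b] == s0 }
      }
    }
    len <- e0 - s0
    sq <- .seq0(genome, chrom, s0, e0)
    if (strand == "-")
      sq <- as.character(reverseComplement(DNAString(sq)))
    ph <- .upstream_phase(models, chrom, strand, s0, e0)
    fr <- exonFrameAnalysis(sq, ph)
    rows[[length(rows) + 1L]] <- DataFrame(
      chrom = chrom, start = s0, end = e0, strand = strand,
      n_supporting_reads = counts[[key]], category = cat_,
      shares_5prime = sh5, shares_3prime = sh3, length = len,
      microexon_class = classifyMicroexon(len),
      frame_class = fr$frame_class, phase_known = fr$phase_known)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Intron coverage statistics for one circRNA
#'
#' For each annotated intron inside the circRNA span: the number of
#' supporting BSJ reads whose corrected span covers the intron position,
#' and the fraction of the intron length covered by the union of their
#' mapped blocks. The circRNA-level intronic fraction — the mean number of
#' intron-mapping bp over the supporting reads divided by their mean
#' gene-mapping bp — is attached to every row.
#'
#' @param cands end-corrected candidate DataFrame for one circRNA
#' @param introns GRanges of annotated introns within the circRNA span
#' @param novelExons optional DataFrame from [detectNovelExons()]; any
#'   non-"known" exon overlapping an intron sets `has_novel_exon_inside`
#' @return DataFrame: chrom, intron_start, intron_end (0-based),
#'   n_bsj_reads_spanning, intron_coverage_fraction, intronic_fraction,
#'   has_novel_exon_inside
#' @export
intronCoverage <- function(cands, introns, novelExons = NULL) {
  empty <- DataFrame(chrom = character(), intron_start = integer(),
                     intron_end = integer(),
                     n_bsj_reads_spanning = integer(),
                     intron_coverage_fraction = numeric(),
                     intronic_fraction = numeric(),
                     has_novel_exon_inside = logical())
  if (is.null(cands) || nrow(cands) == 0L || length(introns) == 0L)
    return(empty)
  mean_gene <- mean(cands$bp_gene)
  frac <- if (mean_gene > 0) mean(cands$bp_intron) / mean_gene else 0
  rows <- list()
  for (j in seq_along(introns)) {
    is0 <- start(introns)[j] - 1L; ie0 <- end(introns)[j]
    chrom <- as.character(seqnames(introns))[j]
    span <- cands$corr_start <= is0 & cands$corr_end >= ie0 &
      cands$t_chrom == chrom
    cc <- cands[span, , drop = FALSE]
    cov_bp <- 0L
    if (nrow(cc)) {
      all_s <- unlist(cc$block_t_starts)
      all_e <- all_s + unlist(cc$block_sizes)
      ov <- all_e > is0 & all_s < ie0
      if (any(ov)) {
        ir <- IRanges::reduce(IRanges(pmax(all_s[ov], is0) + 1L,
                                      pmin(all_e[ov], ie0)))
        cov_bp <- sum(width(ir))
      }
    }
    has_ne <- FALSE
    if (!is.null(novelExons) && nrow(novelExons)) {
      ne <- novelExons[novelExons$category != "known", , drop = FALSE]
      if (nrow(ne))
        has_ne <- any(pmin(ne$end, ie0) - pmax(ne$start, is0) > 0)
    }
    rows[[length(rows) + 1L]] <- DataFrame(
      chrom = chrom, intron_start = is0, intron_end = ie0,
      n_bsj_reads_spanning = nrow(cc),
      intron_coverage_fraction = cov_bp / (ie0 - is0),
      intronic_fraction = frac, has_novel_exon_inside = has_ne)
  }
  do.call(rbind, rows)
}

#' Call retained introns from intron coverage statistics
#'
#' An intron is called retained iff it is spanned by at least `minReads`
#' (20) BSJ reads, at least `minCov` (0.90) of its length is covered, the
#' circRNA-level intronic fraction exceeds `minIntronicFraction` (0.03),
#' and no novel exon was detected inside it.
#'
#' @param stats DataFrame from [intronCoverage()]
#' @param minReads,minCov,minIntronicFraction gates (see above)
#' @return the subset of `stats` called as retained
#' @export
callRetainedIntrons <- function(stats, minReads = 20, minCov = 0.90,
                                minIntronicFraction = 0.03) {
  if (is.null(stats) || nrow(stats) == 0L) return(stats)
  keep <- stats$n_bsj_reads_spanning >= minReads &
    stats$intron_coverage_fraction >= minCov &
    stats$intronic_fraction > minIntronicFraction &
    !stats$has_novel_exon_inside
  stats[keep, , drop = FALSE]
}

#' Exon usage levels within one circRNA
#'
#' For each exon interval: the number of supporting BSJ reads whose
#' corrected genomic span covers the exon position (`n_reads_spanning`),
#' the number of those with sequence mapped to the exon (`n_reads_using`),
#' and the usage level `n_reads_using / n_reads_spanning` (1 =
#' constitutive, 0 = never used). Exons used by fewer than `minReads`
#' reads (10 in circNick mode, 50 in circPanel mode) are flagged
#' `suppressed`.
#'
#' @param cands end-corrected candidate DataFrame for one circRNA
#' @param exons GRanges of exon intervals inside the circRNA span
#' @param minReads suppression gate on `n_reads_using`
#' @param mode convenience switch: "nick" sets minReads 10, "panel" 50
#'   (ignored when `minReads` is given)
#' @return DataFrame: chrom, exon_start, exon_end (0-based),
#'   n_reads_spanning, n_reads_using, usage_level, suppressed
#' @export
exonUsage <- function(cands, exons, minReads = NULL,
                      mode = c("nick", "panel")) {
  mode <- match.arg(mode)
  if (is.null(minReads)) minReads <- if (mode == "nick") 10L else 50L
  empty <- DataFrame(chrom = character(), exon_start = integer(),
                     exon_end = integer(), n_reads_spanning = integer(),
                     n_reads_using = integer(), usage_level = numeric(),
                     suppressed = logical())
  if (is.null(cands) || nrow(cands) == 0L || length(exons) == 0L)
    return(empty)
  rows <- list()
  for (j in seq_along(exons)) {
    es0 <- start(exons)[j] - 1L; ee0 <- end(exons)[j]
    chrom <- as.character(seqnames(exons))[j]
    spanning <- which(cands$corr_start <= es0 & cands$corr_end >= ee0 &
                        cands$t_chrom == chrom)
    using <- 0L
    for (i in spanning) {
      bs <- cands$block_t_starts[[i]]
      be <- bs + cands$block_sizes[[i]]
      if (any(pmin(be, ee0) - pmax(bs, es0) > 0)) using <- using + 1L
    }
    nsp <- length(spanning)
    rows[[length(rows) + 1L]] <- DataFrame(
      chrom = chrom, exon_start = es0, exon_end = ee0,
      n_reads_spanning = nsp, n_reads_using = using,
      usage_level = if (nsp > 0) using / nsp else NA_real_,
      suppressed = nsp == 0L || using < minReads)
  }
  do.call(rbind, rows)
}

#' Exon inclusion fraction in linear-transcript reads
#'
#' Fraction of reads spanning both flanking exons that also contain the
#' exon; used to compare circRNA exon usage with the linear host mRNA.
#'
#' @param nUsing reads including the exon
#' @param nSpanning reads spanning the exon's position (both flanks)
#' @return inclusion fraction; NA (with a warning) when nSpanning is 0
#' @export
linearInclusion <- function(nUsing, nSpanning) {
  out <- ifelse(nSpanning > 0, nUsing / nSpanning, NA_real_)
  if (any(nSpanning == 0))
    warning("no spanning reads: inclusion undefined")
  out
}
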