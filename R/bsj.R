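# Back-splice junction calling: hit scoring, pairing, read classification,
# annotation overlap, end correction and collapsing into unique circRNAs.
#
# A long read crossing a BSJ splits into two genomic alignment segments in
# reversed read order: the read-5' segment maps transcript-downstream
# (greater coordinates on +, smaller on -) of the read-3' segment.
#
# Hot loops run on plain data.frames with list columns (converted once from
# the DataFrame surface) — per-row S4 subsetting is far too slow for
# per-read work.

.gr1 <- function(chrom, start0, end0, strand = "*") {
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
}

# block vector access working for DataFrame rows, base rows and plain lists
.blk <- function(h, nm) {
  v <- h[[nm]]
  if (is.atomic(v)) v else v[[1]]
}

# convert a parsePsl()-style DataFrame to a base data.frame with list
# columns (fast row access); pass-through if already converted
.as_base_hits <- function(hits) {
  if (is.data.frame(hits)) return(hits)
  lst <- c("block_sizes", "block_q_starts", "block_t_starts")
  out <- as.data.frame(hits[, setdiff(names(hits), lst), drop = FALSE])
  for (nm in lst) out[[nm]] <- I(as.list(hits[[nm]]))
  out
}

.row <- function(df, i) df[i, , drop = FALSE]

#' Blat-style score of an alignment hit
#'
#' matches minus mismatches minus one penalty per gap opening on either
#' axis (the UCSC PSL score convention). A hit must reach 30 on both sides
#' of a BSJ to support a circRNA call.
#'
#' @param hits one or more rows of an alignment-hit table ([parsePsl()])
#' @return integer vector of scores
#' @export
blatScore <- function(hits) {
  hits$matches - hits$mismatches - hits$q_gap_count - hits$t_gap_count
}

#' Span-level Jaccard similarity of two intervals
#'
#' Intersection over union of two 0-based half-open intervals on the same
#' chromosome; 0 when disjoint.
#'
#' @param s1,e1,s2,e2 interval bounds (vectorized)
#' @return numeric in \[0, 1\]
#' @export
intervalSimilarity <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  uni <- pmax(e1, e2) - pmin(s1, s2)
  ifelse(uni > 0, inter / uni, 0)
}

#' Pair two alignment hits of one read into a BSJ candidate
#'
#' The pair is accepted iff the hits are (1) on the same chromosome and
#' genomic strand, (2) span at most `maxSpan` (1 Mb), (3) overlap
#' genomically by fewer than `maxOverlap` (50) bp, (4) are in reverse
#' order relative to the read (the read-earlier segment maps
#' transcript-downstream), and (5) each reach a Blat score of `minScore`
#' (30). The decision is independent of argument order.
#'
#' @param hitA,hitB one-row alignment-hit tables from the same read
#' @param maxSpan maximum genomic span of the putative circRNA (bp)
#' @param maxOverlap hits overlapping by this many bp or more are rejected
#' @param minScore minimum per-side Blat score
#' @return a list: `accepted` (logical); on acceptance `candidate` (named
#'   list of BSJ-candidate fields); on rejection `reason`, the first failed
#'   criterion among "chrom", "strand", "distance", "overlap", "order",
#'   "score".
#' @export
pairHits <- function(hitA, hitB, maxSpan = 1e6, maxOverlap = 50,
                     minScore = 30) {
  if (hitA$read_id != hitB$read_id)
    stop("pairHits: hits are from different reads")
  if (hitA$q_start > hitB$q_start) { tmp <- hitA; hitA <- hitB; hitB <- tmp }
  rej <- function(reason) list(accepted = FALSE, reason = reason)
  if (hitA$t_chrom != hitB$t_chrom) return(rej("chrom"))
  if (hitA$strand != hitB$strand) return(rej("strand"))
  circ_start <- min(hitA$t_start, hitB$t_start)
  circ_end <- max(hitA$t_end, hitB$t_end)
  if (circ_end - circ_start > maxSpan) return(rej("distance"))
  overlap <- min(hitA$t_end, hitB$t_end) - max(hitA$t_start, hitB$t_start)
  if (overlap >= maxOverlap) return(rej("overlap"))
  backspliced <- if (hitA$strand == "+") hitA$t_start > hitB$t_start
                 else hitA$t_end < hitB$t_end
  if (!backspliced) return(rej("order"))
  sl <- blatScore(hitA); sr <- blatScore(hitB)
  if (sl < minScore || sr < minScore) return(rej("score"))
  bt <- c(.blk(hitA, "block_t_starts"), .blk(hitB, "block_t_starts"))
  bs <- c(.blk(hitA, "block_sizes"), .blk(hitB, "block_sizes"))
  ord <- order(bt)
  cand <- list(
    read_id = hitA$read_id, t_chrom = hitA$t_chrom, strand = hitA$strand,
    circ_start = circ_start, circ_end = circ_end,
    score_left = sl, score_right = sr,
    block_t_starts = bt[ord], block_sizes = bs[ord])
  list(accepted = TRUE, candidate = cand)
}

# BSJ-consistent adjacency on read-sorted hits of one locus: the later
# segment restarts at or upstream (transcript sense) of the earlier
# segment's transcript start -- the geometry of another pass around the
# circle.
.bsj_adjacent <- function(a, b) {
  if (a$t_chrom != b$t_chrom || a$strand != b$strand) return(FALSE)
  if (a$strand == "+") b$t_start <= a$t_start else b$t_end >= a$t_end
}

#' Classify the alignment hits of one read
#'
#' Exactly two qualifying hits that pass pairing give `bsj_two_hit`; three
#' or more hits tiling one (chromosome, strand) locus within the span limit
#' with at least two BSJ-consistent read-adjacencies give `multi_round`
#' (a concatemeric read from repeated reverse-transcription rounds around
#' the circle); anything else with hits is `linear_like`, and reads whose
#' hits all fail the score threshold are `unmapped_for_circ`.
#'
#' @param hits alignment-hit table for a single read (>= 1 row)
#' @inheritParams pairHits
#' @return list with `class` and, for `bsj_two_hit`, the `candidate`
#' @export
classifyReadHits <- function(hits, minScore = 30, maxSpan = 1e6,
                             maxOverlap = 50) {
  hits <- .as_base_hits(hits)
  if (nrow(hits) == 0L) stop("classifyReadHits: empty hit list")
  if (length(unique(hits$read_id)) != 1L)
    stop("classifyReadHits: hits from several reads")
  scores <- blatScore(hits)
  if (all(scores < minScore)) return(list(class = "unmapped_for_circ"))
  # the multi-round geometry is assessed on all hits: a terminal partial
  # pass may be short, yet still marks another round
  if (nrow(hits) >= 3L &&
      length(unique(hits$t_chrom)) == 1L &&
      length(unique(hits$strand)) == 1L &&
      max(hits$t_end) - min(hits$t_start) <= maxSpan) {
    ord <- order(hits$q_start)
    adj <- sum(vapply(seq_len(nrow(hits) - 1L), function(k)
      .bsj_adjacent(.row(hits, ord[k]), .row(hits, ord[k + 1L])),
      logical(1)))
    if (adj >= 2L) return(list(class = "multi_round"))
  }
  qual_ix <- which(scores >= minScore)
  if (length(qual_ix) == 2L) {
    p <- pairHits(.row(hits, qual_ix[1]), .row(hits, qual_ix[2]),
                  maxSpan = maxSpan, maxOverlap = maxOverlap,
                  minScore = minScore)
    if (p$accepted) return(list(class = "bsj_two_hit",
                                candidate = p$candidate))
  }
  list(class = "linear_like")
}

#' Prepare reduced annotation layers for overlap counting
#'
#' @param models a [GeneModelSet]
#' @param ests GRanges of expressed-sequence-tag intervals (may be empty)
#' @return list of reduced interval tables per layer, indexed by chromosome
#' @export
prepareAnnotation <- function(models, ests = GRanges()) {
  mk <- function(gr) {
    gr <- reduce(granges(gr), ignore.strand = TRUE)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start0 = start(gr) - 1L, end0 = end(gr))
    split(df, df$chrom)
  }
  list(gene = mk(geneRanges(models)),
       exon = mk(unlist(exonsByGene(models), use.names = FALSE)),
       intron = mk(unlist(intronsByGene(models), use.names = FALSE)),
       est = mk(ests))
}

.layer_bp <- function(chrom, bs0, be0, layer) {
  tab <- layer[[chrom]]
  if (is.null(tab) || nrow(tab) == 0L) return(0L)
  tot <- 0L
  for (k in seq_along(bs0)) {
    ov <- pmin(be0[k], tab$end0) - pmax(bs0[k], tab$start0)
    tot <- tot + sum(ov[ov > 0])
  }
  as.integer(tot)
}

#' Base-pair overlap of a hit's blocks with annotation layers
#'
#' Per-layer summed overlap in bp across the hit's blocks; layers are
#' independent (exon + intron need not equal gene when models disagree).
#' A chromosome absent from the annotation yields all zeros.
#'
#' @param hit one-row alignment-hit table (or plain list with `t_chrom`,
#'   `block_t_starts`, `block_sizes`)
#' @param layers output of [prepareAnnotation()]
#' @return named integer vector: bp_gene, bp_exon, bp_intron, bp_est
#' @export
annotateHit <- function(hit, layers) {
  bt <- .blk(hit, "block_t_starts"); bs <- .blk(hit, "block_sizes")
  chrom <- hit$t_chrom[[1]]
  c(bp_gene = .layer_bp(chrom, bt, bt + bs, layers$gene),
    bp_exon = .layer_bp(chrom, bt, bt + bs, layers$exon),
    bp_intron = .layer_bp(chrom, bt, bt + bs, layers$intron),
    bp_est = .layer_bp(chrom, bt, bt + bs, layers$est))
}

.cand_df <- function(cands) {
  if (!length(cands)) return(NULL)
  get <- function(nm) vapply(cands, `[[`, vector(mode = "numeric", 1), nm)
  DataFrame(
    read_id = vapply(cands, `[[`, character(1), "read_id"),
    t_chrom = vapply(cands, `[[`, character(1), "t_chrom"),
    strand = vapply(cands, `[[`, character(1), "strand"),
    circ_start = as.integer(get("circ_start")),
    circ_end = as.integer(get("circ_end")),
    score_left = as.integer(get("score_left")),
    score_right = as.integer(get("score_right")),
    bp_gene = as.integer(get("bp_gene")),
    bp_exon = as.integer(get("bp_exon")),
    bp_intron = as.integer(get("bp_intron")),
    bp_est = as.integer(get("bp_est")),
    corr_start = as.integer(get("corr_start")),
    corr_end = as.integer(get("corr_end")),
    adjust_start = as.integer(get("adjust_start")),
    adjust_end = as.integer(get("adjust_end")),
    snap_mode = vapply(cands, function(x)
      if (is.null(x$snap_mode)) NA_character_ else x$snap_mode,
      character(1)),
    circBase_id = vapply(cands, `[[`, character(1), "circBase_id"),
    circAtlas_id = vapply(cands, `[[`, character(1), "circAtlas_id"),
    CIRCpedia_id = vapply(cands, `[[`, character(1), "CIRCpedia_id"),
    block_t_starts = IRanges::IntegerList(
      lapply(cands, function(x) as.integer(x$block_t_starts))),
    block_sizes = IRanges::IntegerList(
      lapply(cands, function(x) as.integer(x$block_sizes))))
}

#' Classify every read and build annotated BSJ candidates
#'
#' @param hits full alignment-hit table ([parsePsl()])
#' @param models a [GeneModelSet]
#' @param ests GRanges of EST intervals (empty by default)
#' @inheritParams pairHits
#' @return list: `classes` (DataFrame read_id/class) and `candidates`
#'   (list of BSJ-candidate records with bp_gene/exon/intron/est)
#' @export
buildCandidates <- function(hits, models, ests = GRanges(), minScore = 30,
                            maxSpan = 1e6, maxOverlap = 50) {
  layers <- prepareAnnotation(models, ests)
  hits <- .as_base_hits(hits)
  by_read <- split(seq_len(nrow(hits)), hits$read_id)
  ids <- names(by_read)
  classes <- character(length(ids))
  cands <- list()
  for (k in seq_along(ids)) {
    h <- hits[by_read[[k]], , drop = FALSE]
    cl <- classifyReadHits(h, minScore = minScore, maxSpan = maxSpan,
                           maxOverlap = maxOverlap)
    classes[k] <- cl$class
    if (cl$class == "bsj_two_hit") {
      cand <- cl$candidate
      ann <- c(bp_gene = 0L, bp_exon = 0L, bp_intron = 0L, bp_est = 0L)
      qual_ix <- which(blatScore(h) >= minScore)
      for (q in qual_ix)
        ann <- ann + annotateHit(.row(h, q), layers)
      cand[names(ann)] <- as.list(ann)
      cands[[length(cands) + 1L]] <- cand
    }
  }
  list(classes = DataFrame(read_id = ids, class = classes),
       candidates = cands)
}

# Exon boundary pools (0-based) per chromosome:strand.
.boundary_pools <- function(models) {
  ex <- unlist(exonsByGene(models), use.names = FALSE)
  key <- paste(as.character(seqnames(ex)), as.character(strand(ex)),
               sep = ":")
  s_by <- split(start(ex) - 1L, key)
  e_by <- split(end(ex), key)
  pools <- lapply(names(s_by), function(k)
    list(starts0 = sort(unique(s_by[[k]])),
         ends0 = sort(unique(e_by[[k]]))))
  names(pools) <- names(s_by)
  pools
}

# Nearest boundary within snapBp. Ties go to the boundary giving the
# longer circRNA (smaller coordinate for the start, larger for the end).
.snap_boundary <- function(pos, pool, snapBp, side) {
  if (!length(pool)) return(NULL)
  d <- abs(pool - pos)
  ok <- which(d <= snapBp)
  if (!length(ok)) return(NULL)
  best <- ok[d[ok] == min(d[ok])]
  if (length(best) > 1L)
    best <- if (side == "start") min(best) else max(best)
  pool[best[1]]
}

#' Correct the ends of a BSJ candidate against annotation
#'
#' If both circRNA ends lie within `snapBp` (30) bp of an annotated exon
#' boundary on the candidate strand (an exon start for the circ start, an
#' exon end for the circ end), each end snaps to its nearest boundary. If
#' not, and the candidate span has Jaccard overlap of at least
#' `knownJaccard` (0.95) with a known circRNA record, the ends snap to that
#' record (attaching its database identifier). Candidates failing both
#' rules are rejected and excluded from circRNA calling.
#'
#' @param cand a BSJ-candidate record ([pairHits()]/[buildCandidates()])
#' @param models a [GeneModelSet]
#' @param known GRanges of known circRNAs ([readKnownCircs()]; may be NULL)
#' @param snapBp maximum distance to an exon boundary
#' @param knownJaccard minimum span Jaccard with a known record
#' @param pools,knownTab precomputed lookups (internal use)
#' @return list: `accepted`; on acceptance `candidate` with `corr_start`,
#'   `corr_end`, `adjust_start`, `adjust_end`, `snap_mode` and any database
#'   ids; on rejection `reason = "no_anchor"`.
#' @export
correctEnds <- function(cand, models, known = NULL, snapBp = 30,
                        knownJaccard = 0.95, pools = NULL,
                        knownTab = NULL) {
  if (is(cand, "DataFrame") || is.data.frame(cand))
    cand <- as.list(.as_base_hits(cand)[1, , drop = FALSE])
  if (is.null(pools)) pools <- .boundary_pools(models)
  if (is.null(knownTab)) knownTab <- .known_table(known)
  pool <- pools[[paste(cand$t_chrom, cand$strand, sep = ":")]]
  ns <- if (is.null(pool)) NULL
    else .snap_boundary(cand$circ_start, pool$starts0, snapBp, "start")
  ne <- if (is.null(pool)) NULL
    else .snap_boundary(cand$circ_end, pool$ends0, snapBp, "end")
  cand$circBase_id <- NA_character_
  cand$circAtlas_id <- NA_character_
  cand$CIRCpedia_id <- NA_character_
  if (!is.null(ns) && !is.null(ne) && ne > ns) {
    cand$corr_start <- ns; cand$corr_end <- ne
    cand$adjust_start <- abs(cand$circ_start - ns)
    cand$adjust_end <- abs(cand$circ_end - ne)
    cand$snap_mode <- "exon"
  } else if (!is.null(knownTab) && nrow(knownTab)) {
    kn <- knownTab[knownTab$chrom == cand$t_chrom &
                     knownTab$strand == cand$strand, , drop = FALSE]
    if (!nrow(kn)) return(list(accepted = FALSE, reason = "no_anchor"))
    jac <- intervalSimilarity(cand$circ_start, cand$circ_end,
                              kn$start0, kn$end0)
    best <- which.max(jac)
    if (jac[best] < knownJaccard)
      return(list(accepted = FALSE, reason = "no_anchor"))
    cand$corr_start <- kn$start0[best]; cand$corr_end <- kn$end0[best]
    cand$adjust_start <- abs(cand$circ_start - kn$start0[best])
    cand$adjust_end <- abs(cand$circ_end - kn$end0[best])
    cand$snap_mode <- "known"
    col <- paste0(kn$db[best], "_id")
    if (!is.na(kn$db[best]) && col %in% names(cand))
      cand[[col]] <- kn$id[best]
  } else return(list(accepted = FALSE, reason = "no_anchor"))
  list(accepted = TRUE, candidate = cand)
}

.known_table <- function(known) {
  if (is.null(known) || length(known) == 0L) return(NULL)
  data.frame(chrom = as.character(seqnames(known)),
             start0 = start(known) - 1L, end0 = end(known),
             strand = as.character(strand(known)),
             id = mcols(known)$circ_id, db = mcols(known)$db_name,
             stringsAsFactors = FALSE)
}

#' End-correct a whole candidate list
#'
#' @param candidates candidate list from [buildCandidates()]
#' @inheritParams correctEnds
#' @return list: `corrected` (DataFrame, possibly NULL) and `n_rejected`
#' @export
correctAllEnds <- function(candidates, models, known = NULL, snapBp = 30,
                           knownJaccard = 0.95) {
  if (is(candidates, "DataFrame")) {
    base <- .as_base_hits(candidates)
    candidates <- lapply(seq_len(nrow(base)), function(i)
      as.list(base[i, , drop = FALSE]))
    candidates <- lapply(candidates, function(x) {
      x$block_t_starts <- x$block_t_starts[[1]]
      x$block_sizes <- x$block_sizes[[1]]
      x
    })
  }
  if (is.null(candidates) || length(candidates) == 0L)
    return(list(corrected = NULL, n_rejected = 0L))
  pools <- .boundary_pools(models)
  knownTab <- .known_table(known)
  out <- list(); nrej <- 0L
  for (cand in candidates) {
    r <- correctEnds(cand, models, known, snapBp, knownJaccard,
                     pools = pools, knownTab = knownTab)
    if (r$accepted) out[[length(out) + 1L]] <- r$candidate
    else nrej <- nrej + 1L
  }
  list(corrected = .cand_df(out), n_rejected = nrej)
}

#' Collapse end-corrected candidates into a unique circRNA table
#'
#' Candidates on mitochondrial chromosomes or overlapping rRNA gene models
#' are removed before collapsing. One record is produced per unique
#' (chromosome, strand, start, end); supporting-read count, mean annotation
#' overlaps and the min/max/mean of the per-read total end adjustment (sum
#' of bp moved at both ends) are aggregated over supporting reads. Database
#' identifiers are attached by exact BSJ coordinate match against the known
#' catalog; `is_novel` flags circRNAs matching no database. The host gene
#' is the gene model with maximal span overlap.
#'
#' @param corrected end-corrected candidate DataFrame ([correctAllEnds()])
#' @param models a [GeneModelSet]
#' @param known GRanges of known circRNA records (optional)
#' @param mitoChroms chromosome names treated as mitochondrial
#' @return a [CircRNASet]; the filtered candidates, annotated with their
#'   collapsed `circ_key`, are kept in `metadata(circRanges(x))$candidates`
#' @export
collapseCircRNAs <- function(corrected, models, known = NULL,
                             mitoChroms = c("chrM", "MT", "chrMT")) {
  empty <- GRanges()
  mcols(empty) <- DataFrame(n_reads = integer(), host_gene = character(),
    circBase_id = character(), circAtlas_id = character(),
    CIRCpedia_id = character(), mean_bp_gene = numeric(),
    mean_bp_exon = numeric(), mean_bp_intron = numeric(),
    mean_bp_est = numeric(), adjust_min = numeric(),
    adjust_max = numeric(), adjust_mean = numeric(), is_novel = logical())
  if (is.null(corrected) || nrow(corrected) == 0L)
    return(CircRNASet(empty))
  keep <- !(corrected$t_chrom %in% mitoChroms)
  rr <- geneRanges(models)
  rr <- rr[mcols(rr)$is_rRNA]
  if (length(rr)) {
    span <- .gr1(corrected$t_chrom, corrected$corr_start,
                 corrected$corr_end)
    keep <- keep & !overlapsAny(span, rr, ignore.strand = TRUE)
  }
  corrected <- corrected[keep, , drop = FALSE]
  if (nrow(corrected) == 0L) return(CircRNASet(empty))
  key <- paste(corrected$t_chrom, corrected$strand,
               corrected$corr_start, corrected$corr_end, sep = ":")
  corrected$circ_key <- key
  genes <- geneRanges(models)
  gene_tab <- data.frame(chrom = as.character(seqnames(genes)),
                         start0 = start(genes) - 1L, end0 = end(genes),
                         id = mcols(genes)$gene_id,
                         stringsAsFactors = FALSE)
  known_tab <- .known_table(known)
  groups <- split(seq_len(nrow(corrected)), key)
  n <- length(groups)
  chrom <- character(n); strand <- character(n)
  s0 <- integer(n); e0 <- integer(n)
  m <- DataFrame(n_reads = integer(n), host_gene = character(n),
    circBase_id = character(n), circAtlas_id = character(n),
    CIRCpedia_id = character(n), mean_bp_gene = numeric(n),
    mean_bp_exon = numeric(n), mean_bp_intron = numeric(n),
    mean_bp_est = numeric(n), adjust_min = numeric(n),
    adjust_max = numeric(n), adjust_mean = numeric(n),
    is_novel = logical(n))
  first_id <- function(v) { v <- v[!is.na(v)]
    if (length(v)) v[1] else NA_character_ }
  for (g in seq_len(n)) {
    ix <- groups[[g]]
    cc <- corrected[ix, , drop = FALSE]
    chrom[g] <- cc$t_chrom[1]; strand[g] <- cc$strand[1]
    s0[g] <- cc$corr_start[1]; e0[g] <- cc$corr_end[1]
    adj <- cc$adjust_start + cc$adjust_end
    ov <- pmin(e0[g], gene_tab$end0) - pmax(s0[g], gene_tab$start0)
    ov[gene_tab$chrom != chrom[g]] <- 0L
    host <- if (any(ov > 0)) gene_tab$id[which.max(ov)] else NA_character_
    ids <- c(circBase_id = first_id(cc$circBase_id),
             circAtlas_id = first_id(cc$circAtlas_id),
             CIRCpedia_id = first_id(cc$CIRCpedia_id))
    if (!is.null(known_tab)) {
      hit <- which(known_tab$chrom == chrom[g] &
                     known_tab$start0 == s0[g] & known_tab$end0 == e0[g] &
                     known_tab$strand == strand[g])
      for (j in hit) {
        col <- paste0(known_tab$db[j], "_id")
        if (!is.na(known_tab$db[j]) && col %in% names(ids) &&
            is.na(ids[[col]]))
          ids[[col]] <- known_tab$id[j]
      }
    }
    m$n_reads[g] <- length(ix); m$host_gene[g] <- host
    m$circBase_id[g] <- ids[["circBase_id"]]
    m$circAtlas_id[g] <- ids[["circAtlas_id"]]
    m$CIRCpedia_id[g] <- ids[["CIRCpedia_id"]]
    m$mean_bp_gene[g] <- mean(cc$bp_gene)
    m$mean_bp_exon[g] <- mean(cc$bp_exon)
    m$mean_bp_intron[g] <- mean(cc$bp_intron)
    m$mean_bp_est[g] <- mean(cc$bp_est)
    m$adjust_min[g] <- min(adj); m$adjust_max[g] <- max(adj)
    m$adjust_mean[g] <- mean(adj)
    m$is_novel[g] <- all(is.na(ids))
  }
  gr <- .gr1(chrom, s0, e0, strand)
  mcols(gr) <- m
  metadata(gr)$candidates <- corrected
  CircRNASet(gr)
}

#' Summarize a calling run (read-class and circRNA accounting)
#'
#' @param classes DataFrame read_id/class from [buildCandidates()]
#' @param circs a [CircRNASet]
#' @param nFiltered number of quality-filtered reads entering alignment
#' @return list of counts and percentages of filtered reads
#' @export
summarizeRun <- function(classes, circs, nFiltered) {
  m <- mcols(circRanges(circs))
  n_bsj <- sum(classes$class == "bsj_two_hit")
  n_multi <- sum(classes$class == "multi_round")
  n_circ_reads <- if (length(circs)) sum(m$n_reads) else 0L
  pct <- function(x) if (nFiltered > 0) 100 * x / nFiltered else NA_real_
  if (nFiltered <= 0)
    warning("zero filtered reads: percentages undefined")
  list(filtered_reads = nFiltered,
       bsj_reads = n_bsj, bsj_reads_pct = pct(n_bsj),
       circ_mapping_reads = n_circ_reads + n_multi,
       circ_mapping_reads_pct = pct(n_circ_reads + n_multi),
       unique_circRNAs = length(circs),
       circBase_circRNAs = sum(!is.na(m$circBase_id)),
       circAtlas_circRNAs = sum(!is.na(m$circAtlas_id)),
       CIRCpedia_circRNAs = sum(!is.na(m$CIRCpedia_id)),
       novel_circRNAs = sum(m$is_novel),
       multi_round_reads = n_multi)
}

#' Run the full BSJ-calling stage
#'
#' Classify reads, pair hits, annotate, end-correct and collapse.
#'
#' @inheritParams buildCandidates
#' @inheritParams correctEnds
#' @inheritParams collapseCircRNAs
#' @return list: `circs` ([CircRNASet]), `classes`, `candidates`
#'   (end-corrected DataFrame with `circ_key`), `n_rejected_ends`
#' @export
callCircRNAs <- function(hits, models, known = NULL, ests = GRanges(),
                         minScore = 30, maxSpan = 1e6, maxOverlap = 50,
                         snapBp = 30, knownJaccard = 0.95,
                         mitoChroms = c("chrM", "MT", "chrMT")) {
  built <- buildCandidates(hits, models, ests, minScore = minScore,
                           maxSpan = maxSpan, maxOverlap = maxOverlap)
  corr <- correctAllEnds(built$candidates, models, known, snapBp,
                         knownJaccard)
  circs <- collapseCircRNAs(corr$corrected, models, known, mitoChroms)
  list(circs = circs, classes = built$classes,
       candidates = metadata(circRanges(circs))$candidates,
       n_rejected_ends = corr$n_rejected)
}
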