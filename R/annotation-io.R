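# Gene-model, known-circRNA-catalog and BED12 input/output.
#
# On-disk coordinates are 0-based half-open (BED convention); the GRanges
# returned are 1-based closed.

#' Read gene models from a refFlat-like table
#'
#' Tab-separated with header:
#' `gene_id chrom strand exon_starts exon_ends is_rRNA phases`, where
#' `exon_starts`/`exon_ends` are comma-separated 0-based half-open
#' coordinates and `phases` comma-separated codon offsets (0/1/2, or `.`
#' for non-coding exons).
#'
#' @param path input file
#' @return a [GeneModelSet]
#' @export
readGeneModels <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "")
  req <- c("gene_id", "chrom", "strand", "exon_starts", "exon_ends",
           "is_rRNA", "phases")
  if (!all(req %in% names(tb)))
    stop("gene-model file '", path, "' lacks columns: ",
         paste(setdiff(req, names(tb)), collapse = ", "))
  exon_list <- vector("list", nrow(tb))
  for (i in seq_len(nrow(tb))) {
    s0 <- .split_ints(tb$exon_starts[i]); e0 <- .split_ints(tb$exon_ends[i])
    if (length(s0) != length(e0) || any(e0 <= s0))
      stop("gene-model file '", path, "' row ", i, ": bad exon intervals")
    ph <- strsplit(sub(",+$", "", tb$phases[i]), ",")[[1]]
    ph <- suppressWarnings(as.integer(ph))
    if (length(ph) != length(s0)) ph <- rep(NA_integer_, length(s0))
    ex <- GRanges(tb$chrom[i], IRanges(s0 + 1L, e0), strand = tb$strand[i])
    mcols(ex)$phase <- ph
    exon_list[[i]] <- ex
  }
  genes <- GRanges(tb$chrom,
                   IRanges(vapply(exon_list, function(e) min(start(e)),
                                  integer(1)),
                           vapply(exon_list, function(e) max(end(e)),
                                  integer(1))),
                   strand = tb$strand)
  mcols(genes)$gene_id <- tb$gene_id
  mcols(genes)$is_rRNA <- toupper(tb$is_rRNA) %in% c("TRUE", "1", "YES")
  GeneModelSet(genes, GRangesList(exon_list))
}

#' Write a GeneModelSet in the format read by [readGeneModels()]
#' @param models a GeneModelSet
#' @param path output file
#' @export
writeGeneModels <- function(models, path) {
  genes <- geneRanges(models)
  ex <- exonsByGene(models)
  fmt_phase <- function(p) ifelse(is.na(p), ".", as.character(p))
  tb <- data.frame(
    gene_id = mcols(genes)$gene_id,
    chrom = as.character(seqnames(genes)),
    strand = as.character(strand(genes)),
    exon_starts = vapply(ex, function(e)
      paste(start(e) - 1L, collapse = ","), character(1)),
    exon_ends = vapply(ex, function(e)
      paste(end(e), collapse = ","), character(1)),
    is_rRNA = mcols(genes)$is_rRNA,
    phases = vapply(ex, function(e)
      paste(fmt_phase(mcols(e)$phase), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-circRNA catalog
#'
#' Tab-separated, BED-like, no header:
#' `chrom start end strand circ_id db_name` with 0-based half-open
#' coordinates (circBase/circAtlas/CIRCpedia-style exports).
#'
#' @param path input file
#' @param db_name override the db column (recycled) if the file has only 5
#'   columns
#' @return GRanges with mcols `circ_id`, `db_name`
#' @export
readKnownCircs <- function(path, db_name = NULL) {
  tb <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = "character", comment.char = "#")
  if (ncol(tb) < 5L)
    stop("known-circRNA catalog '", path, "' needs >= 5 columns")
  start0 <- as.integer(tb[[2]]); end0 <- as.integer(tb[[3]])
  if (any(is.na(start0)) || any(is.na(end0)) || any(end0 <= start0))
    stop("known-circRNA catalog '", path, "': invalid coordinates")
  gr <- GRanges(tb[[1]], IRanges(start0 + 1L, end0), strand = tb[[4]])
  mcols(gr)$circ_id <- tb[[5]]
  mcols(gr)$db_name <- if (ncol(tb) >= 6L) tb[[6]]
    else if (!is.null(db_name)) db_name
    else NA_character_
  gr
}

#' Write a known-circRNA catalog in the format read by [readKnownCircs()]
#' @param known GRanges with mcols circ_id, db_name
#' @param path output file
#' @export
writeKnownCircs <- function(known, path) {
  tb <- data.frame(as.character(seqnames(known)), start(known) - 1L,
                   end(known), as.character(strand(known)),
                   mcols(known)$circ_id, mcols(known)$db_name)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write circRNA isoform calls as BED12
#'
#' One BED12 row per entry; `blocks` encode the exon structure relative to
#' the interval start (first block must start at 0, last must end at the
#' interval end, per the BED specification).
#'
#' @param gr GRanges with mcols `name`, `score` and `blocks` (an
#'   IRangesList of 1-based block ranges relative to each interval start)
#' @param path output file
#' @export
writeBed12 <- function(gr, path) {
  stopifnot(!is.null(mcols(gr)$blocks))
  for (i in seq_along(gr)) {
    b <- mcols(gr)$blocks[[i]]
    if (length(b) == 0L || start(b)[1] != 1L ||
        end(b)[length(b)] != width(gr)[i])
      stop("BED12 blocks of entry ", i,
           " must start at 0 and end at the interval end")
  }
  mcols(gr)$thick <- IRanges::ranges(gr)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED12 file of circRNA isoform calls
#'
#' @param path input file
#' @return GRanges with mcols `name`, `score`, `blocks` (relative 1-based)
#' @export
readBed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(mcols(gr)$blocks))
    stop("'", path, "' is not BED12 (no block structure)")
  for (i in seq_along(gr)) {
    b <- mcols(gr)$blocks[[i]]
    if (length(b) == 0L || start(b)[1] != 1L ||
        end(b)[length(b)] != width(gr)[i])
      stop("'", path, "' entry ", i,
           ": blockStarts must begin at 0 and blocks must span the entry")
  }
  mcols(gr) <- mcols(gr)[, intersect(c("name", "score", "blocks"),
                                     names(mcols(gr))), drop = FALSE]
  gr
}
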