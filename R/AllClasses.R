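# Central S4 containers.
#
# Coordinate conventions: every on-disk format handled here (PSL, BED, chain,
# the gene-model and catalog TSVs) is 0-based half-open, and all plain
# integer columns in DataFrames (alignment hits, BSJ candidates) keep that
# convention. GRanges-backed slots are 1-based closed as usual for
# Bioconductor; readers/writers convert at the boundary.

#' Gene models on a genome
#'
#' Holds one record per transcript/gene: its span, strand, exon structure,
#' derived introns, an rRNA flag (used to exclude rRNA-mapping reads from
#' circRNA calling) and optional per-exon coding phases (codon offset 0/1/2
#' at the exon 5' end, as in GFF3 CDS phase).
#'
#' @slot genes GRanges, one range per gene span, with mcols `gene_id`
#'   (character) and `is_rRNA` (logical).
#' @slot exons GRangesList parallel to `genes`; each element's mcols carry
#'   `phase` (integer 0/1/2 or NA for non-coding exons).
#' @slot introns GRangesList parallel to `genes`; the gaps between
#'   consecutive exons.
#'
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", exons = "GRangesList",
                 introns = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (length(object@exons) != n || length(object@introns) != n)
    msg <- c(msg, "genes, exons and introns must be parallel")
  if (!all(c("gene_id", "is_rRNA") %in% names(mcols(object@genes))))
    msg <- c(msg, "genes must carry gene_id and is_rRNA mcols")
  for (i in seq_len(n)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) { msg <- c(msg, "gene with no exons"); next }
    if (is.unsorted(start(ex)) ||
        any(start(ex)[-1] <= end(ex)[-length(ex)]))
      msg <- c(msg, sprintf("exons of gene %d not sorted/disjoint", i))
    intr <- object@introns[[i]]
    if (length(ex) > 1L) {
      expected <- IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L)
      if (length(intr) != length(expected) ||
          any(start(intr) != start(expected)) ||
          any(end(intr) != end(expected)))
        msg <- c(msg, sprintf("introns of gene %d do not fill exon gaps", i))
    } else if (length(intr) != 0L) {
      msg <- c(msg, "single-exon gene with introns")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Collapsed unique circRNA calls
#'
#' One record per unique (chrom, strand, start, end) circRNA region, with
#' supporting-read count, host gene, database identifiers, mean annotation
#' overlaps of the supporting reads and the end-adjustment statistics
#' applied during end correction.
#'
#' @slot ranges GRanges (1-based closed) with mcols: `n_reads`, `host_gene`,
#'   `circBase_id`, `circAtlas_id`, `CIRCpedia_id`, `mean_bp_gene`,
#'   `mean_bp_exon`, `mean_bp_intron`, `mean_bp_est`, `adjust_min`,
#'   `adjust_max`, `adjust_mean`, `is_novel`.
#'
#' @export
setClass("CircRNASet", representation(ranges = "GRanges"))

.circ_mcols <- c("n_reads", "host_gene", "circBase_id", "circAtlas_id",
                 "CIRCpedia_id", "mean_bp_gene", "mean_bp_exon",
                 "mean_bp_intron", "mean_bp_est", "adjust_min", "adjust_max",
                 "adjust_mean", "is_novel")

setValidity("CircRNASet", function(object) {
  msg <- character()
  m <- mcols(object@ranges)
  if (!all(.circ_mcols %in% names(m)))
    msg <- c(msg, paste("missing mcols:",
                        paste(setdiff(.circ_mcols, names(m)), collapse = ", ")))
  if (length(object@ranges) && any(m$n_reads < 1L))
    msg <- c(msg, "n_reads must be >= 1")
  if (length(object@ranges) &&
      any(m$adjust_min > m$adjust_mean | m$adjust_mean > m$adjust_max))
    msg <- c(msg, "adjust_min <= adjust_mean <= adjust_max violated")
  if (length(msg)) msg else TRUE
})

#' Chain-file alignment map between two assemblies
#'
#' Parsed UCSC chain file: ordered chains, each with header fields and a
#' block table. Coordinates are kept 0-based half-open as in the format;
#' the "t" (source) side is the assembly being lifted from, the "q"
#' (target) side the assembly lifted to. Minus-strand q coordinates are on
#' the reverse strand, as in the format.
#'
#' @slot chains list of chains; each a list with elements `score`, `t_name`,
#'   `t_size`, `t_start`, `t_end`, `q_name`, `q_size`, `q_strand`,
#'   `q_start`, `q_end`, `id` and `blocks`, a data.frame with columns
#'   `t_start`, `q_start`, `size` (block-level 0-based starts on each side).
#'
#' @export
setClass("ChainMap", representation(chains = "list"))

setValidity("ChainMap", function(object) {
  for (ch in object@chains) {
    b <- ch$blocks
    if (is.unsorted(b$t_start, strictly = TRUE) ||
        is.unsorted(b$q_start, strictly = TRUE))
      return("chain blocks must increase monotonically on both genomes")
    if (any(b$t_start + b$size > ch$t_end))
      return("chain block exceeds chain t extent")
  }
  TRUE
})

#' @describeIn GeneModelSet number of gene models
#' @param x a GeneModelSet
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@genes))

#' @describeIn CircRNASet number of unique circRNAs
#' @param x a CircRNASet
#' @export
setMethod("length", "CircRNASet", function(x) length(x@ranges))

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object), "gene model(s) on",
      length(unique(as.character(seqnames(object@genes)))), "sequence(s)\n")
  if (any(mcols(object@genes)$is_rRNA))
    cat("  ", sum(mcols(object@genes)$is_rRNA), "flagged as rRNA\n")
})

setMethod("show", "CircRNASet", function(object) {
  cat("CircRNASet with", length(object), "unique circRNA(s)\n")
  if (length(object)) {
    m <- mcols(object@ranges)
    cat("  supporting reads:", sum(m$n_reads),
        "| novel:", sum(m$is_novel), "\n")
  }
})

setMethod("show", "ChainMap", function(object) {
  cat("ChainMap with", length(object@chains), "chain(s)\n")
})

#' Extract gene spans, exons or introns from a GeneModelSet
#'
#' @param x a GeneModelSet
#' @return `geneRanges`: GRanges of gene spans; `exonsByGene` /
#'   `intronsByGene`: GRangesList named by gene_id.
#' @export
geneRanges <- function(x) {
  stopifnot(is(x, "GeneModelSet"))
  x@genes
}

#' @rdname geneRanges
#' @export
exonsByGene <- function(x) {
  stopifnot(is(x, "GeneModelSet"))
  setNames(x@exons, mcols(x@genes)$gene_id)
}

#' @rdname geneRanges
#' @export
intronsByGene <- function(x) {
  stopifnot(is(x, "GeneModelSet"))
  setNames(x@introns, mcols(x@genes)$gene_id)
}

#' GRanges of a CircRNASet (1-based closed, with all annotation mcols)
#' @param x a CircRNASet
#' @export
circRanges <- function(x) {
  stopifnot(is(x, "CircRNASet"))
  x@ranges
}

#' Construct a GeneModelSet from parallel containers
#'
#' @param genes GRanges of gene spans with mcols gene_id, is_rRNA
#' @param exons GRangesList of exons per gene (sorted, disjoint); mcols may
#'   carry `phase`
#' @return a validated GeneModelSet; introns are derived.
#' @export
GeneModelSet <- function(genes, exons) {
  exons <- as(exons, "GRangesList")
  if (is.null(mcols(genes)$is_rRNA)) mcols(genes)$is_rRNA <- FALSE
  introns <- lapply(seq_along(exons), function(i) {
    ex <- exons[[i]]
    if (length(ex) < 2L) return(granges(ex)[0])
    GRanges(seqnames(ex)[1],
            IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L),
            strand = as.character(strand(ex))[1])
  })
  new("GeneModelSet", genes = genes, exons = exons,
      introns = as(GRangesList(introns), "GRangesList"))
}

#' Construct a CircRNASet from a GRanges with the required mcols
#' @param ranges GRanges with the mcols documented in [CircRNASet-class]
#' @export
CircRNASet <- function(ranges) new("CircRNASet", ranges = ranges)

#' Coerce a CircRNASet to a data.frame (0-based half-open coordinates)
#'
#' @param x a CircRNASet
#' @param row.names,optional ignored
#' @param ... ignored
#' @export
as.data.frame.CircRNASet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  gr <- x@ranges
  cbind(data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   strand = as.character(strand(gr)),
                   stringsAsFactors = FALSE),
        as.data.frame(mcols(gr)))
}
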