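# Cross-assembly conservation of circRNAs: 20-bp end anchors are lifted
# through a chain map, recombined into a BSJ, and compared for exact
# coordinate matches in both directions.

# Lift both end anchors of a BSJ and recombine. NULL when either anchor is
# unmapped, lands on different chromosomes, or the two anchors disagree on
# orientation.
.lift_bsj <- function(chain, chrom, s0, e0, strand, anchorBp = 20) {
  a1 <- liftAnchor(chain, chrom, s0, min(s0 + anchorBp, e0))
  a2 <- liftAnchor(chain, chrom, max(e0 - anchorBp, s0), e0)
  if (is.null(a1) || is.null(a2)) return(NULL)
  if (a1$chrom != a2$chrom || a1$flipped != a2$flipped) return(NULL)
  ns <- min(a1$start0, a2$start0); ne <- max(a1$end0, a2$end0)
  nstrand <- if (a1$flipped) (if (strand == "+") "-" else "+") else strand
  list(chrom = a1$chrom, start0 = ns, end0 = ne, strand = nstrand)
}

#' Cross-assembly conservation of circRNAs
#'
#' For every circRNA in `setA`, its two `anchorBp` (20) bp end anchors are
#' lifted through `chainsAB`, recombined into a BSJ, and compared for an
#' exact (chromosome, start, end, strand) match in `setB` — internal splice
#' structure is ignored. A pair is conserved only when the reverse lift of
#' the matched circRNA through `chainsBA` also exactly recovers the
#' original BSJ.
#'
#' @param setA,setB [CircRNASet] tables from the two assemblies
#' @param chainsAB,chainsBA [ChainMap]s A-to-B and B-to-A
#' @param anchorBp anchor width in bp (default 20)
#' @return list: `results` (DataFrame per setA circRNA: lifted BSJ, matched
#'   index, `reciprocal_ok`), `n_conserved_pairs`, `fraction_a_pct`,
#'   `fraction_b_pct` (percentages of each set in a conserved pair)
#' @export
conservedCircRNAs <- function(setA, setB, chainsAB, chainsBA,
                              anchorBp = 20) {
  grA <- circRanges(setA); grB <- circRanges(setB)
  bs0 <- start(grB) - 1L; be0 <- end(grB)
  bchr <- as.character(seqnames(grB)); bstr <- as.character(strand(grB))
  n <- length(grA)
  achr <- as.character(seqnames(grA)); as0 <- start(grA) - 1L
  ae0 <- end(grA); astr <- as.character(strand(grA))
  l_chr <- rep(NA_character_, n); l_s <- rep(NA_integer_, n)
  l_e <- rep(NA_integer_, n); l_str <- rep(NA_character_, n)
  m_ix <- rep(NA_integer_, n); recip <- logical(n)
  # reverse lifts are cached per matched target circRNA
  back_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    lf <- .lift_bsj(chainsAB, achr[i], as0[i], ae0[i], astr[i], anchorBp)
    if (is.null(lf)) next
    l_chr[i] <- lf$chrom; l_s[i] <- lf$start0
    l_e[i] <- lf$end0; l_str[i] <- lf$strand
    j <- which(bchr == lf$chrom & bs0 == lf$start0 & be0 == lf$end0 &
                 bstr == lf$strand)
    if (!length(j)) next
    j <- j[1]
    m_ix[i] <- j
    key <- as.character(j)
    back <- if (!is.null(back_cache[[key]])) back_cache[[key]]
      else back_cache[[key]] <- .lift_bsj(chainsBA, bchr[j], bs0[j],
                                          be0[j], bstr[j], anchorBp)
    recip[i] <- !is.null(back) && back$chrom == achr[i] &&
      back$start0 == as0[i] && back$end0 == ae0[i] &&
      back$strand == astr[i]
  }
  res <- DataFrame(chrom = achr, start = as0, end = ae0, strand = astr,
                   lifted_chrom = l_chr, lifted_start = l_s,
                   lifted_end = l_e, lifted_strand = l_str,
                   matched_index = m_ix, reciprocal_ok = recip)
  conserved <- which(res$reciprocal_ok)
  nB <- length(unique(res$matched_index[conserved]))
  list(results = res,
       n_conserved_pairs = length(conserved),
       fraction_a_pct = if (n > 0) 100 * length(conserved) / n else NA_real_,
       fraction_b_pct = if (length(grB) > 0) 100 * nB / length(grB)
                        else NA_real_)
}
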