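# UCSC chain files and strict anchor liftover.
#
# A chain maps its "t" (source) assembly to its "q" (target) assembly
# through ordered ungapped blocks. The lift used for conservation is
# deliberately strict: an anchor maps only when all of its bases fall
# inside a single ungapped block of one chain, so a gap under any base, or
# a target-side split, leaves it unmapped.

#' Read a UCSC chain file
#' @param path chain file
#' @return a [ChainMap]
#' @export
readChain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stop("chain file '", path, "' line ", i, ": expected chain header")
    hdr <- list(score = as.numeric(f[2]),
                t_name = f[3], t_size = as.integer(f[4]),
                t_start = as.integer(f[6]), t_end = as.integer(f[7]),
                q_name = f[8], q_size = as.integer(f[9]),
                q_strand = f[10],
                q_start = as.integer(f[11]), q_end = as.integer(f[12]),
                id = if (length(f) >= 13L) f[13] else NA_character_)
    if (f[5] != "+")
      stop("chain file '", path, "' line ", i, ": tStrand must be +")
    tcur <- hdr$t_start; qcur <- hdr$q_start
    blocks <- list()
    repeat {
      i <- i + 1L
      if (i > length(lines)) stop("chain file '", path,
                                  "': truncated block list")
      bf <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (!length(bf) || !nzchar(bf[1])) next
      size <- as.integer(bf[1])
      blocks[[length(blocks) + 1L]] <- c(t_start = tcur, q_start = qcur,
                                         size = size)
      if (length(bf) == 1L) { i <- i + 1L; break }
      tcur <- tcur + size + as.integer(bf[2])
      qcur <- qcur + size + as.integer(bf[3])
    }
    hdr$blocks <- as.data.frame(do.call(rbind, blocks))
    chains[[length(chains) + 1L]] <- hdr
  }
  new("ChainMap", chains = chains)
}

#' Write a ChainMap as a UCSC chain file
#' @param chain a [ChainMap]
#' @param path output file
#' @export
writeChain <- function(chain, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ch in chain@chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, ch$t_size, "+", ch$t_start, ch$t_end,
                     ch$q_name, ch$q_size, ch$q_strand, ch$q_start,
                     ch$q_end,
                     if (is.na(ch$id)) "1" else ch$id), con)
    b <- ch$blocks
    for (k in seq_len(nrow(b))) {
      if (k < nrow(b)) {
        dt <- b$t_start[k + 1] - (b$t_start[k] + b$size[k])
        dq <- b$q_start[k + 1] - (b$q_start[k] + b$size[k])
        writeLines(paste(b$size[k], dt, dq), con)
      } else writeLines(as.character(b$size[k]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Lift a genomic anchor through a chain map
#'
#' The anchor maps only if every base lies within one ungapped block of a
#' single chain; among chains that fully cover it, the highest-scoring one
#' wins (ties broken by file order). Minus-strand target coordinates are
#' returned on the forward strand, with `flipped = TRUE`.
#'
#' @param chain a [ChainMap]
#' @param chrom source chromosome
#' @param start0,end0 source interval, 0-based half-open
#' @return a list `(chrom, start0, end0, flipped)` or `NULL` when unmapped
#' @export
liftAnchor <- function(chain, chrom, start0, end0) {
  stopifnot(end0 > start0)
  best <- NULL
  for (ch in chain@chains) {
    if (ch$t_name != chrom) next
    b <- ch$blocks
    hit <- which(b$t_start <= start0 & b$t_start + b$size >= end0)
    if (!length(hit)) next
    if (is.null(best) || ch$score > best$score)
      best <- list(score = ch$score, ch = ch, blk = hit[1])
  }
  if (is.null(best)) return(NULL)
  ch <- best$ch; b <- ch$blocks[best$blk, ]
  off <- start0 - b$t_start
  qs <- b$q_start + off
  qe <- qs + (end0 - start0)
  if (ch$q_strand == "-") {
    fs <- ch$q_size - qe; fe <- ch$q_size - qs
    list(chrom = ch$q_name, start0 = fs, end0 = fe, flipped = TRUE)
  } else {
    list(chrom = ch$q_name, start0 = qs, end0 = qe, flipped = FALSE)
  }
}
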