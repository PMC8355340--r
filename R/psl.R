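# PSL (BLAT) alignment parsing and writing.
#
# PSL is 21-column, 0-based half-open. Top-level qStart/qEnd are always on
# the forward (plus) strand of the query; per-block qStarts of minus-strand
# hits are in reverse-complement query coordinates and are normalized to the
# forward read axis at parse time, so downstream "reverse order relative to
# the read" logic sees a single consistent read axis. Blocks are stored in
# ascending target order.

.psl_ncol <- 21L

.split_ints <- function(s) {
  s <- sub(",+$", "", s)
  if (!nzchar(s)) return(integer())
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Parse a PSL alignment file into an alignment-hit table
#'
#' @param path path to a PSL file, with or without the `psLayout` header
#' @return a [S4Vectors::DataFrame] with one row per hit: `read_id`,
#'   `q_size`, `q_start`, `q_end` (forward read axis, 0-based half-open),
#'   `t_chrom`, `t_size`, `t_start`, `t_end`, `strand`, `matches`,
#'   `mismatches`, `q_gap_count`, `t_gap_count`, and block structure as
#'   IntegerList columns `block_sizes`, `block_q_starts` (forward read
#'   axis), `block_t_starts`, blocks sorted by target coordinate.
#' @export
parsePsl <- function(path) {
  lines <- readLines(path)
  offset <- 0L
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    offset <- 5L            # psLayout header block is 5 lines
    lines <- lines[-seq_len(min(5L, length(lines)))]
  }
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + offset
  lines <- lines[keep]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != .psl_ncol)
      stop("PSL line ", lineno[i], ": expected ", .psl_ncol,
           " columns, got ", length(f))
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (any(is.na(num)))
      stop("PSL line ", lineno[i], ": non-numeric field")
    sizes <- .split_ints(f[19]); qs <- .split_ints(f[20])
    ts <- .split_ints(f[21])
    bc <- as.integer(f[18])
    if (length(sizes) != bc || length(qs) != bc || length(ts) != bc)
      stop("PSL line ", lineno[i], ": blockCount (", bc,
           ") disagrees with block lists")
    strand <- f[9]
    if (!strand %in% c("+", "-"))
      stop("PSL line ", lineno[i], ": unsupported strand '", strand, "'")
    if (sum(sizes) != sum(as.integer(f[1:4])))
      stop("PSL line ", lineno[i],
           ": block sizes do not sum to match/mismatch counts")
    q_size <- as.integer(f[11])
    if (strand == "-") qs <- q_size - (qs + sizes)
    ord <- order(ts)
    out[[i]] <- list(
      read_id = f[10], q_size = q_size,
      q_start = as.integer(f[12]), q_end = as.integer(f[13]),
      t_chrom = f[14], t_size = as.integer(f[15]),
      t_start = as.integer(f[16]), t_end = as.integer(f[17]),
      strand = strand,
      matches = as.integer(f[1]), mismatches = as.integer(f[2]),
      rep_matches = as.integer(f[3]), n_count = as.integer(f[4]),
      q_gap_count = as.integer(f[5]), t_gap_count = as.integer(f[7]),
      block_sizes = sizes[ord], block_q_starts = qs[ord],
      block_t_starts = ts[ord])
  }
  .hits_df(out)
}

.hits_df <- function(rows) {
  scalar <- function(nm, mode) {
    if (mode == "c")
      return(vapply(rows, function(r) as.character(r[[nm]]), character(1)))
    as.integer(vapply(rows, function(r) as.numeric(r[[nm]]), numeric(1)))
  }
  ilist <- function(nm) IRanges::IntegerList(
    lapply(rows, function(r) as.integer(r[[nm]])))
  DataFrame(
    read_id = scalar("read_id", "c"),
    q_size = scalar("q_size", "i"),
    q_start = scalar("q_start", "i"), q_end = scalar("q_end", "i"),
    t_chrom = scalar("t_chrom", "c"),
    t_size = scalar("t_size", "i"),
    t_start = scalar("t_start", "i"), t_end = scalar("t_end", "i"),
    strand = scalar("strand", "c"),
    matches = scalar("matches", "i"), mismatches = scalar("mismatches", "i"),
    rep_matches = scalar("rep_matches", "i"),
    n_count = scalar("n_count", "i"),
    q_gap_count = scalar("q_gap_count", "i"),
    t_gap_count = scalar("t_gap_count", "i"),
    block_sizes = ilist("block_sizes"),
    block_q_starts = ilist("block_q_starts"),
    block_t_starts = ilist("block_t_starts"))
}

#' An empty alignment-hit table (the parsePsl schema)
#' @export
emptyHits <- function() .hits_df(list())

#' Write an alignment-hit table back to PSL
#'
#' Inverse of [parsePsl()]: forward-read block coordinates of minus-strand
#' hits are converted back to the PSL reverse-query convention, and blocks
#' are emitted in the format's native order.
#'
#' @param hits a DataFrame as produced by [parsePsl()]
#' @param path output file
#' @param header write the `psLayout` header block
#' @export
writePsl <- function(hits, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("psLayout version 3", "",
      paste("match\tmis- \trep. \tN's\tQ gap\tQ gap\tT gap\tT gap",
            "\tstrand\tQ        \tQ   \tQ    \tQ  \tT        \tT   \tT",
            "    \tT  \tblock\tblockSizes \tqStarts\t tStarts"),
      paste("     \tmatch\tmatch\t   \tcount\tbases\tcount\tbases",
            "\t      \tname     \tsize\tstart\tend\tname     \tsize",
            "\tstart\tend\tcount"),
      strrep("-", 120)), con)
  }
  sizes_l <- as.list(hits$block_sizes)
  qs_l <- as.list(hits$block_q_starts)
  ts_l <- as.list(hits$block_t_starts)
  scalars <- as.data.frame(hits[, !(names(hits) %in%
    c("block_sizes", "block_q_starts", "block_t_starts")), drop = FALSE])
  for (i in seq_len(nrow(hits))) {
    h <- scalars[i, , drop = FALSE]
    sizes <- sizes_l[[i]]; qs <- qs_l[[i]]; ts <- ts_l[[i]]
    if (h$strand == "-") {
      qs <- h$q_size - (qs + sizes)
      ord <- order(qs)          # native order: ascending reversed-q == asc t
    } else ord <- order(ts)
    q_bases <- max(0L, (h$q_end - h$q_start) - sum(sizes))
    t_bases <- max(0L, (h$t_end - h$t_start) - sum(sizes))
    writeLines(paste(
      h$matches, h$mismatches, h$rep_matches, h$n_count,
      h$q_gap_count, q_bases, h$t_gap_count, t_bases,
      h$strand, h$read_id, h$q_size, h$q_start, h$q_end,
      h$t_chrom, h$t_size, h$t_start, h$t_end, length(sizes),
      paste0(paste(sizes[ord], collapse = ","), ","),
      paste0(paste(qs[ord], collapse = ","), ","),
      paste0(paste(ts[ord], collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}
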