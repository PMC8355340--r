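# Read-level quality: Phred conversion, mean read quality, filtering,
# poly(A) stretch flagging.

#' Convert a Phred quality score to an error probability
#'
#' Q = -10 * log10(err), hence err = 10^(-Q/10). A score of 11.95
#' corresponds to an error rate of 0.064.
#'
#' @param q numeric vector of Phred scores, each finite and >= 0
#' @return error probabilities in (0, 1]
#' @examples
#' qToError(c(0, 10, 11.95))
#' @export
qToError <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0))
    stop("Phred scores must be finite and non-negative")
  10^(-q / 10)
}

#' Mean quality of a read
#'
#' The default ("error") converts per-base Phred scores to error
#' probabilities, averages those, and reports the Phred value of the mean
#' error probability — the convention of long-read QC tools, which weights
#' low-quality bases properly. `method = "phred"` is the arithmetic mean of
#' the Phred values instead.
#'
#' @param qualities integer/numeric vector of per-base Phred scores
#' @param method "error" (Phred of mean error probability) or "phred"
#' @return a single Phred-scale value
#' @export
meanQuality <- function(qualities, method = c("error", "phred")) {
  method <- match.arg(method)
  if (length(qualities) == 0L) return(NA_real_)
  if (method == "phred") return(mean(qualities))
  -10 * log10(mean(qToError(qualities)))
}

#' Read a FASTQ file of long reads
#'
#' @param path FASTQ file (Sanger Phred+33)
#' @return a [QualityScaledDNAStringSet][Biostrings::QualityScaledDNAStringSet]
#' @export
readLongReads <- function(path) {
  out <- tryCatch(
    suppressWarnings(
      readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(Biostrings::width(out) != Biostrings::width(quality(out)))
  if (length(bad))
    stop("malformed FASTQ '", path, "': sequence/quality length mismatch ",
         "in record ", bad[1])
  out
}

#' Write long reads to FASTQ
#' @param reads a QualityScaledDNAStringSet
#' @param path output file
#' @export
writeLongReads <- function(reads, path) {
  writeXStringSet(reads, path, format = "fastq",
                  qualities = quality(reads))
}

#' Per-read mean quality of a read set
#' @param reads a QualityScaledDNAStringSet
#' @inheritParams meanQuality
#' @return numeric vector, one Phred value per read
#' @export
readMeanQualities <- function(reads, method = c("error", "phred")) {
  method <- match.arg(method)
  qs <- as(quality(reads), "IntegerList")
  vapply(qs, meanQuality, numeric(1), method = method)
}

#' Filter long reads on mean quality and length
#'
#' Retains exactly the reads with mean quality >= `minQuality` and length
#' >= `minLength` (both inclusive), preserving order. Defaults match
#' standard nanopore pre-filtering: Q >= 7 and >= 250 bp.
#'
#' @param reads a QualityScaledDNAStringSet
#' @param minQuality Phred threshold (inclusive)
#' @param minLength length threshold in bases (inclusive)
#' @inheritParams meanQuality
#' @return the retained subset, same class
#' @export
filterReads <- function(reads, minQuality = 7, minLength = 250,
                        method = c("error", "phred")) {
  method <- match.arg(method)
  keep <- Biostrings::width(reads) >= minLength &
    readMeanQualities(reads, method = method) >= minQuality
  reads[keep]
}

#' Flag sequences containing a poly(A) stretch
#'
#' TRUE iff the sequence contains `k` or more consecutive "A" residues.
#' "N" bases never extend a run. circRNAs with internal stretches of 7 or
#' more A's can bind oligo-dT beads and be depleted during poly(A)-removal
#' enrichment, so flagging them is useful when interpreting abundance.
#'
#' @param sequence character vector (or DNAStringSet) of sequences over
#'   A/C/G/T/N
#' @param k minimum run length (default 7)
#' @return logical vector
#' @export
polyAStretch <- function(sequence, k = 7) {
  if (is(sequence, "XStringSet")) sequence <- as.character(sequence)
  stopifnot(k >= 1)
  grepl(paste0("A{", as.integer(k), ",}"), toupper(sequence))
}
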