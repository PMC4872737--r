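#' Construct a circular mitochondrial reference genome object
#'
#' Coordinates are 1-based throughout the package, matching the convention of
#' rCRS-style mitochondrial variant nomenclature. The molecule is treated as
#' circular: position 1 has the last base as its 5' flank and the last
#' position has position 1 as its 3' flank.
#'
#' @param sequence Character scalar over \code{A,C,G,T,N} (lower case
#'   accepted and upper-cased). Length must be at least 3 so that every
#'   position has a trinucleotide context.
#' @param name Text identifier for the sequence.
#' @return An object of class \code{mt_reference} with fields
#'   \code{name}, \code{sequence}, \code{circular} (always \code{TRUE}) and
#'   \code{length}.
#' @export
#' @examples
#' ref <- mt_reference("ACGT")
#' ref$length
mt_reference <- function(sequence, name = "mt") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L)
    stop("reference sequence must be at least 3 bases long, got ", n)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("illegal characters in reference sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         " (only A, C, G, T, N allowed)")
  structure(
    list(name = name, sequence = sequence, circular = TRUE, length = n),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("mt_reference '", x$name, "': ", x$length, " bp, circular\n", sep = "")
  invisible(x)
}

#' Load a mitochondrial reference genome from a FASTA file
#'
#' The file must contain exactly one DNA record. Ambiguity codes other than
#' N are rejected: heteroplasmy is represented by per-variant allele
#' fractions, not by IUPAC codes in the reference.
#'
#' @param fasta_file Path to a single-record FASTA file.
#' @return An [mt_reference] object.
#' @export
read_mt_reference <- function(fasta_file) {
  if (!file.exists(fasta_file))
    stop("reference FASTA not found: ", fasta_file)
  recs <- tryCatch(
    Biostrings::readBStringSet(fasta_file),
    error = function(e) stop("cannot read FASTA '", fasta_file, "': ",
                             conditionMessage(e))
  )
  if (length(recs) == 0L)
    stop("reference FASTA '", fasta_file, "' contains no sequence record")
  if (length(recs) > 1L)
    stop("reference FASTA '", fasta_file, "' contains ", length(recs),
         " records; exactly one expected")
  mt_reference(as.character(recs[[1]]), name = names(recs)[1])
}

base_at <- function(ref, position) {
  substr(ref$sequence, position, position)
}

#' Trinucleotide context at a position
#'
#' Returns the 3-mer formed by the 5' flanking base, the base itself and the
#' 3' flanking base, with circular wrap-around at both ends of the molecule.
#'
#' @param ref An [mt_reference].
#' @param position Integer vector of 1-based positions.
#' @return Character vector of 3-mers, one per position.
#' @export
#' @examples
#' context_at(mt_reference("ACGT"), 1) # "TAC" (wraps around the origin)
context_at <- function(ref, position) {
  stopifnot(inherits(ref, "mt_reference"))
  position <- as.integer(position)
  if (any(is.na(position) | position < 1L | position > ref$length))
    stop("position out of range 1..", ref$length)
  n <- ref$length
  up <- ((position - 2L) %% n) + 1L
  dn <- (position %% n) + 1L
  paste0(substring(ref$sequence, up, up),
         substring(ref$sequence, position, position),
         substring(ref$sequence, dn, dn))
}

#' Trinucleotide frequencies of the reference genome
#'
#' Every one of the \code{length} circular positions contributes one context,
#' so the frequencies of the (at most 64) observed 3-mers sum to 1. Contexts
#' containing an N are pooled under the key \code{"ambiguous"} and excluded
#' from the unit-sum set.
#'
#' @param ref An [mt_reference].
#' @return Named numeric vector of frequencies.
#' @export
trinucleotide_frequencies <- function(ref) {
  stopifnot(inherits(ref, "mt_reference"))
  ctx <- context_at(ref, seq_len(ref$length))
  amb <- grepl("N", ctx, fixed = TRUE)
  out <- table(ctx[!amb]) / ref$length
  out <- stats::setNames(as.numeric(out), names(out))
  if (any(amb)) out <- c(out, ambiguous = sum(amb) / ref$length)
  out
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over \code{A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
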