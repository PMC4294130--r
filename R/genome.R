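#' Construct a circular genome object
#'
#' A light container for a (typically circular) nucleotide sequence, the
#' common currency of all analysis stages. Sequences are stored uppercased
#' with `U` mapped to `T`; the full IUPAC alphabet is accepted (ambiguity
#' codes such as `R`/`Y` occur in older plastome accessions) but downstream
#' counting operations treat anything outside `A,C,G,T` as missing.
#'
#' @param seq single nucleotide string.
#' @param id sequence label.
#' @param circular logical; plastomes are circular.
#' @return An object of class `cp_genome` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @export
circular_genome <- function(seq, id = "genome", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- chartr("u", "t", seq)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nchar(bad) > 0L) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular),
         length = nchar(seq)),
    class = "cp_genome"
  )
}

#' @export
print.cp_genome <- function(x, ...) {
  cat(sprintf("<cp_genome> %s: %s bp%s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @export
length.cp_genome <- function(x) x$length

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware; thin wrapper over Biostrings.
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## complement without reversal, vectorised over single characters
comp_chars <- function(chars) {
  chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN", chars)
}

#' Extract a (possibly origin-wrapping) substring of a circular genome
#'
#' @param genome a `cp_genome`.
#' @param start 1-based start on the circle.
#' @param len number of bases.
#' @return nucleotide string of length `len`.
#' @export
subseq_circular <- function(genome, start, len) {
  n <- genome$length
  stopifnot(len >= 0L, len <= n)
  if (len == 0L) return("")
  start <- ((start - 1L) %% n) + 1L
  end <- start + len - 1L
  if (end <= n) {
    substr(genome$seq, start, end)
  } else {
    paste0(substr(genome$seq, start, n), substr(genome$seq, 1L, end - n))
  }
}

#' Rotate a circular genome so a given position becomes base 1
#'
#' @param genome a `cp_genome`.
#' @param new_origin 1-based position that becomes the first base.
#' @return rotated `cp_genome`.
#' @export
rotate_genome <- function(genome, new_origin) {
  stopifnot(genome$circular)
  genome$seq <- subseq_circular(genome, new_origin, genome$length)
  genome
}

## split a genome (or string) into a character vector of single bases
seq_chars <- function(x) {
  if (inherits(x, "cp_genome")) x <- x$seq
  strsplit(x, "", fixed = TRUE)[[1]]
}

## GC fraction over A/C/G/T bases only
gc_fraction <- function(genome) {
  ch <- seq_chars(genome)
  acgt <- ch %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(ch[acgt] %in% c("G", "C")) / sum(acgt)
}
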