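#' Read a (multi-record) FASTA file into circular genome objects
#'
#' Sequences are uppercased and `U` is mapped to `T`. Record order is
#' preserved; the identifier is the first whitespace-delimited token of the
#' header line.
#'
#' @param path FASTA file.
#' @param circular logical, applied to every record.
#' @return list of [circular_genome()] objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("malformed FASTA at line %d: expected '>' header, got %s",
                 first, shQuote(substr(lines[first], 1, 30))))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    if (nchar(s) == 0L) stop("empty sequence for record ", ids[i])
    out[[i]] <- circular_genome(s, id = ids[i], circular = circular)
  }
  out
}

#' Write circular genomes to FASTA
#'
#' @param genomes a `cp_genome` or a list of them.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "cp_genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, g$length)),
               con)
  }
  invisible(path)
}

#' Read a FASTQ file (Sanger offset-33 qualities)
#'
#' @param path FASTQ file.
#' @return object of class `cp_reads`: parallel character vectors `id`,
#'   `seq` and `qual` (Phred string, offset 33).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: number of non-empty lines not a multiple of 4")
  }
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  if (!all(startsWith(ids, "@"))) {
    bad <- idx[which(!startsWith(ids, "@"))[1]]
    stop("malformed FASTQ at line ", bad, ": expected '@' header")
  }
  reads(id = sub("\\s.*$", "", sub("^@", "", ids)),
        seq = toupper(lines[idx + 1L]),
        qual = lines[idx + 3L])
}

#' Construct a read set
#'
#' @param id,seq,qual parallel character vectors; `qual` holds offset-33
#'   Phred strings of the same length as `seq`.
#' @return a `cp_reads` object.
#' @export
reads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("read and quality strings differ in length for read(s): ",
         paste(utils::head(id[nchar(seq) != nchar(qual)], 3), collapse = ", "))
  }
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)),
            class = "cp_reads")
}

#' @export
length.cp_reads <- function(x) length(x$id)

#' @export
print.cp_reads <- function(x, ...) {
  cat(sprintf("<cp_reads> %d reads\n", length(x)))
  invisible(x)
}

#' @export
`[.cp_reads` <- function(x, i) {
  reads(x$id[i], x$seq[i], x$qual[i])
}

## decode an offset-33 Phred string to integer qualities
phred_decode <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}
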