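#' Construct a pileup
#'
#' The pileup is the package's canonical alignment-evidence container: one
#' row per covered reference position with per-allele read counts. Alleles
#' are single bases (`"A"`), insertions (`"+SEQ"`, sequence inserted after
#' the position) or deletions (`"-SEQ"`). Depth is always the sum of the
#' allele counts.
#'
#' @param pos integer vector of 1-based positions (strictly increasing).
#' @param ref character vector of reference bases.
#' @param counts list of named integer vectors (allele -> read count).
#' @return object of class `cp_pileup`: data.frame with columns `pos`,
#'   `ref`, `depth` and list-column `counts`.
#' @export
pileup <- function(pos, ref, counts) {
  stopifnot(length(pos) == length(ref), length(ref) == length(counts))
  pos <- as.integer(pos)
  if (anyDuplicated(pos)) stop("duplicate position: ", pos[duplicated(pos)][1])
  for (i in seq_along(counts)) {
    cts <- counts[[i]]
    if (length(cts) && (is.null(names(cts)) || any(!nzchar(names(cts))))) {
      stop("unnamed or empty allele string at pos ", pos[i])
    }
    counts[[i]] <- as.integer(cts)
    names(counts[[i]]) <- names(cts)
  }
  depth <- vapply(counts, function(x) sum(as.integer(x)), integer(1))
  out <- data.frame(pos = pos, ref = as.character(ref), depth = depth)
  out$counts <- counts
  ord <- order(out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cp_pileup", "data.frame")
  out
}

#' Read a pileup TSV
#'
#' Format: one line per position, tab- or space-separated fields
#' `pos ref allele:count [allele:count ...]`. Depth is recomputed from the
#' counts. Lines starting with `#` are ignored; an empty file yields an
#' empty pileup.
#'
#' @param path input file.
#' @return a [pileup()] object.
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(pileup(integer(0), character(0), list()))
  }
  parts <- strsplit(lines, "[\t ]+")
  pos <- integer(length(parts)); ref <- character(length(parts))
  counts <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) stop("malformed pileup line ", i, ": ", lines[i])
    pos[i] <- suppressWarnings(as.integer(p[1]))
    if (is.na(pos[i])) stop("malformed pileup line ", i, ": bad position ", p[1])
    ref[i] <- p[2]
    cts <- integer(0)
    if (length(p) > 2L) {
      kv <- strsplit(p[-(1:2)], ":", fixed = TRUE)
      if (any(lengths(kv) != 2L)) {
        stop("malformed allele:count pair on line ", i)
      }
      cts <- stats::setNames(
        as.integer(vapply(kv, `[`, character(1), 2L)),
        vapply(kv, `[`, character(1), 1L))
      if (anyNA(cts)) stop("non-integer count on line ", i)
    }
    counts[[i]] <- cts
  }
  pileup(pos, ref, counts)
}

#' Write a pileup TSV
#'
#' @param pp a `cp_pileup`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pp, path) {
  lines <- vapply(seq_len(nrow(pp)), function(i) {
    cts <- pp$counts[[i]]
    paste(c(pp$pos[i], pp$ref[i],
            if (length(cts)) paste0(names(cts), ":", cts)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
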