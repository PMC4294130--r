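## Perfect tandem-repeat scanning: microsatellites (SSRs) and long tandem
## repeats, plus annotation context.

#' Default SSR scanning rules
#'
#' Mononucleotide runs are reported from a total length of 10 bases; units
#' of 2-6 bp need at least 3 copies and a total length of at least 10.
#'
#' @param mono_min_total minimum homopolymer run length.
#' @param unit_min,unit_max unit-size range for multimeric SSRs.
#' @param min_copies minimum copy number for multimeric SSRs.
#' @param min_total minimum total repeat length for multimeric SSRs.
#' @return rules list.
#' @export
ssr_rules <- function(mono_min_total = 10L, unit_min = 2L, unit_max = 6L,
                      min_copies = 3L, min_total = 10L) {
  list(mono_min_total = as.integer(mono_min_total),
       unit_min = as.integer(unit_min), unit_max = as.integer(unit_max),
       min_copies = as.integer(min_copies), min_total = as.integer(min_total))
}

#' Default long-tandem-repeat scanning rules
#'
#' Units of at least 7 bp, at least 3 copies, total length at least 20.
#'
#' @param unit_min,unit_max unit-size range.
#' @param min_copies minimum copy number.
#' @param min_total minimum total repeat length.
#' @return rules list.
#' @export
long_repeat_rules <- function(unit_min = 7L, unit_max = 100L,
                              min_copies = 3L, min_total = 20L) {
  list(unit_min = as.integer(unit_min), unit_max = as.integer(unit_max),
       min_copies = as.integer(min_copies), min_total = as.integer(min_total))
}

## is a unit primitive (not itself a repetition of a shorter unit)?
unit_is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u %/% 2L)) {
    if (u %% d == 0L &&
        strrep(substr(unit, 1L, d), u %/% d) == unit) return(FALSE)
  }
  TRUE
}

## core scan over one unit size on a linear character vector; returns
## data.frame(start, copies) of maximal primitive tandem tracts
scan_unit_size <- function(x, s, u, min_copies, min_total) {
  n <- length(x)
  if (n < u * max(2L, min_copies)) return(NULL)
  eq <- x[seq_len(n - u)] == x[seq_len(n - u) + u]
  eq[is.na(eq)] <- FALSE
  ## 'N' never participates in a repeat
  bad <- x == "N"
  if (any(bad)) eq <- eq & !bad[seq_len(n - u)] & !bad[seq_len(n - u) + u]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths + u >= max(min_total, u * min_copies))
  if (length(hit) == 0L) return(NULL)
  out <- lapply(hit, function(h) {
    tract_start <- starts[h]
    tract_len <- r$lengths[h] + u       # perfect-match tract in bases
    copies <- tract_len %/% u
    if (copies < min_copies || copies * u < min_total) return(NULL)
    unit <- substr(s, tract_start, tract_start + u - 1L)
    if (!unit_is_primitive(unit)) return(NULL)
    data.frame(unit = unit, copies = copies, start = tract_start,
               end = tract_start + copies * u - 1L,
               total_len = copies * u)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

scan_tandem <- function(genome, unit_sizes, min_copies, min_total,
                        mono_min_total = NULL, kind) {
  stopifnot(inherits(genome, "cp_genome"))
  n <- genome$length
  ## scan the doubled sequence so origin-spanning repeats are seen; keep
  ## hits starting in the first copy
  s <- if (genome$circular) paste0(genome$seq, genome$seq) else genome$seq
  x <- seq_chars(s)
  hits <- list()
  for (u in unit_sizes) {
    if (u == 1L) {
      h <- scan_unit_size(x, s, 1L, mono_min_total, mono_min_total)
    } else {
      h <- scan_unit_size(x, s, u, min_copies, min_total)
    }
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L) {
    return(empty_repeat_hits(kind))
  }
  hits <- do.call(rbind, hits)
  if (genome$circular) {
    hits <- hits[hits$start <= n & hits$total_len <= n, , drop = FALSE]
    hits$wrap <- hits$end > n
    hits$end <- ((hits$end - 1L) %% n) + 1L
    ## a tract at the very start of the doubled string can be a truncated
    ## image of an origin-wrapping repeat: enforce left-maximality on the
    ## circle
    if (nrow(hits)) {
      u <- nchar(hits$unit)
      prev <- ((hits$start - 2L) %% n) + 1L
      prev_u <- ((hits$start + u - 2L) %% n) + 1L
      xg <- x[seq_len(n)]
      drop <- xg[prev] == xg[prev_u] & xg[prev] != "N"
      hits <- hits[!drop, , drop = FALSE]
    }
  } else {
    hits$wrap <- FALSE
  }
  if (nrow(hits) == 0L) return(empty_repeat_hits(kind))
  hits$kind <- kind
  hits$context <- NA_character_
  hits <- hits[order(hits$start, nchar(hits$unit)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_repeat_hits <- function(kind) {
  data.frame(unit = character(0), copies = integer(0), start = integer(0),
             end = integer(0), total_len = integer(0), wrap = logical(0),
             kind = character(0), context = character(0))
}

#' Scan a genome for perfect simple sequence repeats (microsatellites)
#'
#' Reports every maximal perfect tandem repeat satisfying the rules,
#' sorted by start. The unit is reported in the phase of its first
#' occurrence, and a unit that is itself periodic (e.g. `ATAT`) is never
#' reported — the shorter primitive unit is. Windows containing `N` are
#' skipped. On circular genomes a repeat spanning the origin is reported
#' once with `wrap = TRUE`.
#'
#' @param genome a `cp_genome`.
#' @param rules see [ssr_rules()].
#' @return data.frame of repeat hits: `unit`, `copies`, `start`, `end`,
#'   `total_len`, `wrap`, `kind` (`"ssr"`), `context` (NA until
#'   [annotate_repeats()]).
#' @export
scan_ssrs <- function(genome, rules = ssr_rules()) {
  scan_tandem(genome,
              unit_sizes = c(1L, seq(rules$unit_min, rules$unit_max)),
              min_copies = rules$min_copies, min_total = rules$min_total,
              mono_min_total = rules$mono_min_total, kind = "ssr")
}

#' Scan a genome for long perfect tandem repeats
#'
#' Same contract as [scan_ssrs()] but for longer units; overlap with SSR
#' hits is not suppressed (the two kinds are independent inventories).
#'
#' @param genome a `cp_genome`.
#' @param rules see [long_repeat_rules()].
#' @return data.frame of repeat hits with `kind = "long"`.
#' @export
scan_long_repeats <- function(genome, rules = long_repeat_rules()) {
  scan_tandem(genome,
              unit_sizes = seq(rules$unit_min, rules$unit_max),
              min_copies = rules$min_copies, min_total = rules$min_total,
              kind = "long")
}

#' Fill repeat-hit genomic context from an annotation
#'
#' A hit whose midpoint lies in an exon gets `gene:<id>`; inside a gene
#' span but not an exon, `intron:<id>`; otherwise `intergenic`.
#'
#' @param hits data.frame from [scan_ssrs()] / [scan_long_repeats()].
#' @param ann a `cp_annotation` in the same coordinate frame.
#' @param genome_length circle length (for midpoints of wrapped hits).
#' @return `hits` with the `context` column filled.
#' @export
annotate_repeats <- function(hits, ann, genome_length = NULL) {
  if (nrow(hits) == 0L) return(hits)
  n <- genome_length
  mid <- ifelse(hits$wrap & !is.null(n),
                ((hits$start + (hits$total_len %/% 2L) - 1L) %% n) + 1L,
                hits$start + (hits$total_len %/% 2L))
  hits$context <- vapply(mid, function(p) locate_context(p, ann), character(1))
  hits
}

## classify one position against an annotation: gene:<id> (exonic),
## intron:<id>, or intergenic
locate_context <- function(pos, ann) {
  for (g in ann$genes) {
    sp <- gene_span(g)
    if (pos >= sp["start"] && pos <= sp["end"]) {
      inex <- any(pos >= g$exons[, 1] & pos <= g$exons[, 2])
      return(if (inex) paste0("gene:", g$gene_id)
             else paste0("intron:", g$gene_id))
    }
  }
  "intergenic"
}
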