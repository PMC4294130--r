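## Exon-anchored orthologous fragment partition and region-wise diversity.

exon_table <- function(ann) {
  rows <- lapply(ann$genes, function(g) {
    if (g$type != "protein_coding") return(NULL)
    data.frame(
      anchor = paste0(g$gene_id,
                      ifelse(is.na(g$copy_tag), "", paste0("|", g$copy_tag)),
                      ".e", seq_len(nrow(g$exons))),
      gene = g$gene_id,
      copy = ifelse(is.na(g$copy_tag), "", g$copy_tag),
      start = g$exons[, 1], end = g$exons[, 2])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(tab)
  tab[order(tab$start), , drop = FALSE]
}

#' Partition two genomes into exon-anchored orthologous fragments
#'
#' Each genome is cut at the exon boundaries of its protein-coding genes;
#' intervals flanked by the same exon anchors in both genomes pair up.
#' Exons themselves pair as CDS fragments; the gap between consecutive
#' shared exons is an intron when both anchors belong to the same gene
#' copy, otherwise an intergenic spacer (IGS). Exons present in only one
#' annotation yield no pair and are returned in the `skipped` attribute.
#'
#' @param genome_a,genome_b `cp_genome` objects in the canonical frame.
#' @param ann_a,ann_b matching annotations with shared gene identifiers.
#' @param part_a optional `cp_partition` for genome_a; when given, each
#'   fragment is labelled by the region containing its midpoint
#'   (LSC/SSC/IR, with the IR copy in `ir_copy`).
#' @return data.frame of class `cp_fragments` with columns `anchor_left`,
#'   `anchor_right`, `cls` (`CDS`/`intron`/`IGS`), `gene`, `region`,
#'   `ir_copy`, `seq_a`, `seq_b`; attribute `skipped` lists unpaired
#'   anchors.
#' @export
partition_orthologous_fragments <- function(genome_a, ann_a, genome_b, ann_b,
                                            part_a = NULL) {
  ta <- exon_table(ann_a); tb <- exon_table(ann_b)
  if (is.null(ta) || is.null(tb)) stop("no protein-coding exons to anchor on")
  shared <- intersect(ta$anchor, tb$anchor)
  skipped <- c(setdiff(ta$anchor, shared), setdiff(tb$anchor, shared))
  ta2 <- ta[ta$anchor %in% shared, , drop = FALSE]
  tb2 <- tb[tb$anchor %in% shared, , drop = FALSE]
  if (!identical(ta2$anchor, tb2$anchor)) {
    bad <- ta2$anchor[which(ta2$anchor != tb2$anchor)[1]]
    stop("inconsistent exon order between genomes at anchor ", bad)
  }
  m <- nrow(ta2)
  if (m < 2L) stop("need at least two shared exon anchors")
  rows <- list()
  add <- function(al, ar, cls, gene, sa, sb, mid) {
    rows[[length(rows) + 1L]] <<- data.frame(
      anchor_left = al, anchor_right = ar, cls = cls, gene = gene,
      seq_a = sa, seq_b = sb, mid_a = mid)
  }
  na <- genome_a$length
  for (i in seq_len(m)) {
    ## the exon itself
    add(ta2$anchor[i], ta2$anchor[i], "CDS", ta2$gene[i],
        substr(genome_a$seq, ta2$start[i], ta2$end[i]),
        substr(genome_b$seq, tb2$start[i], tb2$end[i]),
        (ta2$start[i] + ta2$end[i]) %/% 2L)
    ## the gap to the next shared exon (circular at the last)
    j <- if (i < m) i + 1L else 1L
    same_gene <- ta2$gene[i] == ta2$gene[j] && ta2$copy[i] == ta2$copy[j]
    gs_a <- ta2$end[i] + 1L; gs_b <- tb2$end[i] + 1L
    len_a <- if (i < m) ta2$start[j] - gs_a
             else (ta2$start[j] - gs_a) %% na
    len_b <- if (i < m) tb2$start[j] - gs_b
             else (tb2$start[j] - gs_b) %% genome_b$length
    sa <- if (len_a > 0L) subseq_circular(genome_a, gs_a, len_a) else ""
    sb <- if (len_b > 0L) subseq_circular(genome_b, gs_b, len_b) else ""
    if (len_a > 0L || len_b > 0L) {
      add(ta2$anchor[i], ta2$anchor[j],
          if (same_gene) "intron" else "IGS",
          if (same_gene) ta2$gene[i] else NA_character_, sa, sb,
          ((gs_a + max(len_a, 1L) %/% 2L - 1L) %% na) + 1L)
    }
  }
  out <- do.call(rbind, rows)
  ## region by fragment midpoint on genome_a
  out$region <- NA_character_; out$ir_copy <- NA_character_
  if (!is.null(part_a)) {
    out$region <- vapply(out$mid_a, function(p) {
      if (circ_contains(part_a$lsc, p, na)) "LSC"
      else if (circ_contains(part_a$ssc, p, na)) "SSC"
      else "IR"
    }, character(1))
    out$ir_copy <- vapply(out$mid_a, function(p) {
      if (circ_contains(part_a$ira, p, na)) "ira"
      else if (circ_contains(part_a$irb, p, na)) "irb"
      else NA_character_
    }, character(1))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("cp_fragments", "data.frame")
  out
}

## globally align two fragments; returns equal-length gapped strings
align_fragment_pair <- function(sa, sb, params) {
  if (sa == sb) return(list(a = sa, b = sb))
  if (nchar(sa) == 0L) return(list(a = strrep("-", nchar(sb)), b = sb))
  if (nchar(sb) == 0L) return(list(a = sa, b = strrep("-", nchar(sa))))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = "global",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_ext)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Default fragment-alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_ext affine-gap alignment scores
#'   (penalties positive).
#' @return parameter list.
#' @export
aligner_params <- function(match = 1, mismatch = -1, gap_open = 5,
                           gap_ext = 1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

## column tallies for one gapped alignment: substitutions and ungapped
## comparable (both A/C/G/T) columns
alignment_column_counts <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  c(np = sum(ok & ca != cb), ungapped = sum(ok), cols = length(ca))
}

#' Region-wise nucleotide diversity over orthologous fragments
#'
#' Each fragment pair is globally aligned (affine gaps) and alignments are
#' concatenated per region and functional class. `NP` counts alignment
#' columns with two different bases; `ND` is `NP` divided by the number of
#' ungapped comparable columns (p-distance). Columns where either sequence
#' carries an IUPAC ambiguity code are excluded from both numerator and
#' denominator. `TOTAL` rows are sums of `NP` with length-weighted `ND`.
#' The IR is counted on one copy only (IRa) so that the two identical IR
#' copies are not double-counted.
#'
#' @param pairs a `cp_fragments` from [partition_orthologous_fragments()]
#'   with region labels.
#' @param params see [aligner_params()].
#' @param one_ir_copy drop IRb-copy fragments (default TRUE).
#' @return data.frame with columns `cls`, `region`, `NP`, `ND`,
#'   `aligned_len`; includes per-class `TOTAL` rows and a grand total.
#' @export
region_diversity <- function(pairs, params = aligner_params(),
                             one_ir_copy = TRUE) {
  stopifnot(inherits(pairs, "cp_fragments"))
  if (one_ir_copy) {
    pairs <- pairs[!(pairs$region %in% "IR" & pairs$ir_copy %in% "irb"), ,
                   drop = FALSE]
  }
  counts <- t(vapply(seq_len(nrow(pairs)), function(i) {
    al <- align_fragment_pair(pairs$seq_a[i], pairs$seq_b[i], params)
    alignment_column_counts(al$a, al$b)
  }, numeric(3)))
  agg_row <- function(cls, region, keep) {
    np <- sum(counts[keep, "np"]); ug <- sum(counts[keep, "ungapped"])
    data.frame(cls = cls, region = region, NP = np,
               ND = if (ug > 0) np / ug else NA_real_,
               aligned_len = sum(counts[keep, "cols"]))
  }
  regions <- c("LSC", "IR", "SSC")
  out <- list()
  for (cls in c("CDS", "intron", "IGS")) {
    for (r in regions) {
      out[[length(out) + 1L]] <-
        agg_row(cls, r, pairs$cls == cls & pairs$region %in% r)
    }
    out[[length(out) + 1L]] <- agg_row(cls, "TOTAL", pairs$cls == cls)
  }
  out[[length(out) + 1L]] <- agg_row("TOTAL", "TOTAL",
                                     rep(TRUE, nrow(pairs)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
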