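## Whole-plastome comparison of two near-identical genomes: anchored global
## alignment, variant extraction, normalisation and repeat-context profile.

## IUPAC base sets for ambiguity-aware comparison
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_compatible <- function(b1, b2) {
  s1 <- iupac_sets[[b1]]; s2 <- iupac_sets[[b2]]
  if (is.null(s1) || is.null(s2)) return(FALSE)
  length(intersect(s1, s2)) > 0L
}

## anchored global alignment of two near-identical sequences: find a k-mer
## unique to both near the middle, recurse on both sides, align leaf
## segments with an affine-gap aligner. Returns equal-length gapped strings.
anchored_align <- function(sa, sb, params, k = 64L, leaf_max = 3000L,
                           hard_max = 20000L) {
  na <- nchar(sa); nb <- nchar(sb)
  if (sa == sb) return(list(a = sa, b = sb))
  if (max(na, nb) <= leaf_max) return(align_fragment_pair(sa, sb, params))
  anchor <- find_middle_anchor(sa, sb, k)
  if (is.null(anchor)) {
    if (max(na, nb) > hard_max) {
      stop("sequences too divergent for whole-genome comparison (no shared ",
           "anchor); use the orthologous-fragment comparison instead")
    }
    return(align_fragment_pair(sa, sb, params))
  }
  left <- anchored_align(substr(sa, 1L, anchor$ia - 1L),
                         substr(sb, 1L, anchor$ib - 1L), params, k, leaf_max,
                         hard_max)
  right <- anchored_align(substr(sa, anchor$ia + k, na),
                          substr(sb, anchor$ib + k, nb), params, k, leaf_max,
                          hard_max)
  mid <- substr(sa, anchor$ia, anchor$ia + k - 1L)
  list(a = paste0(left$a, mid, right$a),
       b = paste0(left$b, mid, right$b))
}

## a k-mer near the middle of `sa` occurring exactly once in each sequence,
## with a plausible diagonal shift
find_middle_anchor <- function(sa, sb, k) {
  na <- nchar(sa); nb <- nchar(sb)
  centre <- (na - k) %/% 2L + 1L
  max_shift <- max(1000L, ceiling(0.05 * max(na, nb)))
  offs <- unique(as.integer(c(0, outer(seq_len(200L) * (k - 3L), c(1, -1)))))
  for (o in offs) {
    ia <- centre + o
    if (ia < 1L || ia + k - 1L > na) next
    kmer <- substr(sa, ia, ia + k - 1L)
    if (grepl("N", kmer, fixed = TRUE)) next
    occ_a <- gregexpr(kmer, sa, fixed = TRUE)[[1]]
    if (length(occ_a) != 1L || occ_a[1] == -1L) next
    occ_b <- gregexpr(kmer, sb, fixed = TRUE)[[1]]
    if (length(occ_b) != 1L || occ_b[1] == -1L) next
    if (abs(occ_b[1] - ia) > max_shift) next
    return(list(ia = ia, ib = as.integer(occ_b[1])))
  }
  NULL
}

#' Call variants between two near-identical plastomes
#'
#' Globally aligns the query against the reference (anchored alignment,
#' affine gaps within segments), merges adjacent gap columns into indel
#' events, converts paired insertion/deletion runs into single-base
#' substitutions, left-normalises indels against the reference, and drops
#' positions where one genome carries an IUPAC ambiguity code consistent
#' with the other genome's base. Multi-base substitutions are reported as
#' adjacent single-base substitutions.
#'
#' @param ref_genome,qry_genome `cp_genome` objects on the same canonical
#'   frame.
#' @param ann optional reference annotation; fills the `context` column.
#' @param params alignment scores for divergent segments
#'   ([aligner_params()]).
#' @param min_identity guard: error if alignment identity falls below this
#'   (default 0.95); such pairs belong in the cross-species comparison.
#' @return data.frame of class `cp_variants`: `pos` (1-based on the
#'   reference), `kind` (`substitution`/`insertion`/`deletion`),
#'   `ref_allele`, `alt_allele` (VCF-style, anchor base included for
#'   indels), `context`, `homopolymer_unit_run`. Attributes: `identity`,
#'   `n_excluded_ambiguous`.
#' @export
pairwise_variants <- function(ref_genome, qry_genome, ann = NULL,
                              params = aligner_params(),
                              min_identity = 0.95) {
  al <- anchored_align(ref_genome$seq, qry_genome$seq, params)
  ca <- seq_chars(al$a); cb <- seq_chars(al$b)
  ident <- sum(ca == cb & ca != "-") / length(ca)
  if (ident < min_identity) {
    stop(sprintf(paste0("alignment identity %.3f below %.2f: these genomes ",
                        "are not within-species near-identical; use the ",
                        "orthologous-fragment comparison instead"),
                 ident, min_identity))
  }
  refpos <- cumsum(ca != "-")      # reference coordinate per column
  state <- ifelse(ca == "-", "ins", ifelse(cb == "-", "del",
                  ifelse(ca == cb, "match", "mismatch")))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  events <- list()
  n_amb <- 0L
  i <- 1L
  while (i <= length(r$values)) {
    v <- r$values[i]
    if (v == "match") { i <- i + 1L; next }
    if (v == "mismatch") {
      for (col in starts[i]:ends[i]) {
        b1 <- ca[col]; b2 <- cb[col]
        amb <- !(b1 %in% c("A", "C", "G", "T")) ||
               !(b2 %in% c("A", "C", "G", "T"))
        if (amb && iupac_compatible(b1, b2)) { n_amb <- n_amb + 1L; next }
        events[[length(events) + 1L]] <- list(
          kind = "substitution", pos = refpos[col], ref = b1, alt = b2)
      }
      i <- i + 1L; next
    }
    ## gap run; check whether the next run is the complementary gap kind
    ## (an adjacent ins+del block is a substitution cluster)
    run_cols <- starts[i]:ends[i]
    if (i < length(r$values) && r$values[i + 1L] %in% c("ins", "del") &&
        r$values[i + 1L] != v) {
      cols2 <- starts[i + 1L]:ends[i + 1L]
      del_cols <- if (v == "del") run_cols else cols2
      ins_cols <- if (v == "ins") run_cols else cols2
      npair <- min(length(del_cols), length(ins_cols))
      for (t in seq_len(npair)) {
        events[[length(events) + 1L]] <- list(
          kind = "substitution", pos = refpos[del_cols[t]],
          ref = ca[del_cols[t]], alt = cb[ins_cols[t]])
      }
      if (length(del_cols) > npair) {
        extra <- del_cols[(npair + 1L):length(del_cols)]
        events[[length(events) + 1L]] <- list(
          kind = "deletion", pos = refpos[extra[1]],
          deleted = paste(ca[extra], collapse = ""))
      } else if (length(ins_cols) > npair) {
        extra <- ins_cols[(npair + 1L):length(ins_cols)]
        events[[length(events) + 1L]] <- list(
          kind = "insertion", pos = refpos[extra[1]],
          inserted = paste(cb[extra], collapse = ""))
      }
      i <- i + 2L; next
    }
    if (v == "del") {
      events[[length(events) + 1L]] <- list(
        kind = "deletion", pos = refpos[run_cols[1]],
        deleted = paste(ca[run_cols], collapse = ""))
    } else {
      events[[length(events) + 1L]] <- list(
        kind = "insertion", pos = refpos[run_cols[1]],
        inserted = paste(cb[run_cols], collapse = ""))
    }
    i <- i + 1L
  }
  rchars <- seq_chars(ref_genome)
  rows <- lapply(events, normalize_event, rchars = rchars)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), kind = character(0),
               ref_allele = character(0), alt_allele = character(0))
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$context <- if (!is.null(ann)) {
    vapply(seq_len(nrow(out)), function(i) {
      p <- if (out$kind[i] == "substitution") out$pos[i] else
        min(out$pos[i] + 1L, ref_genome$length)
      variant_context(p, ann)
    }, character(1))
  } else rep(NA_character_, nrow(out))
  out$homopolymer_unit_run <- homopolymer_run(out, rchars)
  attr(out, "identity") <- ident
  attr(out, "n_excluded_ambiguous") <- n_amb
  class(out) <- c("cp_variants", "data.frame")
  out
}

## left-normalise one event and emit a VCF-style row
normalize_event <- function(ev, rchars) {
  n <- length(rchars)
  if (ev$kind == "substitution") {
    return(data.frame(pos = ev$pos, kind = "substitution",
                      ref_allele = ev$ref, alt_allele = ev$alt))
  }
  if (ev$kind == "deletion") {
    seqd <- seq_chars(ev$deleted)
    p <- ev$pos                    # first deleted base
    while (p > 1L && rchars[p - 1L] == seqd[length(seqd)]) {
      seqd <- c(rchars[p - 1L], seqd[-length(seqd)])
      p <- p - 1L
    }
    anchor <- if (p > 1L) rchars[p - 1L] else rchars[p + length(seqd)]
    ## VCF convention: anchor precedes the event (or follows at genome start)
    if (p > 1L) {
      data.frame(pos = p - 1L, kind = "deletion",
                 ref_allele = paste(c(anchor, seqd), collapse = ""),
                 alt_allele = anchor)
    } else {
      data.frame(pos = 1L, kind = "deletion",
                 ref_allele = paste(c(seqd, anchor), collapse = ""),
                 alt_allele = anchor)
    }
  } else {                          # insertion before ref position ev$pos + 1
    seqi <- seq_chars(ev$inserted)
    p <- ev$pos                     # insertion occurs after ref position p
    while (p >= 1L && rchars[p] == seqi[length(seqi)]) {
      seqi <- c(seqi[length(seqi)], seqi[-length(seqi)])
      p <- p - 1L
    }
    if (p >= 1L) {
      data.frame(pos = p, kind = "insertion",
                 ref_allele = rchars[p],
                 alt_allele = paste(c(rchars[p], seqi), collapse = ""))
    } else {
      data.frame(pos = 1L, kind = "insertion",
                 ref_allele = rchars[1L],
                 alt_allele = paste(c(seqi, rchars[1L]), collapse = ""))
    }
  }
}

## context labels distinguishing tRNA/rRNA genes
variant_context <- function(pos, ann) {
  for (g in ann$genes) {
    sp <- gene_span(g)
    if (pos >= sp["start"] && pos <= sp["end"]) {
      inex <- any(pos >= g$exons[, 1] & pos <= g$exons[, 2])
      if (!inex) return(paste0("intron:", g$gene_id))
      return(switch(g$type,
                    protein_coding = paste0("gene:", g$gene_id),
                    tRNA = paste0("tRNA:", g$gene_id),
                    rRNA = paste0("rRNA:", g$gene_id)))
    }
  }
  "intergenic"
}

## homopolymer run length on the reference containing each variant; runs of
## length 1 report 0 (no repeat context)
homopolymer_run <- function(variants, rchars) {
  if (nrow(variants) == 0L) return(integer(0))
  runs <- rle(rchars)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  run_at <- function(p) {
    idx <- findInterval(p, run_start)
    runs$lengths[idx]
  }
  vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$pos[i]
    if (variants$kind[i] != "substitution") {
      p <- min(p + 1L, length(rchars))   # first changed base after the anchor
    }
    rl <- run_at(p)
    if (rl >= 2L) as.integer(rl) else 0L
  }, integer(1))
}

#' Summarise the repeat context of called variants
#'
#' @param variants a `cp_variants` data.frame.
#' @param min_run homopolymer run length counting as a repeat region
#'   (default 5).
#' @return list with totals: `n_variants`, `n_substitutions`, `n_indels`,
#'   and `n_indels_in_runs` (indels inside reference homopolymer runs of
#'   at least `min_run` bases).
#' @export
repeat_context_profile <- function(variants, min_run = 5L) {
  is_indel <- variants$kind != "substitution"
  list(n_variants = nrow(variants),
       n_substitutions = sum(!is_indel),
       n_indels = sum(is_indel),
       n_indels_in_runs = sum(is_indel &
                                variants$homopolymer_unit_run >= min_run))
}

#' Write variants as minimal VCF 4.2
#'
#' @param variants a `cp_variants`.
#' @param ref_genome the reference `cp_genome` (for the header).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, ref_genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", ref_genome$id,
                       ref_genome$length),
               "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Genomic context\">",
               "##INFO=<ID=HPRUN,Number=1,Type=Integer,Description=\"Homopolymer run length\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    info <- sprintf("CONTEXT=%s;HPRUN=%d",
                    ifelse(is.na(variants$context[i]), ".",
                           variants$context[i]),
                    variants$homopolymer_unit_run[i])
    writeLines(paste(ref_genome$id, variants$pos[i], ".",
                     variants$ref_allele[i], variants$alt_allele[i],
                     ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}
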