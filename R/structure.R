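## Quadripartite structure: inverted-repeat detection, canonical rotation,
## IR-junction (pseudogene-fragment) reporting.

#' Construct a quadripartite partition
#'
#' Coordinates are 1-based inclusive on the circle; an interval with
#' `start > end` wraps the origin. On the canonical rotation the regions
#' tile `[1, n]` in the order LSC, IRa, SSC, IRb.
#'
#' @param lsc,ira,ssc,irb length-2 integer vectors `(start, end)`.
#' @param genome_length circle length in bases.
#' @return object of class `cp_partition`.
#' @export
quadripartite_partition <- function(lsc, ira, ssc, irb, genome_length) {
  iv <- function(v) {
    v <- as.integer(v); stopifnot(length(v) == 2L); v
  }
  lsc <- iv(lsc); ira <- iv(ira); ssc <- iv(ssc); irb <- iv(irb)
  n <- as.integer(genome_length)
  ilen <- function(v) ((v[2] - v[1]) %% n) + 1L
  if (ilen(ira) != ilen(irb)) stop("IR copies differ in length")
  if (ilen(lsc) + ilen(ssc) + 2L * ilen(ira) != n) {
    stop("partition does not tile the circle: ",
         ilen(lsc), "+", ilen(ssc), "+2*", ilen(ira), " != ", n)
  }
  if (ilen(lsc) <= ilen(ssc)) stop("LSC must be longer than SSC")
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 ir_len = ilen(ira), genome_length = n),
            class = "cp_partition")
}

#' @export
print.cp_partition <- function(x, ...) {
  n <- x$genome_length
  rl <- function(v) ((v[2] - v[1]) %% n) + 1L
  cat(sprintf(paste0("<cp_partition> genome %s bp\n",
                     "  LSC %d..%d (%s bp)\n  IRa %d..%d (%s bp)\n",
                     "  SSC %d..%d (%s bp)\n  IRb %d..%d (%s bp)\n"),
              format(n, big.mark = ","),
              x$lsc[1], x$lsc[2], format(rl(x$lsc), big.mark = ","),
              x$ira[1], x$ira[2], format(rl(x$ira), big.mark = ","),
              x$ssc[1], x$ssc[2], format(rl(x$ssc), big.mark = ","),
              x$irb[1], x$irb[2], format(rl(x$irb), big.mark = ",")))
  invisible(x)
}

region_length <- function(part, region) {
  v <- part[[region]]
  ((v[2] - v[1]) %% part$genome_length) + 1L
}

## circular-interval helpers ------------------------------------------------

## does circular interval (s,e) contain pos?
circ_contains <- function(interval, pos, n) {
  s <- interval[1]; e <- interval[2]
  if (s <= e) pos >= s & pos <= e else pos >= s | pos <= e
}

## split a circular interval into linear pieces
circ_pieces <- function(interval, n) {
  s <- interval[1]; e <- interval[2]
  if (s <= e) list(c(s, e)) else list(c(s, n), c(1L, e))
}

## overlap length of two circular intervals on a circle of length n
circ_intersect_len <- function(a, b, n) {
  tot <- 0L
  for (pa in circ_pieces(a, n)) {
    for (pb in circ_pieces(b, n)) {
      tot <- tot + max(0L, min(pa[2], pb[2]) - max(pa[1], pb[1]) + 1L)
    }
  }
  tot
}

## detection ---------------------------------------------------------------

#' Detect the quadripartite structure of a plastid genome
#'
#' Finds the maximal-length pair of exact inverted repeats (length >=
#' `min_ir_len`) whose two copies partition the circle into four arcs; the
#' longer single-copy arc is labelled LSC, the shorter SSC. Detection is
#' seed-and-extend: exact k-mer seeds between the genome and its reverse
#' complement are grouped by anti-diagonal and each group is extended
#' maximally in both directions.
#'
#' @param genome a `cp_genome` (circular).
#' @param min_ir_len minimum IR length to report (default 1000; must be
#'   >= 100).
#' @return a [quadripartite_partition()] in the input coordinate frame.
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 1000L) {
  stopifnot(inherits(genome, "cp_genome"), genome$circular)
  min_ir_len <- as.integer(min_ir_len)
  if (min_ir_len < 100L) stop("min_ir_len must be >= 100")
  n <- genome$length
  if (n < 4L * min_ir_len / 2L + 2L || n < 2L * min_ir_len + 2L) {
    stop("no quadripartite structure: genome too short for IR >= ",
         min_ir_len)
  }
  k <- min(min_ir_len, 32L)
  s2 <- paste0(genome$seq, substr(genome$seq, 1L, k - 1L))
  kmer_f <- substring(s2, seq_len(n), seq_len(n) + k - 1L)
  rc2 <- revcomp(s2)
  L2 <- nchar(s2)
  kmer_rc <- substring(rc2, L2 - seq_len(n) - k + 2L, L2 - seq_len(n) + 1L)
  ## all (i, j) with forward k-mer at i equal to the reverse complement of
  ## the k-mer at j; group by anti-diagonal (i + j) mod n
  fac <- factor(kmer_f)
  rc_idx <- split(seq_len(n), factor(kmer_rc, levels = levels(fac)))
  f_idx <- split(seq_len(n), fac)
  keys <- names(f_idx)[lengths(rc_idx[names(f_idx)]) > 0L]
  if (length(keys) == 0L) {
    stop("no quadripartite structure: no inverted repeat >= ", min_ir_len)
  }
  pi <- pj <- vector("list", length(keys))
  for (q in seq_along(keys)) {
    ii <- f_idx[[keys[q]]]; jj <- rc_idx[[keys[q]]]
    g <- expand.grid(i = ii, j = jj)
    pi[[q]] <- g$i; pj[[q]] <- g$j
  }
  i <- unlist(pi, use.names = FALSE); j <- unlist(pj, use.names = FALSE)
  keep <- i <= j
  i <- i[keep]; j <- j[keep]
  D <- (i + j) %% n
  reps <- !duplicated(D)
  x <- seq_chars(genome)
  cx <- comp_chars(x)
  midx <- function(v) ((v - 1L) %% n) + 1L
  ## vectorised run of matches x[startA + dirA*t] == comp(x[startB + dirB*t])
  run_len <- function(startA, dirA, startB, dirB, cap) {
    if (cap <= 0L) return(0L)
    t <- 0:(cap - 1L)
    m <- x[midx(startA + dirA * t)] == cx[midx(startB + dirB * t)]
    if (all(m)) cap else which(!m)[1] - 1L
  }
  cands <- list()
  for (r in which(reps)) {
    a <- i[r]; b <- j[r]
    aend <- a + k - 1L; bend <- b + k - 1L           # may exceed n (wrap)
    ## skip seeds whose arms overlap on the circle
    if (circ_intersect_len(midx(c(a, aend)), midx(c(b, bend)), n) > 0L) next
    gap1 <- (a - 1L - bend) %% n      # bases strictly between B-end and A-start
    gap2 <- (b - 1L - aend) %% n      # bases strictly between A-end and B-start
    e1 <- run_len(a - 1L, -1L, bend + 1L, +1L, (gap1 - 1L) %/% 2L)
    e2 <- run_len(aend + 1L, +1L, b - 1L, -1L, (gap2 - 1L) %/% 2L)
    Lir <- k + e1 + e2
    if (Lir < min_ir_len) next
    cands[[length(cands) + 1L]] <-
      c(startA = midx(a - e1), startB = midx(b - e2), len = Lir)
  }
  if (length(cands) == 0L) {
    stop("no quadripartite structure: no inverted repeat >= ", min_ir_len)
  }
  cm <- do.call(rbind, cands)
  ## canonical key: unordered pair of start positions + length
  key <- apply(cm, 1L, function(r) {
    paste(sort(c(r["startA"], r["startB"])), r["len"], collapse = "_")
  })
  cm <- cm[!duplicated(key), , drop = FALSE]
  best <- cm[cm[, "len"] == max(cm[, "len"]), , drop = FALSE]
  if (nrow(best) > 1L) {
    stop("ambiguous quadripartite structure: multiple maximal inverted ",
         "repeats of length ", best[1, "len"], " at starts ",
         paste(apply(best, 1L, function(r)
       sprintf("(%d,%d)", r["startA"], r["startB"])), collapse = ", "))
  }
  a <- best[1, "startA"]; b <- best[1, "startB"]; Lir <- best[1, "len"]
  aend <- midx(a + Lir - 1L); bend <- midx(b + Lir - 1L)
  gap_after_A <- c(midx(aend + 1L), midx(b - 1L))   # between arm A and arm B
  gap_after_B <- c(midx(bend + 1L), midx(a - 1L))
  glen <- function(v) ((v[2] - v[1]) %% n) + 1L
  if ((b - 1L - aend) %% n == 0L || (a - 1L - bend) %% n == 0L) {
    stop("no quadripartite structure: inverted repeat copies are adjacent")
  }
  if (glen(gap_after_A) >= glen(gap_after_B)) {
    lsc <- gap_after_A; ssc <- gap_after_B
    ira <- c(midx(b), bend); irb <- c(midx(a), aend)
  } else {
    lsc <- gap_after_B; ssc <- gap_after_A
    ira <- c(midx(a), aend); irb <- c(midx(b), bend)
  }
  quadripartite_partition(lsc, ira, ssc, irb, n)
}

#' Validate a partition against its genome
#'
#' Checks the tiling invariant and that IRb is exactly the reverse
#' complement of IRa.
#'
#' @param genome a `cp_genome`.
#' @param part a `cp_partition`.
#' @return TRUE invisibly, or an error.
#' @export
validate_partition <- function(genome, part) {
  n <- genome$length
  stopifnot(part$genome_length == n)
  ira_seq <- subseq_circular(genome, part$ira[1], part$ir_len)
  irb_seq <- subseq_circular(genome, part$irb[1], part$ir_len)
  if (revcomp(ira_seq) != irb_seq) {
    stop("IRb is not the reverse complement of IRa")
  }
  covered <- region_length(part, "lsc") + region_length(part, "ssc") +
    2L * part$ir_len
  if (covered != n) stop("partition does not tile the circle")
  invisible(TRUE)
}

## canonical rotation -------------------------------------------------------

## rotate a 1-based circular coordinate: new origin at position `origin`
rotate_pos <- function(pos, origin, n) ((pos - origin) %% n) + 1L
## flip (reverse-complement) a coordinate
flip_pos <- function(pos, n) n - pos + 1L

transform_annotation <- function(ann, n, flip = FALSE, origin = 1L) {
  if (is.null(ann)) return(NULL)
  genes <- lapply(ann$genes, function(g) {
    ex <- g$exons
    strand <- g$strand
    if (flip) {
      ex <- cbind(flip_pos(ex[, 2], n), flip_pos(ex[, 1], n))
      strand <- if (strand == "+") "-" else "+"
    }
    ex <- cbind(rotate_pos(ex[, 1], origin, n), rotate_pos(ex[, 2], origin, n))
    gene_model(g$gene_id, g$type, strand, ex, g$copy_tag)
  })
  annotation(ann$genome_id, genes)
}

#' Canonically rotate (and orient) a genome given its partition
#'
#' Rotates (and reverse-complements if required) the genome so that base 1
#' is the first LSC base and the region order is LSC, IRa, SSC, IRb. The
#' canonical strand is the one on which a `psbA`-like gene (first
#' protein-coding LSC gene named `psbA*`) lies on the plus strand when an
#' annotation is supplied; otherwise the strand giving the
#' lexicographically smaller LSC sequence.
#'
#' @param genome a `cp_genome`.
#' @param part its [quadripartite_partition()] (same coordinate frame).
#' @param ann optional `cp_annotation` in the same frame; returned
#'   transformed to the canonical frame.
#' @return list with `genome`, `partition`, `annotation` (NULL if not
#'   given), and `flipped` (logical).
#' @export
canonicalize <- function(genome, part, ann = NULL) {
  n <- genome$length
  ## candidate 1: forward strand, origin at LSC start
  fwd <- list(genome = rotate_genome(genome, part$lsc[1]), flip = FALSE,
              origin = part$lsc[1])
  ## candidate 2: flipped strand. After reverse-complementing, the old LSC
  ## maps to [n - e + 1, n - s + 1] and the IR copies swap roles.
  flip_lsc_start <- flip_pos(part$lsc[2], n)
  gflip <- genome; gflip$seq <- revcomp(genome$seq)
  rev_ <- list(genome = rotate_genome(gflip, flip_lsc_start), flip = TRUE,
               origin = flip_lsc_start)
  lsc_len <- region_length(part, "lsc")
  pick_fwd <- NA
  if (!is.null(ann)) {
    psba <- Filter(function(g) {
      grepl("^psbA", g$gene_id, ignore.case = TRUE) &&
        g$type == "protein_coding" &&
        circ_contains(part$lsc, gene_span(g)["start"], n)
    }, ann$genes)
    if (length(psba) > 0L) pick_fwd <- psba[[1]]$strand == "+"
  }
  if (is.na(pick_fwd)) {
    lsc_fwd <- substr(fwd$genome$seq, 1L, lsc_len)
    lsc_rev <- substr(rev_$genome$seq, 1L, lsc_len)
    pick_fwd <- lsc_fwd <= lsc_rev
  }
  ch <- if (pick_fwd) fwd else rev_
  canon_part <- quadripartite_partition(
    lsc = c(1L, lsc_len),
    ira = c(lsc_len + 1L, lsc_len + part$ir_len),
    ssc = c(lsc_len + part$ir_len + 1L,
            n - part$ir_len),
    irb = c(n - part$ir_len + 1L, n),
    genome_length = n)
  validate_partition(ch$genome, canon_part)
  list(genome = ch$genome, partition = canon_part,
       annotation = transform_annotation(ann, n, ch$flip, ch$origin),
       flipped = ch$flip)
}

## junction report ----------------------------------------------------------

#' Report genes at the four region boundaries
#'
#' For each boundary (LSC/IRa, IRa/SSC, SSC/IRb, IRb/LSC) reports the gene
#' crossing (or, failing that, nearest within `window` of) the boundary,
#' and the length of the gene's overlap with the adjacent inverted-repeat
#' copy — the pseudogene (psi) fragment length for junction-spanning genes.
#'
#' @param part a canonical-frame `cp_partition`.
#' @param ann a `cp_annotation` on the same frame.
#' @param window search window in bases around each boundary (default 1000).
#' @return data.frame with columns `boundary`, `gene_id`, `copy_tag`,
#'   `crosses` (logical) and `psi_len` (bases of gene inside the adjacent
#'   IR); genes absent within the window give an `NA` row.
#' @export
junction_report <- function(part, ann, window = 1000L) {
  n <- part$genome_length
  bounds <- list(
    "LSC/IRa" = list(left = part$lsc[2], ir = part$ira),
    "IRa/SSC" = list(left = part$ira[2], ir = part$ira),
    "SSC/IRb" = list(left = part$ssc[2], ir = part$irb),
    "IRb/LSC" = list(left = part$irb[2], ir = part$irb)
  )
  rows <- lapply(names(bounds), function(bn) {
    b <- bounds[[bn]]
    p <- b$left; p1 <- (p %% n) + 1L
    spans <- lapply(ann$genes, gene_span)
    crosses <- vapply(seq_along(ann$genes), function(gi) {
      sp <- c(spans[[gi]]["start"], spans[[gi]]["end"])
      circ_contains(sp, p, n) && circ_contains(sp, p1, n)
    }, logical(1))
    win_iv <- c(((p - window) %% n) + 1L, ((p + window - 1L) %% n) + 1L)
    near <- vapply(seq_along(ann$genes), function(gi) {
      sp <- c(spans[[gi]]["start"], spans[[gi]]["end"])
      circ_intersect_len(sp, win_iv, n) > 0L
    }, logical(1))
    pick <- if (any(crosses)) which(crosses)[1]
            else if (any(near)) which(near)[1] else NA_integer_
    if (is.na(pick)) {
      data.frame(boundary = bn, gene_id = NA_character_,
                 copy_tag = NA_character_, crosses = FALSE, psi_len = 0L)
    } else {
      g <- ann$genes[[pick]]
      sp <- gene_span(g)
      psi <- circ_intersect_len(c(sp["start"], sp["end"]), b$ir, n)
      data.frame(boundary = bn, gene_id = g$gene_id, copy_tag = g$copy_tag,
                 crosses = crosses[pick], psi_len = psi)
    }
  })
  do.call(rbind, rows)
}
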