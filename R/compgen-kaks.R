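## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, CDS extraction,
## and codon usage.

.kaks_cache <- new.env(parent = emptyenv())

get_code <- function(genetic_code = "11") {
  key <- paste0("code_", genetic_code)
  if (is.null(.kaks_cache[[key]])) {
    .kaks_cache[[key]] <- Biostrings::getGeneticCode(genetic_code)
  }
  .kaks_cache[[key]]
}

## fraction of synonymous one-step changes per codon position, summed over
## the 3 positions; changes creating a stop codon count as nonsynonymous so
## that syn + nonsyn sites == 3 per codon
codon_syn_sites <- function(codon, code) {
  key <- paste0("sites_", codon)
  hit <- .kaks_cache[[key]]
  if (!is.null(hit)) return(hit)
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  cc <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(bases, cc[p])) {
      alt <- cc; alt[p] <- b
      alt_aa <- code[[paste(alt, collapse = "")]]
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  .kaks_cache[[key]] <- s
  s
}

## average (syn, nonsyn) substitution counts between two codons over all
## minimal mutational pathways; pathways passing through an intermediate
## stop codon are excluded (all pathways kept if every one is excluded)
codon_pair_subs <- function(c1, c2, code) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0("subs_", c1, "_", c2)
  hit <- .kaks_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffpos <- which(a != b)
  perms <- switch(as.character(length(diffpos)),
                  "1" = list(diffpos),
                  "2" = list(diffpos, rev(diffpos)),
                  "3" = {
                    p <- diffpos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  path_counts <- function(order) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) return(NULL)  # intermediate stop
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- lapply(perms, path_counts)
  ok <- counts[!vapply(counts, is.null, logical(1))]
  if (length(ok) == 0L) {
    ok <- lapply(perms, function(o) {   # fall back: keep stop-passing paths
      cur <- a; sd <- 0; nd <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- b[p]
        if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  res <- colMeans(do.call(rbind, ok))
  .kaks_cache[[key]] <- res
  res
}

split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) log(1 - 4p/3)`; returns `NA` when `p >= 0.75` (saturation).
#'
#' @param p proportion of sites differing.
#' @return corrected distance.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Synonymous/nonsynonymous site counts are averaged over both sequences;
#' substitution counts per differing codon pair are averaged over all
#' minimal mutational pathways with equal weights; the Jukes-Cantor
#' correction is applied separately to the synonymous and nonsynonymous
#' proportions. The p-value is a two-tailed z-test of Ka == Ks with the
#' large-sample NG86 variance.
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame coding sequences
#'   (A/C/G/T only, length divisible by 3, no internal stop codons; a
#'   shared terminal stop codon is dropped).
#' @param genetic_code NCBI genetic-code id; default `"11"`
#'   (bacterial/plastid).
#' @return object of class `kaks_result`: list with `Ka`, `Ks`, `ratio`
#'   (NA when `Ks == 0`), `p_value`, `Na`, `Ns` (nonsynonymous/synonymous
#'   substitution counts), `Sa`, `Ss` (nonsynonymous/synonymous site
#'   counts) and `n_codons`.
#' @export
ng86_kaks <- function(cds_a, cds_b, genetic_code = "11") {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("kaks_length_mismatch: sequences differ in length (",
         nchar(cds_a), " vs ", nchar(cds_b), ")")
  }
  if (nchar(cds_a) %% 3L != 0L) {
    stop("kaks_frame_violation: length not divisible by 3")
  }
  if (grepl("[^ACGT]", cds_a) || grepl("[^ACGT]", cds_b)) {
    stop("kaks_invalid_base: sequences must be gap-free A/C/G/T")
  }
  code <- get_code(genetic_code)
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  aa_a <- unname(code[ca]); aa_b <- unname(code[cb])
  nc <- length(ca)
  if (nc > 1L && aa_a[nc] == "*" && aa_b[nc] == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]
    aa_a <- aa_a[-nc]; aa_b <- aa_b[-nc]
    nc <- nc - 1L
  }
  if (any(aa_a == "*") || any(aa_b == "*")) {
    stop("kaks_internal_stop: internal stop codon at codon ",
         which(aa_a == "*" | aa_b == "*")[1])
  }
  S_a <- sum(vapply(ca, codon_syn_sites, numeric(1), code = code))
  S_b <- sum(vapply(cb, codon_syn_sites, numeric(1), code = code))
  Ss <- (S_a + S_b) / 2
  Sa <- 3 * nc - Ss
  diffs <- which(ca != cb)
  Sd <- 0; Nd <- 0
  for (i in diffs) {
    cnt <- codon_pair_subs(ca[i], cb[i], code)
    Sd <- Sd + cnt[["sd"]]; Nd <- Nd + cnt[["nd"]]
  }
  pS <- if (Ss > 0) Sd / Ss else 0
  pN <- if (Sa > 0) Nd / Sa else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  var_d <- function(p, sites) {
    if (sites <= 0 || is.na(p) || p >= 0.75) return(NA_real_)
    9 * p * (1 - p) / ((3 - 4 * p)^2 * sites)
  }
  vKs <- var_d(pS, Ss); vKa <- var_d(pN, Sa)
  if (Sd + Nd == 0 || is.na(Ka) || is.na(Ks) || (vKa + vKs) <= 0) {
    z <- NA_real_; pv <- NA_real_
  } else {
    z <- (Ka - Ks) / sqrt(vKa + vKs)
    pv <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(Ka = Ka, Ks = Ks,
                 ratio = if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks
                         else NA_real_,
                 p_value = pv, z = z,
                 Na = unname(Nd), Ns = unname(Sd),
                 Sa = Sa, Ss = Ss, n_codons = nc),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %d codons: Ka=%.4g Ks=%.4g Ka/Ks=%s (p=%.3g)\n",
              x$n_codons, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio),
              x$p_value))
  invisible(x)
}

#' Extract the mRNA-sense CDS of a gene
#'
#' Exon sequences are concatenated in ascending genome order and
#' reverse-complemented for minus-strand genes, yielding the coding
#' sequence in transcription order.
#'
#' @param genome a `cp_genome`.
#' @param gene a `cp_gene`.
#' @return nucleotide string.
#' @export
extract_cds <- function(genome, gene) {
  pieces <- vapply(seq_len(nrow(gene$exons)), function(i) {
    s <- gene$exons[i, 1]; e <- gene$exons[i, 2]
    len <- if (s <= e) e - s + 1L else genome$length - s + 1L + e
    subseq_circular(genome, s, len)
  }, character(1))
  cds <- paste(pieces, collapse = "")
  if (gene$strand == "-") cds <- revcomp(cds)
  cds
}

#' Per-gene Ka/Ks table between two annotated genomes
#'
#' One row per protein-coding gene shared by both annotations (first copy
#' of inverted-repeat duplicates). Genes whose extracted CDSs differ in
#' length, violate frame, or contain internal stops are flagged and
#' skipped, not fatal. Identical orthologs give `Ka = Ks = 0` and ratio
#' `NA`.
#'
#' @param genome_a,genome_b `cp_genome` objects.
#' @param ann_a,ann_b matching `cp_annotation` objects.
#' @param genetic_code NCBI genetic-code id (default `"11"`).
#' @return data.frame with columns `gene`, `n_codons`, `Na`, `Ns`, `Sa`,
#'   `Ss`, `Ka`, `Ks`, `ratio`, `p_value`, `note`.
#' @export
gene_kaks_table <- function(genome_a, ann_a, genome_b, ann_b,
                            genetic_code = "11") {
  first_copy <- function(ann) {
    ids <- vapply(ann$genes, `[[`, character(1), "gene_id")
    types <- vapply(ann$genes, `[[`, character(1), "type")
    keep <- types == "protein_coding" & !duplicated(ids)
    stats::setNames(ann$genes[keep],
                    ids[keep])
  }
  ga <- first_copy(ann_a); gb <- first_copy(ann_b)
  shared <- intersect(names(ga), names(gb))
  rows <- lapply(shared, function(id) {
    base <- data.frame(gene = id, n_codons = NA_integer_, Na = NA_real_,
                       Ns = NA_real_, Sa = NA_real_, Ss = NA_real_,
                       Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                       p_value = NA_real_, note = "")
    cds_a <- extract_cds(genome_a, ga[[id]])
    cds_b <- extract_cds(genome_b, gb[[id]])
    res <- tryCatch(ng86_kaks(cds_a, cds_b, genetic_code),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      base$note <- sub(":.*$", "", res)
      return(base)
    }
    base[c("n_codons", "Na", "Ns", "Sa", "Ss", "Ka", "Ks", "ratio",
           "p_value")] <-
      res[c("n_codons", "Na", "Ns", "Sa", "Ss", "Ka", "Ks", "ratio",
            "p_value")]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Codon usage over all protein-coding genes
#'
#' Counts codons across every protein-coding gene model (inverted-repeat
#' duplicates counted per copy), strand-corrected. Genes whose CDS length
#' is not divisible by 3 are excluded with a warning.
#'
#' @param genome a `cp_genome`.
#' @param ann a `cp_annotation`.
#' @param genetic_code NCBI genetic-code id (default `"11"`).
#' @return data.frame with columns `codon`, `aa`, `count`; the `total`
#'   attribute holds the summed codon count.
#' @export
codon_usage <- function(genome, ann, genetic_code = "11") {
  code <- get_code(genetic_code)
  all_codons <- character(0)
  for (g in ann$genes) {
    if (g$type != "protein_coding") next
    cds <- extract_cds(genome, g)
    if (nchar(cds) %% 3L != 0L) {
      warning("gene ", g$gene_id, ": CDS length not divisible by 3; excluded")
      next
    }
    all_codons <- c(all_codons, split_codons(cds))
  }
  total <- length(all_codons)
  tab <- table(all_codons)
  out <- data.frame(codon = names(tab), count = as.integer(tab))
  out$aa <- ifelse(out$codon %in% names(code), unname(code[out$codon]),
                   NA_character_)
  out <- out[order(out$codon), c("codon", "aa", "count")]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
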