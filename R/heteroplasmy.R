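## Minor-allele (heteroplasmy) site calling from pileups, site
## classification, per-strain summaries and cross-strain overlap.

#' Call minor-allele sites from a pileup
#'
#' A site is reported when its depth reaches `depth_min` and the
#' second-most-frequent allele has frequency at least `maf_min`
#' (inclusive). Ties for the major allele are broken lexicographically, as
#' are ties among candidate minor alleles. Indel minor alleles (`+SEQ` /
#' `-SEQ`) additionally require a read count of at least
#' `indel_depth_min`. Columns with depth 0 are skipped with a warning.
#'
#' @param pp a `cp_pileup` (assumed deduplicated and base-quality filtered
#'   upstream).
#' @param maf_min minor-allele frequency threshold (default 0.05).
#' @param depth_min minimum site depth (default 10).
#' @param indel_depth_min minimum read count for indel minor alleles
#'   (default 5).
#' @param strain strain label attached to every site.
#' @return data.frame of class `cp_sites`: `pos`, `major_allele`,
#'   `minor_allele`, `maf`, `depth`, `strain`, `var_type`, plus
#'   classification columns (`ts_tv`, `region`, `context`,
#'   `coding_effect`) filled by [classify_sites()].
#' @export
call_minor_alleles <- function(pp, maf_min = 0.05, depth_min = 10L,
                               indel_depth_min = 5L, strain = "strain") {
  stopifnot(inherits(pp, "cp_pileup"))
  if (maf_min <= 0 || maf_min > 0.5) stop("maf_min must be in (0, 0.5]")
  rows <- vector("list", nrow(pp))
  for (i in seq_len(nrow(pp))) {
    depth <- pp$depth[i]
    if (depth == 0L) {
      warning("pileup column at pos ", pp$pos[i], " has depth 0; skipped")
      next
    }
    cts <- pp$counts[[i]]
    if (length(cts) < 2L) next
    ## order by count desc, allele string asc (deterministic tie-break)
    ord <- order(-cts, names(cts))
    major <- names(cts)[ord[1]]
    minor <- names(cts)[ord[2]]
    mcount <- cts[[ord[2]]]
    maf <- mcount / depth
    if (depth < depth_min || maf < maf_min) next
    is_indel <- substr(minor, 1L, 1L) %in% c("+", "-")
    if (is_indel && mcount < indel_depth_min) next
    rows[[i]] <- data.frame(
      pos = pp$pos[i], major_allele = major, minor_allele = minor,
      maf = maf, depth = depth, strain = strain,
      var_type = if (substr(minor, 1L, 1L) == "+") "insertion"
                 else if (substr(minor, 1L, 1L) == "-") "deletion"
                 else "substitution")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), major_allele = character(0),
               minor_allele = character(0), maf = numeric(0),
               depth = integer(0), strain = character(0),
               var_type = character(0))
  out$ts_tv <- rep(NA_character_, nrow(out))
  out$region <- rep(NA_character_, nrow(out))
  out$context <- rep(NA_character_, nrow(out))
  out$coding_effect <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cp_sites", "data.frame")
  out
}

#' Classify minor-allele sites
#'
#' Fills `ts_tv` (transition when both alleles are purines or both
#' pyrimidines; transversion otherwise; substitutions only), `region`
#' (LSC/IRa/SSC/IRb from the partition), `context` (`CDS:<gene>`,
#' `intron:<gene>`, `tRNA:<id>`, `rRNA:<id>`, `intergenic`) and, for
#' substitutions in protein-coding exons, `coding_effect`
#' (synonymous/nonsynonymous) by substituting the minor allele into its
#' codon — strand-corrected and exon-aware — and translating with the
#' bacterial/plastid genetic code.
#'
#' @param sites a `cp_sites` data.frame.
#' @param ann a `cp_annotation` on the canonical frame.
#' @param part the `cp_partition` on the same frame.
#' @param genome the reference `cp_genome`.
#' @param genetic_code NCBI genetic-code id (default `"11"`).
#' @return `sites` with classification columns filled.
#' @export
classify_sites <- function(sites, ann, part, genome, genetic_code = "11") {
  if (nrow(sites) == 0L) return(sites)
  code <- get_code(genetic_code)
  n <- part$genome_length
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    sites$region[i] <-
      if (circ_contains(part$lsc, p, n)) "LSC"
      else if (circ_contains(part$ira, p, n)) "IRa"
      else if (circ_contains(part$ssc, p, n)) "SSC"
      else "IRb"
    if (sites$var_type[i] == "substitution") {
      pair <- c(sites$major_allele[i], sites$minor_allele[i])
      sites$ts_tv[i] <-
        if (all(pair %in% purines) || all(pair %in% pyrimidines))
          "transition" else "transversion"
    }
    ctx <- site_context(p, ann)
    sites$context[i] <- ctx$label
    if (!is.null(ctx$gene) && ctx$gene$type == "protein_coding" &&
        ctx$exonic && sites$var_type[i] == "substitution") {
      sites$coding_effect[i] <- coding_effect(
        p, sites$minor_allele[i], ctx$gene, genome, code)
    }
  }
  sites
}

## context of one position: label plus the gene hit (if any)
site_context <- function(pos, ann) {
  for (g in ann$genes) {
    sp <- gene_span(g)
    if (pos >= sp["start"] && pos <= sp["end"]) {
      exonic <- any(pos >= g$exons[, 1] & pos <= g$exons[, 2])
      label <- if (!exonic) paste0("intron:", g$gene_id)
               else switch(g$type,
                           protein_coding = paste0("CDS:", g$gene_id),
                           tRNA = paste0("tRNA:", g$gene_id),
                           rRNA = paste0("rRNA:", g$gene_id))
      return(list(label = label, gene = g, exonic = exonic))
    }
  }
  list(label = "intergenic", gene = NULL, exonic = FALSE)
}

## synonymous/nonsynonymous effect of substituting `alt` at genome position
## `pos` inside protein-coding gene `g`
coding_effect <- function(pos, alt, g, genome, code) {
  if (!alt %in% c("A", "C", "G", "T")) return(NA_character_)
  cds <- extract_cds(genome, g)
  ## index of `pos` within the mRNA-sense CDS
  exlens <- g$exons[, 2] - g$exons[, 1] + 1L
  hit <- which(pos >= g$exons[, 1] & pos <= g$exons[, 2])
  if (length(hit) == 0L) return(NA_character_)
  off_plus <- sum(exlens[seq_len(hit - 1L)]) + (pos - g$exons[hit, 1] + 1L)
  idx <- if (g$strand == "+") off_plus else sum(exlens) - off_plus + 1L
  alt_base <- if (g$strand == "+") alt else comp_chars(alt)
  ci <- (idx - 1L) %/% 3L + 1L
  if (3L * ci > nchar(cds)) return(NA_character_)
  codon <- substr(cds, 3L * ci - 2L, 3L * ci)
  if (grepl("[^ACGT]", codon)) {
    warning("codon containing ambiguous base at pos ", pos)
    return(NA_character_)
  }
  within <- idx - (3L * ci - 3L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_base
  if (code[[codon]] == code[[alt_codon]]) "synonymous" else "nonsynonymous"
}

## display rounding: half-up to `digits` decimals
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-strain summary of minor-allele sites
#'
#' @param sites a `cp_sites` for one strain.
#' @param genome_length reference genome length in bases.
#' @return list with `strain`, `n_sites`, `density_per_kb` (sites per kb,
#'   rounded half-up to 2 decimals for display) and `breakdowns` (tables
#'   by region, variant type, transition/transversion pair and coding
#'   effect).
#' @export
strain_summary <- function(sites, genome_length) {
  strain <- if (nrow(sites)) sites$strain[1] else NA_character_
  n <- nrow(sites)
  list(strain = strain, n_sites = n,
       density_per_kb = round_half_up(n / (genome_length / 1000), 2L),
       breakdowns = list(
         region = table(sites$region),
         var_type = table(sites$var_type),
         ts_tv = table(paste(pmin(sites$major_allele, sites$minor_allele),
                             pmax(sites$major_allele, sites$minor_allele),
                             sep = "-")[sites$var_type == "substitution"]),
         coding_effect = table(sites$coding_effect)))
}

site_keys <- function(sites) paste(sites$pos, sites$minor_allele, sep = ":")

#' Overlap analysis of minor-allele sites across strains
#'
#' Sites are keyed by (position, minor allele). Returns the count of every
#' non-empty strain subset (Venn cells, exact membership) and the
#' strain-exclusive sites usable as markers.
#'
#' @param site_lists named list of `cp_sites`, one per strain (at least
#'   two).
#' @return list with `venn` (named integer vector; names are
#'   `&`-separated strain subsets), `exclusive` (named list of site keys
#'   private to each strain) and `shared_all` (count of sites present in
#'   every strain).
#' @export
overlap_analysis <- function(site_lists) {
  if (length(site_lists) < 2L) stop("need at least two strains")
  strains <- names(site_lists)
  if (is.null(strains) || any(!nzchar(strains))) {
    stop("site_lists must be a named list")
  }
  keys <- lapply(site_lists, site_keys)
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(row)
    paste(strains[row], collapse = "&"))
  venn <- table(pattern)
  venn <- stats::setNames(as.integer(venn), names(venn))
  exclusive <- lapply(strains, function(s) {
    universe[pattern == s]
  })
  names(exclusive) <- strains
  list(venn = venn, exclusive = exclusive,
       shared_all = sum(pattern == paste(strains, collapse = "&")))
}

#' Collapse inverted-repeat site pairs onto the IRa copy
#'
#' The two IR copies carry mirrored evidence for the same biological site;
#' this helper maps IRb positions onto their IRa mirror (complementing
#' base alleles) and deduplicates, so IR sites are counted once.
#'
#' @param sites a `cp_sites` with `region` filled.
#' @param part the `cp_partition`.
#' @return `cp_sites` with IRb rows remapped and duplicates removed.
#' @export
collapse_ir_pairs <- function(sites, part) {
  if (nrow(sites) == 0L) return(sites)
  irb <- which(sites$region == "IRb")
  for (i in irb) {
    mirrored <- part$ira[1] + (part$irb[2] - sites$pos[i])
    sites$pos[i] <- mirrored
    sites$region[i] <- "IRa"
    for (col in c("major_allele", "minor_allele")) {
      al <- sites[[col]][i]
      if (al %in% c("A", "C", "G", "T")) {
        sites[[col]][i] <- comp_chars(al)
      }
    }
  }
  dup <- duplicated(paste(sites$pos, sites$minor_allele, sites$strain))
  out <- sites[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}
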