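## Synthetic plastome generator: quadripartite genome with planted genes,
## repeats and heteroplasmic pileups, all with recorded ground truth.

#' Default parameters for the synthetic genome
#'
#' The defaults emulate a miniature plastome: quadripartite, AT-rich
#' (GC 0.38), gene-dense, with a gene crossing each single-copy/IR
#' junction so that pseudogene-fragment reporting is exercised.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bases.
#' @param gc_fraction background GC content.
#' @param n_protein_lsc protein-coding genes placed in the LSC.
#' @param n_trna_lsc tRNA genes placed in the LSC.
#' @param n_planted_ssrs perfect SSRs planted in single-copy regions.
#' @param n_planted_long_repeats long tandem repeats planted likewise.
#' @return parameter list.
#' @export
sim_genome_params <- function(lsc_len = 8000L, ssc_len = 2000L,
                              ir_len = 3000L, gc_fraction = 0.38,
                              n_protein_lsc = 8L, n_trna_lsc = 3L,
                              n_planted_ssrs = 5L,
                              n_planted_long_repeats = 2L) {
  list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
       ir_len = as.integer(ir_len), gc_fraction = gc_fraction,
       n_protein_lsc = as.integer(n_protein_lsc),
       n_trna_lsc = as.integer(n_trna_lsc),
       n_planted_ssrs = as.integer(n_planted_ssrs),
       n_planted_long_repeats = as.integer(n_planted_long_repeats))
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## a random ORF of n_codons codons: ATG + non-stop codons + TAA; codons are
## weighted by the background base composition so coding regions do not
## distort the genome-wide GC fraction
random_orf <- function(n_codons, gc = 0.38, code = get_code("11")) {
  non_stop <- setdiff(names(code)[code != "*"], "ATG")
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(strsplit(non_stop, ""), function(b) prod(pbase[b]), numeric(1))
  body <- sample(non_stop, n_codons - 2L, replace = TRUE, prob = w)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Simulate a quadripartite plastome with annotation and ground truth
#'
#' Builds `LSC + IRa + SSC + revcomp(IRa)` over i.i.d. background bases
#' with the requested GC. Protein-coding genes are valid ORFs written into
#' the sequence on either strand (one multi-exon); genes fully inside the
#' IR are duplicated into IRb with mirrored coordinates and flipped
#' strand; one gene crosses the LSC/IRa boundary and one the SSC/IRb
#' boundary (their IR overlap is recorded as the expected pseudogene
#' fragment length). SSRs and long tandem repeats are planted at recorded
#' positions with flanking bases forced off-phase so the planted repeat is
#' maximal. Boundary bases are adjusted so the planted IR pair is exactly
#' maximal.
#'
#' @param params see [sim_genome_params()].
#' @param seed RNG seed; all randomness flows from it.
#' @return list with `genome` (`cp_genome`), `ann` (`cp_annotation`),
#'   `partition` (`cp_partition`, the planted coordinates) and `truth`
#'   (list: params, seed, planted repeats data.frame, planted genes,
#'   junction overlaps).
#' @export
simulate_genome <- function(params = sim_genome_params(), seed = 1L) {
  set.seed(seed)
  lsc <- params$lsc_len; ssc <- params$ssc_len; ir <- params$ir_len
  gc <- params$gc_fraction
  if (lsc <= ssc) stop("lsc_len must exceed ssc_len")
  Lt <- lsc + ir + ssc
  n <- Lt + ir
  x <- random_bases(Lt, gc)

  genes <- list()
  occupied <- matrix(integer(0), ncol = 2L)   # reserved template intervals
  reserve <- function(s, e) {
    occupied <<- rbind(occupied, c(s, e))
  }
  is_free <- function(s, e) {
    nrow(occupied) == 0L ||
      all(e < occupied[, 1] | s > occupied[, 2])
  }
  write_seq <- function(s, string) {
    x[s:(s + nchar(string) - 1L)] <<- seq_chars(string)
  }

  ## --- junction-crossing genes (recorded psi-fragment truth) -------------
  psi_ira <- 300L   # bases of the LSC/IRa gene inside IRa
  psi_irb <- 240L   # bases of the SSC/IRb gene inside IRb
  j1_len <- 3L * ((psi_ira + 450L) %/% 3L)
  j1_start <- lsc - (j1_len - psi_ira) + 1L
  genes[[length(genes) + 1L]] <- gene_model(
    "jlsc", "protein_coding", "+", cbind(j1_start, j1_start + j1_len - 1L))
  reserve(j1_start, j1_start + j1_len - 1L)
  j2_len <- 3L * ((psi_irb + 360L) %/% 3L)
  j2_start <- Lt - (j2_len - psi_irb) + 1L       # ends psi_irb into IRb
  genes[[length(genes) + 1L]] <- gene_model(
    "jssc", "protein_coding", "+", cbind(j2_start, j2_start + j2_len - 1L))
  reserve(j2_start, Lt)
  ## the IRb part of jssc mirrors the IRa tail: keep it gene-free
  reserve(lsc + ir - psi_irb - 50L, lsc + ir)

  ## --- genes fully inside regions ---------------------------------------
  place_gene <- function(gene_id, type, region_start, region_end, len,
                         strand, exonic = 1L, orf = FALSE) {
    for (try in 1:200) {
      s <- sample(region_start:(region_end - len + 1L), 1L)
      if (is_free(s - 20L, s + len + 19L)) {
        if (exonic == 1L) {
          exons <- cbind(s, s + len - 1L)
        } else {
          ## split the coding length into exons with random introns
          elens <- rep(len %/% exonic, exonic)
          elens[exonic] <- len - sum(elens[-exonic])
          ilens <- sample(50:120, exonic - 1L, replace = TRUE)
          tot <- sum(elens) + sum(ilens)
          if (s + tot - 1L > region_end || !is_free(s - 20L, s + tot + 19L)) next
          starts <- s + cumsum(c(0L, utils::head(elens, -1L) + ilens))
          exons <- cbind(starts, starts + elens - 1L)
        }
        if (orf) {
          ## write the CDS so that strand-corrected extraction recovers it:
          ## the plus-strand genomic text of the gene body is the CDS
          ## (plus strand) or its reverse complement (minus strand)
          cds <- random_orf(len %/% 3L, gc = gc)
          genomic <- if (strand == "-") revcomp(cds) else cds
          elens <- exons[, 2] - exons[, 1] + 1L
          off <- 0L
          for (ei in seq_len(nrow(exons))) {
            write_seq(exons[ei, 1], substr(genomic, off + 1L, off + elens[ei]))
            off <- off + elens[ei]
          }
        }
        reserve(min(exons), max(exons))
        genes[[length(genes) + 1L]] <<- gene_model(gene_id, type, strand,
                                                   exons)
        return(TRUE)
      }
    }
    FALSE
  }

  ## LSC protein-coding genes; the first is psbA-like on + (fixes the
  ## canonical strand)
  for (i in seq_len(params$n_protein_lsc)) {
    nm <- if (i == 1L) "psbA" else sprintf("pcg%02d", i)
    strand <- if (i == 1L) "+" else sample(c("+", "-"), 1L)
    len <- 3L * sample(60:160, 1L)
    nex <- if (i == 3L) 3L else if (i == 4L) 2L else 1L
    place_gene(nm, "protein_coding", 150L, lsc - 900L, len, strand,
               exonic = nex, orf = TRUE)
  }
  for (i in seq_len(params$n_trna_lsc)) {
    place_gene(sprintf("trn%02d", i), "tRNA", 150L, lsc - 900L, 75L,
               sample(c("+", "-"), 1L))
  }
  ## one protein gene in SSC
  place_gene("pcgS1", "protein_coding", lsc + ir + 150L, Lt - j2_len - 200L,
             3L * sample(80:140, 1L), "-", orf = TRUE)
  ## IR-resident genes (away from both IR ends)
  place_gene("rrnA", "rRNA", lsc + 200L, lsc + ir - psi_irb - 400L,
             600L, "+")
  place_gene("pcgIR1", "protein_coding", lsc + 200L,
             lsc + ir - psi_irb - 400L, 3L * sample(70:120, 1L), "-",
             orf = TRUE)

  ## --- planted repeats ---------------------------------------------------
  plant <- list()
  plant_repeat <- function(unit, copies, region_start, region_end, kind) {
    total <- nchar(unit) * copies
    for (try in 1:200) {
      s <- sample(region_start:(region_end - total - 2L), 1L)
      if (!is_free(s - nchar(unit) - 2L, s + total + nchar(unit) + 2L)) next
      write_seq(s, strrep(unit, copies))
      ## break the phase on both flanks so the planted repeat is maximal
      left_expect <- substr(unit, nchar(unit), nchar(unit))
      x[s - 1L] <<- sample(setdiff(c("A", "C", "G", "T"), left_expect), 1L)
      right_expect <- substr(unit, 1L, 1L)
      x[s + total] <<- sample(setdiff(c("A", "C", "G", "T"), right_expect), 1L)
      reserve(s - 1L, s + total)
      plant[[length(plant) + 1L]] <<- data.frame(
        unit = unit, copies = copies, start = s, end = s + total - 1L,
        total_len = total, kind = kind)
      return(TRUE)
    }
    FALSE
  }
  ssr_units <- c("A", "T", "AT", "AAG", "AATT", "ATTAG", "CATAGT")
  for (i in seq_len(params$n_planted_ssrs)) {
    u <- ssr_units[((i - 1L) %% length(ssr_units)) + 1L]
    copies <- max(3L, ceiling(12L / nchar(u)))
    plant_repeat(u, copies, 150L, lsc - 900L, "ssr")
  }
  for (i in seq_len(params$n_planted_long_repeats)) {
    u <- paste(random_bases(sample(12:20, 1L), gc), collapse = "")
    if (!unit_is_primitive(u)) u <- paste0(substr(u, 1, nchar(u) - 1L), "R")
    plant_repeat(u, sample(3:4, 1L), lsc + ir + 100L, Lt - j2_len - 150L,
                 "long")
  }

  ## --- IR maximality fix-ups --------------------------------------------
  ## left edge: last LSC base must not pair with the first genome base
  if (x[lsc] == comp_chars(x[1L])) {
    x[lsc] <- sample(setdiff(c("A", "C", "G", "T"), comp_chars(x[1L])), 1L)
  }
  ## right edge: first SSC base must not pair with the last SSC base
  if (x[lsc + ir + 1L] == comp_chars(x[Lt])) {
    x[lsc + ir + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                       comp_chars(x[Lt])), 1L)
  }

  template <- paste(x, collapse = "")
  ira_seq <- substr(template, lsc + 1L, lsc + ir)
  genome <- circular_genome(paste0(template, revcomp(ira_seq)),
                            id = sprintf("sim%d", seed))

  ## mirror IR-resident genes into IRb: template position p in IRa maps to
  ## genome position n + lsc + 1 - p on the reverse-complemented copy
  mirror <- function(p) n + lsc + 1L - p
  ira_lo <- lsc + 1L; ira_hi <- lsc + ir
  for (g in genes) {
    sp <- gene_span(g)
    if (sp["start"] >= ira_lo && sp["end"] <= ira_hi) {
      ex <- cbind(mirror(g$exons[, 2]), mirror(g$exons[, 1]))
      genes[[length(genes) + 1L]] <- gene_model(
        g$gene_id, g$type, if (g$strand == "+") "-" else "+", ex, "irb")
    }
  }
  ## tag the originals that now have IRb twins
  genes <- lapply(genes, function(g) {
    sp <- gene_span(g)
    if (is.na(g$copy_tag) && sp["start"] >= ira_lo && sp["end"] <= ira_hi) {
      g$copy_tag <- "ira"
    }
    g
  })

  ann <- annotation(genome$id, genes, genome_length = n)
  part <- quadripartite_partition(
    lsc = c(1L, lsc), ira = c(lsc + 1L, lsc + ir),
    ssc = c(lsc + ir + 1L, Lt), irb = c(Lt + 1L, n), genome_length = n)
  validate_partition(genome, part)
  truth <- list(seed = seed, params = params,
                partition = list(lsc = part$lsc, ira = part$ira,
                                 ssc = part$ssc, irb = part$irb,
                                 ir_len = part$ir_len),
                repeats = do.call(rbind, plant),
                junctions = list(psi_ira = psi_ira, psi_irb = psi_irb,
                                 lsc_ira_gene = "jlsc",
                                 ssc_irb_gene = "jssc"))
  list(genome = genome, ann = ann, partition = part, truth = truth)
}

#' Simulate heteroplasmic pileups for a set of strains
#'
#' Per strain, every genome position receives depth `~ Poisson(coverage)`.
#' At designed sites the minor-allele count is `Binomial(depth, MAF)`; at
#' all other positions sequencing errors arise with probability
#' `error_rate` per read and are spread uniformly over the three
#' non-reference bases.
#'
#' @param genome the reference `cp_genome`.
#' @param site_design data.frame with columns `strain`, `pos`,
#'   `minor_allele` (base, `+SEQ` or `-SEQ`) and `maf` (in `[0, 0.5]`).
#' @param coverage mean depth (>= 50 recommended).
#' @param error_rate per-read substitution error probability (in
#'   `[0, 0.01]`).
#' @param seed RNG seed.
#' @return list with `pileups` (named list of `cp_pileup`, one per strain
#'   appearing in `site_design`) and `truth` (the design plus simulation
#'   settings).
#' @export
simulate_heteroplasmy <- function(genome, site_design, coverage = 100,
                                  error_rate = 0.001, seed = 1L) {
  stopifnot(all(c("strain", "pos", "minor_allele", "maf") %in%
                  names(site_design)))
  if (any(site_design$maf > 0.5)) stop("designed MAF must be <= 0.5")
  if (error_rate < 0 || error_rate > 0.01) {
    stop("error_rate must lie in [0, 0.01]")
  }
  set.seed(seed)
  n <- genome$length
  refc <- seq_chars(genome)
  bases <- c("A", "C", "G", "T")
  strains <- unique(site_design$strain)
  pileups <- stats::setNames(vector("list", length(strains)), strains)
  for (s in strains) {
    depth <- stats::rpois(n, coverage)
    design <- site_design[site_design$strain == s & site_design$maf > 0, ,
                          drop = FALSE]
    counts <- vector("list", n)
    err <- if (error_rate > 0) stats::rbinom(n, depth, error_rate)
           else integer(n)
    designed <- logical(n); designed[design$pos] <- TRUE
    for (p in seq_len(n)) {
      if (designed[p] || err[p] > 0L) next
      counts[[p]] <- stats::setNames(depth[p], refc[p])
    }
    ## error-only positions
    for (p in which(err > 0L & !designed)) {
      alt <- sample(setdiff(bases, refc[p]), err[p], replace = TRUE)
      tab <- table(alt)
      counts[[p]] <- c(stats::setNames(depth[p] - err[p], refc[p]),
                       stats::setNames(as.integer(tab), names(tab)))
    }
    ## designed heteroplasmic sites
    for (k in seq_len(nrow(design))) {
      p <- design$pos[k]
      dk <- depth[p]
      mc <- stats::rbinom(1L, dk, design$maf[k])
      counts[[p]] <- stats::setNames(c(dk - mc, mc),
                                     c(refc[p], design$minor_allele[k]))
      if (mc == 0L) counts[[p]] <- counts[[p]][1L]
    }
    nonzero <- which(depth > 0L)
    pileups[[s]] <- pileup(nonzero, refc[nonzero], counts[nonzero])
  }
  list(pileups = pileups,
       truth = list(design = site_design, coverage = coverage,
                    error_rate = error_rate, seed = seed))
}

#' Simulate a four-strain family of MAF profiles along a planted tree
#'
#' Minor-allele-frequency vectors evolve along the fixed topology
#' `((A,B),(C,D))` by Gaussian perturbations truncated to `[0, 0.5]`:
#' one clade-level perturbation per clade (scale `between_scale`) and one
#' strain-level perturbation per strain (scale `within_scale`).
#'
#' @param genome the reference `cp_genome` (site positions are drawn from
#'   it, excluding designed duplicates).
#' @param strains four strain labels, in the order (A, B, C, D).
#' @param n_sites number of polymorphic sites.
#' @param between_scale,within_scale Gaussian perturbation standard
#'   deviations for clade and strain branches.
#' @param maf_range range of root MAFs.
#' @param seed RNG seed.
#' @return list with `site_design` (long data.frame for
#'   [simulate_heteroplasmy()]) and `truth` (planted topology as a Newick
#'   string, scales, root MAFs, site keys).
#' @export
simulate_strain_family <- function(genome,
                                   strains = c("A", "B", "C", "D"),
                                   n_sites = 200L,
                                   between_scale = 0.10,
                                   within_scale = 0.02,
                                   maf_range = c(0.08, 0.42),
                                   seed = 1L) {
  stopifnot(length(strains) == 4L)
  set.seed(seed)
  refc <- seq_chars(genome)
  ok <- which(refc %in% c("A", "C", "G", "T"))
  pos <- sort(sample(ok, n_sites))
  minor <- vapply(pos, function(p) {
    sample(setdiff(c("A", "C", "G", "T"), refc[p]), 1L)
  }, character(1))
  clamp <- function(v) pmin(pmax(v, 0), 0.5)
  root <- stats::runif(n_sites, maf_range[1], maf_range[2])
  clade1 <- clamp(root + stats::rnorm(n_sites, 0, between_scale))
  clade2 <- clamp(root + stats::rnorm(n_sites, 0, between_scale))
  leaf <- list(
    clamp(clade1 + stats::rnorm(n_sites, 0, within_scale)),
    clamp(clade1 + stats::rnorm(n_sites, 0, within_scale)),
    clamp(clade2 + stats::rnorm(n_sites, 0, within_scale)),
    clamp(clade2 + stats::rnorm(n_sites, 0, within_scale)))
  design <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(strain = strains[i], pos = pos, minor_allele = minor,
               maf = leaf[[i]])
  }))
  design <- design[design$maf > 0, , drop = FALSE]
  rownames(design) <- NULL
  list(site_design = design,
       truth = list(
         topology = sprintf("((%s,%s),(%s,%s));", strains[1], strains[2],
                            strains[3], strains[4]),
         between_scale = between_scale, within_scale = within_scale,
         root_maf = root, pos = pos, minor_allele = minor, seed = seed))
}

#' Write a simulation's truth record as JSON
#'
#' @param truth a truth list from a `simulate_*` function.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a simulation truth record
#'
#' @param path JSON file written by [write_sim_truth()].
#' @return truth list.
#' @export
read_sim_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
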