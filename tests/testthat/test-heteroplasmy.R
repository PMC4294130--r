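mini_pileup <- function(...) {
  cols <- list(...)
  pileup(pos = vapply(cols, `[[`, 0L, "pos"),
         ref = vapply(cols, `[[`, "", "ref"),
         counts = lapply(cols, `[[`, "counts"))
}

test_that("the MAF threshold is inclusive and depth rules apply", {
  pp <- mini_pileup(
    list(pos = 10L, ref = "A", counts = c(A = 95L, C = 5L)),    # maf 0.05
    list(pos = 20L, ref = "A", counts = c(A = 96L, C = 4L)),    # maf 0.04
    list(pos = 30L, ref = "T", counts = c(T = 5L, G = 3L)),     # depth 8
    list(pos = 40L, ref = "G", counts = c(G = 900L, `+A` = 100L)),
    list(pos = 50L, ref = "G", counts = c(G = 96L, `+A` = 4L)), # indel < 5
    list(pos = 60L, ref = "C", counts = c(C = 50L, A = 50L)))   # maf 0.5
  s <- call_minor_alleles(pp, maf_min = 0.05, depth_min = 10L,
                          indel_depth_min = 5L)
  expect_setequal(s$pos, c(10L, 40L, 60L))
  expect_equal(s$maf[s$pos == 10L], 0.05)
  expect_equal(s$var_type[s$pos == 40L], "insertion")
  expect_equal(s$maf[s$pos == 60L], 0.5)
  ## ties for major allele break lexicographically: at 50/50, A is major
  expect_equal(s$major_allele[s$pos == 60L], "A")
  expect_equal(s$minor_allele[s$pos == 60L], "C")
})

test_that("zero-depth columns are skipped with a warning", {
  pp <- mini_pileup(list(pos = 5L, ref = "A", counts = integer(0)),
                    list(pos = 6L, ref = "A", counts = c(A = 90L, G = 10L)))
  expect_warning(s <- call_minor_alleles(pp, maf_min = 0.05), "depth 0")
  expect_equal(s$pos, 6L)
})

test_that("threshold monotonicity: stricter MAF cutoffs give nested site sets", {
  sim <- shared_sim
  set.seed(14)
  design <- data.frame(
    strain = "S",
    pos = sample(16000L, 120L),
    minor_allele = sample(c("A", "C", "G", "T"), 120L, replace = TRUE),
    maf = stats::runif(120L, 0.005, 0.45))
  het <- simulate_heteroplasmy(sim$genome, design, coverage = 300,
                               seed = 14)
  pp <- het$pileups$S
  keys <- function(maf) site_keys <- paste(
    call_minor_alleles(pp, maf_min = maf)$pos,
    call_minor_alleles(pp, maf_min = maf)$minor_allele)
  k10 <- keys(0.10); k05 <- keys(0.05); k01 <- keys(0.01)
  expect_true(all(k10 %in% k05))
  expect_true(all(k05 %in% k01))
  expect_gt(length(k01), length(k05))
})

test_that("estimated MAF stays within 3-sigma binomial bounds at coverage 1000", {
  sim <- shared_sim
  set.seed(15)
  n_sites <- 500L
  pos <- sample(16000L, n_sites)
  refc <- strsplit(sim$genome$seq, "")[[1]]
  design <- data.frame(
    strain = "S", pos = pos,
    minor_allele = vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"), refc[p]), 1), ""),
    maf = stats::runif(n_sites, 0.05, 0.45))
  het <- simulate_heteroplasmy(sim$genome, design, coverage = 1000,
                               error_rate = 0, seed = 15)
  s <- call_minor_alleles(het$pileups$S, maf_min = 0.01, depth_min = 100L)
  m <- merge(design, s[, c("pos", "minor_allele", "maf", "depth")],
             by = c("pos", "minor_allele"), suffixes = c("_true", "_est"))
  expect_gte(nrow(m), n_sites - 5L)    # a handful may fall below threshold
  bound <- 3 * sqrt(m$maf_true * (1 - m$maf_true) / m$depth)
  frac_within <- mean(abs(m$maf_est - m$maf_true) <= bound)
  expect_gte(frac_within, 0.99)
})

test_that("substitutions classify as transition or transversion with coding effects", {
  sim <- shared_sim
  ## take a plus-strand single-exon gene and craft codon-level checks
  genes <- sim$ann$genes
  plus_gene <- Filter(function(g) g$type == "protein_coding" &&
                        g$strand == "+" && nrow(g$exons) == 1 &&
                        g$gene_id != "jlsc" && g$gene_id != "jssc",
                      genes)[[1]]
  gstart <- plus_gene$exons[1, 1]
  cds <- extract_cds(sim$genome, plus_gene)
  code <- Biostrings::getGeneticCode("11")
  ## find a codon where a third-position change is synonymous
  syn_pos <- NA
  for (ci in seq_len(nchar(cds) %/% 3)) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 3, 3))) {
      alt <- codon; substr(alt, 3, 3) <- b
      if (code[[alt]] == code[[codon]]) { syn_pos <- c(ci, b); break }
    }
    if (!is.na(syn_pos[1])) break
  }
  ci <- as.integer(syn_pos[1]); alt_base <- syn_pos[2]
  gpos <- gstart + 3L * ci - 1L       # third codon position
  ref_base <- substr(sim$genome$seq, gpos, gpos)
  pp <- mini_pileup(
    list(pos = gpos, ref = ref_base,
         counts = stats::setNames(c(80L, 20L), c(ref_base, alt_base))),
    list(pos = 16000L, ref = substr(sim$genome$seq, 16000L, 16000L),
         counts = stats::setNames(c(90L, 10L),
                                  c(substr(sim$genome$seq, 16000L, 16000L),
                                    setdiff(c("A", "C"),
                                            substr(sim$genome$seq, 16000L,
                                                   16000L))[1]))))
  s <- call_minor_alleles(pp, maf_min = 0.05)
  s <- classify_sites(s, sim$ann, sim$partition, sim$genome)
  row <- s[s$pos == gpos, ]
  expect_equal(row$context, paste0("CDS:", plus_gene$gene_id))
  expect_equal(row$coding_effect, "synonymous")
  expected_tstv <- if (all(c(ref_base, alt_base) %in% c("A", "G")) ||
                       all(c(ref_base, alt_base) %in% c("C", "T")))
    "transition" else "transversion"
  expect_equal(row$ts_tv, expected_tstv)
  expect_equal(s$region[s$pos == 16000L], "IRb")
})

test_that("minus-strand coding effects agree with a direct translation oracle", {
  sim <- shared_sim
  genes <- sim$ann$genes
  minus_gene <- Filter(function(g) g$type == "protein_coding" &&
                         g$strand == "-" && nrow(g$exons) == 1,
                       genes)[[1]]
  code <- Biostrings::getGeneticCode("11")
  set.seed(16)
  span <- gene_span(minus_gene)
  for (k in 1:12) {
    gpos <- sample(span["start"]:span["end"], 1)
    ref_base <- substr(sim$genome$seq, gpos, gpos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    pp <- mini_pileup(list(
      pos = gpos, ref = ref_base,
      counts = stats::setNames(c(85L, 15L), c(ref_base, alt))))
    s <- classify_sites(call_minor_alleles(pp, maf_min = 0.05),
                        sim$ann, sim$partition, sim$genome)
    ## oracle: rebuild the whole genome with the substitution, re-extract
    ## the CDS and compare full translations
    x <- strsplit(sim$genome$seq, "")[[1]]
    x[gpos] <- alt
    g2 <- circular_genome(paste(x, collapse = ""), id = "mut")
    aa1 <- as.character(Biostrings::translate(
      Biostrings::DNAString(extract_cds(sim$genome, minus_gene)),
      genetic.code = code))
    aa2 <- as.character(Biostrings::translate(
      Biostrings::DNAString(extract_cds(g2, minus_gene)),
      genetic.code = code))
    expect_equal(s$coding_effect,
                 if (aa1 == aa2) "synonymous" else "nonsynonymous",
                 info = sprintf("pos %d %s>%s", gpos, ref_base, alt))
  }
})

test_that("per-strain densities reproduce the published arithmetic", {
  fake_sites <- function(n) {
    data.frame(pos = seq_len(n), major_allele = rep("A", n),
               minor_allele = rep("C", n), maf = rep(0.1, n),
               depth = rep(100L, n), strain = rep("s", n),
               var_type = rep("substitution", n),
               ts_tv = rep("transversion", n), region = rep("LSC", n),
               context = rep("intergenic", n),
               coding_effect = rep(NA_character_, n))
  }
  glen <- 156354L
  expect_equal(strain_summary(fake_sites(116L), glen)$density_per_kb, 0.74)
  expect_equal(strain_summary(fake_sites(92L), glen)$density_per_kb, 0.59)
  expect_equal(strain_summary(fake_sites(152L), glen)$density_per_kb, 0.97)
  expect_equal(strain_summary(fake_sites(193L), glen)$density_per_kb, 1.23)
  empty <- fake_sites(0L)
  expect_equal(strain_summary(empty, glen)$density_per_kb, 0)
  ## breakdown sum rule
  s <- fake_sites(17L)
  summ <- strain_summary(s, glen)
  expect_equal(sum(summ$breakdowns$region), summ$n_sites)
  expect_equal(sum(summ$breakdowns$var_type), summ$n_sites)
})

test_that("overlap analysis produces exact Venn cells and exclusive markers", {
  mk <- function(strain, pos) {
    data.frame(pos = pos, major_allele = "A", minor_allele = "C",
               maf = 0.2, depth = 100L, strain = strain,
               var_type = "substitution")
  }
  two <- overlap_analysis(list(X = mk("X", c(1L, 2L, 3L, 7L)),
                               Y = mk("Y", c(2L, 3L, 7L, 9L))))
  expect_equal(unname(two$venn["X&Y"]), 3L)
  expect_equal(two$exclusive$X, "1:C")
  expect_equal(two$exclusive$Y, "9:C")
  disjoint <- overlap_analysis(list(X = mk("X", 1:3), Y = mk("Y", 4:6)))
  expect_false("X&Y" %in% names(disjoint$venn))
  expect_equal(disjoint$shared_all, 0L)
})

test_that("IR site pairs collapse onto the IRa copy with complemented alleles", {
  sim <- shared_sim
  part <- sim$partition
  ## one biological site observed in both IR copies
  pos_a <- part$ira[1] + 100L
  pos_b <- part$irb[2] - 100L         # exact mirror
  s <- data.frame(pos = c(pos_a, pos_b),
                  major_allele = c("A", "T"), minor_allele = c("G", "C"),
                  maf = c(0.2, 0.21), depth = c(100L, 98L), strain = "s",
                  var_type = "substitution",
                  ts_tv = "transition", region = c("IRa", "IRb"),
                  context = "intergenic", coding_effect = NA_character_)
  collapsed <- collapse_ir_pairs(s, part)
  expect_equal(nrow(collapsed), 1L)
  expect_equal(collapsed$pos, pos_a)
  expect_equal(collapsed$region, "IRa")
})
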