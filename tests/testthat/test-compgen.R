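test_that("orthologous fragments pair identically for identical genomes", {
  sim <- shared_sim
  fr <- partition_orthologous_fragments(sim$genome, sim$ann,
                                        sim$genome, sim$ann,
                                        part_a = sim$partition)
  expect_true(all(fr$seq_a == fr$seq_b))
  expect_setequal(unique(fr$cls), c("CDS", "intron", "IGS"))
  ## CDS fragments concatenated per gene are in frame
  for (gid in unique(fr$gene[fr$cls == "CDS"])) {
    cds_len <- sum(nchar(fr$seq_a[fr$cls == "CDS" & fr$gene %in% gid]))
    expect_equal(cds_len %% 3L, 0L, info = gid)
  }
})

test_that("planted substitutions appear only in their fragment's diversity cell", {
  sim <- shared_sim
  g <- sim$genome
  fr0 <- partition_orthologous_fragments(g, sim$ann, g, sim$ann,
                                         part_a = sim$partition)
  target <- fr0[fr0$cls == "IGS" & fr0$region == "SSC", ][1, ]
  x <- strsplit(g$seq, "")[[1]]
  pos <- target$mid_a + seq(-9, 9, by = 2)
  for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  g2 <- circular_genome(paste(x, collapse = ""), id = "mut")
  fr <- partition_orthologous_fragments(g, sim$ann, g2, sim$ann,
                                        part_a = sim$partition)
  div <- region_diversity(fr)
  expect_equal(div$NP[div$cls == "IGS" & div$region == "SSC"], 10)
  expect_equal(div$NP[div$cls == "TOTAL"], 10)
  expect_equal(sum(div$NP[div$region %in% c("LSC", "IR") |
                            div$cls %in% c("CDS", "intron")]), 0)
  ## ND of the hit cell equals a literal column recount
  cell <- fr[fr$cls == "IGS" & fr$region == "SSC", ]
  counts <- colSums(t(vapply(seq_len(nrow(cell)), function(i)
    oracle_nd_count(cell$seq_a[i], cell$seq_b[i]), c(np = 0, ungapped = 0))))
  expect_equal(div$ND[div$cls == "IGS" & div$region == "SSC"],
               counts["np"] / counts["ungapped"], ignore_attr = TRUE)
})

test_that("inconsistent exon order between genomes raises a named error", {
  sim <- shared_sim
  genes <- sim$ann$genes
  ids <- vapply(genes, `[[`, "", "gene_id")
  i <- which(ids == "pcg02"); j <- which(ids == "psbA")
  swapped <- genes
  swapped[[i]] <- gene_model(genes[[j]]$gene_id, genes[[j]]$type,
                             genes[[j]]$strand, genes[[i]]$exons)
  swapped[[j]] <- gene_model(genes[[i]]$gene_id, genes[[i]]$type,
                             genes[[i]]$strand, genes[[j]]$exons)
  ann_b <- annotation(sim$ann$genome_id, swapped)
  expect_error(
    partition_orthologous_fragments(sim$genome, sim$ann, sim$genome, ann_b),
    "inconsistent exon order")
})

test_that("genes missing from one annotation are skipped, not fatal", {
  sim <- shared_sim
  genes_b <- Filter(function(g) g$gene_id != "pcg05", sim$ann$genes)
  ann_b <- annotation(sim$ann$genome_id, genes_b)
  fr <- partition_orthologous_fragments(sim$genome, sim$ann,
                                        sim$genome, ann_b,
                                        part_a = sim$partition)
  expect_true(any(grepl("^pcg05", attr(fr, "skipped"))))
  expect_false(any(fr$gene %in% "pcg05" & fr$cls == "CDS"))
})

test_that("NG86 handles identical, single-codon and degenerate-site cases", {
  r0 <- ng86_kaks("ATGAAACCCTAA", "ATGAAACCCTAA")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  ## single differing codon agrees with the pathway-enumeration oracle
  r1 <- ng86_kaks("TTT", "TTA")
  o1 <- oracle_ng86("TTT", "TTA")
  expect_equal(r1$Na, o1$Na)
  expect_equal(r1$Ns, o1$Ns)
  expect_equal(r1$Sa, o1$Sa)
  expect_equal(r1$Ss, o1$Ss)
  ## substitutions planted only at 4-fold degenerate third positions
  set.seed(21)
  fourfold <- c("GC", "GG", "CC", "CG", "CT", "GT", "AC", "TC")
  stems <- sample(fourfold, 300, replace = TRUE)
  third_a <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  cds_a <- paste(paste0(stems, third_a), collapse = "")
  third_b <- third_a
  mut <- sample(300, 40)
  third_b[mut] <- vapply(third_a[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  cds_b <- paste(paste0(stems, third_b), collapse = "")
  r2 <- ng86_kaks(cds_a, cds_b)
  expect_equal(r2$Ka, 0)
  expect_gt(r2$Ks, 0)
})

test_that("NG86 input contracts are enforced with typed errors", {
  expect_error(ng86_kaks("ATGAAA", "ATG"), "length_mismatch")
  expect_error(ng86_kaks("ATGA", "ATGC"), "frame_violation")
  expect_error(ng86_kaks("ATGTAACCC", "ATGTACCCC"), "internal_stop")
  expect_error(ng86_kaks("ATGAN-", "ATGANA"), "invalid_base")
})

test_that("NG86 is symmetric and matches the oracle on random codon pairs", {
  set.seed(33)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  code <- Biostrings::getGeneticCode("11")
  sense <- codons[code[codons] != "*"]
  for (k in 1:250) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    r <- ng86_kaks(c1, c2)
    o <- oracle_ng86(c1, c2)
    expect_equal(r$Na, o$Na, tolerance = 1e-12, info = paste(c1, c2))
    expect_equal(r$Ns, o$Ns, tolerance = 1e-12, info = paste(c1, c2))
    expect_equal(r$Sa, o$Sa, tolerance = 1e-12, info = paste(c1, c2))
    expect_equal(r$Ss, o$Ss, tolerance = 1e-12, info = paste(c1, c2))
    rs <- ng86_kaks(c2, c1)
    expect_equal(r$Na, rs$Na)
    expect_equal(r$Ns, rs$Ns)
  }
})

test_that("the Jukes-Cantor correction reduces to p as p approaches 0", {
  expect_lt(abs(jukes_cantor(1e-6) - 1e-6), 1e-9)
  expect_true(is.na(jukes_cantor(0.8)))
  expect_equal(jukes_cantor(0), 0)
})

test_that("the Ka==Ks z-test rejects near the nominal 5% level under neutrality", {
  ## random mutations irrespective of coding effect: Ka and Ks estimate the
  ## same underlying rate, so the two-tailed test should reject ~5% of runs
  set.seed(55)
  n_codons <- 200L
  reps <- 1000L
  rejections <- 0L
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  for (r in seq_len(reps)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    mutate <- function(codvec, k) {
      s <- paste(codvec, collapse = "")
      repeat {
        x <- strsplit(s, "")[[1]]
        pos <- sample(length(x), k)
        x[pos] <- vapply(x[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        s2 <- paste(x, collapse = "")
        cods <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
        if (!any(code[cods] == "*")) return(s2)
      }
    }
    a <- mutate(anc, 15L)
    b <- mutate(anc, 15L)
    res <- ng86_kaks(a, b)
    if (!is.na(res$p_value) && res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / reps, 0.03)
  expect_lte(rejections / reps, 0.07)
})

test_that("per-gene Ka/Ks table flags problem genes and counts planted changes", {
  sim <- shared_sim
  tab0 <- gene_kaks_table(sim$genome, sim$ann, sim$genome, sim$ann)
  ok <- tab0[tab0$note == "", ]
  expect_gt(nrow(ok), 3L)
  expect_true(all(ok$Ka == 0 & ok$Ks == 0))
  expect_true(all(is.na(ok$ratio)))
  ## plant one nonsynonymous change in a clean single-exon gene: the first
  ## codon's ATG -> ATC (Met -> Ile) is nonsynonymous on either strand
  genes <- sim$ann$genes
  ids <- vapply(genes, `[[`, "", "gene_id")
  cand <- which(ids == "pcg02")[1]
  gene <- genes[[cand]]
  x <- strsplit(sim$genome$seq, "")[[1]]
  if (gene$strand == "+") {
    p <- gene$exons[1, 1] + 2L
    x[p] <- "C"
  } else {
    p <- gene$exons[nrow(gene$exons), 2] - 2L
    x[p] <- "G"
  }
  g2 <- circular_genome(paste(x, collapse = ""), id = "mut")
  tab <- gene_kaks_table(sim$genome, sim$ann, g2, sim$ann)
  row <- tab[tab$gene == "pcg02", ]
  expect_equal(row$Na, 1)
  expect_equal(row$Ns, 0)
  expect_gt(row$Ka, 0)
  expect_equal(row$Ks, 0)
})

test_that("minus-strand multi-exon CDS extraction round-trips the mRNA sense", {
  g <- circular_genome(random_seq(400), id = "ex")
  cds <- "ATGGATTACGCTGAGTTGTAA"
  ## write revcomp(cds) across two plus-strand intervals; the gene is on -
  genomic <- revcomp(cds)
  x <- strsplit(g$seq, "")[[1]]
  x[101:110] <- strsplit(substr(genomic, 1, 10), "")[[1]]
  x[151:161] <- strsplit(substr(genomic, 11, 21), "")[[1]]
  g <- circular_genome(paste(x, collapse = ""), id = "ex")
  gene <- gene_model("m", "protein_coding", "-",
                     rbind(c(101L, 110L), c(151L, 161L)))
  expect_equal(extract_cds(g, gene), cds)
})

test_that("codon usage counts all protein-coding CDSs strand-corrected", {
  g <- circular_genome(paste0(random_seq(50), "ATGAAATAG", random_seq(50)),
                       id = "cu", circular = FALSE)
  ann <- annotation("cu", list(
    gene_model("one", "protein_coding", "+", cbind(51L, 59L))))
  cu <- codon_usage(g, ann)
  expect_equal(attr(cu, "total"), 3L)
  expect_equal(cu$count[cu$codon == "ATG"], 1L)
  expect_equal(cu$count[cu$codon == "AAA"], 1L)
  expect_equal(cu$count[cu$codon == "TAG"], 1L)
  ## duplicated gene doubles the counts
  ann2 <- annotation("cu", list(
    gene_model("one", "protein_coding", "+", cbind(51L, 59L), "ira"),
    gene_model("one", "protein_coding", "+", cbind(51L, 59L), "irb")))
  cu2 <- codon_usage(g, ann2)
  expect_equal(attr(cu2, "total"), 6L)
  expect_equal(cu2$count[cu2$codon == "ATG"], 2L)
  ## synthetic genome total equals the brute-force sum of CDS lengths / 3
  sim <- shared_sim
  expected <- sum(vapply(sim$ann$genes, function(gg) {
    if (gg$type != "protein_coding") return(0L)
    len <- sum(gg$exons[, 2] - gg$exons[, 1] + 1L)
    if (len %% 3L == 0L) len %/% 3L else 0L
  }, integer(1)))
  cu3 <- suppressWarnings(codon_usage(sim$genome, sim$ann))
  expect_equal(attr(cu3, "total"), expected)
})
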