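mutate_genome <- function(genome, subs = integer(0), dels = list(),
                          ins = list()) {
  ## subs: positions; dels: list of c(start, len); ins: list of
  ## list(after = pos, seq = string). Returns the mutated genome and the
  ## planting record (on reference coordinates).
  x <- strsplit(genome$seq, "")[[1]]
  rec <- list()
  for (p in subs) {
    old <- x[p]
    x[p] <- setdiff(c("A", "C", "G", "T"), old)[1]
    rec[[length(rec) + 1L]] <- data.frame(pos = p, kind = "substitution")
  }
  keep <- rep(TRUE, length(x))
  for (d in dels) {
    keep[d[1]:(d[1] + d[2] - 1L)] <- FALSE
    rec[[length(rec) + 1L]] <- data.frame(pos = d[1], kind = "deletion")
  }
  parts <- character(0)
  last <- 1L
  insertions <- ins[order(vapply(ins, `[[`, 0, "after"))]
  out <- character(0)
  prev <- 0L
  for (iv in insertions) {
    out <- c(out, x[keep & seq_along(x) > prev & seq_along(x) <= iv$after],
             strsplit(iv$seq, "")[[1]])
    prev <- iv$after
    rec[[length(rec) + 1L]] <- data.frame(pos = iv$after, kind = "insertion")
  }
  out <- c(out, x[keep & seq_along(x) > prev])
  list(genome = circular_genome(paste(out, collapse = ""), id = "qry"),
       record = do.call(rbind, rec))
}

test_that("identical genomes yield no variants", {
  g <- shared_sim$genome
  v <- pairwise_variants(g, g)
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "identity"), 1)
})

test_that("planted substitutions and deletions are recovered exactly", {
  g <- shared_sim$genome
  mut <- mutate_genome(g, subs = c(1500L, 6200L, 12100L),
                       dels = list(c(3500L, 1L), c(9000L, 3L)))
  v <- pairwise_variants(g, mut$genome)
  expect_equal(nrow(v), 5L)
  expect_equal(sum(v$kind == "substitution"), 3L)
  expect_equal(sum(v$kind == "deletion"), 2L)
  expect_setequal(v$pos[v$kind == "substitution"], c(1500L, 6200L, 12100L))
  ## deletions may left-shift inside repeat context but never past the
  ## planted run; the deleted content must match
  for (d in list(c(3500L, 1L), c(9000L, 3L))) {
    row <- v[v$kind == "deletion" &
               abs(v$pos - d[1]) <= 10L, ]
    expect_equal(nrow(row), 1L)
    expect_equal(nchar(row$ref_allele) - nchar(row$alt_allele), d[2])
  }
  ## substitutions + indel events == total variants
  expect_equal(sum(v$kind == "substitution") + sum(v$kind != "substitution"),
               nrow(v))
})

test_that("a single intron insertion is located and annotated", {
  sim <- shared_sim
  g <- sim$genome
  ## find an intron of a multi-exon gene and insert one base inside it
  genes <- sim$ann$genes
  multi <- Filter(function(x) nrow(x$exons) > 1, genes)[[1]]
  ipos <- multi$exons[1, 2] + 3L        # inside the first intron
  base <- "T"
  mut <- mutate_genome(g, ins = list(list(after = ipos, seq = base)))
  v <- pairwise_variants(g, mut$genome, ann = sim$ann)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "insertion")
  ## left-normalisation can shift within a homopolymer but stays local
  expect_lte(abs(v$pos - ipos), 10L)
  expect_equal(v$context, paste0("intron:", multi$gene_id))
})

test_that("left-normalisation is a fixpoint: indels cannot shift further left", {
  g <- shared_sim$genome
  set.seed(4)
  dels <- lapply(sample(seq(500L, 15000L, by = 400L), 12L),
                 function(p) c(p, sample(1:3, 1)))
  mut <- mutate_genome(g, dels = dels)
  v <- pairwise_variants(g, mut$genome)
  x <- strsplit(g$seq, "")[[1]]
  for (i in which(v$kind == "deletion")) {
    deleted <- substr(v$ref_allele[i], 2L, nchar(v$ref_allele[i]))
    ## shifting once more left would require the base before the anchor to
    ## equal the last deleted base
    if (v$pos[i] > 1L) {
      expect_false(x[v$pos[i]] == substr(deleted, nchar(deleted),
                                         nchar(deleted)) &&
                     x[v$pos[i]] == x[v$pos[i] + nchar(deleted)])
    }
  }
})

test_that("variant calls are invariant to rotating both genomes together", {
  g <- shared_sim$genome
  mut <- mutate_genome(g, subs = c(2000L, 7000L), dels = list(c(11000L, 2L)))
  v0 <- pairwise_variants(g, mut$genome)
  off <- 4321L
  gr <- rotate_genome(g, off)
  qr <- rotate_genome(mut$genome, off)
  vr <- pairwise_variants(gr, qr)
  expect_equal(nrow(vr), nrow(v0))
  expect_setequal(vr$kind, v0$kind)
})

test_that("ambiguity codes consistent with the other genome are excluded", {
  g <- circular_genome(paste0(random_seq(300), "A", random_seq(300),
                              "C", random_seq(300)), id = "ref",
                       circular = FALSE)
  x <- strsplit(g$seq, "")[[1]]
  x[301] <- "R"      # purine, consistent with ref A
  x[602] <- "A"      # real substitution C -> A
  q <- circular_genome(paste(x, collapse = ""), id = "qry",
                       circular = FALSE)
  v <- pairwise_variants(g, q)
  expect_equal(attr(v, "n_excluded_ambiguous"), 1L)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 602L)
  ## an inconsistent ambiguity (Y vs ref A) is kept as a substitution
  x2 <- strsplit(g$seq, "")[[1]]
  x2[301] <- "Y"
  q2 <- circular_genome(paste(x2, collapse = ""), id = "q2",
                        circular = FALSE)
  v2 <- pairwise_variants(g, q2)
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$pos, 301L)
})

test_that("homopolymer context is profiled for indels", {
  ## deletion of one A inside an A6 run
  g <- circular_genome(paste0(random_seq(200), "GC", strrep("A", 6), "GC",
                              random_seq(200)), id = "hp", circular = FALSE)
  mut <- mutate_genome(g, dels = list(c(205L, 1L)))
  v <- pairwise_variants(g, mut$genome)
  expect_equal(nrow(v), 1L)
  expect_equal(v$homopolymer_unit_run, 6L)
  prof <- repeat_context_profile(v)
  expect_equal(prof$n_indels_in_runs, 1L)
  ## a substitution in non-repetitive context reports run 0
  g2 <- circular_genome("ACGTACGTACGTACGTACGT", id = "nr", circular = FALSE)
  m2 <- mutate_genome(g2, subs = 10L)
  v2 <- pairwise_variants(g2, m2$genome, min_identity = 0.9)
  expect_equal(v2$homopolymer_unit_run, 0L)
})

test_that("half of planted indels inside long runs are counted as repeat-context", {
  set.seed(9)
  ## build a reference alternating unique spacers with A-runs of length 6
  blocks <- character(0)
  run_pos <- integer(0)
  pos <- 0L
  for (k in 1:50) {
    sp <- random_seq(37, gc = 0.6)
    substr(sp, 37, 37) <- "C"
    blocks <- c(blocks, sp)
    pos <- pos + 37L
    blocks <- c(blocks, strrep("A", 6))
    run_pos <- c(run_pos, pos + 1L)
    pos <- pos + 6L
    blocks <- c(blocks, "G")
    pos <- pos + 1L
  }
  g <- circular_genome(paste(blocks, collapse = ""), id = "runs",
                       circular = FALSE)
  ## delete one A from 25 runs and one spacer base next to 25 other runs
  dels <- c(lapply(run_pos[1:25], function(p) c(p + 2L, 1L)),
            lapply(run_pos[26:50], function(p) c(p - 10L, 1L)))
  mut <- mutate_genome(g, dels = dels)
  v <- pairwise_variants(g, mut$genome)
  prof <- repeat_context_profile(v)
  expect_equal(prof$n_indels, 50L)
  expect_equal(prof$n_indels_in_runs, 25L)
})

test_that("divergent genomes are rejected with advice", {
  set.seed(12)
  a <- circular_genome(random_seq(3000), id = "a", circular = FALSE)
  b <- circular_genome(random_seq(3000), id = "b", circular = FALSE)
  expect_error(pairwise_variants(a, b), "identity|anchor")
})

test_that("variants serialise to minimal VCF", {
  g <- shared_sim$genome
  mut <- mutate_genome(g, subs = 5000L, dels = list(c(9000L, 2L)))
  v <- pairwise_variants(g, mut$genome, ann = shared_sim$ann)
  p <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, g, p)
  lines <- readLines(p)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(v))
  expect_true(all(grepl("CONTEXT=", body)))
})
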