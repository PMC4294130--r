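## End-to-end orchestration: one entry point wiring the analysis stages
## together with a serialisable config, logging and a checksummed manifest.

#' Build a run configuration
#'
#' @param subcommand one of `simulate`, `structure`, `repeats`, `compare`,
#'   `pairdiff`, `hetero`, `tree`.
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed for stages with randomness.
#' @param ... subcommand parameters: input paths (`fasta`, `gff3`,
#'   `fasta_b`, `gff3_b`, `ref`, `qry`, `pileups`, `sites`), thresholds
#'   (`maf_min`, `depth_min`, `indel_depth_min`, `min_ir_len`), alignment
#'   scores, `metric`, `outgroup_label`, `outgroup_divergence`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(subcommand, out_dir, seed = 1L, ...) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "structure", "repeats", "compare",
                            "pairdiff", "hetero", "tree"))
  cfg <- c(list(subcommand = subcommand, out_dir = out_dir,
                seed = as.integer(seed)), list(...))
  if (!is.null(cfg$maf_min) && (cfg$maf_min <= 0 || cfg$maf_min > 0.5)) {
    stop("invalid maf_min ", cfg$maf_min,
         ": a minor allele frequency cannot exceed 0.5")
  }
  if (!is.null(cfg$min_ir_len) && cfg$min_ir_len < 100) {
    stop("invalid min_ir_len: must be >= 100")
  }
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

#' Run one pipeline stage from a configuration
#'
#' Executes the configured subcommand, writes its outputs plus the
#' resolved configuration (`config.json`) into `out_dir`, and returns a
#' manifest listing every output with its MD5 checksum
#' (`manifest.json`). On error, partially written outputs are removed.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(cfg$out_dir, fname)
    writer(path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  need <- function(key) {
    v <- cfg[[key]]
    if (is.null(v)) stop("missing required input '", key, "' for ",
                         cfg$subcommand)
    if (is.character(v) && !all(file.exists(v))) {
      stop("input file not found: ", paste(v[!file.exists(v)], collapse = ", "))
    }
    v
  }
  log_msg("INFO", "subcommand=", cfg$subcommand, " seed=", cfg$seed)

  if (cfg$subcommand == "simulate") {
    sim <- simulate_genome(do.call(sim_genome_params,
                                   cfg$genome_params %||% list()),
                           seed = cfg$seed)
    fam <- simulate_strain_family(sim$genome, seed = cfg$seed)
    het <- simulate_heteroplasmy(sim$genome, fam$site_design,
                                 coverage = cfg$coverage %||% 100,
                                 error_rate = cfg$error_rate %||% 0.001,
                                 seed = cfg$seed)
    emit("genome.fa", function(p) write_fasta(sim$genome, p))
    emit("genome.gff3", function(p) write_gff3(sim$ann, p))
    for (s in names(het$pileups)) {
      local({
        ss <- s
        emit(paste0("pileup_", ss, ".tsv"),
             function(p) write_pileup_tsv(het$pileups[[ss]], p))
      })
    }
    emit("truth.json", function(p)
      write_sim_truth(list(genome = sim$truth, family = fam$truth), p))
  } else if (cfg$subcommand == "structure") {
    g <- read_fasta(need("fasta"))[[1]]
    ann <- if (!is.null(cfg$gff3)) read_gff3(need("gff3"), g) else NULL
    part <- detect_inverted_repeats(g, cfg$min_ir_len %||% 1000L)
    canon <- canonicalize(g, part, ann)
    report <- list(
      genome = g$id, length = g$length, flipped = canon$flipped,
      partition = list(lsc = canon$partition$lsc, ira = canon$partition$ira,
                       ssc = canon$partition$ssc, irb = canon$partition$irb,
                       ir_len = canon$partition$ir_len),
      junctions = if (!is.null(canon$annotation))
        junction_report(canon$partition, canon$annotation) else NULL)
    emit("structure.json", function(p)
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA))
  } else if (cfg$subcommand == "repeats") {
    g <- read_fasta(need("fasta"))[[1]]
    hits <- rbind(scan_ssrs(g), scan_long_repeats(g))
    if (!is.null(cfg$gff3)) {
      ann <- read_gff3(need("gff3"), g)
      hits <- annotate_repeats(hits, ann, g$length)
    }
    emit("repeats.tsv", function(p)
      utils::write.table(hits, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  } else if (cfg$subcommand == "compare") {
    ga <- read_fasta(need("fasta"))[[1]]
    gb <- read_fasta(need("fasta_b"))[[1]]
    aa <- read_gff3(need("gff3"), ga)
    ab <- read_gff3(need("gff3_b"), gb)
    part <- detect_inverted_repeats(ga, cfg$min_ir_len %||% 1000L)
    frags <- partition_orthologous_fragments(ga, aa, gb, ab, part_a = part)
    div <- region_diversity(frags)
    kaks <- gene_kaks_table(ga, aa, gb, ab)
    emit("diversity.tsv", function(p)
      utils::write.table(div, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("kaks_genes.tsv", function(p)
      utils::write.table(kaks, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  } else if (cfg$subcommand == "pairdiff") {
    ref <- read_fasta(need("ref"))[[1]]
    qry <- read_fasta(need("qry"))[[1]]
    ann <- if (!is.null(cfg$gff3)) read_gff3(need("gff3"), ref) else NULL
    vars <- pairwise_variants(ref, qry, ann)
    emit("variants.vcf", function(p) write_variants_vcf(vars, ref, p))
  } else if (cfg$subcommand == "hetero") {
    g <- read_fasta(need("fasta"))[[1]]
    ann <- read_gff3(need("gff3"), g)
    part <- detect_inverted_repeats(g, cfg$min_ir_len %||% 1000L)
    paths <- need("pileups")
    strains <- names(paths) %||%
      sub("\\.tsv$", "", sub("^pileup_", "", basename(paths)))
    site_lists <- stats::setNames(vector("list", length(paths)), strains)
    for (i in seq_along(paths)) {
      pp <- read_pileup_tsv(paths[i])
      sites <- call_minor_alleles(pp, maf_min = cfg$maf_min %||% 0.05,
                                  depth_min = cfg$depth_min %||% 10L,
                                  indel_depth_min = cfg$indel_depth_min %||% 5L,
                                  strain = strains[i])
      site_lists[[i]] <- classify_sites(sites, ann, part, g)
    }
    all_sites <- do.call(rbind, site_lists)
    emit("sites.tsv", function(p)
      utils::write.table(all_sites, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    tab2list <- function(t) as.list(stats::setNames(as.integer(t), names(t)))
    summaries <- lapply(site_lists, function(s) {
      su <- strain_summary(s, genome_length = g$length)
      su$breakdowns <- lapply(su$breakdowns, tab2list)
      su
    })
    ov <- if (length(site_lists) >= 2L) overlap_analysis(site_lists) else NULL
    emit("summary.json", function(p)
      jsonlite::write_json(
        list(thresholds = list(maf_min = cfg$maf_min %||% 0.05,
                               depth_min = cfg$depth_min %||% 10L,
                               indel_depth_min = cfg$indel_depth_min %||% 5L),
             strains = summaries,
             overlap = if (!is.null(ov))
               list(venn = as.list(ov$venn), shared_all = ov$shared_all)),
        p, auto_unbox = TRUE, digits = NA))
  } else if (cfg$subcommand == "tree") {
    tab <- utils::read.table(need("sites"), sep = "\t", header = TRUE,
                             colClasses = c(minor_allele = "character"))
    site_lists <- split(tab, tab$strain)
    m <- maf_matrix(site_lists)
    tr <- upgma(maf_distance(m, cfg$metric %||% "euclidean"))
    if (!is.null(cfg$outgroup_label)) {
      tr <- attach_outgroup(tr, cfg$outgroup_label,
                            need("outgroup_divergence"))
    }
    emit("tree.nwk", function(p) ape::write.tree(tr, file = p))
  }

  emit("config.json", function(p)
    jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  log_msg("INFO", "wrote ", nrow(manifest), " files to ", cfg$out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
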