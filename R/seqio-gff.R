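#' Construct a gene model
#'
#' Coordinates are 1-based inclusive. An exon whose `start > end` is taken
#' to wrap the circular origin.
#'
#' @param gene_id gene identifier (e.g. `"psbA"`).
#' @param type one of `"protein_coding"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), one row per exon, in
#'   ascending genome order.
#' @param copy_tag optional label distinguishing inverted-repeat duplicates
#'   (e.g. `"ira"`, `"irb"`).
#' @return object of class `cp_gene`.
#' @export
gene_model <- function(gene_id, type = c("protein_coding", "tRNA", "rRNA"),
                       strand = c("+", "-"), exons, copy_tag = NA_character_) {
  type <- match.arg(type)
  strand <- match.arg(strand)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  wrap <- exons[, 1] > exons[, 2]
  if (nrow(exons) > 1L) {
    ord <- order(exons[, 1])
    exons <- exons[ord, , drop = FALSE]
    wrap <- wrap[ord]
    body <- exons[!wrap, , drop = FALSE]
    if (nrow(body) > 1L &&
        any(body[-1L, 1] <= body[-nrow(body), 2])) {
      stop("gene ", gene_id, ": overlapping exons")
    }
  }
  structure(list(gene_id = as.character(gene_id), type = type,
                 strand = strand, exons = exons, wrap = wrap,
                 copy_tag = as.character(copy_tag)),
            class = "cp_gene")
}

gene_span <- function(gene) {
  c(start = min(gene$exons[, 1]), end = max(gene$exons[, 2]))
}

#' Construct an annotation
#'
#' @param genome_id identifier of the annotated genome.
#' @param genes list of [gene_model()] objects.
#' @param genome_length optional; when given, gene coordinates are
#'   validated against it.
#' @return object of class `cp_annotation`.
#' @export
annotation <- function(genome_id, genes, genome_length = NULL) {
  stopifnot(is.list(genes))
  keys <- vapply(genes, function(g) paste0(g$gene_id, "|", g$copy_tag),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate gene id (up to copy_tag): ", keys[duplicated(keys)][1])
  }
  if (!is.null(genome_length)) {
    for (g in genes) {
      if (any(g$exons < 1L) || any(g$exons > genome_length)) {
        stop("gene ", g$gene_id, ": coordinates outside [1, ",
             genome_length, "]")
      }
    }
  }
  structure(list(genome_id = as.character(genome_id), genes = genes),
            class = "cp_annotation")
}

#' @export
print.cp_annotation <- function(x, ...) {
  types <- vapply(x$genes, `[[`, character(1), "type")
  cat(sprintf("<cp_annotation> %s: %d genes (%d protein_coding, %d tRNA, %d rRNA)\n",
              x$genome_id, length(x$genes), sum(types == "protein_coding"),
              sum(types == "tRNA"), sum(types == "rRNA")))
  invisible(x)
}

#' Summarise gene content of an annotation
#'
#' Counts genes by type, distinguishing unique genes from
#' inverted-repeat duplicates (same `gene_id`, different copies), and
#' tallies multi-exon genes.
#'
#' @param object a `cp_annotation`.
#' @param ... unused.
#' @return data.frame with one row per gene type plus a `total` row.
#' @export
summary.cp_annotation <- function(object, ...) {
  types <- vapply(object$genes, `[[`, character(1), "type")
  ids <- vapply(object$genes, `[[`, character(1), "gene_id")
  nex <- vapply(object$genes, function(g) nrow(g$exons), integer(1))
  per_type <- function(keep) {
    data.frame(
      n_features = sum(keep),
      n_genes = length(unique(ids[keep])),
      n_duplicated = sum(table(ids[keep]) > 1L),
      n_multi_exon = length(unique(ids[keep & nex > 1L]))
    )
  }
  out <- do.call(rbind, lapply(
    c("protein_coding", "tRNA", "rRNA"),
    function(t) cbind(type = t, per_type(types == t))))
  rbind(out, cbind(type = "total", per_type(rep(TRUE, length(ids)))))
}

#' Read a GFF3 annotation
#'
#' Understands plain GFF3 with `gene` features carrying `ID`, optional
#' `Name` (gene symbol; falls back to `ID`), optional `biotype` /
#' `gene_biotype` and `copy_tag` attributes, and child `CDS` / `exon`
#' features linked by `Parent` (directly or through one intermediate
#' `mRNA` level). CDS features define the exons of protein-coding genes;
#' `exon` features define tRNA/rRNA gene bodies. Coordinates are 1-based
#' inclusive per the GFF3 standard.
#'
#' @param path GFF3 file.
#' @param genome a `cp_genome`; coordinates are validated against its
#'   length.
#' @return a [annotation()] object.
#' @export
read_gff3 <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) return(annotation(genome$id, list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    stop("malformed GFF3: expected 9 tab-separated fields, got ",
         nf[nf != 9L][1])
  }
  tab <- data.frame(
    type = vapply(parts, `[`, character(1), 3L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 4L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 5L))),
    strand = vapply(parts, `[`, character(1), 7L),
    attrs = vapply(parts, `[`, character(1), 9L),
    stringsAsFactors = FALSE
  )
  if (anyNA(tab$start) || anyNA(tab$end)) stop("malformed GFF3: non-numeric coordinates")
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  tab$ID <- attr_get(tab$attrs, "ID")
  tab$Parent <- attr_get(tab$attrs, "Parent")
  bad <- which(tab$start < 1L | tab$end > genome$length | tab$end < tab$start)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "GFF3 feature out of range (GFF3 is 1-based, genome length %d): %s %d..%d",
      genome$length, tab$type[b], tab$start[b], tab$end[b]))
  }
  ## resolve each feature's gene ancestor (<= one mRNA level)
  gene_rows <- which(tab$type == "gene")
  gene_of <- stats::setNames(tab$ID[gene_rows], tab$ID[gene_rows])
  mrna_rows <- which(tab$type %in% c("mRNA", "transcript"))
  for (i in mrna_rows) {
    if (!is.na(tab$Parent[i]) && tab$Parent[i] %in% names(gene_of)) {
      gene_of[tab$ID[i]] <- gene_of[[tab$Parent[i]]]
    }
  }
  genes <- list()
  for (i in gene_rows) {
    gid_uid <- tab$ID[i]
    name <- attr_get(tab$attrs[i], "Name")
    if (is.na(name)) name <- gid_uid
    biotype <- attr_get(tab$attrs[i], "biotype")
    if (is.na(biotype)) biotype <- attr_get(tab$attrs[i], "gene_biotype")
    copy_tag <- attr_get(tab$attrs[i], "copy_tag")
    kid <- which(tab$type %in% c("CDS", "exon") & !is.na(tab$Parent) &
                   tab$Parent %in% names(gene_of) &
                   unname(gene_of[tab$Parent]) == gid_uid)
    cds_kid <- kid[tab$type[kid] == "CDS"]
    exon_kid <- kid[tab$type[kid] == "exon"]
    if (is.na(biotype)) biotype <- "protein_coding"
    use <- if (biotype == "protein_coding" && length(cds_kid)) cds_kid
           else if (length(exon_kid)) exon_kid
           else if (length(cds_kid)) cds_kid
           else i
    genes[[length(genes) + 1L]] <- gene_model(
      gene_id = name, type = biotype, strand = tab$strand[i],
      exons = cbind(tab$start[use], tab$end[use]),
      copy_tag = if (is.na(copy_tag)) NA_character_ else copy_tag)
  }
  annotation(genome$id, genes, genome_length = genome$length)
}

#' Write an annotation to GFF3
#'
#' Emits the dialect [read_gff3()] reads back: one `gene` feature per gene
#' with `ID`, `Name`, `biotype` and (when set) `copy_tag` attributes, and
#' `CDS` (protein-coding) or `exon` (tRNA/rRNA) children.
#'
#' @param ann a `cp_annotation`.
#' @param path output file.
#' @param seqid sequence name for column 1; defaults to the annotation's
#'   genome id.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, seqid = ann$genome_id) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_along(ann$genes)) {
    g <- ann$genes[[k]]
    uid <- if (is.na(g$copy_tag)) g$gene_id else paste0(g$gene_id, "_", g$copy_tag)
    span <- gene_span(g)
    attrs <- sprintf("ID=%s;Name=%s;biotype=%s", uid, g$gene_id, g$type)
    if (!is.na(g$copy_tag)) attrs <- paste0(attrs, ";copy_tag=", g$copy_tag)
    writeLines(paste(seqid, "plastidpoly", "gene", span["start"], span["end"],
                     ".", g$strand, ".", attrs, sep = "\t"), con)
    child_type <- if (g$type == "protein_coding") "CDS" else "exon"
    for (e in seq_len(nrow(g$exons))) {
      writeLines(paste(seqid, "plastidpoly", child_type,
                       g$exons[e, 1], g$exons[e, 2], ".", g$strand,
                       if (child_type == "CDS") "0" else ".",
                       sprintf("ID=%s.%d;Parent=%s", uid, e, uid),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
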