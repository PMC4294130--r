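## Strain clustering from minor-allele-frequency profiles: MAF matrix,
## distances, UPGMA and outgroup attachment.

#' Build a strains x sites matrix of minor-allele frequencies
#'
#' Sites are keyed by (position, minor allele); a strain lacking a site
#' contributes MAF 0 there (absence of the minor allele). Site columns
#' that are zero everywhere are dropped.
#'
#' @param site_lists named list of `cp_sites`, one per strain.
#' @return numeric matrix of class `maf_matrix` (strains in rows, site
#'   keys in columns), values in `[0, 0.5]`.
#' @export
maf_matrix <- function(site_lists) {
  strains <- names(site_lists)
  if (is.null(strains)) stop("site_lists must be a named list")
  keys <- sort(unique(unlist(lapply(site_lists, site_keys))))
  m <- matrix(0, nrow = length(strains), ncol = length(keys),
              dimnames = list(strains, keys))
  for (s in strains) {
    k <- site_keys(site_lists[[s]])
    m[s, k] <- site_lists[[s]]$maf
  }
  if (any(m < 0 | m > 0.5)) stop("MAF values must lie in [0, 0.5]")
  m <- m[, colSums(m) > 0, drop = FALSE]
  class(m) <- c("maf_matrix", "matrix", "array")
  m
}

#' Distances between strain MAF profiles
#'
#' @param m a [maf_matrix()] (or any numeric matrix with strain rows).
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return a symmetric `dist` object over strains.
#' @export
maf_distance <- function(m, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2L) stop("need at least two strains")
  stats::dist(unclass(m), method = metric)
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters; the distance between clusters is
#' the arithmetic average over all member pairs (maintained by
#' size-weighted updates); a merge at distance d creates a node at height
#' d/2. Ties are broken deterministically by the lexicographically
#' smallest member label (then the second label). The result is
#' ultrametric by construction.
#'
#' @param d a `dist` or symmetric matrix with zero diagonal and labels.
#' @return an [ape::phylo] tree (rooted, ultrametric, binary); node
#'   heights recoverable from branch lengths.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (any(is.na(dm))) stop("NA/NaN in distance matrix")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (!isTRUE(all.equal(dm, t(dm)))) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 2L) stop("need at least two leaves")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ## active clusters: id (negative = leaf index, positive = merge index),
  ## size, smallest member label (for tie-breaks)
  active <- data.frame(id = -seq_len(n), size = 1L, lab = labels,
                       stringsAsFactors = FALSE)
  D <- dm
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- nrow(D)
    ## closest pair with deterministic lexicographic tie-break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cand_lab <- sort(c(active$lab[i], active$lab[j]))
        if (is.null(best) || D[i, j] < best$d - 1e-12 ||
            (abs(D[i, j] - best$d) <= 1e-12 &&
             (cand_lab[1] < best$lab[1] ||
              (cand_lab[1] == best$lab[1] && cand_lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = D[i, j], lab = cand_lab)
        }
      }
    }
    i <- best$i; j <- best$j
    merges[step, ] <- c(active$id[i], active$id[j])
    heights[step] <- best$d
    ## size-weighted (arithmetic over member pairs) distance update
    ni <- active$size[i]; nj <- active$size[j]
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    new_active <- rbind(
      active[keep, , drop = FALSE],
      data.frame(id = step, size = ni + nj,
                 lab = min(active$lab[i], active$lab[j]),
                 stringsAsFactors = FALSE))
    active <- new_active
  }
  hc <- structure(list(
    merge = t(vapply(seq_len(n - 1L), function(s) {
      v <- merges[s, ]
      ## hclust convention: negative = singleton, positive = earlier merge
      as.integer(v)
    }, integer(2))),
    height = heights, order = seq_len(n), labels = labels,
    method = "upgma"), class = "hclust")
  ## put leaves in a plottable order
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))
  tr <- ape::as.phylo(hc)   # node heights = merge height / 2 (UPGMA)
  tr
}

#' Node heights of an ultrametric tree
#'
#' @param tree a rooted ultrametric `phylo`.
#' @return root height (max leaf depth from root).
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Attach an outgroup above the root of an ultrametric tree
#'
#' The outgroup joins at height `divergence / 2`, preserving
#' ultrametricity.
#'
#' @param tree a rooted ultrametric `phylo` (the ingroup).
#' @param outgroup_label leaf label for the outgroup.
#' @param divergence distance between the outgroup and the ingroup; must
#'   exceed twice the ingroup root height.
#' @return a `phylo` with the outgroup attached.
#' @export
attach_outgroup <- function(tree, outgroup_label, divergence) {
  h <- tree_height(tree)
  if (divergence / 2 <= h) {
    stop("outgroup divergence/2 (", divergence / 2,
         ") must exceed the ingroup root height (", h, ")")
  }
  ing <- ape::write.tree(tree)
  ing <- sub(";$", "", ing)
  nwk <- sprintf("(%s:%.10g,%s:%.10g);", ing, divergence / 2 - h,
                 outgroup_label, divergence / 2)
  ape::read.tree(text = nwk)
}
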