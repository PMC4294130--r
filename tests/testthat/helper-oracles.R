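## Independent brute-force oracles used to validate the implementation.
## These deliberately re-derive each quantity by the most literal method
## available, sharing no code path with the package internals.

random_seq <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## exhaustive tandem-repeat scan: tests every (start, unit size) pair
oracle_tandem_scan <- function(seq, unit_sizes, min_copies, min_total,
                               mono_min_total = NULL) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  primitive <- function(unit) {
    u <- nchar(unit)
    if (u == 1L) return(TRUE)
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L &&
          paste(rep(substr(unit, 1, d), u / d), collapse = "") == unit) {
        return(FALSE)
      }
    }
    TRUE
  }
  hits <- list()
  for (u in unit_sizes) {
    mc <- if (u == 1L && !is.null(mono_min_total)) mono_min_total else min_copies
    mt <- if (u == 1L && !is.null(mono_min_total)) mono_min_total else min_total
    for (s in seq_len(n - 2L * u + 1L)) {
      unit <- substr(seq, s, s + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      ## tract-level left maximality: the perfect-match tract must start here
      if (s > 1L && s - 1L + u <= n && x[s - 1L] == x[s - 1L + u] &&
          x[s - 1L] != "N") next
      copies <- 1L
      while (s + (copies + 1L) * u - 1L <= n &&
             substr(seq, s + copies * u, s + (copies + 1L) * u - 1L) == unit) {
        copies <- copies + 1L
      }
      if (copies < mc || copies * u < mt) next
      if (!primitive(unit)) next
      hits[[length(hits) + 1L]] <- data.frame(
        unit = unit, copies = copies, start = s,
        end = s + copies * u - 1L, total_len = copies * u)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      total_len = integer(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, nchar(out$unit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## literal re-statement of the five read-QC rules
oracle_qc_reason <- function(bases, quals) {
  L <- nchar(bases)
  if (L == 0L) return("empty")
  q <- utf8ToInt(quals) - 33L
  if (length(grep("N", strsplit(bases, "")[[1]], fixed = TRUE)) > 0L) {
    return("rule_i")
  }
  if (sum(q < 10) / L > 0) return("rule_ii")
  if (sum(q < 15) / L > 0.03) return("rule_iii")
  if (sum(q < 20) / L > 0.05) return("rule_iv")
  if (sum(q) / L < 30) return("rule_v")
  "pass"
}

## longest inverted-repeat arm length in a linear sequence, by scanning
## every anti-diagonal of the complementarity matrix
oracle_longest_ir <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  cx <- chartr("ACGT", "TGCA", x)
  n <- length(x)
  best <- 0L
  for (cc in 3:(2L * n - 1L)) {
    imax <- min(n, cc - 1L)
    i <- seq_len(min(imax, floor((cc - 1L) / 2)))
    i <- i[cc - i <= n]
    if (length(i) == 0L) next
    m <- x[i] == cx[cc - i]
    r <- rle(m)
    if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
  }
  best
}

## NG86 by literal recursion: per-codon site fractions and depth-first
## pathway enumeration between differing codons
oracle_ng86 <- function(cds1, cds2, code = Biostrings::getGeneticCode("11")) {
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- codons(cds1); c2 <- codons(cds2)
  if (length(c1) > 1 && code[[c1[length(c1)]]] == "*" &&
      code[[c2[length(c2)]]] == "*") {
    c1 <- c1[-length(c1)]; c2 <- c2[-length(c2)]
  }
  syn_sites <- function(codon) {
    total <- 0
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, p, p)) next
        alt <- codon
        substr(alt, p, p) <- b
        if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) {
          total <- total + 1 / 3
        }
      }
    }
    total
  }
  ## depth-first enumeration of all orderings of the differing positions
  paths <- function(from, to) {
    d <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(d) == 0L) return(list(list(sd = 0, nd = 0)))
    out <- list()
    for (p in d) {
      step <- from
      substr(step, p, p) <- substr(to, p, p)
      if (code[[step]] == "*" && step != to) next
      for (rest in paths(step, to)) {
        syn <- code[[from]] == code[[step]]
        out[[length(out) + 1L]] <- list(sd = rest$sd + as.integer(syn),
                                        nd = rest$nd + as.integer(!syn))
      }
    }
    out
  }
  Ss <- (sum(vapply(c1, syn_sites, 0)) + sum(vapply(c2, syn_sites, 0))) / 2
  Sa <- 3 * length(c1) - Ss
  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    pw <- paths(c1[i], c2[i])
    if (length(pw) == 0L) {
      ## all pathways pass through a stop: enumerate ignoring the exclusion
      d <- which(strsplit(c1[i], "")[[1]] != strsplit(c2[i], "")[[1]])
      perms <- if (length(d) == 1) list(d) else
        if (length(d) == 2) list(d, rev(d)) else
          lapply(seq_len(6), function(k) {
            p <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                       c(3,2,1))[k, ]
            d[p]
          })
      pw <- lapply(perms, function(ord) {
        cur <- c1[i]; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2[i], p, p)
          if (code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        list(sd = sd, nd = nd)
      })
    }
    Sd <- Sd + mean(vapply(pw, `[[`, 0, "sd"))
    Nd <- Nd + mean(vapply(pw, `[[`, 0, "nd"))
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Sa = Sa, Ss = Ss, Na = Nd, Ns = Sd,
       Ka = jc(if (Sa > 0) Nd / Sa else 0),
       Ks = jc(if (Ss > 0) Sd / Ss else 0))
}

## column-by-column recount of substitution and comparable columns
oracle_nd_count <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  np <- 0L; ug <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("A", "C", "G", "T") && cb[i] %in% c("A", "C", "G", "T")) {
      ug <- ug + 1L
      if (ca[i] != cb[i]) np <- np + 1L
    }
  }
  c(np = np, ungapped = ug)
}

## a random ultrametric tree on k leaves: random merge order with strictly
## increasing heights; returns its cophenetic distance matrix and newick
random_ultrametric <- function(k, labels = LETTERS[seq_len(k)]) {
  heights <- sort(stats::runif(k - 1L, 0.5, 10))
  clusters <- as.list(labels)
  depth <- stats::setNames(rep(0, k), labels)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  nwk <- stats::setNames(labels, labels)
  key <- labels
  for (s in seq_len(k - 1L)) {
    pick <- sample(length(clusters), 2L)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    h <- heights[s]
    for (x in a) for (y in b) { D[x, y] <- 2 * h; D[y, x] <- 2 * h }
    ka <- paste(sort(a), collapse = ","); kb <- paste(sort(b), collapse = ",")
    ha <- max(depth[a]); hb <- max(depth[b])
    nk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[[ka]], h - ha, nwk[[kb]], h - hb)
    merged <- c(a, b)
    clusters <- c(clusters[-pick], list(merged))
    nwk[[paste(sort(merged), collapse = ",")]] <- nk
    depth[merged] <- h
  }
  list(D = D, newick = paste0(nwk[[paste(sort(labels), collapse = ",")]], ";"))
}
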