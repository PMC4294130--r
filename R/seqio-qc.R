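#' Quality-control filter for sequencing reads
#'
#' A read passes only if all five rules hold:
#' \enumerate{
#'   \item no `N` anywhere in the read;
#'   \item no base with quality < 10;
#'   \item at most 3\% of bases with quality < 15;
#'   \item at most 5\% of bases with quality < 20;
#'   \item mean base quality >= 30.
#' }
#' Rejected reads are tallied under the first rule they fail (checked in the
#' order above); zero-length reads are tallied separately as `"empty"`.
#'
#' @param rds a `cp_reads` object (see [reads()], [read_fastq()]).
#' @param q15_max,q20_max,mean_min rule thresholds, exposed for
#'   sensitivity analyses; defaults are the filter described above.
#' @return list with `pass` (a `cp_reads` of passing reads, input order
#'   preserved) and `rejected` (named integer vector of counts for
#'   `empty`, `rule_i` .. `rule_v`).
#' @export
qc_filter_reads <- function(rds, q15_max = 0.03, q20_max = 0.05,
                            mean_min = 30) {
  stopifnot(inherits(rds, "cp_reads"))
  n <- length(rds)
  reason <- character(n)
  for (i in seq_len(n)) {
    reason[i] <- qc_read_reason(rds$seq[i], phred_decode(rds$qual[i]),
                                q15_max, q20_max, mean_min)
  }
  keys <- c("empty", "rule_i", "rule_ii", "rule_iii", "rule_iv", "rule_v")
  rejected <- vapply(keys, function(k) sum(reason == k), integer(1))
  list(pass = rds[reason == "pass"], rejected = rejected)
}

qc_read_reason <- function(seq, q, q15_max, q20_max, mean_min) {
  L <- nchar(seq)
  if (L == 0L) return("empty")
  if (grepl("N", seq, fixed = TRUE)) return("rule_i")
  if (any(q < 10L)) return("rule_ii")
  if (sum(q < 15L) / L > q15_max) return("rule_iii")
  if (sum(q < 20L) / L > q20_max) return("rule_iv")
  if (mean(q) < mean_min) return("rule_v")
  "pass"
}
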