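#' Motif co-occurrence table
#'
#' Scans a sequence set with two PWMs and tabulates how many sequences carry
#' both, only one, or neither motif (per-sequence hit indicators from
#' [scanHits()]).
#'
#' @param pwmA,pwmB `MotifModel`s or W x 4 PWMs.
#' @param seqs Character vector or `DNAStringSet`.
#' @param hitFraction Hit threshold fraction (see [scanHits()]).
#' @return Named list of counts `nBoth`, `nAOnly`, `nBOnly`, `nNeither`
#'   (summing to `length(seqs)`).
#' @export
cooccurrenceTable <- function(pwmA, pwmB, seqs, hitFraction = 0.8) {
  ha <- scanHits(pwmA, seqs, hitFraction)$hit
  hb <- scanHits(pwmB, seqs, hitFraction)$hit
  list(nBoth = sum(ha & hb), nAOnly = sum(ha & !hb),
       nBOnly = sum(!ha & hb), nNeither = sum(!ha & !hb))
}

#' Reconstruct a co-occurrence table from printed marginals
#'
#' Given the universe size, the two single-motif totals and the shared
#' count, fills in the remaining 2x2 cells.
#'
#' @param total Number of scanned enhancers.
#' @param nA,nB Enhancers carrying motif A resp. B.
#' @param nBoth Enhancers carrying both.
#' @return Count list as in [cooccurrenceTable()].
#' @export
cooccurrenceFromMarginals <- function(total, nA, nB, nBoth) {
  tab <- list(nBoth = nBoth, nAOnly = nA - nBoth, nBOnly = nB - nBoth,
              nNeither = total - nA - nB + nBoth)
  if (any(unlist(tab) < 0)) stop("inconsistent marginals")
  tab
}

#' Fisher exact test on a co-occurrence table
#'
#' Two-sided Fisher exact test of association between the two motifs' hit
#' indicators; the odds ratio is the sample OR with Haldane correction when
#' any cell is zero. The test is direction-agnostic: an odds ratio below 1
#' means the motifs share sequences less often than independence predicts.
#'
#' @param tab Count list from [cooccurrenceTable()] (or a 2x2 matrix
#'   `rbind(c(both, aOnly), c(bOnly, neither))`).
#' @return List with `oddsRatio` and `p.value`.
#' @export
fisherCooccurrence <- function(tab) {
  m <- if (is.matrix(tab)) tab
       else matrix(c(tab$nBoth, tab$nBOnly, tab$nAOnly, tab$nNeither), 2, 2)
  if (any(m < 0)) stop("negative cell count")
  list(oddsRatio = .sampleOR(m),
       p.value = stats::fisher.test(m, alternative = "two.sided")$p.value)
}
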