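#' Read peak intervals from a BED/narrowPeak file
#'
#' Parses a tab-separated BED3+ or narrowPeak file into a `GRanges`. Input
#' coordinates are taken verbatim as 0-based half-open (the BED standard) and
#' converted to the 1-based closed convention `GRanges` uses; all exported
#' interval operations in this package round-trip through that conversion, so
#' callers thinking in BED coordinates get BED semantics.
#'
#' @param path Path to a BED3+/narrowPeak file.
#' @return A [GenomicRanges::GRanges] in file order; column 5, when present
#'   and numeric, is kept as a `score` metadata column, column 6 as strand.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t600", "chr1\t800\t900"), bed)
#' readPeakIntervals(bed)
#' @export
readPeakIntervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- idx[which(nf < 3)[1]]
    stop("malformed line ", bad, ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop("malformed line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("malformed line ", idx[bad[1]],
         ": requires 0 <= start < end, got [", start0[bad[1]], ", ",
         end0[bad[1]], ")")
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5
  if (any(has5)) {
    s <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[[`, character(1), 5L)))
    score[has5] <- s
  }
  strand <- rep("*", length(idx))
  has6 <- nf >= 6
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, character(1), 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand)
  gr$score <- score
  gr
}

#' Split candidate intervals by overlap with a mark
#'
#' Partitions open-chromatin candidates into those overlapping (by at least
#' one base, same chromosome) any interval of `marks` - the putative active
#' enhancers - and those that do not - the non-active enhancers.
#'
#' @param candidates,marks `GRanges` objects.
#' @return A list with elements `withMark` and `withoutMark`; their union is
#'   `candidates` and their intersection is empty.
#' @export
splitByOverlap <- function(candidates, marks) {
  if (length(marks) == 0) {
    return(list(withMark = candidates[0], withoutMark = candidates))
  }
  hit <- IRanges::overlapsAny(candidates, marks, minoverlap = 1L,
                              ignore.strand = TRUE)
  list(withMark = candidates[hit], withoutMark = candidates[!hit])
}

#' Remove intervals falling in promoter-proximal windows
#'
#' Drops any interval overlapping the window `[tss + upstream, tss + downstream)`
#' (BED coordinates) around a transcription start site on the + strand; for -
#' strand TSS the window is mirrored to `[tss - downstream, tss - upstream)` so
#' that "upstream" keeps its biological meaning. The default window is
#' (-1000, +100), the usual promoter-TSS annotation rule.
#'
#' @param intervals `GRanges` of candidate intervals.
#' @param tss `GRanges` of 1-bp TSS positions with strand (for wider ranges
#'   the 5' end is used: start on +, end on -).
#' @param window Length-2 numeric, offsets `(upstream, downstream)` in bp
#'   relative to the TSS, upstream < downstream.
#' @return The retained intervals, in input order.
#' @export
excludePromoters <- function(intervals, tss, window = c(-1000, 100)) {
  if (length(window) != 2 || window[1] >= window[2])
    stop("'window' must be (upstream, downstream) with upstream < downstream")
  if (length(tss) == 0) return(intervals)
  minus <- as.character(GenomicRanges::strand(tss)) == "-"
  # 0-based TSS position: 5' end of the feature
  t0 <- ifelse(minus, GenomicRanges::end(tss) - 1, GenomicRanges::start(tss) - 1)
  # BED window [t+up, t+down) on +, [t-down, t-up) on -
  ws <- ifelse(minus, t0 - window[2], t0 + window[1])
  we <- ifelse(minus, t0 - window[1], t0 + window[2])
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(tss),
    ranges = IRanges::IRanges(start = pmax(ws, 0) + 1, end = we))
  hit <- IRanges::overlapsAny(intervals, win, minoverlap = 1L,
                              ignore.strand = TRUE)
  intervals[!hit]
}

#' Centre intervals and fix their length
#'
#' Replaces each interval by the fixed-length window around its centre: in
#' BED coordinates the centre is `c = floor((start + end) / 2)` and the output
#' is `[c - floor(N/2), c + ceiling(N/2))`, so even N splits symmetrically and
#' odd N puts the extra base downstream. Intervals that would extend past
#' chromosome bounds (when `seqlengths` are available, or past position 0) are
#' dropped with a warning.
#'
#' @param intervals `GRanges`.
#' @param N Target length in bp (> 0).
#' @return `GRanges` of width-N intervals; idempotent for fixed N.
#' @export
centerFixLength <- function(intervals, N) {
  if (!is.numeric(N) || length(N) != 1 || N <= 0 || N != floor(N))
    stop("target length N must be a positive integer")
  N <- as.integer(N)
  if (length(intervals) == 0) return(intervals)
  start0 <- GenomicRanges::start(intervals) - 1
  end0 <- GenomicRanges::end(intervals)
  ctr <- (start0 + end0) %/% 2
  ns0 <- ctr - N %/% 2
  ne0 <- ctr + as.integer(ceiling(N / 2))
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(intervals),
    ranges = IRanges::IRanges(start = ns0 + 1, end = ne0),
    strand = GenomicRanges::strand(intervals))
  S4Vectors::mcols(out) <- S4Vectors::mcols(intervals)
  sl <- GenomeInfoDb::seqlengths(intervals)
  lim <- sl[as.character(GenomicRanges::seqnames(out))]
  oob <- ns0 < 0 | (!is.na(lim) & ne0 > lim)
  if (any(oob)) {
    warning(sum(oob), " interval(s) dropped: fixed-length window out of bounds")
    out <- out[!oob]
  }
  out
}

#' Filter candidate intervals by mean signal
#'
#' Convenience surrogate for an upstream enhancer-prediction step: keeps
#' candidates whose coverage-weighted mean signal, read from a bedGraph
#' track, exceeds a threshold. This is a simple heuristic stand-in, not a
#' trained enhancer predictor; use it only when no predicted candidate set
#' is available.
#'
#' @param candidates `GRanges` of candidate intervals.
#' @param bedgraph Path to a 4-column bedGraph (chrom, start, end, value;
#'   BED coordinates).
#' @param threshold Minimum mean signal over the interval (uncovered bases
#'   count as 0).
#' @return The retained candidates, in input order, with a `meanSignal`
#'   metadata column.
#' @export
filterBySignal <- function(candidates, bedgraph, threshold) {
  if (!file.exists(bedgraph)) stop("file not found: ", bedgraph)
  df <- utils::read.table(bedgraph, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  track <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1, end = df$end),
    value = df$value)
  hits <- GenomicRanges::findOverlaps(candidates, track,
                                      ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(candidates[S4Vectors::queryHits(hits)],
                                  track[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  contrib <- GenomicRanges::width(ov) *
    track$value[S4Vectors::subjectHits(hits)]
  total <- numeric(length(candidates))
  agg <- rowsum(contrib, S4Vectors::queryHits(hits))
  total[as.integer(rownames(agg))] <- agg[, 1]
  meanSig <- total / GenomicRanges::width(candidates)
  out <- candidates[meanSig > threshold]
  out$meanSignal <- meanSig[meanSig > threshold]
  out
}

#' Brute-force overlap oracle
#'
#' Quadratic all-pairs overlap check used as an independent oracle for
#' [splitByOverlap()] in tests. Not exported.
#' @noRd
.overlapBruteForce <- function(candidates, marks) {
  n <- length(candidates)
  hit <- logical(n)
  cs <- as.character(GenomicRanges::seqnames(candidates))
  ms <- as.character(GenomicRanges::seqnames(marks))
  c1 <- GenomicRanges::start(candidates); c2 <- GenomicRanges::end(candidates)
  m1 <- GenomicRanges::start(marks); m2 <- GenomicRanges::end(marks)
  for (i in seq_len(n)) {
    for (j in seq_along(marks)) {
      if (cs[i] == ms[j] && c1[i] <= m2[j] && m1[j] <= c2[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}
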