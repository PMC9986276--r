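#' Construct an EnhancerSet
#'
#' @param positive,negative DNA sequences of the active (label 1) and
#'   non-active (label 0) classes: `DNAStringSet` or character vectors.
#' @param posRanges,negRanges Optional `GRanges` provenance, parallel to the
#'   two sequence sets.
#' @return An [EnhancerSet-class].
#' @export
enhancerSet <- function(positive, negative,
                        posRanges = NULL, negRanges = NULL) {
  pos <- Biostrings::DNAStringSet(positive)
  neg <- Biostrings::DNAStringSet(negative)
  if (length(pos) && is.null(names(pos)))
    names(pos) <- paste0("pos", seq_along(pos))
  if (length(neg) && is.null(names(neg)))
    names(neg) <- paste0("neg", seq_along(neg))
  rng <- GenomicRanges::GRanges()
  if (!is.null(posRanges) && !is.null(negRanges))
    rng <- suppressWarnings(c(posRanges, negRanges))
  new("EnhancerSet",
      seqs = c(pos, neg),
      label = c(rep(1L, length(pos)), rep(0L, length(neg))),
      ranges = rng)
}

#' @describeIn enhancerSet Sequences of the set.
#' @param x An `EnhancerSet`.
#' @export
setMethod("sequences", "EnhancerSet", function(x) x@seqs)

#' @describeIn enhancerSet Binary labels of the set.
#' @export
setMethod("enhancerLabels", "EnhancerSet", function(x) x@label)

#' Positive (active) subset of an EnhancerSet
#' @param x An `EnhancerSet`.
#' @return `DNAStringSet` of the label-1 sequences.
#' @export
positiveSet <- function(x) x@seqs[x@label == 1L]

#' Negative (non-active) subset of an EnhancerSet
#' @param x An `EnhancerSet`.
#' @return `DNAStringSet` of the label-0 sequences.
#' @export
negativeSet <- function(x) x@seqs[x@label == 0L]

#' Extract interval sequences from a genome
#'
#' Fetches the uppercased sequence of each interval from a genome and drops
#' examples whose fraction of N bases exceeds `maxNFraction` (default 0: any N
#' disqualifies, since N cannot be one-hot encoded).
#'
#' @param intervals `GRanges` of equal or varying width.
#' @param genome A named `DNAStringSet`, or the path to a FASTA file.
#' @param label Binary label to attach (0 or 1), kept in the result.
#' @param maxNFraction Tolerated fraction of N bases per sequence.
#' @return A list with `seqs` (`DNAStringSet`, names `chrom:start-end|label`
#'   in BED coordinates), `label`, and the retained `intervals`.
#' @export
extractSequences <- function(intervals, genome, label = 1L,
                             maxNFraction = 0) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("'genome' must be a DNAStringSet or FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome not in genome: ", paste(missing, collapse = ", "))
  st <- GenomicRanges::start(intervals)
  en <- GenomicRanges::end(intervals)
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(st < 1 | en > lens))
    stop("interval out of chromosome bounds")
  out <- Biostrings::DNAStringSet(vapply(seq_along(intervals), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[chrom[i]]], st[i], en[i])))
  }, character(1)))
  names(out) <- sprintf("%s:%d-%d|%d", chrom, st - 1, en, label)
  nf <- Biostrings::letterFrequency(out, "N", as.prob = TRUE)[, 1]
  drop <- nf > maxNFraction + 1e-12
  if (any(drop))
    message(sum(drop), " sequence(s) dropped for N fraction > ", maxNFraction)
  list(seqs = out[!drop], label = rep(as.integer(label), sum(!drop)),
       intervals = intervals[!drop])
}

#' GC fraction of sequences
#'
#' `(#G + #C) / (length excluding N)` per sequence; `NA` when a sequence is
#' all N.
#'
#' @param x Character vector or `DNAStringSet`.
#' @return Numeric vector in `[0, 1]` (or `NA`).
#' @examples
#' gcFraction(c("GGCC", "ATAT", "ACGT"))
#' @export
gcFraction <- function(x) {
  xs <- Biostrings::DNAStringSet(x)
  if (any(Biostrings::width(xs) == 0)) stop("empty sequence")
  fr <- Biostrings::letterFrequency(xs, c("GC", "N"))
  denom <- Biostrings::width(xs) - fr[, "N"]
  unname(ifelse(denom == 0, NA_real_, fr[, "G|C"] / denom))
}

#' Compare GC composition of two sequence sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-sequence GC
#' fractions of two unpaired sets, the appropriate rank-based two-sample test
#' for sets of different sizes.
#'
#' @param setA,setB Character vectors or `DNAStringSet`s (>= 2 sequences each).
#' @return List with `statistic` (rank-sum W) and `p.value`.
#' @export
compareGC <- function(setA, setB) {
  ga <- gcFraction(setA)
  gb <- gcFraction(setB)
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  if (length(ga) < 2 || length(gb) < 2)
    stop("each set needs at least 2 sequences with defined GC")
  wt <- stats::wilcox.test(ga, gb, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Write an EnhancerSet as a FASTA pair plus manifest
#'
#' Writes `positive.fa`, `negative.fa` and a `manifest.tsv` with per-example
#' name, label and GC fraction.
#'
#' @param x An `EnhancerSet`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
writeEnhancerSet <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  posF <- file.path(dir, "positive.fa")
  negF <- file.path(dir, "negative.fa")
  Biostrings::writeXStringSet(positiveSet(x), posF)
  Biostrings::writeXStringSet(negativeSet(x), negF)
  man <- data.frame(name = names(x@seqs), label = x@label,
                    gc = round(gcFraction(x@seqs), 6))
  manF <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manF, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(positive = posF, negative = negF, manifest = manF))
}

#' Read an EnhancerSet from a FASTA pair
#'
#' @param positiveFa,negativeFa FASTA paths for the two classes.
#' @return An [EnhancerSet-class].
#' @export
readEnhancerSet <- function(positiveFa, negativeFa) {
  enhancerSet(Biostrings::readDNAStringSet(positiveFa),
              Biostrings::readDNAStringSet(negativeFa))
}
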