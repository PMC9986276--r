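#' Random background sequences
#'
#' I.i.d. (order-0) bases with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`; deterministic per seed.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc Background GC fraction in (0, 1).
#' @param seed RNG seed.
#' @return Character vector of sequences.
#' @export
randomBackground <- function(n, length, gc = 0.5, seed = 1L) {
  stopifnot(n >= 0, length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(sample(BASES, n * length, replace = TRUE, prob = prob),
              n, length)
  apply(m, 1, paste, collapse = "")
}

.sampleInstance <- function(motif) {
  if (is.character(motif)) return(motif)
  pwm <- .asPWM(motif)
  paste(vapply(seq_len(nrow(pwm)), function(j)
    sample(BASES, 1, prob = pwm[j, ]), character(1)), collapse = "")
}

#' Implant motif instances into sequences
#'
#' A Bernoulli(`frequency`) subset of the sequences receives one instance of
#' the motif (the consensus string, or a sample from a PWM) at a uniformly
#' random position, overwriting the background so lengths stay fixed. The
#' truth manifest records which sequence, where, and what was written.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param motif Consensus string, `MotifModel`, or W x 4 PWM.
#' @param frequency Implantation probability per sequence in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `seqs` (modified vector) and `manifest` (data frame
#'   `index`, `position` (1-based start), `instance`).
#' @export
implantMotif <- function(seqs, motif, frequency = 1, seed = 1L) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  wm <- if (is.character(motif)) nchar(motif) else nrow(.asPWM(motif))
  if (wm >= L) stop("motif too wide for the sequences")
  set.seed(seed)
  pick <- which(stats::runif(length(seqs)) < frequency)
  if (!length(pick))
    return(list(seqs = seqs,
                manifest = data.frame(index = integer(), position = integer(),
                                      instance = character())))
  pos <- sample.int(L - wm + 1L, length(pick), replace = TRUE)
  inst <- vapply(seq_along(pick), function(i) .sampleInstance(motif),
                 character(1))
  for (i in seq_along(pick)) {
    substr(seqs[pick[i]], pos[i], pos[i] + wm - 1L) <- inst[i]
  }
  list(seqs = seqs,
       manifest = data.frame(index = pick, position = pos, instance = inst))
}

#' Simulate the enhancer classification study set
#'
#' Generates the benchmark the classifier is trained on: positives at higher
#' background GC than negatives (0.55 vs 0.45, mirroring the GC-content
#' difference between active and non-active enhancers), with an ASCL1-like
#' E-box consensus (CAGCTGC) implanted in a fraction of the positives.
#'
#' @param nPos,nNeg Set sizes (default 2000 each).
#' @param length Sequence length in bp (default 200).
#' @param gcPos,gcNeg Background GC of the two classes.
#' @param motif Implanted consensus (default "CAGCTGC").
#' @param frequency Implantation frequency among positives (default 0.4).
#' @param seed RNG seed.
#' @return List with `set` (an [EnhancerSet-class]) and `manifest`.
#' @export
simulateEnhancerStudy <- function(nPos = 2000L, nNeg = 2000L, length = 200L,
                                  gcPos = 0.55, gcNeg = 0.45,
                                  motif = "CAGCTGC", frequency = 0.4,
                                  seed = 1L) {
  pos <- randomBackground(nPos, length, gcPos, seed = seed)
  neg <- randomBackground(nNeg, length, gcNeg, seed = seed + 1L)
  imp <- implantMotif(pos, motif, frequency, seed = seed + 2L)
  list(set = enhancerSet(imp$seqs, neg), manifest = imp$manifest)
}

#' Simulate the two-motif AND (cooperative) task
#'
#' A task whose signal is motif co-occurrence rather than motif content:
#' every positive carries one instance each of motifs A and B; every negative
#' carries two instances of a single motif (A for half the negatives, B for
#' the other half). Per-motif expected instance counts are thereby equal in
#' both classes, so a linear scanner carries no signal while presence-AND
#' remains learnable.
#'
#' @param nPos,nNeg Set sizes.
#' @param length Sequence length in bp.
#' @param gc Shared background GC.
#' @param motifA,motifB Consensus strings (defaults CAGCTGC, CCTTTGT).
#' @param seed RNG seed.
#' @return An [EnhancerSet-class].
#' @export
simulateCooperativeStudy <- function(nPos = 2000L, nNeg = 2000L,
                                     length = 200L, gc = 0.5,
                                     motifA = "CAGCTGC", motifB = "CCTTTGT",
                                     seed = 1L) {
  half <- length %/% 2L
  implantAt <- function(seqs, motif, lo, hi, seed) {
    set.seed(seed)
    w <- nchar(motif)
    pos <- lo + sample.int(hi - w - lo + 1L, length(seqs),
                           replace = TRUE) - 1L
    for (i in seq_along(seqs)) substr(seqs[i], pos[i], pos[i] + w - 1L) <- motif
    seqs
  }
  pos <- randomBackground(nPos, length, gc, seed = seed)
  pos <- implantAt(pos, motifA, 1L, half, seed + 10L)
  pos <- implantAt(pos, motifB, half + 1L, length, seed + 11L)
  neg <- randomBackground(nNeg, length, gc, seed = seed + 1L)
  aIdx <- seq_len(nNeg) <= nNeg / 2
  negA <- neg[aIdx]; negB <- neg[!aIdx]
  negA <- implantAt(negA, motifA, 1L, half, seed + 12L)
  negA <- implantAt(negA, motifA, half + 1L, length, seed + 13L)
  negB <- implantAt(negB, motifB, 1L, half, seed + 14L)
  negB <- implantAt(negB, motifB, half + 1L, length, seed + 15L)
  enhancerSet(pos, c(negA, negB))
}

#' Write a toy genome with planted peaks
#'
#' Builds one toy chromosome and plants candidate open-chromatin peaks, a
#' chosen subset of overlapping H3K27ac mark peaks, and TSS positions whose
#' promoter windows cover a chosen subset of candidates, so the dataset
#' builder reproduces known active/non-active/promoter counts. Writes
#' `genome.fa`, `candidates.bed`, `marks.bed`, `tss.bed` and returns the
#' ground truth.
#'
#' @param dir Output directory.
#' @param nCandidates Number of candidate peaks.
#' @param nActive How many candidates get an overlapping mark peak.
#' @param nPromoter How many candidates fall inside a promoter-TSS window.
#' @param peakWidth Candidate peak width in bp.
#' @param spacing Distance between candidate peak starts in bp.
#' @param seed RNG seed (background sequence).
#' @return List with file paths and the truth counts
#'   (`nActive`, `nNonActive`, `nPromoter`, candidate index sets).
#' @export
makeToyGenome <- function(dir, nCandidates = 10L, nActive = 4L,
                          nPromoter = 0L, peakWidth = 600L, spacing = 2000L,
                          seed = 1L) {
  stopifnot(nActive <= nCandidates, nPromoter <= nCandidates)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chromLen <- (nCandidates + 1L) * spacing
  genome <- randomBackground(1, chromLen, 0.5, seed = seed)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(structure(genome, names = "chrT")), fa)
  starts <- spacing * seq_len(nCandidates) - peakWidth %/% 2L  # 0-based
  cand <- data.frame(chrom = "chrT", start = starts,
                     end = starts + peakWidth)
  activeIdx <- seq_len(nActive)
  promoterIdx <- if (nPromoter) nCandidates - seq_len(nPromoter) + 1L
                 else integer()
  marks <- data.frame(chrom = "chrT",
                      start = cand$start[activeIdx] + peakWidth %/% 4L,
                      end = cand$end[activeIdx] + peakWidth %/% 4L)
  # a TSS 200 bp downstream of the peak end puts the peak inside (-1000,+100)
  tss <- if (length(promoterIdx))
    data.frame(chrom = "chrT", start = cand$end[promoterIdx] + 200L,
               end = cand$end[promoterIdx] + 201L,
               name = paste0("gene", seq_along(promoterIdx)),
               score = 0L, strand = "+")
  else data.frame()
  writeBed <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  candF <- file.path(dir, "candidates.bed"); writeBed(cand, candF)
  markF <- file.path(dir, "marks.bed")
  if (nrow(marks)) writeBed(marks, markF) else file.create(markF)
  tssF <- file.path(dir, "tss.bed")
  if (nrow(tss)) writeBed(tss, tssF) else file.create(tssF)
  list(genome = fa, candidates = candF, marks = markF, tss = tssF,
       chromLen = chromLen,
       truth = list(nActive = nActive, nNonActive = nCandidates - nActive,
                    nPromoter = nPromoter, activeIdx = activeIdx,
                    promoterIdx = promoterIdx))
}

#' Toy staged expression table
#'
#' Eight TFs whose motifs the discovery pipeline can surface, with staged
#' expression patterns: the active-set TFs (ASCL1, NHLH1, SOX4, SOX11) and
#' most non-active-set TFs (ZEB1, NEUROG2, NR2F1) rise at least 2-fold into
#' Day 26 and do not rise after; CTCF is high and flat across all three
#' stages and therefore fails the 2-fold rule; decoys cover flat, falling and
#' late-rising patterns.
#'
#' @return Data frame with columns `tf`, `day0`, `day26`, `day39`.
#' @export
makeExpressionFixture <- function() {
  data.frame(
    tf = c("ASCL1", "NHLH1", "SOX4", "SOX11", "ZEB1", "NEUROG2", "NR2F1",
           "CTCF", "DECOY_FLAT", "DECOY_DOWN", "DECOY_LATE"),
    day0 = c(5, 4, 10, 8, 6, 3, 7, 95, 10, 40, 5),
    day26 = c(40, 22, 55, 30, 28, 18, 25, 100, 10, 15, 8),
    day39 = c(30, 20, 50, 22, 25, 12, 20, 98, 10, 5, 60),
    stringsAsFactors = FALSE)
}

.consensusToPWM <- function(cons, p = 0.85, jitter = 0) {
  codes <- .seqToCodes(cons)
  pwm <- matrix(0, length(codes), 4, dimnames = list(NULL, BASES))
  for (j in seq_along(codes)) {
    rem <- (1 - p) * (1 / 3 + stats::runif(3, -jitter, jitter))
    pwm[j, -codes[j]] <- rem
    pwm[j, codes[j]] <- p
    pwm[j, ] <- pwm[j, ] / sum(pwm[j, ])
  }
  pwm
}

#' Toy known-motif database
#'
#' PWMs for the eight TFs of [makeExpressionFixture()] built from their
#' consensus binding sites at moderate per-position stringency, plus random
#' decoy motifs. Off-consensus probability mass is lightly jittered (seeded)
#' so that, as in curated databases, no two columns are exactly collinear.
#' Serves as the TOMTOM-style target database in tests and pipelines.
#'
#' @param nDecoys Number of random decoy PWMs (default 50).
#' @param p Consensus base probability per position (default 0.85, about
#'   1.15 bits: informative but far from stringent).
#' @param jitter Relative jitter of the off-consensus mass (default 0.05).
#' @param seed RNG seed for jitter and decoys.
#' @return A [MotifSet-class] named by TF.
#' @export
toyMotifDatabase <- function(nDecoys = 50L, p = 0.85, jitter = 0.05,
                             seed = 1L) {
  cons <- c(ASCL1 = "CAGCTGC", NHLH1 = "CAGCTGT", SOX4 = "CCTTTGT",
            SOX11 = "CCTTTGTC", ZEB1 = "CCAGGTG", NEUROG2 = "GTCATATG",
            CTCF = "CCAGGGGGCGA", NR2F1 = "GAGGTCAA")
  set.seed(seed)
  motifs <- lapply(cons, .consensusToPWM, p = p, jitter = jitter)
  for (i in seq_len(nDecoys)) {
    w <- sample(6:10, 1)
    motifs[[paste0("DECOY", i)]] <-
      .consensusToPWM(paste(sample(BASES, w, replace = TRUE), collapse = ""),
                      p = p, jitter = jitter)
  }
  ms <- lapply(names(motifs), function(nm) {
    pwm <- motifs[[nm]]
    new("MotifModel", pwm = pwm, importanceScore = 0, nSeqlets = 0L,
        consensus = paste(BASES[max.col(pwm, ties.method = "first")],
                          collapse = ""),
        ledger = list())
  })
  names(ms) <- names(motifs)
  new("MotifSet", motifs = ms)
}
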