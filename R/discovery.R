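.windowSums <- function(v, W) {
  cs <- cumsum(c(0, v))
  cs[(W + 1):length(cs)] - cs[1:(length(cs) - W)]
}

.revcompMat <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1),
                             drop = FALSE]

#' Extract high-attribution seqlets
#'
#' Scores every sliding window of width `W` by its summed importance and
#' keeps windows whose absolute score exceeds the given percentile of a
#' per-sequence permutation null: the sequence's importance values are
#' randomly permuted (`nPerm` times, fixed seed) and the window scores of
#' the permuted tracks form that sequence's null. A per-sequence null
#' separates sharply localised attribution (motifs) from diffusely elevated
#' tracks (e.g. composition signal), which a pooled null would flood.
#' Overlapping keepers within one sequence are resolved greedily by
#' descending absolute score, so returned seqlets never share a base.
#'
#' @param attr An [AttributionSet-class].
#' @param W Window width in bp (default 15; must not exceed sequence length).
#' @param percentile Null percentile for the keep threshold (default 99).
#' @param nPerm Permutations per sequence for the null (default 5).
#' @param seed Seed for the permutation null.
#' @return List of seqlets; each is a list with `idx` (source example),
#'   `start`, `end` (0-based half-open within the sequence), `score` (signed
#'   summed importance), `onehot` and `hyp` (W x 4 slices).
#' @export
extractSeqlets <- function(attr, W = 15L, percentile = 99, nPerm = 5L,
                           seed = 1L) {
  W <- as.integer(W)
  L <- nchar(attr@seqs[1])
  if (W > L) stop("window width W (", W, ") exceeds sequence length (", L, ")")
  n <- length(attr@seqs)
  imps <- lapply(attr@importance, rowSums)
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    v <- imps[[i]]
    nullScores <- unlist(lapply(seq_len(nPerm), function(p)
      abs(.windowSums(sample(v), W))))
    thr <- stats::quantile(nullScores, percentile / 100, names = FALSE)
    ws <- .windowSums(v, W)
    keep <- which(abs(ws) > thr)
    if (!length(keep)) next
    keep <- keep[order(abs(ws[keep]), decreasing = TRUE)]
    taken <- logical(L)
    oh <- oneHotEncode(attr@seqs[i])
    for (p in keep) {
      span <- p:(p + W - 1L)
      if (any(taken[span])) next
      taken[span] <- TRUE
      out[[length(out) + 1L]] <- list(
        idx = i, start = p - 1L, end = p - 1L + W, score = ws[p],
        onehot = oh[span, , drop = FALSE],
        hyp = attr@hypothetical[[i]][span, , drop = FALSE])
    }
  }
  out
}

#' Partition seqlets by importance sign
#'
#' Positive-score seqlets come from the active-set direction, negative from
#' the non-active direction; exact zeros are discarded.
#'
#' @param seqlets List of seqlets from [extractSeqlets()].
#' @return List with elements `positive` and `negative`.
#' @export
partitionBySign <- function(seqlets) {
  sc <- vapply(seqlets, `[[`, numeric(1), "score")
  list(positive = seqlets[sc > 0], negative = seqlets[sc < 0])
}

# best ungapped alignment of member matrix `m` against centroid matrix `cen`
# over offsets with >= minOverlap column overlap, both orientations.
# Returns list(r, offset, rc).
.bestAlign <- function(m, cen, minOverlap = 0.7) {
  W <- nrow(cen); Wm <- nrow(m)
  minCols <- max(2L, as.integer(ceiling(minOverlap * min(W, Wm))))
  best <- list(r = -Inf, offset = 0L, rc = FALSE)
  for (rc in c(FALSE, TRUE)) {
    mm <- if (rc) .revcompMat(m) else m
    for (o in seq(-(Wm - minCols), W - minCols)) {
      i1 <- max(1L, 1L - o); i2 <- min(Wm, W - o)
      if (i2 - i1 + 1L < minCols) next
      a <- as.vector(mm[i1:i2, , drop = FALSE])
      b <- as.vector(cen[(i1 + o):(i2 + o), , drop = FALSE])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(a, b)
      if (r > best$r) best <- list(r = r, offset = as.integer(o), rc = rc)
    }
  }
  best
}

#' Greedy centroid clustering of same-sign seqlets
#'
#' Processes seqlets by descending absolute score. Each seqlet's hypothetical
#' slice is compared to every existing centroid by best-offset Pearson
#' correlation (offsets allowing at least 70% column overlap; the reverse
#' complement of the slice is also tried and, if it wins, the slice is stored
#' complemented). The seqlet joins the best centroid when the correlation
#' reaches `corThreshold`, else founds a new cluster. Centroids are running
#' means of aligned member hypothetical slices.
#'
#' @param seqlets Seqlets of one sign.
#' @param corThreshold Joining threshold (default 0.7).
#' @param minOverlap Minimum column-overlap fraction for alignment offsets.
#' @return List of clusters; each has `centroid` (W x 4), `n`, and `members`
#'   (each member holding oriented `onehot`/`hyp` slices, `offset`, `score`,
#'   `idx`).
#' @export
clusterSeqlets <- function(seqlets, corThreshold = 0.7, minOverlap = 0.7) {
  if (!length(seqlets)) return(list())
  sc <- vapply(seqlets, `[[`, numeric(1), "score")
  ord <- order(abs(sc), decreasing = TRUE)
  clusters <- list()
  for (i in ord) {
    s <- seqlets[[i]]
    bestC <- 0L; bestA <- list(r = -Inf)
    for (ci in seq_along(clusters)) {
      al <- .bestAlign(s$hyp, clusters[[ci]]$centroid, minOverlap)
      if (al$r > bestA$r) { bestA <- al; bestC <- ci }
    }
    if (bestC > 0L && bestA$r >= corThreshold) {
      cl <- clusters[[bestC]]
      hyp <- if (bestA$rc) .revcompMat(s$hyp) else s$hyp
      oh <- if (bestA$rc) .revcompMat(s$onehot) else s$onehot
      member <- list(idx = s$idx, offset = bestA$offset, rc = bestA$rc,
                     score = s$score, onehot = oh, hyp = hyp)
      cl$members[[length(cl$members) + 1L]] <- member
      # running mean over the columns the member covers in the centroid frame
      W <- nrow(cl$centroid); Wm <- nrow(hyp)
      i1 <- max(1L, 1L - bestA$offset); i2 <- min(Wm, W - bestA$offset)
      rows <- (i1 + bestA$offset):(i2 + bestA$offset)
      cnt <- cl$count
      cnt[rows] <- cnt[rows] + 1
      cl$centroid[rows, ] <- cl$centroid[rows, ] +
        (hyp[i1:i2, , drop = FALSE] - cl$centroid[rows, , drop = FALSE]) /
        cnt[rows]
      cl$count <- cnt
      cl$n <- cl$n + 1L
      clusters[[bestC]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <- list(
        centroid = s$hyp, count = rep(1, nrow(s$hyp)), n = 1L,
        members = list(list(idx = s$idx, offset = 0L, rc = FALSE,
                            score = s$score, onehot = s$onehot, hyp = s$hyp)))
    }
  }
  clusters
}

#' Build a PWM motif from a seqlet cluster
#'
#' Members are aligned at their joining offsets; the PWM is the column-wise
#' base frequency of the aligned one-hot slices with a pseudocount (split
#' evenly over the four bases), renormalised per column. Columns covered by
#' fewer than `minCoverage` of the members are dropped from both flanks, so
#' a stray far-offset member cannot widen the motif with single-seqlet
#' columns (which would carry spuriously high information content). The
#' motif importance score is the mean member summed importance; its sign
#' marks the enriched set (positive = active set).
#'
#' @param cluster A cluster from [clusterSeqlets()].
#' @param pseudocount Total pseudocount per column (default 0.5).
#' @param minCoverage Minimum fraction of members a flank column must be
#'   covered by to be kept (default 0.5; has no effect on single-member or
#'   zero-offset clusters).
#' @return A [MotifModel-class].
#' @export
buildMotif <- function(cluster, pseudocount = 0.5, minCoverage = 0.5) {
  if (!length(cluster$members)) stop("empty cluster")
  offs <- vapply(cluster$members, `[[`, integer(1), "offset")
  wid <- vapply(cluster$members, function(m) nrow(m$onehot), integer(1))
  lo <- min(offs)
  hi <- max(offs + wid)
  width <- hi - lo
  counts <- matrix(0, width, 4, dimnames = list(NULL, BASES))
  cov <- numeric(width)
  for (m in cluster$members) {
    rows <- (m$offset - lo + 1L):(m$offset - lo + nrow(m$onehot))
    counts[rows, ] <- counts[rows, ] + m$onehot
    cov[rows] <- cov[rows] + 1
  }
  need <- max(1, ceiling(minCoverage * length(cluster$members)))
  ok <- which(cov >= need)
  if (length(ok)) {
    keep <- min(ok):max(ok)
    counts <- counts[keep, , drop = FALSE]
    cov <- cov[keep]
  }
  denom <- cov + pseudocount
  pwm <- (counts + pseudocount / 4) / denom
  if (any(denom == 0)) pwm[denom == 0, ] <- 0.25
  sc <- vapply(cluster$members, `[[`, numeric(1), "score")
  new("MotifModel", pwm = pwm,
      importanceScore = mean(sc),
      nSeqlets = length(cluster$members),
      consensus = paste(BASES[max.col(pwm, ties.method = "first")],
                        collapse = ""),
      ledger = list(memberIdx = vapply(cluster$members,
                                       function(m) as.integer(m$idx),
                                       integer(1)),
                    offsets = offs))
}

#' Discover signed motifs from attribution tracks
#'
#' The full aggregation pipeline: seqlet extraction, sign partitioning,
#' greedy clustering per sign, and PWM building. Motifs are ordered within
#' each sign by descending member count (positive-sign motifs first).
#'
#' @param attr An [AttributionSet-class].
#' @param W Seqlet window width.
#' @param percentile Seqlet extraction percentile.
#' @param nPerm Permutations per sequence for the extraction null.
#' @param corThreshold Clustering correlation threshold.
#' @param pseudocount PWM pseudocount.
#' @param minSeqlets Drop clusters with fewer members (default 2).
#' @param seed Seed for the extraction null.
#' @return A [MotifSet-class].
#' @export
discoverMotifs <- function(attr, W = 15L, percentile = 99, nPerm = 5L,
                           corThreshold = 0.7, pseudocount = 0.5,
                           minSeqlets = 2L, seed = 1L) {
  seqlets <- extractSeqlets(attr, W = W, percentile = percentile,
                            nPerm = nPerm, seed = seed)
  parts <- partitionBySign(seqlets)
  motifs <- list()
  for (sgn in c("positive", "negative")) {
    cls <- clusterSeqlets(parts[[sgn]], corThreshold = corThreshold)
    if (!length(cls)) next
    ms <- lapply(cls, buildMotif, pseudocount = pseudocount)
    ms <- ms[vapply(ms, function(m) m@nSeqlets >= minSeqlets, logical(1))]
    if (!length(ms)) next
    ms <- ms[order(vapply(ms, function(m) m@nSeqlets, integer(1)),
                   decreasing = TRUE)]
    motifs <- c(motifs, ms)
  }
  if (length(motifs)) names(motifs) <- paste0("motif", seq_along(motifs))
  new("MotifSet", motifs = motifs)
}
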