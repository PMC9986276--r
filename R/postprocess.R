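.asPWM <- function(x) {
  if (methods::is(x, "MotifModel")) x@pwm else x
}

#' Information content of a PWM column
#'
#' `IC = 2 + sum_i p_i log2 p_i` (with `0 log 0 = 0`), in bits: 0 for a
#' uniform column, 2 for a deterministic one.
#'
#' @param p Probability 4-vector (entries >= 0, summing to 1 within 1e-6).
#' @return IC in bits, in `[0, 2]`.
#' @examples
#' columnIC(c(0.25, 0.25, 0.25, 0.25))  # 0
#' columnIC(c(1, 0, 0, 0))              # 2
#' columnIC(c(0.5, 0.5, 0, 0))          # 1
#' @export
columnIC <- function(p) {
  if (length(p) != 4 || any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("'p' must be a probability 4-vector summing to 1")
  terms <- ifelse(p > 0, p * log2(p), 0)
  2 + sum(terms)
}

#' Per-position information content of a PWM
#' @param pwm W x 4 probability matrix (rows are positions) or `MotifModel`.
#' @return Numeric vector of per-position IC in bits.
#' @export
positionIC <- function(pwm) {
  pwm <- .asPWM(pwm)
  apply(pwm, 1, columnIC)
}

#' Trim uninformative motif flanks
#'
#' The first position (from either side) with information content above the
#' threshold delimits the motif; everything outside is removed. With no
#' position above threshold the motif is empty and flagged degenerate.
#'
#' @param motif A `MotifModel` or W x 4 PWM matrix.
#' @param threshold IC threshold in bits (default 0.3).
#' @return For a matrix input, a list with `pwm`, `start`, `end` (1-based
#'   inclusive kept range; `NA` when degenerate) and `degenerate`. For a
#'   `MotifModel`, the trimmed model with trim offsets in its ledger.
#' @export
trimMotif <- function(motif, threshold = 0.3) {
  pwm <- .asPWM(motif)
  ic <- positionIC(pwm)
  above <- which(ic > threshold)
  if (!length(above)) {
    res <- list(pwm = pwm[0, , drop = FALSE], start = NA_integer_,
                end = NA_integer_, degenerate = TRUE)
  } else {
    res <- list(pwm = pwm[min(above):max(above), , drop = FALSE],
                start = min(above), end = max(above), degenerate = FALSE)
  }
  if (!methods::is(motif, "MotifModel")) return(res)
  out <- motif
  out@pwm <- res$pwm
  out@consensus <- if (nrow(res$pwm))
    paste(BASES[max.col(res$pwm, ties.method = "first")], collapse = "")
  else ""
  out@ledger$trim <- res[c("start", "end", "degenerate")]
  methods::validObject(out)
  out
}

#' Fraction of stringent motif positions
#'
#' A stringent position has IC above 1.9 bits (nearly deterministic); true TF
#' motifs are rarely stringent throughout, so a high fraction flags an
#' artefact.
#'
#' @param pwm `MotifModel` or W x 4 PWM.
#' @param threshold Stringency IC threshold in bits (default 1.9).
#' @return Fraction of positions with IC above the threshold.
#' @export
stringentFraction <- function(pwm, threshold = 1.9) {
  ic <- positionIC(pwm)
  if (!length(ic)) stop("empty PWM")
  mean(ic > threshold)
}

# standardized motif columns for fast pairwise Pearson: returns a 4 x W
# matrix Z with crossprod(Z[,i], Z2[,j]) == cor(col_i, col_j); zero-variance
# columns map to zero vectors (contributing 0) and are flagged.
.stdCols <- function(pwm) {
  M <- t(pwm)  # 4 x W
  mu <- colMeans(M)
  Z <- sweep(M, 2, mu)
  ss <- sqrt(colSums(Z^2))
  degen <- ss < 1e-12
  ss[degen] <- 1
  Z <- sweep(Z, 2, ss, "/")
  Z[, degen] <- 0
  list(Z = Z, degen = degen)
}

# all permutations of 1..n as rows (n small)
.allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[as.vector(sub)], nrow(sub), n - 1L))
  }))
}

# permutation null for the similarity test: enumerate the full column
# permutation group when it is no larger than the requested sample (exact
# test), otherwise sample with replacement.
.similarityPerms <- function(wq, nShuffles) {
  if (factorial(wq) <= nShuffles) {
    list(perms = .allPerms(wq), exact = TRUE)
  } else {
    list(perms = t(replicate(nShuffles, sample(wq))), exact = FALSE)
  }
}

# alignment candidates between query width wq and target width wt:
# offset o places query column i on target column i + o; >= 2 overlapping
# columns required.
.alignOffsets <- function(wq, wt) {
  offs <- seq(-(wq - 2L), wt - 2L)
  lapply(offs, function(o) {
    i1 <- max(1L, 1L - o); i2 <- min(wq, wt - o)
    if (i2 - i1 + 1L < 2L) return(NULL)
    list(offset = o, q = i1:i2, t = (i1:i2) + o)
  })
}

#' Ungapped similarity of two motifs
#'
#' Scans all ungapped offsets in both orientations (>= 2 overlapping
#' columns); the score at an offset is the mean per-query-column Pearson
#' correlation of the aligned probability columns, with query columns
#' outside the overlap contributing zero (i.e. the summed column correlation
#' divided by the query width). Normalising by the query width rather than
#' the overlap keeps short chance alignments from saturating the score,
#' which would otherwise degenerate the permutation null. The p-value comes
#' from a null of column-shuffled queries (fixed seed) scored the same way.
#' Zero-variance (uniform) columns contribute 0 and set the degenerate flag.
#' For short queries whose full column-permutation group is no larger than
#' `nShuffles`, the null is enumerated exactly instead of sampled.
#' Ties in the best score are broken towards larger overlap, then smaller
#' |offset|, then the forward orientation.
#'
#' @param query,target `MotifModel`s or W x 4 PWMs (width >= 2).
#' @param nShuffles Size of the column-permutation null (default 1000).
#' @param seed Seed for the null.
#' @return List with `score`, `offset`, `orientation` (`"+"`/`"-"`),
#'   `overlap` (overlapping columns / query width), `p.value`, `degenerate`.
#' @export
motifSimilarity <- function(query, target, nShuffles = 1000L, seed = 1L) {
  q <- .asPWM(query); t <- .asPWM(target)
  if (nrow(q) < 2 || nrow(t) < 2) stop("both motifs need width >= 2")
  set.seed(seed)
  pp <- .similarityPerms(nrow(q), nShuffles)
  .similarityCore(q, t, pp$perms, exact = pp$exact)
}

.similarityCore <- function(q, t, perms, exact = FALSE) {
  wq <- nrow(q); wt <- nrow(t)
  zq <- .stdCols(q)
  best <- list(score = -Inf, offset = 0L, orientation = "+", overlap = 0,
               degenerate = FALSE)
  nullBest <- rep(-Inf, nrow(perms))
  for (ori in c("+", "-")) {
    tt <- if (ori == "-") .revcompMat(t) else t
    zt <- .stdCols(tt)
    C <- crossprod(zq$Z, zt$Z)  # wq x wt column correlations
    for (al in .alignOffsets(wq, wt)) {
      if (is.null(al)) next
      m <- length(al$q)
      obs <- sum(C[cbind(al$q, al$t)]) / wq
      better <- obs > best$score + 1e-12 ||
        (abs(obs - best$score) <= 1e-12 &&
           (m > best$overlap * wq + 1e-9 ||
              (abs(m - best$overlap * wq) <= 1e-9 &&
                 abs(al$offset) < abs(best$offset))))
      if (better)
        best <- list(score = obs, offset = al$offset, orientation = ori,
                     overlap = m / wq,
                     degenerate = any(zq$degen[al$q]) || any(zt$degen[al$t]))
      if (nrow(perms)) {
        idx <- perms[, al$q, drop = FALSE] + wq * rep(al$t - 1L, each = nrow(perms))
        nullBest <- pmax(nullBest,
                         rowSums(matrix(C[as.vector(idx)],
                                        nrow(perms), m)) / wq)
      }
    }
  }
  nGE <- sum(nullBest >= best$score - 1e-12)
  best$p.value <- if (!nrow(perms)) NA_real_
                  else if (exact) nGE / nrow(perms)
                  else (1 + nGE) / (nrow(perms) + 1)
  best
}

#' Match a motif against a known-motif database
#'
#' Runs [motifSimilarity()] against every database entry (sharing one set of
#' column permutations for the null), corrects p-values to q-values by
#' Benjamini-Hochberg across the database, and ranks ascending by q.
#'
#' @param query `MotifModel` or PWM.
#' @param db A [MotifSet-class] with TF names.
#' @param nShuffles Column-permutation null size (default 2000, chosen so the
#'   smallest attainable p-value resolves q < 0.05 under BH across databases
#'   of ~50 entries).
#' @param seed Seed for the null.
#' @return Data frame with one row per database entry: `tf`, `score`,
#'   `offset`, `orientation`, `overlap`, `p.value`, `q.value`, `degenerate`,
#'   ordered by increasing q (ties by p, then decreasing score).
#' @export
matchKnown <- function(query, db, nShuffles = 2000L, seed = 1L) {
  if (!length(db)) stop("empty motif database")
  q <- .asPWM(query)
  if (nrow(q) < 2) stop("query motif needs width >= 2")
  set.seed(seed)
  pp <- .similarityPerms(nrow(q), nShuffles)
  rows <- lapply(seq_along(db@motifs), function(i) {
    hit <- .similarityCore(q, .asPWM(db@motifs[[i]]), pp$perms,
                           exact = pp$exact)
    data.frame(tf = names(db@motifs)[i], score = hit$score,
               offset = hit$offset, orientation = hit$orientation,
               overlap = hit$overlap, p.value = hit$p.value,
               degenerate = hit$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q.value <- stats::p.adjust(out$p.value, method = "BH")
  out <- out[order(out$q.value, out$p.value, -out$score), ]
  rownames(out) <- NULL
  out
}

#' Scan sequences for PWM hits
#'
#' Scores every window on both strands by log2 odds against a uniform 0.25
#' background; a sequence is a hit when its best window reaches
#' `hitFraction` of the PWM's maximum achievable log-odds score. PWM entries
#' are floored at 1e-6 before taking logs.
#'
#' @param pwm `MotifModel` or W x 4 PWM (width <= sequence length).
#' @param seqs Character vector or `DNAStringSet` of equal-length sequences.
#' @param hitFraction Fraction of the maximum log-odds that counts as a hit
#'   (default 0.8).
#' @return List with `hit` (logical per sequence), `best` (best window score
#'   per sequence), `threshold`, and `maxScore`.
#' @export
scanHits <- function(pwm, seqs, hitFraction = 0.8) {
  pwm <- .asPWM(pwm)
  codes <- .codesMatrix(seqs)
  w <- nrow(pwm); L <- ncol(codes); n <- nrow(codes)
  if (w > L) stop("PWM width (", w, ") exceeds sequence length (", L, ")")
  lo <- log2(pmax(pwm, 1e-6) / 0.25)
  maxScore <- sum(apply(lo, 1, max))
  thr <- hitFraction * maxScore
  P <- L - w + 1L
  bestOf <- function(lom) {
    sc <- matrix(0, n, P)
    for (j in seq_len(w)) {
      sc <- sc + matrix(lom[j, codes[, j:(j + P - 1L), drop = FALSE]], n, P)
    }
    sc[cbind(seq_len(n), max.col(sc, ties.method = "first"))]
  }
  bf <- bestOf(lo)
  br <- bestOf(.revcompMat(lo))
  best <- pmax(bf, br)
  list(hit = best >= thr - 1e-9, best = best, threshold = thr,
       maxScore = maxScore)
}

#' Motif enrichment between two sequence sets
#'
#' Builds the hit/no-hit by positive/negative 2x2 table from [scanHits()]
#' and applies the two-sided Fisher exact test. The odds ratio is the sample
#' OR, with the Haldane 0.5 correction when any cell is zero.
#'
#' @param pwm `MotifModel` or PWM.
#' @param positives,negatives Sequence sets (character or `DNAStringSet`).
#' @param hitFraction Hit threshold fraction (see [scanHits()]).
#' @return List with `table` (2x2 matrix), `oddsRatio`, `p.value`.
#' @export
enrichmentTest <- function(pwm, positives, negatives, hitFraction = 0.8) {
  hp <- scanHits(pwm, positives, hitFraction)$hit
  hn <- scanHits(pwm, negatives, hitFraction)$hit
  tab <- matrix(c(sum(hp), sum(!hp), sum(hn), sum(!hn)), 2, 2,
                dimnames = list(c("hit", "nohit"),
                                c("positive", "negative")))
  list(table = tab, oddsRatio = .sampleOR(tab),
       p.value = stats::fisher.test(tab)$p.value)
}

.sampleOR <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Transcription status of a TF from staged expression
#'
#' A TF counts as transcribed in progenitors when its expression rises at
#' least `fold`-fold from Day 0 to Day 26 and does not rise from Day 26 to
#' Day 39. A pseudocount guards the ratio against zero baselines.
#'
#' @param tf TF name (must be present in `table`).
#' @param table Expression table: data frame with columns `tf`, `day0`,
#'   `day26`, `day39` (or row names as TF names).
#' @param fold Required fold change (default 2).
#' @param eps Pseudocount in expression units (default 1).
#' @return List with `transcribed`, `foldUp` ((day26+eps)/(day0+eps)), and
#'   the Day 26 -> Day 39 direction check `nonIncreasing`.
#' @export
expressionStatus <- function(tf, table, fold = 2, eps = 1) {
  if ("tf" %in% names(table)) {
    i <- match(tf, table$tf)
  } else {
    i <- match(tf, rownames(table))
  }
  if (is.na(i)) stop("TF not found in expression table: ", tf)
  d0 <- table$day0[i]; d26 <- table$day26[i]; d39 <- table$day39[i]
  foldUp <- (d26 + eps) / (d0 + eps)
  nonInc <- d39 <= d26
  list(transcribed = foldUp >= fold && nonInc, foldUp = foldUp,
       nonIncreasing = nonInc)
}

#' Seven-criterion spurious-motif filter
#'
#' Evaluates a trimmed motif against the filter ledger: (1) composition bias
#' - the fraction of positions whose preferred base is G/C must be below
#' `biasMax`, and likewise for A/T; (2) trimmed length above 4; (3) stringent
#' positions (IC > 1.9) below 75%; (4) correspondence to a known TF - best
#' database match with similarity score at least `matchScoreMin`; (5) best
#' match aligns with overlap of at least 70% of the query; (6) best match
#' q-value below 0.05; (7) the matched TF passes the 2-fold expression rule.
#' Overall pass is the conjunction of all seven.
#'
#' @param motif `MotifModel` or PWM (trimmed; untrimmed motifs are trimmed
#'   first).
#' @param db Known-motif [MotifSet-class].
#' @param expr Expression table (see [expressionStatus()]).
#' @param biasMax Criterion-1 bound (default 0.8).
#' @param minLength Criterion-2 bound (default 4, exclusive).
#' @param stringentMax Criterion-3 bound (default 0.75).
#' @param matchScoreMin Criterion-4 similarity score bound (default 0.5).
#' @param overlapMin Criterion-5 bound (default 0.7).
#' @param qMax Criterion-6 bound (default 0.05).
#' @param nShuffles,seed Similarity null parameters (see [matchKnown()]).
#' @return A one-row data frame with measured values, the seven pass flags
#'   (`pass1` ... `pass7`) and `pass` (their conjunction).
#' @export
applyFilters <- function(motif, db, expr, biasMax = 0.8, minLength = 4L,
                         stringentMax = 0.75, matchScoreMin = 0.5,
                         overlapMin = 0.7, qMax = 0.05,
                         nShuffles = 2000L, seed = 1L) {
  pwm <- trimMotif(.asPWM(motif))$pwm  # idempotent on already-trimmed input
  len <- nrow(pwm)
  if (len == 0) {
    bias <- c(gc = NA_real_, at = NA_real_)
    stringent <- NA_real_
  } else {
    am <- max.col(pwm, ties.method = "first")
    bias <- c(gc = mean(am %in% c(2, 3)), at = mean(am %in% c(1, 4)))
    stringent <- stringentFraction(pwm)
  }
  canMatch <- len >= 2
  if (canMatch) {
    matches <- matchKnown(pwm, db, nShuffles = nShuffles, seed = seed)
    best <- matches[1, ]
  } else {
    best <- data.frame(tf = NA_character_, score = NA_real_,
                       overlap = NA_real_, q.value = NA_real_)
  }
  exprOk <- FALSE; foldUp <- NA_real_
  if (canMatch && !is.na(best$tf) &&
      (("tf" %in% names(expr) && best$tf %in% expr$tf) ||
         best$tf %in% rownames(expr))) {
    es <- expressionStatus(best$tf, expr)
    exprOk <- es$transcribed
    foldUp <- es$foldUp
  }
  pass1 <- !anyNA(bias) && bias["gc"] < biasMax && bias["at"] < biasMax
  pass2 <- len > minLength
  pass3 <- !is.na(stringent) && stringent < stringentMax
  pass4 <- canMatch && !is.na(best$score) && best$score >= matchScoreMin
  pass5 <- canMatch && !is.na(best$overlap) && best$overlap >= overlapMin
  pass6 <- canMatch && !is.na(best$q.value) && best$q.value < qMax
  pass7 <- exprOk
  data.frame(
    length = len, biasGC = unname(bias["gc"]), biasAT = unname(bias["at"]),
    stringent = stringent, bestTF = if (canMatch) best$tf else NA_character_,
    bestScore = if (canMatch) best$score else NA_real_,
    bestOverlap = if (canMatch) best$overlap else NA_real_,
    bestQ = if (canMatch) best$q.value else NA_real_,
    foldUp = foldUp,
    pass1 = pass1, pass2 = pass2, pass3 = pass3, pass4 = pass4,
    pass5 = pass5, pass6 = pass6, pass7 = pass7,
    pass = pass1 && pass2 && pass3 && pass4 && pass5 && pass6 && pass7,
    stringsAsFactors = FALSE)
}

#' Vet a set of motifs
#'
#' Trims every motif and applies the seven-criterion filter, returning one
#' verdict row per motif.
#'
#' @param motifs A [MotifSet-class].
#' @param db Known-motif database ([MotifSet-class]).
#' @param expr Expression table.
#' @param ... Passed to [applyFilters()].
#' @return Data frame of verdicts, row-named by motif.
#' @export
vetMotifs <- function(motifs, db, expr, ...) {
  rows <- lapply(seq_along(motifs@motifs), function(i)
    applyFilters(motifs@motifs[[i]], db, expr, ...))
  out <- do.call(rbind, rows)
  rownames(out) <- names(motifs@motifs)
  out
}
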