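# shared fixture builders; everything is generated in code, seeded.

BASES4 <- c("A", "C", "G", "T")

codesOf <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], BASES4)

# consensus -> PWM with per-position dominant probabilities and a small
# jitter on the off-consensus mass (so no two columns are exactly collinear)
pwmFrom <- function(cons, ps, jitter = 0.03, seed = 7) {
  set.seed(seed)
  codes <- codesOf(cons)
  if (length(ps) == 1) ps <- rep(ps, length(codes))
  pwm <- matrix(0, length(codes), 4, dimnames = list(NULL, BASES4))
  for (j in seq_along(codes)) {
    rem <- (1 - ps[j]) * (1 / 3 + stats::runif(3, -jitter, jitter))
    pwm[j, -codes[j]] <- rem
    pwm[j, codes[j]] <- ps[j]
    pwm[j, ] <- pwm[j, ] / sum(pwm[j, ])
  }
  pwm
}

# random PWM with rows summing to 1
randomPWM <- function(w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(w * 4), w, 4, dimnames = list(NULL, BASES4))
  m / rowSums(m)
}

mkDB <- function(pwms) {
  ms <- lapply(names(pwms), function(nm)
    new("MotifModel", pwm = pwms[[nm]], importanceScore = 0, nSeqlets = 0L,
        consensus = "", ledger = list()))
  names(ms) <- names(pwms)
  new("MotifSet", motifs = ms)
}

# target weakly but consistently similar to a consensus query: the query's
# base is only slightly elevated, the rest of the mass is spread unevenly
weakTarget <- function(cons, pMatch = 0.30, seed = 30) {
  set.seed(seed)
  codes <- codesOf(cons)
  pwm <- matrix(0, length(codes), 4, dimnames = list(NULL, BASES4))
  for (j in seq_along(codes)) {
    rest <- stats::runif(3, 0.2, 1)
    pwm[j, -codes[j]] <- (1 - pMatch) * rest / sum(rest)
    pwm[j, codes[j]] <- pMatch
  }
  pwm
}

randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 5000,
                            maxWidth = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(start = st, end = st + w))
}

writeTempBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# both-ends information-content trim oracle
trimOracle <- function(pwm, threshold = 0.3) {
  ic <- apply(pwm, 1, function(p) {
    t <- ifelse(p > 0, p * log2(p), 0)
    2 + sum(t)
  })
  i <- 1
  while (i <= nrow(pwm) && ic[i] <= threshold) i <- i + 1
  j <- nrow(pwm)
  while (j >= 1 && ic[j] <= threshold) j <- j - 1
  if (i > j) return(NULL)
  c(start = i, end = j)
}

# two-sided Fisher p by hypergeometric enumeration
fisherOracle <- function(a, b, c, d) {
  r <- a + b; s <- c + d; k <- a + c; n <- r + s
  xs <- max(0, k - s):min(r, k)
  dens <- stats::dhyper(xs, r, s, k)
  sum(dens[dens <= stats::dhyper(a, r, s, k) * (1 + 1e-7)])
}

# brute-force PWM scan oracle: best log2-odds window over both strands
scanOracle <- function(pwm, seq) {
  lo <- log2(pmax(pwm, 1e-6) / 0.25)
  codes <- codesOf(seq)
  w <- nrow(pwm)
  rc <- lo[rev(seq_len(w)), c(4, 3, 2, 1)]
  best <- -Inf
  for (p in 1:(length(codes) - w + 1)) {
    win <- codes[p:(p + w - 1)]
    sF <- sum(lo[cbind(seq_len(w), win)])
    sR <- sum(rc[cbind(seq_len(w), win)])
    best <- max(best, sF, sR)
  }
  best
}

# matched-GC study set shared by the model-based tests
tinyStudySet <- function() {
  simulateEnhancerStudy(nPos = 300, nNeg = 300, length = 100,
                        gcPos = 0.5, gcNeg = 0.5, frequency = 0.8,
                        seed = 77)
}

# small trained model cache for attribution tests (built once per run)
tinyTrainedModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tinyStudySet()
      hp <- cnnHyperparams(nFilters = 16, kernelSize = 8, denseUnits = 16,
                           maxEpochs = 40, patience = 12, seed = 77)
      cache <<- trainCNN(sim$set, hp, nRestarts = 2)
    }
    cache
  }
})
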