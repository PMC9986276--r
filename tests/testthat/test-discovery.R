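# hand-built AttributionSet: importance spikes where we plant them,
# hypotheticals proportional to a chosen pattern
mkAttr <- function(seqs, spikes, pattern = NULL) {
  L <- nchar(seqs[1])
  imp <- list(); hyp <- list()
  for (i in seq_along(seqs)) {
    oh <- oneHotEncode(seqs[i])
    v <- rep(0, L)
    for (sp in spikes[[i]]) v[sp$at:(sp$at + sp$w - 1)] <- sp$h
    imp[[i]] <- oh * v
    hyp[[i]] <- if (is.null(pattern)) matrix(v, L, 4) * 0.75
                else pattern[[i]]
  }
  new("AttributionSet", seqs = seqs, importance = imp, hypothetical = hyp,
      predictions = rep(0.5, length(seqs)), gaps = rep(0, length(seqs)),
      nSteps = 64L, baseline = "uniform")
}

test_that("seqlet extraction finds planted spikes and nothing in silence", {
  seqs <- randomBackground(3, 80, seed = 1)
  # all-zero attributions -> zero seqlets
  quiet <- mkAttr(seqs, list(list(), list(), list()))
  expect_length(extractSeqlets(quiet, W = 15), 0)

  # one spike at positions 50-56 -> exactly one seqlet covering it
  att <- mkAttr(seqs, list(list(list(at = 50, w = 7, h = 1)), list(), list()))
  sl <- extractSeqlets(att, W = 15, seed = 2)
  expect_length(sl, 1)
  expect_equal(sl[[1]]$idx, 1L)
  expect_lte(sl[[1]]$start, 49)   # 0-based window containing 49..55
  expect_gte(sl[[1]]$end, 56)
  expect_equal(sl[[1]]$end - sl[[1]]$start, 15)
  expect_gt(sl[[1]]$score, 0)
  expect_error(extractSeqlets(att, W = 100), "exceeds")
})

test_that("seqlets within a sequence never overlap", {
  seqs <- randomBackground(10, 120, seed = 3)
  spikes <- lapply(1:10, function(i)
    list(list(at = 10, w = 7, h = 2), list(at = 40, w = 7, h = 1.5),
         list(at = 90, w = 7, h = -2)))
  sl <- extractSeqlets(mkAttr(seqs, spikes), W = 15, seed = 4)
  expect_gt(length(sl), 0)
  byIdx <- split(sl, vapply(sl, `[[`, integer(1), "idx"))
  for (g in byIdx) {
    spans <- lapply(g, function(s) (s$start + 1):s$end)
    expect_equal(length(unlist(spans)), length(unique(unlist(spans))))
  }
})

test_that("sign partitioning is a true partition that drops zeros", {
  sl <- list(list(score = 3), list(score = -2), list(score = 1),
             list(score = 0))
  parts <- partitionBySign(sl)
  expect_length(parts$positive, 2)
  expect_length(parts$negative, 1)
  expect_equal(length(parts$positive) + length(parts$negative), 3)
  allPos <- partitionBySign(sl[c(1, 3)])
  expect_length(allPos$negative, 0)
})

test_that("clustering groups identical seqlets and separates distinct motifs", {
  oh <- oneHotEncode(paste0("CAGCTGC", "ACGTACGT"))
  s1 <- list(idx = 1L, start = 0L, end = 15L, score = 2,
             onehot = oh, hyp = oh * 0.5 + 0.01)
  s2 <- s1; s2$idx <- 2L
  cl <- clusterSeqlets(list(s1, s2))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n, 2L)

  # one seqlet -> one singleton cluster
  expect_length(clusterSeqlets(list(s1)), 1)

  # two disjoint implanted motifs end up in different clusters
  mk <- function(motif, idx, score) {
    pad <- paste(rep("A", 15 - nchar(motif)), collapse = "")
    oh <- oneHotEncode(paste0(motif, pad))
    hyp <- oh * abs(score) + matrix(stats::runif(60, 0, 0.02), 15, 4)
    list(idx = idx, start = 0L, end = 15L, score = score, onehot = oh,
         hyp = hyp * sign(score))
  }
  set.seed(5)
  sls <- c(lapply(1:6, function(i) mk("CAGCTGC", i, 2)),
           lapply(7:12, function(i) mk("GAGGTCAA", i, 2)))
  cls <- clusterSeqlets(sls)
  expect_gte(length(cls), 2)
  members <- lapply(cls, function(cl)
    vapply(cl$members, `[[`, integer(1), "idx"))
  for (m in members)
    expect_true(all(m <= 6) || all(m >= 7))  # no mixed cluster
})

test_that("PWM building follows the pseudocount frequency formula", {
  oh <- oneHotEncode("CAGCTGCAACGTACG")
  mem <- function(i) list(idx = i, offset = 0L, rc = FALSE, score = 1.5,
                          onehot = oh, hyp = oh)
  cl <- list(members = lapply(1:4, mem))
  m <- buildMotif(cl, pseudocount = 0.5)
  expect_s4_class(m, "MotifModel")
  expect_equal(m@consensus, "CAGCTGCAACGTACG")
  # n identical slices: max column probability (n + pc/4) / (n + pc)
  expect_equal(max(m@pwm[1, ]), (4 + 0.125) / 4.5)
  expect_equal(unname(rowSums(m@pwm)), rep(1, 15))
  expect_equal(m@importanceScore, 1.5)
  expect_equal(m@nSeqlets, 4L)

  # zero pseudocount on a single member: exact one-hot rows
  m0 <- buildMotif(list(members = list(mem(1))), pseudocount = 0)
  expect_equal(unname(m0@pwm), unname(oh))
})

test_that("discovery orders signed motifs and respects determinism", {
  seqs <- randomBackground(16, 80, gc = 0.5, seed = 6)
  spikes <- c(lapply(1:10, function(i) list(list(at = 20, w = 7, h = 2))),
              lapply(11:16, function(i) list(list(at = 50, w = 7, h = -2))))
  seqs <- vapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    if (i <= 10) substr(s, 20, 26) <- "CAGCTGC"
    else substr(s, 50, 56) <- "GAGGTCA"
    s
  }, character(1))
  att <- mkAttr(seqs, spikes)
  m1 <- discoverMotifs(att, seed = 7)
  m2 <- discoverMotifs(att, seed = 7)
  expect_identical(lapply(seq_len(length(m1)), function(i) m1[[i]]@pwm),
                   lapply(seq_len(length(m2)), function(i) m2[[i]]@pwm))
  signs <- vapply(seq_len(length(m1)), function(i)
    sign(m1[[i]]@importanceScore), numeric(1))
  # positive-sign motifs come first
  expect_true(!is.unsorted(rev(signs)))
})
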