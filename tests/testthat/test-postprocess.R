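test_that("column information content matches its closed forms", {
  expect_equal(columnIC(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(columnIC(c(1, 0, 0, 0)), 2)
  expect_equal(columnIC(c(0.5, 0.5, 0, 0)), 1)
  expect_error(columnIC(c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_error(columnIC(c(0.5, 0.5)), "4-vector")
})

test_that("trimming matches the scan-from-both-ends rule", {
  # construct a PWM with prescribed column ICs via two-state columns
  colWithIC <- function(keep) if (keep) c(0.97, 0.01, 0.01, 0.01)
                              else c(0.25, 0.25, 0.25, 0.25)
  pwm <- rbind(colWithIC(FALSE), colWithIC(FALSE), colWithIC(TRUE),
               colWithIC(TRUE), colWithIC(TRUE), colWithIC(FALSE),
               colWithIC(FALSE))
  tr <- trimMotif(pwm)
  expect_equal(c(tr$start, tr$end), c(3, 5))
  expect_equal(nrow(tr$pwm), 3)
  expect_false(tr$degenerate)

  # all uniform -> empty, degenerate
  uni <- matrix(0.25, 5, 4)
  trU <- trimMotif(uni)
  expect_true(trU$degenerate)
  expect_equal(nrow(trU$pwm), 0)

  # all informative -> identity
  hot <- diag(4)[c(1, 2, 3, 4, 1), ]
  expect_equal(trimMotif(hot)$pwm, hot)
})

test_that("trimming equals the brute-force oracle on 1000 random PWMs", {
  set.seed(42)
  for (i in 1:1000) {
    w <- sample(3:14, 1)
    pwm <- randomPWM(w)
    # sharpen a random subset so both branches occur
    sharp <- sample(w, sample(0:w, 1))
    pwm[sharp, ] <- 0.02
    pwm[cbind(sharp, sample(4, length(sharp), TRUE))] <- 0.94
    pwm <- pwm / rowSums(pwm)
    got <- trimMotif(pwm)
    want <- trimOracle(pwm)
    if (is.null(want)) {
      expect_true(got$degenerate)
    } else {
      expect_equal(c(got$start, got$end), unname(want))
    }
  }
})

test_that("stringency counts near-deterministic positions", {
  expect_equal(stringentFraction(diag(4)), 1)
  # IC(0.97 column) ~ 1.758: not stringent; IC(0.997) ~ 1.966: stringent
  c97 <- c(0.97, 0.01, 0.01, 0.01)
  c997 <- c(0.997, 0.001, 0.001, 0.001)
  expect_equal(columnIC(c97), 1.758, tolerance = 1e-3)
  expect_equal(columnIC(c997), 1.966, tolerance = 1e-3)
  expect_equal(stringentFraction(rbind(c97, c997)), 0.5)
})

test_that("motif similarity recognises itself in both orientations", {
  q <- pwmFrom("CAGTCA", 0.85, seed = 1)
  self <- motifSimilarity(q, q, nShuffles = 200)
  expect_equal(self$score, 1.0, tolerance = 1e-9)
  expect_equal(self$offset, 0L)
  expect_equal(self$orientation, "+")
  expect_equal(self$overlap, 1.0)

  rc <- q[rev(seq_len(nrow(q))), c(4, 3, 2, 1)]
  vsRC <- motifSimilarity(q, rc, nShuffles = 200)
  expect_equal(vsRC$score, 1.0, tolerance = 1e-9)
  expect_equal(vsRC$orientation, "-")

  # uniform columns: degenerate, score contract returns 0
  uni <- matrix(0.25, 5, 4)
  deg <- motifSimilarity(uni, uni, nShuffles = 50)
  expect_equal(deg$score, 0)
  expect_true(deg$degenerate)
  expect_error(motifSimilarity(q[1, , drop = FALSE], q), "width >= 2")
})

test_that("database matching ranks self first with monotone q-values", {
  db <- toyMotifDatabase(nDecoys = 20)
  q <- db[["NEUROG2"]]@pwm
  mk <- matchKnown(q, db, nShuffles = 500, seed = 3)
  expect_equal(mk$tf[1], "NEUROG2")
  expect_equal(mk$score[1], 1.0, tolerance = 1e-9)
  expect_true(all(mk$q.value[1] <= mk$q.value))
  expect_true(!is.unsorted(mk$q.value))  # monotone along the ranking
  expect_true(all(mk$q.value >= mk$p.value - 1e-12))
  expect_error(matchKnown(q, new("MotifSet", motifs = list())), "empty")
})

test_that("PWM scanning matches a brute-force rescan oracle", {
  pwm <- pwmFrom("CAGCTGC", 0.9, seed = 4)
  seqs <- randomBackground(100, 60, seed = 5)
  got <- scanHits(pwm, seqs, hitFraction = 0.8)
  oracle <- vapply(seqs, function(s) scanOracle(pwm, s), numeric(1))
  expect_equal(unname(got$best), unname(oracle))
  expect_equal(unname(got$hit), unname(oracle >= got$threshold - 1e-9))

  # the consensus embedded in background achieves the max score
  hit <- randomBackground(1, 60, seed = 6)
  substr(hit, 20, 26) <- "CAGCTGC"
  expect_true(scanHits(pwm, hit)$hit)
  expect_equal(scanHits(pwm, hit)$best, scanHits(pwm, hit)$maxScore)
  expect_error(scanHits(pwm, "ACG"), "exceeds")
})

test_that("enrichment testing recovers implanted differences", {
  pwm <- pwmFrom("CAGCTGC", 0.9, seed = 4)
  pos <- implantMotif(randomBackground(400, 80, seed = 7), "CAGCTGC",
                      frequency = 0.5, seed = 8)$seqs
  neg <- implantMotif(randomBackground(400, 80, seed = 9), "CAGCTGC",
                      frequency = 0.05, seed = 10)$seqs
  er <- enrichmentTest(pwm, pos, neg)
  expect_lt(er$p.value, 1e-10)
  expect_gt(er$oddsRatio, 1)
  # swapping the sets inverts the odds ratio
  er2 <- enrichmentTest(pwm, neg, pos)
  expect_equal(er2$oddsRatio, 1 / er$oddsRatio, tolerance = 1e-9)
  expect_equal(er2$p.value, er$p.value)
  # identical sets: no enrichment
  er0 <- enrichmentTest(pwm, pos, pos)
  expect_equal(er0$oddsRatio, 1, tolerance = 1e-9)
  expect_equal(er0$p.value, 1)
})

test_that("the 2-fold expression rule classifies staged profiles", {
  tab <- data.frame(tf = c("UP_KEEP", "WEAK", "ZERO", "LATE"),
                    day0 = c(10, 10, 0, 5),
                    day26 = c(25, 15, 8, 20),
                    day39 = c(20, 5, 8, 30))
  expect_true(expressionStatus("UP_KEEP", tab)$transcribed)
  # 1.5-fold rise is not enough
  expect_false(expressionStatus("WEAK", tab)$transcribed)
  # pseudocount: (8+1)/(0+1) = 9-fold, day39 flat
  zero <- expressionStatus("ZERO", tab)
  expect_true(zero$transcribed)
  expect_equal(zero$foldUp, 9)
  # rising after day 26 disqualifies
  expect_false(expressionStatus("LATE", tab)$transcribed)
  expect_error(expressionStatus("MISSING", tab), "not found")
})

test_that("the filter verdict is the conjunction of its seven criteria", {
  expr <- makeExpressionFixture()
  db <- toyMotifDatabase(nDecoys = 5)
  # a 3-column motif fails the length criterion regardless of the rest
  short <- pwmFrom("CAG", 0.9, seed = 11)
  v <- applyFilters(short, db, expr, nShuffles = 200)
  expect_false(v$pass2)
  expect_false(v$pass)
  # an all-one-hot 10-column motif fails stringency
  hot <- diag(4)[rep(1:4, length.out = 10), ]
  hot <- 0.999 * hot + 0.001 / 3 * (1 - hot)
  hot <- hot / rowSums(hot)
  v2 <- applyFilters(hot, db, expr, nShuffles = 200)
  expect_false(v2$pass3)
  expect_false(v2$pass)
  # conjunction property on assorted fixtures
  for (v in list(v, v2))
    expect_equal(v$pass, all(unlist(v[paste0("pass", 1:7)])))
})

test_that("motif sets round-trip through MEME motif format", {
  db <- toyMotifDatabase(nDecoys = 2)
  f <- tempfile(fileext = ".meme")
  writeMEME(db, f)
  back <- readMEME(f)
  expect_equal(names(back), names(db))
  for (nm in names(db))
    expect_equal(back[[nm]]@pwm, db[[nm]]@pwm, tolerance = 1e-5)
  expect_error(readMEME(writeTempBed("no motifs here")), "no MOTIF")
})
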