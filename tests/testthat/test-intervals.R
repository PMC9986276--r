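test_that("BED/narrowPeak parsing keeps coordinates verbatim and in order", {
  f <- writeTempBed(c("chr1\t100\t600", "chr2\t0\t50\tpeak1\t7.5\t+"))
  gr <- readPeakIntervals(f)
  expect_length(gr, 2)
  # 0-based half-open [100, 600) -> GRanges 101..600
  expect_equal(GenomicRanges::start(gr)[1], 101)
  expect_equal(GenomicRanges::end(gr)[1], 600)
  expect_equal(gr$score[2], 7.5)
  expect_equal(as.character(GenomicRanges::strand(gr))[2], "+")

  np <- writeTempBed(paste(c("chr1", 10, 80, "p", 123, ".", 5.5, 3.2, -1, 40),
                           collapse = "\t"))
  expect_equal(readPeakIntervals(np)$score, 123)
})

test_that("malformed interval lines are rejected with their line number", {
  expect_error(readPeakIntervals(writeTempBed("chr1\t600\t100")),
               "line 1.*start < end")
  expect_error(readPeakIntervals(writeTempBed(c("chr1\t1\t2", "chr1\tx\t5"))),
               "line 2.*non-integer")
  expect_error(readPeakIntervals(writeTempBed("chr1\t100")), "line 1")
  expect_error(readPeakIntervals(tempfile()), "not found")
})

test_that("overlap split matches the definition on boundary cases", {
  cand <- readPeakIntervals(writeTempBed("chr1\t100\t600"))
  markOver <- readPeakIntervals(writeTempBed("chr1\t550\t700"))
  markTouch <- readPeakIntervals(writeTempBed("chr1\t600\t700"))
  sp <- splitByOverlap(cand, markOver)
  expect_length(sp$withMark, 1)
  expect_length(sp$withoutMark, 0)
  # half-open: [100,600) and [600,700) share no base
  sp2 <- splitByOverlap(cand, markTouch)
  expect_length(sp2$withMark, 0)
  expect_length(sp2$withoutMark, 1)
  # empty marks -> everything without
  sp3 <- splitByOverlap(cand, cand[0])
  expect_length(sp3$withoutMark, 1)
})

test_that("overlap split agrees with the all-pairs brute-force oracle", {
  for (seed in 1:5) {
    cand <- randomIntervals(200, seed = seed)
    marks <- randomIntervals(25, seed = seed + 100)
    sp <- splitByOverlap(cand, marks)
    oracle <- remotif:::.overlapBruteForce(cand, marks)
    expect_length(sp$withMark, sum(oracle))
    expect_length(sp$withoutMark, sum(!oracle))
    # partition property
    expect_equal(length(sp$withMark) + length(sp$withoutMark), length(cand))
    expect_equal(sort(c(GenomicRanges::start(sp$withMark),
                        GenomicRanges::start(sp$withoutMark))),
                 sort(GenomicRanges::start(cand)))
  }
})

test_that("promoter exclusion applies the strand-mirrored TSS window", {
  iv <- readPeakIntervals(writeTempBed("chr1\t5000\t5500"))
  tssPlus <- readPeakIntervals(writeTempBed("chr1\t5600\t5601\tg\t0\t+"))
  # window [4600, 5700) overlaps [5000, 5500)
  expect_length(excludePromoters(iv, tssPlus), 0)

  far <- readPeakIntervals(writeTempBed("chr1\t100\t200"))
  tssFar <- readPeakIntervals(writeTempBed("chr1\t10000\t10001\tg\t0\t+"))
  expect_length(excludePromoters(far, tssFar), 1)

  # minus-strand TSS at 1000: window [900, 2000)
  tssMinus <- readPeakIntervals(writeTempBed("chr1\t1000\t1001\tg\t0\t-"))
  inWin <- readPeakIntervals(writeTempBed("chr1\t1900\t1990"))
  outWin <- readPeakIntervals(writeTempBed("chr1\t2000\t2100"))
  expect_length(excludePromoters(inWin, tssMinus), 0)
  expect_length(excludePromoters(outWin, tssMinus), 1)

  # empty TSS list is the identity
  many <- randomIntervals(50, seed = 3)
  expect_identical(excludePromoters(many, tssMinus[0]), many)
  expect_error(excludePromoters(many, tssMinus, window = c(100, -100)),
               "upstream < downstream")
})

test_that("centre-and-fix-length follows the floor midpoint rule", {
  iv <- readPeakIntervals(writeTempBed("chr1\t100\t600"))
  out <- centerFixLength(iv, 100)
  expect_equal(GenomicRanges::start(out) - 1, 300)  # BED [300, 400)
  expect_equal(GenomicRanges::end(out), 400)

  # odd input length: centre floor((100+601)/2) = 350
  ivOdd <- readPeakIntervals(writeTempBed("chr1\t100\t601"))
  outOdd <- centerFixLength(ivOdd, 100)
  expect_equal(GenomicRanges::start(outOdd) - 1, 300)

  # odd N: upstream floor(N/2), downstream ceiling(N/2)
  out101 <- centerFixLength(iv, 101)
  expect_equal(GenomicRanges::start(out101) - 1, 350 - 50)
  expect_equal(GenomicRanges::end(out101), 350 + 51)
  expect_equal(GenomicRanges::width(out101), 101)

  expect_error(centerFixLength(iv, 0), "positive")
})

test_that("fixed-length windows outside chromosome bounds are dropped", {
  iv <- readPeakIntervals(writeTempBed("chr1\t10\t30"))
  GenomeInfoDb::seqlengths(iv) <- c(chr1 = 400)
  expect_warning(out <- centerFixLength(iv, 500), "dropped")
  expect_length(out, 0)
})

test_that("centre-and-fix-length is idempotent", {
  iv <- randomIntervals(100, seed = 9)
  once <- centerFixLength(iv, 120)
  twice <- centerFixLength(once, 120)
  expect_equal(GenomicRanges::start(once), GenomicRanges::start(twice))
  expect_equal(GenomicRanges::end(once), GenomicRanges::end(twice))
})

test_that("signal filtering keeps candidates above the mean-signal cut", {
  bg <- writeTempBed(c("chr1\t0\t100\t2.0", "chr1\t100\t200\t0.0",
                       "chr1\t300\t400\t5.0"))
  cand <- readPeakIntervals(writeTempBed(c(
    "chr1\t0\t200",      # mean (100*2 + 100*0)/200 = 1.0
    "chr1\t300\t400",    # mean 5.0
    "chr1\t500\t600")))  # uncovered: mean 0
  kept <- filterBySignal(cand, bg, threshold = 0.5)
  expect_length(kept, 2)
  expect_equal(kept$meanSignal, c(1, 5))
  expect_length(filterBySignal(cand, bg, threshold = 4), 1)
  expect_error(filterBySignal(cand, tempfile(), 1), "not found")
})
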