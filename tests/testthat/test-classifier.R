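test_that("one-hot encoding matches its definition and round-trips", {
  m <- oneHotEncode("ACGT")
  expect_equal(m, matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1),
                         4, 4, byrow = TRUE, dimnames = list(NULL, BASES4)))
  expect_equal(colSums(oneHotEncode("AAAA")), c(A = 4, C = 0, G = 0, T = 0))
  expect_true(all(rowSums(m) == 1))
  set.seed(5)
  for (i in 1:100) {
    s <- paste(sample(BASES4, sample(5:60, 1), replace = TRUE), collapse = "")
    expect_equal(oneHotDecode(oneHotEncode(s)), s)
  }
  expect_error(oneHotEncode("ACGN"), "non-ACGT")
})

test_that("model outputs are probabilities and respect the architecture", {
  hp <- cnnHyperparams(nFilters = 32, kernelSize = 12, seed = 1)
  m <- buildCNN(hp, 500)
  seqs <- randomBackground(5, 500, seed = 2)
  fw <- remotif:::.cnnForwardCodes(m@weights, hp,
                                   remotif:::.codesMatrix(seqs))
  expect_equal(dim(fw$pooled), c(5, 32))  # flattened width = nFilters
  p <- predict(m, seqs)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))

  # zeroed output layer -> sigmoid(0) = 0.5 on any input
  m0 <- m
  m0@weights$W2[] <- 0
  m0@weights$b2 <- 0
  expect_equal(unname(predict(m0, seqs)), rep(0.5, 5))

  # prediction is invariant to example order within a batch
  ord <- c(3, 1, 5, 2, 4)
  expect_equal(predict(m, seqs[ord]), p[ord])

  expect_error(buildCNN(cnnHyperparams(kernelSize = 600), 500), "exceeds")
  expect_error(cnnHyperparams(nFilters = 0), "positive")
})

test_that("analytic gradients agree with finite differences", {
  hp <- cnnHyperparams(nFilters = 3, kernelSize = 4, denseUnits = 5, seed = 7)
  m <- buildCNN(hp, 12)
  set.seed(1)
  Sb <- matrix(sample(1:4, 4 * 12, TRUE), 4, 12)
  y <- c(1, 0, 1, 0)
  w <- m@weights
  fw <- remotif:::.cnnForwardCodes(w, hp, Sb)
  gr <- remotif:::.cnnBackwardCodes(w, hp, Sb, fw, (fw$prob - y) / 4)
  lossAt <- function(w) {
    p <- remotif:::.cnnForwardCodes(w, hp, Sb)$prob
    mean(-(y * log(p) + (1 - y) * log(1 - p)))
  }
  eps <- 1e-6
  for (nm in names(gr)) {
    idx <- seq_len(min(length(w[[nm]]), 10))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      expect_equal(as.vector(gr[[nm]])[i],
                   (lossAt(wp) - lossAt(wm)) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training requires two adequately sized classes", {
  tiny <- enhancerSet(randomBackground(5, 40, seed = 1),
                      randomBackground(30, 40, seed = 2))
  expect_error(trainCNN(tiny, cnnHyperparams(kernelSize = 8)), "fewer than 10")
  onlyPos <- enhancerSet(randomBackground(20, 40, seed = 1), character())
  expect_error(trainCNN(onlyPos, cnnHyperparams(kernelSize = 8)),
               "both classes")
})

test_that("training with a fixed seed is reproducible", {
  es <- simulateEnhancerStudy(nPos = 60, nNeg = 60, length = 60,
                              frequency = 0.8, seed = 11)$set
  hp <- cnnHyperparams(nFilters = 6, kernelSize = 6, denseUnits = 6,
                       maxEpochs = 3, seed = 11)
  f1 <- trainCNN(es, hp)
  f2 <- trainCNN(es, hp)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model@weights, f2$model@weights)
})

test_that("a trained model beats its label-shuffled control and tolerates motif shifts", {
  fit <- tinyTrainedModel()
  sim <- tinyStudySet()
  hp <- fit$model@hyperparams
  sh <- trainCNN(sim$set, hp, shuffleLabels = TRUE)
  expect_gte(fit$report$auroc, sh$report$auroc + 0.3)

  # global max pooling -> translation tolerance: implant the motif centred
  # vs shifted +/-20 bp and compare predictions
  bg <- randomBackground(40, 100, gc = 0.5, seed = 123)
  centre <- 47
  atPos <- function(seqs, pos) {
    substr(seqs, pos, pos + 6) <- "CAGCTGC"
    seqs
  }
  pC <- predict(fit$model, atPos(bg, centre))
  pL <- predict(fit$model, atPos(bg, centre - 20))
  pR <- predict(fit$model, atPos(bg, centre + 20))
  expect_lt(mean(abs(pC - pL)), 0.2)
  expect_lt(mean(abs(pC - pR)), 0.2)
})

test_that("grid search trains every valid cell and returns the argmax", {
  es <- simulateEnhancerStudy(nPos = 80, nNeg = 80, length = 50,
                              frequency = 0.8, seed = 13)$set
  grid <- list(
    cnnHyperparams(nFilters = 4, kernelSize = 6, denseUnits = 4,
                   maxEpochs = 3, seed = 13),
    cnnHyperparams(nFilters = 8, kernelSize = 8, denseUnits = 4,
                   maxEpochs = 3, seed = 13),
    cnnHyperparams(nFilters = 4, kernelSize = 60, denseUnits = 4,
                   maxEpochs = 3, seed = 13))  # kernel > L: invalid cell
  gs <- gridSearchCNN(es, grid)
  expect_equal(nrow(gs$table), 3)
  expect_match(gs$table$status[3], "invalid")
  expect_true(is.na(gs$table$valAuroc[3]))
  valid <- gs$table$valAuroc[1:2]
  expect_equal(gs$best$kernelSize,
               grid[[which.max(valid)]]$kernelSize)
  expect_gte(max(valid, na.rm = TRUE), gs$table$valAuroc[1])
  # grid of one returns that combination
  gs1 <- gridSearchCNN(es, grid[1])
  expect_equal(gs1$best$nFilters, 4L)
  expect_error(gridSearchCNN(es, list()), "empty")
})

test_that("evaluation metrics agree with an independent AUROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- rbinom(300, 1, 0.4)
  s <- runif(300) + 0.4 * y
  rep <- evalReport(s, y)
  expect_equal(rep$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_true(rep$auprc >= 0 && rep$auprc <= 1)
})

test_that("model checkpoints round-trip through JSON", {
  fit <- tinyTrainedModel()
  f <- tempfile(fileext = ".json")
  writeCNNModel(fit$model, f)
  back <- readCNNModel(f)
  seqs <- randomBackground(10, 100, seed = 3)
  expect_equal(predict(back, seqs), predict(fit$model, seqs))
  expect_true(back@trained)
})

test_that("the default grid spans the documented hyper-parameter space", {
  g <- defaultCNNGrid(seed = 5, maxEpochs = 2)
  expect_length(g, 24)
  combos <- unique(t(sapply(g, function(h)
    c(h$nFilters, h$kernelSize, h$learningRate))))
  expect_equal(nrow(combos), 24)
  expect_true(all(sapply(g, `[[`, "seed") == 5))
  expect_true(all(sapply(g, `[[`, "maxEpochs") == 2))
  expect_setequal(unique(sapply(g, `[[`, "kernelSize")), c(8, 12, 16, 24))
})
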