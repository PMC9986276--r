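#' Hyper-parameters for the convolutional enhancer classifier
#'
#' Defaults are standard for shallow genomics CNNs of this depth: 32 filters
#' of width 16, one dense ReLU layer of 32 units, Adam at 1e-3, batches of 64,
#' up to 100 epochs with early stopping (patience 10) on validation loss, and
#' a stratified 70/15/15 train/validation/test split.
#'
#' @param nFilters Number of convolutional filters.
#' @param kernelSize Filter width in bp (must not exceed sequence length).
#' @param denseUnits Units in the fully connected layer.
#' @param learningRate Adam learning rate.
#' @param batchSize Minibatch size.
#' @param maxEpochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param valFraction,testFraction Stratified split fractions.
#' @param classWeights Use inverse-frequency class weights in the loss.
#' @param seed RNG seed governing split, initialisation and batch order.
#' @return Named list of hyper-parameters.
#' @export
cnnHyperparams <- function(nFilters = 32L, kernelSize = 16L, denseUnits = 32L,
                           learningRate = 1e-3, batchSize = 64L,
                           maxEpochs = 100L, patience = 10L,
                           valFraction = 0.15, testFraction = 0.15,
                           classWeights = TRUE, seed = 1L) {
  hp <- list(nFilters = as.integer(nFilters),
             kernelSize = as.integer(kernelSize),
             denseUnits = as.integer(denseUnits),
             learningRate = learningRate, batchSize = as.integer(batchSize),
             maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
             valFraction = valFraction, testFraction = testFraction,
             classWeights = isTRUE(classWeights), seed = as.integer(seed))
  if (hp$nFilters < 1 || hp$kernelSize < 1 || hp$denseUnits < 1 ||
      hp$batchSize < 1 || hp$maxEpochs < 1)
    stop("all counts in the hyper-parameters must be positive")
  hp
}

#' Build an untrained convolutional classifier
#'
#' Architecture: conv1d(nFilters, kernelSize) -> ReLU -> per-filter global
#' max pooling -> flatten (width nFilters) -> dense(denseUnits, ReLU) ->
#' single sigmoid output.
#'
#' @param hp Hyper-parameters from [cnnHyperparams()].
#' @param L Input sequence length in bp.
#' @return An untrained [EnhancerCNN-class] with He-initialised weights
#'   (seeded by `hp$seed`).
#' @export
buildCNN <- function(hp = cnnHyperparams(), L) {
  L <- as.integer(L)
  if (hp$kernelSize > L)
    stop("kernelSize (", hp$kernelSize, ") exceeds input length (", L, ")")
  k <- hp$kernelSize; nF <- hp$nFilters; H <- hp$denseUnits
  set.seed(hp$seed)
  w <- list(
    Wm = matrix(stats::rnorm(4 * k * nF, sd = sqrt(2 / (4 * k))), 4 * k, nF),
    bc = numeric(nF),
    W1 = matrix(stats::rnorm(nF * H, sd = sqrt(2 / nF)), nF, H),
    b1 = numeric(H),
    W2 = matrix(stats::rnorm(H, sd = sqrt(2 / H)), H, 1),
    b2 = 0)
  new("EnhancerCNN", hyperparams = hp, weights = w, inputLength = L,
      trained = FALSE, history = data.frame())
}

# forward pass on an integer-code batch (one-hot implicit).
# conv activation row order: r = b + (p-1)*B, i.e. batch index fastest.
.cnnForwardCodes <- function(w, hp, Sb) {
  B <- nrow(Sb); L <- ncol(Sb)
  k <- hp$kernelSize; nF <- hp$nFilters
  P <- L - k + 1L
  conv <- matrix(w$bc, B * P, nF, byrow = TRUE)
  for (j in seq_len(k)) {
    rows <- (j - 1L) * 4L + as.vector(Sb[, j:(j + P - 1L), drop = FALSE])
    conv <- conv + w$Wm[rows, , drop = FALSE]
  }
  conv[conv < 0] <- 0
  pooled <- matrix(0, B, nF)
  amax <- matrix(0L, B, nF)
  for (f in seq_len(nF)) {
    sl <- matrix(conv[, f], B, P)
    im <- max.col(sl, ties.method = "first")
    amax[, f] <- im
    pooled[, f] <- sl[cbind(seq_len(B), im)]
  }
  H1 <- pooled %*% w$W1 + matrix(w$b1, B, hp$denseUnits, byrow = TRUE)
  A1 <- pmax(H1, 0)
  logit <- drop(A1 %*% w$W2) + w$b2
  list(pooled = pooled, amax = amax, H1 = H1, A1 = A1, logit = logit,
       prob = 1 / (1 + exp(-logit)))
}

# gradients of the loss w.r.t. all weights, given dL/dlogit per example.
# exploits max-pool sparsity: only the argmax window of each (example, filter)
# receives gradient.
.cnnBackwardCodes <- function(w, hp, Sb, fw, dlogit) {
  B <- nrow(Sb)
  k <- hp$kernelSize; nF <- hp$nFilters
  dlogit <- matrix(dlogit, B, 1)
  dW2 <- crossprod(fw$A1, dlogit)
  db2 <- sum(dlogit)
  dH1 <- (dlogit %*% t(w$W2)) * (fw$H1 > 0)
  dW1 <- crossprod(fw$pooled, dH1)
  db1 <- colSums(dH1)
  g <- tcrossprod(dH1, w$W1) * (fw$pooled > 0)
  dWm <- matrix(0, 4L * k, nF)
  gv <- as.vector(g)
  bIdx <- rep(seq_len(B), nF)
  fOff <- (rep(seq_len(nF), each = B) - 1L) * (4L * k)
  for (j in seq_len(k)) {
    codes <- Sb[cbind(bIdx, as.vector(fw$amax) + j - 1L)]
    agg <- rowsum(gv, fOff + (j - 1L) * 4L + codes)
    at <- as.integer(rownames(agg))
    dWm[at] <- dWm[at] + agg[, 1]
  }
  list(Wm = dWm, bc = colSums(g), W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

.adamInit <- function(w) {
  zero <- lapply(w, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(w, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(w = w, st = st)
}

.bceLoss <- function(p, y, wgt = rep(1, length(y))) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(wgt * -(y * log(p) + (1 - y) * log(1 - p))) / sum(wgt)
}

# stratified train/val/test index split, deterministic per current RNG state
.stratifiedSplit <- function(y, valFraction, testFraction) {
  tr <- va <- te <- integer()
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    n <- length(idx)
    nTe <- round(n * testFraction)
    nVa <- round(n * valFraction)
    te <- c(te, idx[seq_len(nTe)])
    va <- c(va, idx[nTe + seq_len(nVa)])
    tr <- c(tr, idx[(nTe + nVa + 1):n])
  }
  list(train = sort(tr), val = sort(va), test = sort(te))
}

.predictCodes <- function(model, codes, chunk = 512L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- .cnnForwardCodes(model@weights, model@hyperparams,
                                 codes[s:e, , drop = FALSE])$prob
  }
  out
}

#' Predict active-enhancer probabilities
#'
#' @param object A trained (or untrained) [EnhancerCNN-class].
#' @param newdata Sequences: `EnhancerSet`, `DNAStringSet`, or character
#'   vector, all of the model's input length.
#' @return Numeric vector of sigmoid probabilities in (0, 1).
#' @export
setMethod("predict", "EnhancerCNN", function(object, newdata) {
  seqs <- if (methods::is(newdata, "EnhancerSet")) sequences(newdata)
          else newdata
  codes <- .codesMatrix(seqs)
  if (ncol(codes) != object@inputLength)
    stop("sequences have length ", ncol(codes), ", model expects ",
         object@inputLength)
  .predictCodes(object, codes)
})

#' Classification metrics for a score vector
#'
#' AUROC by the rank (Mann-Whitney) formula, AUPRC as average precision,
#' accuracy at the 0.5 cut, and mean binary cross-entropy.
#'
#' @param scores Predicted probabilities.
#' @param y Binary labels.
#' @return List `auroc`, `auprc`, `accuracy`, `loss`, `n`.
#' @export
evalReport <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  yo <- y[o]
  prec <- cumsum(yo) / seq_along(yo)
  auprc <- sum(prec[yo == 1]) / n1
  list(auroc = auroc, auprc = auprc,
       accuracy = mean((scores >= 0.5) == (y == 1)),
       loss = .bceLoss(scores, y), n = length(y))
}

#' Train the convolutional enhancer classifier
#'
#' Minimises class-weighted binary cross-entropy with Adam on a stratified
#' 70/15/15 split, with early stopping on validation loss. Fully seeded: two
#' runs with the same data and hyper-parameters produce identical models and
#' reports.
#'
#' @param x An [EnhancerSet-class] with both classes present.
#' @param hp Hyper-parameters from [cnnHyperparams()].
#' @param shuffleLabels Permute labels before splitting (negative control).
#' @param nRestarts Independent training runs from different initialisations
#'   (seeds `hp$seed + 1000 * 0:(nRestarts-1)`); the run with the best
#'   validation AUROC is kept. Restarts guard against initialisations that
#'   memorise before finding weak sequence signal. Default 1.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained [EnhancerCNN-class]) and `report`
#'   (held-out-test metrics from [evalReport()] plus `valAuroc`, `valLoss`
#'   and split sizes).
#' @export
trainCNN <- function(x, hp = cnnHyperparams(), shuffleLabels = FALSE,
                     nRestarts = 1L, verbose = FALSE) {
  if (nRestarts > 1) {
    runs <- lapply(seq_len(nRestarts) - 1L, function(r) {
      hpR <- hp
      hpR$seed <- hp$seed + 1000L * r
      trainCNN(x, hpR, shuffleLabels = shuffleLabels, verbose = verbose)
    })
    vals <- vapply(runs, function(f) f$report$valAuroc, numeric(1))
    return(runs[[which.max(vals)]])
  }
  codes <- .codesMatrix(sequences(x))
  y <- enhancerLabels(x)
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (min(table(y)) < 10)
    stop("fewer than 10 examples in a class; provide more data")
  L <- ncol(codes)
  if (hp$kernelSize > L)
    stop("kernelSize (", hp$kernelSize, ") exceeds input length (", L, ")")
  set.seed(hp$seed)
  if (shuffleLabels) y <- sample(y)
  sp <- .stratifiedSplit(y, hp$valFraction, hp$testFraction)
  yTr <- y[sp$train]
  wgt <- rep(1, length(yTr))
  if (hp$classWeights) {
    wPos <- length(yTr) / (2 * sum(yTr == 1))
    wNeg <- length(yTr) / (2 * sum(yTr == 0))
    wgt <- ifelse(yTr == 1, wPos, wNeg)
  }
  model <- buildCNN(hp, L)   # reseeds with hp$seed
  set.seed(hp$seed + 1L)     # stream for batch shuffling
  w <- model@weights
  st <- .adamInit(w)
  codesTr <- codes[sp$train, , drop = FALSE]
  codesVa <- codes[sp$val, , drop = FALSE]
  yVa <- y[sp$val]
  nTr <- nrow(codesTr)
  bestLoss <- Inf; bestW <- w; wait <- 0L
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  for (epoch in seq_len(hp$maxEpochs)) {
    ord <- sample(nTr)
    epLoss <- 0; epW <- 0
    for (s in seq(1, nTr, by = hp$batchSize)) {
      idx <- ord[s:min(s + hp$batchSize - 1L, nTr)]
      Sb <- codesTr[idx, , drop = FALSE]
      yb <- yTr[idx]; wb <- wgt[idx]
      fw <- .cnnForwardCodes(w, hp, Sb)
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      epLoss <- epLoss + sum(wb * -(yb * log(p) + (1 - yb) * log(1 - p)))
      epW <- epW + sum(wb)
      dlogit <- wb * (fw$prob - yb) / sum(wb)
      gr <- .cnnBackwardCodes(w, hp, Sb, fw, dlogit)
      upd <- .adamStep(w, gr, st, hp$learningRate)
      w <- upd$w; st <- upd$st
    }
    tmp <- model; tmp@weights <- w
    pVa <- .predictCodes(tmp, codesVa)
    vaLoss <- .bceLoss(pVa, yVa)
    hist <- rbind(hist, data.frame(epoch = epoch, train = epLoss / epW,
                                   val = vaLoss))
    if (verbose)
      message(sprintf("epoch %3d train %.4f val %.4f", epoch,
                      epLoss / epW, vaLoss))
    if (vaLoss < bestLoss - 1e-6) {
      bestLoss <- vaLoss; bestW <- w; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  model@weights <- bestW
  model@trained <- TRUE
  model@history <- hist
  pVa <- .predictCodes(model, codesVa)
  pTe <- .predictCodes(model, codes[sp$test, , drop = FALSE])
  report <- evalReport(pTe, y[sp$test])
  report$valAuroc <- evalReport(pVa, yVa)$auroc
  report$valLoss <- .bceLoss(pVa, yVa)
  report$split <- c(train = length(sp$train), val = length(sp$val),
                    test = length(sp$test))
  list(model = model, report = report)
}

#' Default hyper-parameter grid
#'
#' The standard search grid: filters {16, 32, 64} x kernel {8, 12, 16, 24}
#' x learning rate {1e-3, 1e-4}, everything else at the defaults.
#'
#' @param seed Seed shared by all cells (identical splits).
#' @param ... Overrides applied to every cell (e.g. `maxEpochs`).
#' @return A list of hyper-parameter lists for [gridSearchCNN()].
#' @export
defaultCNNGrid <- function(seed = 1L, ...) {
  cells <- expand.grid(nFilters = c(16L, 32L, 64L),
                       kernelSize = c(8L, 12L, 16L, 24L),
                       learningRate = c(1e-3, 1e-4))
  lapply(seq_len(nrow(cells)), function(i)
    cnnHyperparams(nFilters = cells$nFilters[i],
                   kernelSize = cells$kernelSize[i],
                   learningRate = cells$learningRate[i],
                   seed = seed, ...))
}

#' Grid search over CNN hyper-parameters
#'
#' Trains every combination with identical splits and seed; cells whose
#' kernel exceeds the sequence length are marked invalid and skipped. The
#' best combination is the one with the highest validation AUROC.
#'
#' @param x An [EnhancerSet-class].
#' @param grid A list of hyper-parameter lists (each from [cnnHyperparams()]).
#' @return List with `best` (the winning hyper-parameters), `bestModel`, and
#'   `table` (a data frame of all cells with validation AUROC and status).
#' @export
gridSearchCNN <- function(x, grid) {
  if (!length(grid)) stop("empty grid")
  L <- unique(Biostrings::width(sequences(x)))
  rows <- list(); best <- NULL; bestAuc <- -Inf; bestModel <- NULL
  for (i in seq_along(grid)) {
    hp <- grid[[i]]
    row <- data.frame(cell = i, nFilters = hp$nFilters,
                      kernelSize = hp$kernelSize, denseUnits = hp$denseUnits,
                      learningRate = hp$learningRate,
                      valAuroc = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (hp$kernelSize > L) {
      row$status <- "invalid: kernel exceeds sequence length"
    } else {
      fit <- trainCNN(x, hp)
      row$valAuroc <- fit$report$valAuroc
      if (row$valAuroc > bestAuc) {
        bestAuc <- row$valAuroc; best <- hp; bestModel <- fit
      }
    }
    rows[[i]] <- row
  }
  list(best = best, bestModel = bestModel, table = do.call(rbind, rows))
}

#' Save / load an EnhancerCNN as JSON
#'
#' The checkpoint holds architecture, weights and seed in one portable text
#' file.
#' @param model An [EnhancerCNN-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCNNModel <- function(model, path) {
  obj <- list(hyperparams = model@hyperparams,
              inputLength = model@inputLength,
              trained = model@trained,
              weights = lapply(model@weights, function(m) {
                if (is.matrix(m)) list(dim = dim(m), data = as.vector(m))
                else list(dim = NULL, data = as.vector(m))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCNNModel
#' @export
readCNNModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(el) {
    if (!is.null(el$dim) && length(el$dim) == 2)
      matrix(el$data, el$dim[1], el$dim[2])
    else as.numeric(el$data)
  })
  hp <- obj$hyperparams
  intFields <- c("nFilters", "kernelSize", "denseUnits", "batchSize",
                 "maxEpochs", "patience", "seed")
  for (f in intFields) hp[[f]] <- as.integer(hp[[f]])
  new("EnhancerCNN", hyperparams = hp, weights = w,
      inputLength = as.integer(obj$inputLength),
      trained = isTRUE(obj$trained), history = data.frame())
}
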