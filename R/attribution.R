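#' Construct a linear sequence scorer
#'
#' @param weights L x 4 numeric matrix.
#' @param bias Intercept (default 0).
#' @return A [LinearSeqModel-class].
#' @export
linearSeqModel <- function(weights, bias = 0) {
  stopifnot(is.matrix(weights), ncol(weights) == 4)
  new("LinearSeqModel", weights = weights, bias = as.numeric(bias))
}

#' @describeIn linearSeqModel Score of a dense or one-hot input.
#' @param object A `LinearSeqModel`.
#' @param newdata L x 4 matrix or character sequence.
#' @export
setMethod("predict", "LinearSeqModel", function(object, newdata) {
  X <- if (is.character(newdata)) oneHotEncode(newdata) else newdata
  sum(object@weights * X) + object@bias
})

.uniformBaseline <- function(L) matrix(0.25, L, 4,
                                       dimnames = list(NULL, BASES))

.asDenseInput <- function(x) {
  if (is.character(x) || methods::is(x, "DNAString")) oneHotEncode(x)
  else if (is.matrix(x) && ncol(x) == 4) x
  else stop("'x' must be a DNA string or an L x 4 matrix")
}

# shared Riemann-sum engine: meanGradFn(x, baseline, alphas) must return the
# L x 4 mean of the output gradient over the interpolated inputs
# baseline + alpha * (x - baseline).
.igEngine <- function(x, baseline, nSteps, meanGradFn, predFn) {
  if (!identical(dim(x), dim(baseline)))
    stop("x and baseline must share shape")
  nSteps <- as.integer(nSteps)
  if (nSteps < 1) stop("nSteps must be positive")
  alphas <- seq_len(nSteps) / nSteps
  meanGrad <- meanGradFn(x, baseline, alphas)
  raw <- (x - baseline) * meanGrad
  deltaF <- predFn(x) - predFn(baseline)
  list(raw = raw, meanGrad = meanGrad, deltaF = deltaF,
       gap = abs(sum(raw) - deltaF))
}

# batched dense forward + input gradient for the CNN. Xstack rows are ordered
# (s-1)*P + p (position fastest). Returns the summed input gradient over
# steps, divided by S by the caller.
.cnnMeanGrad <- function(model, on) {
  w <- model@weights; hp <- model@hyperparams
  k <- hp$kernelSize; nF <- hp$nFilters; H <- hp$denseUnits
  function(x, baseline, alphas) {
    L <- nrow(x); P <- L - k + 1L; S <- length(alphas)
    XcX <- matrix(0, P, 4L * k)
    XcB <- matrix(0, P, 4L * k)
    for (j in seq_len(k)) {
      cols <- (j - 1L) * 4L + 1:4
      XcX[, cols] <- x[j:(j + P - 1L), , drop = FALSE]
      XcB[, cols] <- baseline[j:(j + P - 1L), , drop = FALSE]
    }
    Xc <- kronecker(matrix(alphas, S, 1), XcX) +
          kronecker(matrix(1 - alphas, S, 1), XcB)
    conv <- Xc %*% w$Wm + matrix(w$bc, S * P, nF, byrow = TRUE)
    conv[conv < 0] <- 0
    pooled <- matrix(0, S, nF); amax <- matrix(0L, S, nF)
    for (f in seq_len(nF)) {
      sl <- matrix(conv[, f], P, S)
      im <- max.col(t(sl), ties.method = "first")
      amax[, f] <- im
      pooled[, f] <- sl[cbind(im, seq_len(S))]
    }
    H1 <- pooled %*% w$W1 + matrix(w$b1, S, H, byrow = TRUE)
    A1 <- pmax(H1, 0)
    dlogit <- if (on == "prob") {
      p <- 1 / (1 + exp(-(drop(A1 %*% w$W2) + w$b2)))
      p * (1 - p)
    } else rep(1, S)
    dH1 <- (matrix(dlogit, S, 1) %*% t(w$W2)) * (H1 > 0)
    dpool <- tcrossprod(dH1, w$W1) * (pooled > 0)
    sumGrad <- matrix(0, L, 4)
    for (f in seq_len(nF)) {
      if (all(dpool[, f] == 0)) next
      Wblk <- t(matrix(w$Wm[, f], 4, k))  # k x 4 kernel block
      agg <- rowsum(dpool[, f], amax[, f])
      ps <- as.integer(rownames(agg))
      for (ii in seq_along(ps)) {
        if (agg[ii, 1] == 0) next
        rows <- ps[ii]:(ps[ii] + k - 1L)
        sumGrad[rows, ] <- sumGrad[rows, ] + agg[ii, 1] * Wblk
      }
    }
    sumGrad / S
  }
}

.cnnPredDense <- function(model, on) {
  w <- model@weights; hp <- model@hyperparams
  k <- hp$kernelSize; nF <- hp$nFilters
  function(x) {
    L <- nrow(x); P <- L - k + 1L
    Xc <- matrix(0, P, 4L * k)
    for (j in seq_len(k))
      Xc[, (j - 1L) * 4L + 1:4] <- x[j:(j + P - 1L), , drop = FALSE]
    conv <- Xc %*% w$Wm + matrix(w$bc, P, nF, byrow = TRUE)
    conv[conv < 0] <- 0
    pooled <- apply(conv, 2, max)
    a1 <- pmax(drop(pooled %*% w$W1) + w$b1, 0)
    logit <- sum(a1 * w$W2) + w$b2
    if (on == "prob") 1 / (1 + exp(-logit)) else logit
  }
}

.attributeOne <- function(model, x, baseline, nSteps, on) {
  X <- .asDenseInput(x)
  if (is.null(baseline)) baseline <- .uniformBaseline(nrow(X))
  if (methods::is(model, "EnhancerCNN")) {
    if (nrow(X) != model@inputLength)
      stop("sequence length ", nrow(X), " does not match model input length ",
           model@inputLength)
    eng <- .igEngine(X, baseline, nSteps,
                     .cnnMeanGrad(model, on), .cnnPredDense(model, on))
  } else if (methods::is(model, "LinearSeqModel")) {
    W <- model@weights
    eng <- .igEngine(X, baseline, nSteps,
                     function(x, b, a) W,
                     function(x) sum(W * x) + model@bias)
  } else stop("unsupported model class: ", class(model))
  eng$hypothetical <- eng$meanGrad * (1 - baseline)
  obs <- X > 0.5  # observed-base mask (one-hot inputs)
  eng$importance <- eng$raw * obs
  eng
}

#' @rdname integratedGradients
#' @export
setMethod("integratedGradients", "EnhancerCNN",
  function(model, x, baseline = NULL, nSteps = 128L,
           on = c("logit", "prob")) {
    on <- match.arg(on)
    if (nSteps < 16) warning("nSteps < 16 gives a coarse Riemann sum")
    .attributeOne(model, x, baseline, nSteps, on)$raw
  })

#' @rdname integratedGradients
#' @export
setMethod("integratedGradients", "LinearSeqModel",
  function(model, x, baseline = NULL, nSteps = 128L,
           on = c("logit", "prob")) {
    .attributeOne(model, x, baseline, nSteps, "logit")$raw
  })

#' @rdname hypotheticalScores
#' @export
setMethod("hypotheticalScores", "EnhancerCNN",
  function(model, x, baseline = NULL, nSteps = 128L,
           on = c("logit", "prob")) {
    on <- match.arg(on)
    .attributeOne(model, x, baseline, nSteps, on)$hypothetical
  })

#' @rdname hypotheticalScores
#' @export
setMethod("hypotheticalScores", "LinearSeqModel",
  function(model, x, baseline = NULL, nSteps = 128L,
           on = c("logit", "prob")) {
    .attributeOne(model, x, baseline, nSteps, "logit")$hypothetical
  })

#' Attribution tracks for a whole dataset
#'
#' Runs Integrated Gradients on every sequence, projecting raw attributions
#' onto the observed bases (the importance track) and recording hypothetical
#' scores, model predictions, and the per-example completeness gap
#' `|sum(raw) - (f(x) - f(baseline))|`. Violations of the completeness
#' tolerance are reported with a message.
#'
#' @param model A trained [EnhancerCNN-class].
#' @param x Sequences: `EnhancerSet`, `DNAStringSet`, or character vector.
#' @param nSteps Interpolation steps (default 128).
#' @param baseline L x 4 baseline matrix; default uniform 0.25.
#' @param on Attribute the `"logit"` (default) or the `"prob"`.
#' @param tolerance Completeness gap above which an example is flagged.
#' @return An [AttributionSet-class].
#' @export
batchAttributions <- function(model, x, nSteps = 128L, baseline = NULL,
                              on = c("logit", "prob"), tolerance = 0.01) {
  on <- match.arg(on)
  if (!model@trained) stop("model is untrained; train it before attribution")
  seqs <- if (methods::is(x, "EnhancerSet")) as.character(sequences(x))
          else as.character(x)
  n <- length(seqs)
  if (!n) stop("no sequences to attribute")
  imp <- vector("list", n); hyp <- vector("list", n)
  preds <- numeric(n); gaps <- numeric(n)
  for (i in seq_len(n)) {
    a <- .attributeOne(model, seqs[i], baseline, nSteps, on)
    imp[[i]] <- a$importance
    hyp[[i]] <- a$hypothetical
    gaps[i] <- a$gap
    preds[i] <- predict(model, seqs[i])
  }
  nbad <- sum(gaps > tolerance)
  if (nbad) message(nbad, " example(s) exceed completeness tolerance ",
                    tolerance)
  new("AttributionSet", seqs = seqs, importance = imp, hypothetical = hyp,
      predictions = preds, gaps = gaps, nSteps = as.integer(nSteps),
      baseline = if (is.null(baseline)) "uniform" else "custom")
}
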