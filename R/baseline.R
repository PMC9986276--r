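#' Linear baseline classifier
#'
#' A single affine map on the flattened one-hot encoding with a sigmoid link
#' (logistic regression, lightly ridge-regularised for numerical stability),
#' trained and evaluated on the same stratified splits as [trainCNN()] under
#' the same seed, so its report is directly comparable to the CNN's.
#'
#' @param x An [EnhancerSet-class].
#' @param seed Split seed (match the CNN's `hp$seed` for identical splits).
#' @param valFraction,testFraction Split fractions (defaults match
#'   [cnnHyperparams()]).
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @param shuffleLabels Permute labels before splitting (negative control).
#' @return List with `fit` (the glmnet object) and `report` (held-out-test
#'   metrics from [evalReport()] plus split sizes).
#' @export
linearBaseline <- function(x, seed = 1L, valFraction = 0.15,
                           testFraction = 0.15, lambda = 1e-3,
                           shuffleLabels = FALSE) {
  codes <- .codesMatrix(sequences(x))
  y <- enhancerLabels(x)
  n <- nrow(codes); L <- ncol(codes)
  set.seed(seed)
  if (shuffleLabels) y <- sample(y)
  sp <- .stratifiedSplit(y, valFraction, testFraction)
  X <- matrix(0, n, 4L * L)
  X[cbind(rep(seq_len(n), L),
          (rep(seq_len(L), each = n) - 1L) * 4L + as.vector(codes))] <- 1
  fit <- glmnet::glmnet(X[sp$train, , drop = FALSE], y[sp$train],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  pTe <- as.numeric(stats::predict(fit, X[sp$test, , drop = FALSE],
                                   type = "response"))
  pVa <- as.numeric(stats::predict(fit, X[sp$val, , drop = FALSE],
                                   type = "response"))
  report <- evalReport(pTe, y[sp$test])
  report$valAuroc <- evalReport(pVa, y[sp$val])$auroc
  report$split <- c(train = length(sp$train), val = length(sp$val),
                    test = length(sp$test))
  list(fit = fit, report = report)
}
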