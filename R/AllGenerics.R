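#' Extract the sequences of a dataset
#' @param x An object holding sequences.
#' @return A [Biostrings::DNAStringSet].
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Extract the binary labels of a dataset
#' @param x An object holding labels.
#' @return Integer vector of 0/1 labels.
#' @export
setGeneric("enhancerLabels", function(x) standardGeneric("enhancerLabels"))

#' Integrated Gradients attribution for one sequence
#'
#' Computes the raw L x 4 attribution of a model output with respect to the
#' one-hot input, along the straight path from `baseline` to `x`, using a
#' right Riemann sum over `nSteps` interpolation points:
#' `attr_ij = (x_ij - baseline_ij) * mean_k grad_ij(baseline + (k/nSteps)(x - baseline))`.
#'
#' @param model A model with a differentiable scalar output
#'   ([EnhancerCNN-class] or [LinearSeqModel-class]).
#' @param x Sequence to attribute: a character string over ACGT or an L x 4
#'   one-hot (or dense) matrix.
#' @param baseline Reference input, L x 4 matrix; default uniform 0.25.
#' @param nSteps Number of interpolation steps (>= 16 recommended; default 128).
#' @param on Scale of the attributed output: `"logit"` (default; avoids
#'   sigmoid saturation) or `"prob"`.
#' @return L x 4 numeric matrix of raw attributions.
#' @seealso [hypotheticalScores()], [batchAttributions()]
#' @export
setGeneric("integratedGradients",
  function(model, x, baseline = NULL, nSteps = 128L, on = c("logit", "prob"))
    standardGeneric("integratedGradients"))

#' Hypothetical importance scores
#'
#' The attribution each base *would* receive at each position were it the
#' observed base: `hyp_jb = meanPathGrad_jb * (1 - baseline_jb)`. Entries at
#' the observed base equal the actual (projected) importance.
#'
#' @inheritParams integratedGradients
#' @return L x 4 numeric matrix of hypothetical importances.
#' @export
setGeneric("hypotheticalScores",
  function(model, x, baseline = NULL, nSteps = 128L, on = c("logit", "prob"))
    standardGeneric("hypotheticalScores"))
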