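#' @import methods
#' @importFrom Biostrings DNAStringSet width
#' @importFrom GenomicRanges GRanges
NULL

#' Labelled enhancer sequence set
#'
#' Container for a fixed-length, binary-labelled DNA sequence dataset: the
#' positive class are putative active enhancers (open chromatin overlapping an
#' H3K27ac peak), the negative class are non-active enhancers (open chromatin
#' without the mark). All sequences share one length; provenance intervals are
#' optional (synthetic sets carry an empty `GRanges`).
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width sequences.
#' @slot label Integer vector, 1 = active, 0 = non-active, parallel to `seqs`.
#' @slot ranges A [GenomicRanges::GRanges] of source intervals (may be empty).
#'
#' @seealso [enhancerSet()], [simulateEnhancerStudy()]
#' @export
setClass("EnhancerSet",
  slots = c(seqs = "DNAStringSet", label = "integer", ranges = "GRanges"),
  validity = function(object) {
    msg <- character()
    if (length(object@seqs) != length(object@label))
      msg <- c(msg, "lengths of 'seqs' and 'label' differ")
    if (length(object@label) && !all(object@label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0 or 1")
    w <- unique(width(object@seqs))
    if (length(w) > 1)
      msg <- c(msg, "all sequences must share one length")
    if (length(object@ranges) && length(object@ranges) != length(object@seqs))
      msg <- c(msg, "'ranges', when non-empty, must be parallel to 'seqs'")
    if (length(msg)) msg else TRUE
  }
)

#' Trained (or untrained) convolutional enhancer classifier
#'
#' A single-convolutional-layer binary classifier: conv1d over one-hot DNA,
#' ReLU, per-filter global max pooling, one dense ReLU layer, and a sigmoid
#' output neuron. Weights are stored as plain numeric matrices so the model is
#' fully serialisable and its input gradients are available for attribution.
#'
#' @slot hyperparams List of hyper-parameters (see [cnnHyperparams()]).
#' @slot weights List of weight matrices (`Wm`, `bc`, `W1`, `b1`, `W2`, `b2`).
#' @slot inputLength Integer, expected sequence length L.
#' @slot trained Logical flag.
#' @slot history Data frame of per-epoch training/validation loss.
#'
#' @seealso [buildCNN()], [trainCNN()]
#' @export
setClass("EnhancerCNN",
  slots = c(hyperparams = "list", weights = "list", inputLength = "integer",
            trained = "logical", history = "data.frame"))

#' Linear sequence scorer
#'
#' An affine map on the flattened one-hot encoding, `f(x) = <W, x> + b`. Used
#' as a closed-form oracle for the attribution machinery (Integrated Gradients
#' is exact on linear models for any step count).
#'
#' @slot weights L x 4 numeric matrix of per-position, per-base weights.
#' @slot bias Numeric scalar intercept.
#' @export
setClass("LinearSeqModel", slots = c(weights = "matrix", bias = "numeric"))

#' Per-sequence attribution tracks
#'
#' Integrated-Gradients results for a set of sequences: projected importance
#' (attribution mass on the observed base, zero elsewhere), hypothetical
#' importance (what each base would receive were it observed), model outputs,
#' and per-example completeness gaps measured on the raw attribution.
#'
#' @slot seqs Character vector of the attributed sequences.
#' @slot importance List of L x 4 matrices (observed-base mass only).
#' @slot hypothetical List of L x 4 matrices.
#' @slot predictions Numeric vector of model probabilities.
#' @slot gaps Numeric vector, |sum(raw) - (f(x) - f(baseline))| per example.
#' @slot nSteps Integer, interpolation steps used.
#' @slot baseline Character, baseline description ("uniform" by default).
#' @export
setClass("AttributionSet",
  slots = c(seqs = "character", importance = "list", hypothetical = "list",
            predictions = "numeric", gaps = "numeric", nSteps = "integer",
            baseline = "character"))

#' Signed position weight matrix motif
#'
#' A motif aggregated from attribution seqlets. The sign of `importanceScore`
#' carries the direction of enrichment: positive means enriched in the active
#' (positive) set, negative in the non-active set.
#'
#' @slot pwm W x 4 probability matrix, rows are positions and sum to 1,
#'   columns ordered A, C, G, T.
#' @slot importanceScore Mean summed importance of member seqlets (signed).
#' @slot nSeqlets Number of member seqlets.
#' @slot consensus Argmax-base consensus string.
#' @slot ledger List of annotations accumulated by post-processing
#'   (trim offsets, filter verdicts, provenance).
#' @export
setClass("MotifModel",
  slots = c(pwm = "matrix", importanceScore = "numeric", nSeqlets = "integer",
            consensus = "character", ledger = "list"),
  validity = function(object) {
    p <- object@pwm
    if (ncol(p) != 4) return("pwm must have 4 columns (A,C,G,T)")
    if (nrow(p) > 0) {
      if (any(p < 0)) return("pwm entries must be non-negative")
      if (any(abs(rowSums(p) - 1) > 1e-6)) return("pwm rows must sum to 1")
    }
    TRUE
  }
)

#' Collection of motifs
#'
#' A named list of [MotifModel-class] objects; doubles as the known-motif
#' database container, in which names are transcription-factor names.
#'
#' @slot motifs Named list of `MotifModel` objects.
#' @export
setClass("MotifSet", slots = c(motifs = "list"),
  validity = function(object) {
    if (length(object@motifs) &&
        !all(vapply(object@motifs, is, logical(1), "MotifModel")))
      return("all elements must be MotifModel objects")
    TRUE
  }
)

#' @export
setMethod("show", "EnhancerSet", function(object) {
  n <- length(object@seqs)
  cat("EnhancerSet with", n, "sequences of length",
      if (n) width(object@seqs)[1] else NA, "\n")
  cat("  active (label 1):    ", sum(object@label == 1L), "\n")
  cat("  non-active (label 0):", sum(object@label == 0L), "\n")
  if (length(object@ranges)) cat("  provenance ranges attached\n")
})

#' @export
setMethod("show", "EnhancerCNN", function(object) {
  hp <- object@hyperparams
  cat("EnhancerCNN (", if (object@trained) "trained" else "untrained", ")\n",
      sep = "")
  cat("  input length:", object@inputLength,
      "| filters:", hp$nFilters, "x", hp$kernelSize,
      "| dense:", hp$denseUnits, "\n")
  if (nrow(object@history))
    cat("  epochs run:", nrow(object@history), "\n")
})

#' @export
setMethod("show", "AttributionSet", function(object) {
  cat("AttributionSet with", length(object@seqs), "tracks (nSteps =",
      object@nSteps, ", baseline =", object@baseline, ")\n")
  if (length(object@gaps))
    cat("  median completeness gap:", signif(stats::median(object@gaps), 3), "\n")
})

#' @export
setMethod("show", "MotifModel", function(object) {
  cat("MotifModel ", object@consensus,
      " (width ", nrow(object@pwm),
      ", n_seqlets ", object@nSeqlets,
      ", importance ", signif(object@importanceScore, 3), ")\n", sep = "")
})

#' @export
setMethod("show", "MotifSet", function(object) {
  cat("MotifSet of", length(object@motifs), "motifs\n")
  nm <- names(object@motifs)
  for (i in seq_along(object@motifs)) {
    m <- object@motifs[[i]]
    cat(sprintf("  [%d] %s %s (n=%d, score=%.3g)\n", i,
                if (!is.null(nm)) nm[i] else "", m@consensus,
                m@nSeqlets, m@importanceScore))
  }
})

#' @export
setMethod("length", "EnhancerSet", function(x) length(x@seqs))

#' @export
setMethod("length", "MotifSet", function(x) length(x@motifs))

#' @export
setMethod("[[", "MotifSet", function(x, i) x@motifs[[i]])

#' @export
setMethod("names", "MotifSet", function(x) names(x@motifs))
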