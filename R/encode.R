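BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Row i of the result is the indicator of base i in the fixed order
#' A, C, G, T; every row sums to 1.
#'
#' @param x A character string (or `DNAString`) over ACGT.
#' @return L x 4 numeric matrix with columns named A, C, G, T.
#' @examples
#' oneHotEncode("ACGT")
#' @export
oneHotEncode <- function(x) {
  codes <- .seqToCodes(as.character(x))
  L <- length(codes)
  m <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  m[cbind(seq_len(L), codes)] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' @param m L x 4 one-hot matrix (columns A, C, G, T).
#' @return Character string of length-L DNA.
#' @export
oneHotDecode <- function(m) {
  stopifnot(ncol(m) == 4)
  paste(BASES[max.col(m, ties.method = "first")], collapse = "")
}

# integer codes A=1 C=2 G=3 T=4 for one sequence; errors on anything else
.seqToCodes <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(ch, BASES)
  if (anyNA(codes))
    stop("non-ACGT character in sequence: '",
         ch[which(is.na(codes))[1]], "'")
  codes
}

# n x L integer code matrix for a set of equal-length sequences
.codesMatrix <- function(seqs) {
  seqs <- as.character(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must share one length")
  ch <- strsplit(seqs, "", fixed = TRUE)
  m <- matrix(match(unlist(ch), BASES), nrow = length(seqs), ncol = L,
              byrow = TRUE)
  if (anyNA(m)) stop("non-ACGT character in sequences")
  m
}
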