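#' Write motifs in MEME motif format
#'
#' Minimal MEME version 4 text format with uniform background and one
#' `letter-probability matrix` block per motif. A JSON-lines sidecar with
#' importance score, seqlet count and consensus can be written alongside.
#'
#' @param motifs A [MotifSet-class], or a named list of PWMs / `MotifModel`s.
#' @param path Output `.meme` path.
#' @param sidecar Optional path for a JSON-lines metadata sidecar.
#' @return `path`, invisibly.
#' @export
writeMEME <- function(motifs, path, sidecar = NULL) {
  if (methods::is(motifs, "MotifSet")) motifs <- motifs@motifs
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    names(motifs) <- paste0("motif", seq_along(motifs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  meta <- character()
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    pwm <- if (methods::is(m, "MotifModel")) m@pwm else m
    nsites <- if (methods::is(m, "MotifModel")) max(m@nSeqlets, 1L) else 20L
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(pwm), nsites), con)
    writeLines(apply(pwm, 1, function(r)
      paste(sprintf("%.6f", r), collapse = "  ")), con)
    writeLines("", con)
    if (methods::is(m, "MotifModel"))
      meta <- c(meta, jsonlite::toJSON(
        list(name = nm, importance_score = m@importanceScore,
             n_seqlets = m@nSeqlets, consensus = m@consensus),
        auto_unbox = TRUE, digits = NA))
  }
  if (!is.null(sidecar) && length(meta)) writeLines(meta, sidecar)
  invisible(path)
}

#' Read motifs from a MEME motif format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections into a
#' [MotifSet-class]; names are the motif identifiers (for a known-motif
#' database, the TF names).
#'
#' @param path Path to a MEME motif file.
#' @return A [MotifSet-class].
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  motifs <- list()
  for (s in starts) {
    toks <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    nm <- toks[2]
    h <- s
    while (h <= length(lines) &&
           !grepl("^letter-probability matrix", lines[h])) h <- h + 1
    if (h > length(lines))
      stop("motif ", nm, ": no letter-probability matrix header")
    wTok <- regmatches(lines[h], regexpr("w=\\s*\\d+", lines[h]))
    w <- if (length(wTok)) as.integer(sub("w=\\s*", "", wTok)) else NA
    rows <- list()
    i <- h + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    pwm <- do.call(rbind, rows)
    if (!is.na(w) && nrow(pwm) != w)
      stop("motif ", nm, ": matrix has ", nrow(pwm), " rows, header says ", w)
    if (any(abs(rowSums(pwm) - 1) > 1e-4))
      stop("motif ", nm, ": rows do not sum to 1")
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- BASES
    motifs[[nm]] <- new("MotifModel", pwm = pwm, importanceScore = 0,
                        nSeqlets = 0L,
                        consensus = paste(
                          BASES[max.col(pwm, ties.method = "first")],
                          collapse = ""),
                        ledger = list())
  }
  new("MotifSet", motifs = motifs)
}
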