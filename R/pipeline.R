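#' Run the full enhancer-motif pipeline
#'
#' Executes the stages build -> train -> attribute -> discover -> vet ->
#' cooccur into a run directory, recording every stage's parameters, seed
#' and outputs in `manifest.json`. The one global seed fans out to per-stage
#' seeds by fixed offsets, so any stage is reproducible in isolation. A
#' stage failure halts the run with the failing stage named; outputs of
#' completed stages are preserved, and with `resume = TRUE` stages whose
#' outputs already exist are skipped.
#'
#' Configuration is a nested list (or the path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{outDir}{run directory (required)}
#'   \item{seed}{global seed, default 1}
#'   \item{simulate}{arguments for [simulateEnhancerStudy()] to generate the
#'     dataset, \emph{or}}
#'   \item{inputs}{paths `candidates`, `marks`, `tss`, `genome` plus
#'     `length`, to build the dataset from interval files}
#'   \item{train}{overrides for [cnnHyperparams()]}
#'   \item{attribute}{`n` sequences per class (default 100) and `nSteps`
#'     (default 64)}
#'   \item{discover}{arguments for [discoverMotifs()]}
#'   \item{vet}{`db` (MEME path; default the toy database) and `expr`
#'     (TSV with columns tf/day0/day26/day39; default the toy fixture)}
#' }
#'
#' @param config Nested list or YAML path.
#' @return Invisibly, a list with the dataset, model, motifs, verdicts and
#'   co-occurrence result.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$outDir)) stop("config$outDir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  resume <- isTRUE(config$resume)

  if (!is.null(config$inputs)) {
    needed <- unlist(config$inputs[c("candidates", "marks", "tss", "genome")])
    missing <- needed[!file.exists(needed)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  manifest <- list(seed = seed, stages = list())
  record <- function(stage, params, outputs) {
    manifest$stages[[stage]] <<- list(seed = params$seed, params = params,
                                      outputs = outputs)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  runStage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- build ---------------------------------------------------------------
  dsDir <- file.path(outDir, "dataset")
  dataset <- runStage("build", function() {
    if (resume && file.exists(file.path(dsDir, "positive.fa")))
      return(readEnhancerSet(file.path(dsDir, "positive.fa"),
                             file.path(dsDir, "negative.fa")))
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      cand <- readPeakIntervals(inp$candidates)
      marks <- readPeakIntervals(inp$marks)
      tss <- readPeakIntervals(inp$tss)
      sp <- splitByOverlap(cand, marks)
      act <- excludePromoters(sp$withMark, tss)
      non <- excludePromoters(sp$withoutMark, tss)
      N <- if (is.null(inp$length)) 500L else as.integer(inp$length)
      genome <- Biostrings::readDNAStringSet(inp$genome)
      names(genome) <- sub("\\s.*$", "", names(genome))
      GenomeInfoDb::seqlengths(act) <-
        Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(act),
                                        names(genome))]
      GenomeInfoDb::seqlengths(non) <-
        Biostrings::width(genome)[match(GenomeInfoDb::seqlevels(non),
                                        names(genome))]
      act <- centerFixLength(act, N)
      non <- centerFixLength(non, N)
      pos <- extractSequences(act, genome, 1L)
      neg <- extractSequences(non, genome, 0L)
      ds <- enhancerSet(pos$seqs, neg$seqs, pos$intervals, neg$intervals)
    } else {
      simArgs <- if (is.null(config$simulate)) list() else config$simulate
      simArgs$seed <- seed + 101L
      ds <- do.call(simulateEnhancerStudy, simArgs)$set
    }
    writeEnhancerSet(ds, dsDir)
    record("build", list(seed = seed + 101L),
           list(dir = dsDir, nPos = sum(enhancerLabels(ds) == 1),
                nNeg = sum(enhancerLabels(ds) == 0)))
    ds
  })

  # -- train ---------------------------------------------------------------
  modelPath <- file.path(outDir, "model.json")
  fit <- runStage("train", function() {
    hpArgs <- if (is.null(config$train)) list() else config$train
    hpArgs$seed <- seed + 202L
    hp <- do.call(cnnHyperparams, hpArgs)
    if (resume && file.exists(modelPath))
      return(list(model = readCNNModel(modelPath), report = NULL))
    fit <- trainCNN(dataset, hp)
    writeCNNModel(fit$model, modelPath)
    jsonlite::write_json(fit$report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    record("train", hp, list(model = modelPath,
                             testAuroc = fit$report$auroc))
    fit
  })

  # -- attribute -----------------------------------------------------------
  attrPath <- file.path(outDir, "attributions.rds")
  attr <- runStage("attribute", function() {
    if (resume && file.exists(attrPath)) return(readRDS(attrPath))
    aConf <- config$attribute
    nPer <- if (is.null(aConf$n)) 100L else as.integer(aConf$n)
    nSteps <- if (is.null(aConf$nSteps)) 64L else as.integer(aConf$nSteps)
    # attribute the most confidently classified examples of each class
    pos <- as.character(positiveSet(dataset))
    neg <- as.character(negativeSet(dataset))
    pos <- pos[order(predict(fit$model, pos), decreasing = TRUE)]
    neg <- neg[order(predict(fit$model, neg))]
    seqs <- c(utils::head(pos, nPer), utils::head(neg, nPer))
    a <- batchAttributions(fit$model, seqs, nSteps = nSteps)
    saveRDS(a, attrPath)
    record("attribute", list(seed = NA, n = nPer, nSteps = nSteps),
           list(attributions = attrPath))
    a
  })

  # -- discover ------------------------------------------------------------
  memePath <- file.path(outDir, "motifs.meme")
  motifs <- runStage("discover", function() {
    dConf <- if (is.null(config$discover)) list() else config$discover
    dConf$attr <- attr
    dConf$seed <- seed + 303L
    m <- do.call(discoverMotifs, dConf)
    if (length(m))
      writeMEME(m, memePath, sidecar = file.path(outDir, "motifs.jsonl"))
    record("discover", list(seed = seed + 303L),
           list(meme = memePath, nMotifs = length(m)))
    m
  })

  # -- vet -----------------------------------------------------------------
  verdictPath <- file.path(outDir, "verdicts.tsv")
  verdicts <- runStage("vet", function() {
    if (!length(motifs)) return(NULL)
    vConf <- config$vet
    db <- if (is.null(vConf$db)) toyMotifDatabase() else readMEME(vConf$db)
    expr <- if (is.null(vConf$expr)) makeExpressionFixture()
            else utils::read.delim(vConf$expr, stringsAsFactors = FALSE)
    v <- vetMotifs(motifs, db, expr, seed = seed + 404L)
    utils::write.table(cbind(motif = rownames(v), v), verdictPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("vet", list(seed = seed + 404L), list(verdicts = verdictPath))
    v
  })

  # -- cooccur -------------------------------------------------------------
  cooccur <- runStage("cooccur", function() {
    if (length(motifs) < 2) return(NULL)
    trims <- lapply(seq_len(length(motifs)), function(i)
      trimMotif(motifs[[i]]))
    ok <- which(vapply(trims, function(m) nrow(m@pwm) >= 2, logical(1)))
    if (length(ok) < 2) return(NULL)
    a <- trims[[ok[1]]]; b <- trims[[ok[2]]]
    tab <- cooccurrenceTable(a, b, positiveSet(dataset))
    fis <- fisherCooccurrence(tab)
    res <- c(tab, fis)
    jsonlite::write_json(res, file.path(outDir, "cooccur.json"),
                         auto_unbox = TRUE, digits = NA)
    record("cooccur", list(seed = NA),
           list(json = file.path(outDir, "cooccur.json")))
    res
  })

  invisible(list(dataset = dataset, model = fit$model,
                 report = fit$report, attributions = attr,
                 motifs = motifs, verdicts = verdicts, cooccur = cooccur))
}
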