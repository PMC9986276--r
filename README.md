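# remotif

Discovering transcription-factor motifs in **active** and **non-active
enhancers** by interrogating a trained sequence classifier.

Open-chromatin regions (ATAC peaks) that overlap an H3K27ac ChIP-seq peak
behave as active enhancers; open regions without the mark are a mixed pool
of poised enhancers, repressed enhancers and silencers. `remotif` builds
labelled fixed-length sequence sets from such interval files, trains a small
one-dimensional convolutional network to separate the two classes, and then
extracts the sequence features the network learned:

* **Classifier** — conv1d → ReLU → global max pooling → dense → sigmoid,
  trained with class-weighted cross-entropy, early stopping, seeded end to
  end; plus a logistic baseline on the flattened one-hot encoding and a
  grid search over hyper-parameters.
* **Attribution** — Integrated Gradients (right Riemann sum, uniform 0.25
  baseline) yielding importance and hypothetical-importance tracks per
  sequence, with the completeness axiom checked per example.
* **Motif discovery** — high-attribution seqlets (per-sequence permutation
  null), signed by direction of enrichment (positive = active set), greedily
  clustered by best-offset correlation of hypothetical slices, and averaged
  into position weight matrices.
* **Vetting** — information-content trimming (IC = 2 + Σ p log₂ p; 0.3-bit
  threshold), stringency (IC > 1.9), a TOMTOM-style similarity search with
  permutation-null q-values against a known-motif database (MEME motif
  format in and out), an AME-style Fisher enrichment test, a seven-criterion
  spurious-motif filter, a 2-fold staged-expression rule for the matched TF,
  and motif co-occurrence tests.
* **Synthetic data** — seeded generators for backgrounds with controlled GC,
  motif implantation with truth manifests, toy genomes with planted peak
  files, a toy motif database and a staged expression fixture, so the whole
  pipeline is exercisable without any external data.

## Worked example

Train on a synthetic study set (positives: GC 0.55 with the ASCL1-like
E-box `CAGCTGC` implanted in 40%; negatives: GC 0.45), then recover the
implanted motif from the trained network:

```r
library(remotif)

sim <- simulateEnhancerStudy(seed = 11)       # 2000 + 2000 x 200 bp
fit <- trainCNN(sim$set, cnnHyperparams(seed = 11))
round(unlist(fit$report[c("auroc", "auprc", "accuracy")]), 3)
#>    auroc    auprc accuracy
#>    0.949    0.951    0.885

## attribution and discovery on a matched-GC recovery set
db  <- toyMotifDatabase()
rec <- simulateEnhancerStudy(nPos = 800, nNeg = 800, gcPos = 0.5,
                             gcNeg = 0.5, seed = 101)
cnn <- trainCNN(rec$set, cnnHyperparams(kernelSize = 8, seed = 101,
                                        maxEpochs = 80, patience = 15),
                nRestarts = 2)
pos <- as.character(positiveSet(rec$set))
pos <- pos[order(predict(cnn$model, pos), decreasing = TRUE)]
att <- batchAttributions(cnn$model, head(pos, 200), nSteps = 64)
mot <- discoverMotifs(att, seed = 101)
trimMotif(mot[[1]])@consensus
#> [1] "CAGCTGC"
head(matchKnown(mot[[1]], db), 1)[, c("tf", "score", "overlap", "q.value")]
#>      tf     score   overlap    q.value
#> 1 ASCL1 0.4666264 0.4666667 0.01449275
```

The held-out AUROC of 0.949 reflects both signals the positives carry
(composition and motif); the top discovered positive-sign motif trims to the
implanted E-box and matches the ASCL1 entry of the toy database at
q < 0.05. Vetting a discovered motif set and testing motif co-occurrence:

```r
verdicts <- vetMotifs(mot, db, makeExpressionFixture())
tab <- cooccurrenceFromMarginals(total = 18686, nA = 13688, nB = 10334,
                                 nBoth = 6944)
fisherCooccurrence(tab)
#> $oddsRatio
#> [1] 0.4884032
#>
#> $p.value
#> [1] 4.918845e-98
```

A full run (build → train → attribute → discover → vet → cooccur) is one
call, `runPipeline(config)`, with a YAML or list configuration; a thin
command-line wrapper lives in `inst/scripts/remotif-run.R`.

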