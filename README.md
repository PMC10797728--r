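# tmegraph

Predicting neoadjuvant chemotherapy (NAC) response in triple-negative
breast cancer from H&E histology, in two steps:

1. **Tile level.** 224×224 tissue tiles, cut from annotated regions that
   a tile must overlap by at least 90%, are stain-normalized and
   color-deconvolved; an 80-dimensional texture vector (GLCM, Gabor,
   LBP, Tamura, and histogram families) is computed on the hematoxylin
   channel of each tile. After excluding all-zero, NA and duplicate
   features, four classifiers (1NN, linear SVM, RBF SVM, RUSBoost
   ensemble trees) are compared under stratified eightfold
   cross-validation, and the predicted tile classes are assembled into a
   per-patient *histology classification map*.

2. **Patient level.** For every pair of histology classes, connected
   tile clusters become nodes of an undirected, unweighted
   tumor-microenvironment (TME) graph G = (V, E) with an edge whenever
   two cluster centroids lie within a Euclidean radius. Twenty features
   per pair — texture averages over cluster members, spectral node
   statistics (degree moments, clustering, spectral radius, algebraic
   connectivity λ₂, normalized-Laplacian energy), and minimum-spanning-
   tree connectivity — are weighted by ReliefF; the top 8 feed a
   classifier evaluated by leave-one-out cross-validation (LOO-CV)
   against the binary endpoint pCR (pathological complete response,
   positive class) vs RD (residual disease).

A synthetic-data generator produces class-conditional tile textures
(Gaussian random fields plus nucleus disks, rendered through two-stain
optical-density mixing), spatially coherent label maps, and cohorts with
a *planted* outcome-linked tumor–tTIL interface signal of controlled
standardized effect size, so the entire pipeline is testable without
imaging data.

## Worked example

```r
library(tmegraph)

# published-style confusion counts -> metrics
m <- binary_metrics(binary_confusion(TP = 42, FP = 5, TN = 29, FN = 9))
round(100 * c(accuracy = m$accuracy, sensitivity = m$sensitivity,
              specificity = m$specificity), 2)
#>    accuracy sensitivity specificity
#>       83.53       82.35       85.29

# full synthetic pipeline: cohort -> tiles -> maps -> graphs -> LOO
res <- run_end_to_end(list(seed = 7))
res$loocv
#> Leave-one-out response prediction (rbfSVM, nested selection)
#>   n = 60   accuracy 86.67%  sensitivity 84.85%  specificity 88.89%
#>   precision 0.903  F1 0.875  AUC 0.900
```

The first block turns leave-one-out confusion counts (42 of 51 pCR and
29 of 34 RD patients correct) into the standard binary metrics with pCR
as the positive class. The second generates a 60-patient synthetic
cohort whose tumor–tTIL interface density is higher in pCR patients by
two within-group standard deviations, runs tile classification, map
assembly, pair-feature extraction and ReliefF selection, and reports
leave-one-out response prediction — the AUC well above chance shows the
planted spatial interaction being recovered end to end.

A command-line wrapper with `synth`, `demo`, `predict` and `report`
verbs lives at `inst/cli/tmegraph.R`.

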