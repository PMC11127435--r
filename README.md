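# kinepose

Skeleton field synthesis, multi-person pose assembly, and movement
classification for camera-based human-movement monitoring.

## The problem

Monitoring movement (and movement-related injury risk) from video
reduces to a chain of well-defined computations once a keypoint
detector has done its work: associate detected joints into per-person
skeletons, standardize the resulting coordinate sequences so camera
position and body size drop out, summarize each sequence as a
fixed-length kinematic feature vector, and classify. `kinepose`
implements that whole chain — plus a synthetic-motion generator that
renders the ground-truth fields a detector would predict — so every
stage is testable end to end with no trained network and no external
recordings. It is aimed at researchers building or auditing
skeleton-based activity/risk classifiers who need a transparent,
deterministic reference pipeline.

## The model in brief

* **Confidence maps** (per joint *j*, person *n*):
  `s*_{j,n}(q) = exp(-||q - x_{j,n}||² / σ²)`, fused over persons by
  the pointwise maximum.
* **Part affinity fields** (per limb *c*): the unit vector
  `V = (x_{j1,n} - x_{j2,n}) / ||·||` on the limb's support band,
  averaged over overlapping persons.
* **Affinity reliability** of a candidate joint pair:
  `E = (1/K) Σ_k L_c(q(u_k)) · d̂` along `q(u) = (1-u)d_{j1} + u d_{j2}`,
  K = 10 uniform samples; limbs are accepted greedily by descending E.
* **Standardization**: per-sequence range normalization of x to
  [-200, 200] and y to [-800, 800], then per-frame Procrustes
  calibration — centroid translation, per-axis RMS scaling
  `S_F = sqrt(mean(x̂²))`, closed-form least-squares rotation — with
  the residual Procrustes distance `P²_d` recorded per frame.
* **Features**: per body segment (BB/UB/LB) and axis, degree-5
  least-squares polynomial of the segment centroid trajectory over
  normalized time plus its `R² = 1 - SS_res/SS_tot`; 42 values per
  sequence.
* **Reduction**: five-stage PCA (train mean, scatter matrix,
  eigendecomposition, cumulative-variance component selection at
  precision 0.95, projection), always centring with the training mean.
* **Classification**: one-vs-rest RBF SVM (C = 1), 70/30 stratified
  split, reporting per-class and macro precision / sensitivity /
  specificity in percent.

## Worked example

```r
library(kinepose)

## simulate one running sequence, render one frame, re-detect it
p  <- SceneParams(64, 64, sigma = 3, limbWidth = 2, noiseSd = 1)
m  <- makeMotion("running", nFrames = 40, seed = 1, params = p)
sc <- makeScene(list(m), frameIdx = 1, params = p)
assembleScene(sc)[[1]]
#> AssembledSkeleton: 15/15 joints, 14 limbs, mean E 0.894

## the full benchmark: 3 activity classes x 60 sequences through
## assembly, calibration, features, PCA and the SVM
res <- benchmarkSuite(benchmarkConfig(), seed = 1)
res$report
#> ClassifierReport: accuracy 100.00% over 54 samples
#>   macro precision 100.00%, sensitivity 100.00%, specificity 100.00%
#>                aerobics running table_tennis
#>   aerobics           18       0            0
#>   running             0      18            0
#>   table_tennis        0       0           18
res$pca
#> PCAModel: 42 -> 3 components (precision 0.95, mode standard), explained 0.9791
```

The assembled skeleton recovers all 15 joints of the rendered person
with near-unit limb reliabilities; the end-to-end run classifies the
54 held-out sequences by activity, and the report prints the confusion
matrix with per-class metrics in percent.

A command-line wrapper over the same functions ships at
`inst/cli/kinepose.R`:

```sh
Rscript inst/cli/kinepose.R pipeline --config my_config.yaml --seed 1 --out results/
```

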