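# qmapsynth

Synthesis of quantitative T1rho maps from T2 maps for knee MRI, as a
fully simulated, tested pipeline in R.

## The problem

T1rho relaxation times of knee cartilage are sensitive to the
proteoglycan loss that marks early osteoarthritis, but T1rho mapping is
slow to acquire and rarely part of clinical protocols; T2 mapping is far
more common. Image synthesis offers a way out: learn the mapping from T2
maps to T1rho maps, so a T1rho biomarker can be read out of data that
already exists. `qmapsynth` implements that pipeline end to end for
method development at desk scale, with synthetic knee phantoms standing
in for patient cohorts:

1. **Phantoms** — stylized sagittal knees with six cartilage
   compartments (MF, LF, MT, LT, PAT, TRO), bone, muscle and background;
   ground-truth T1rho/T2/S0 volumes; focal OA-like T1rho lesions; and
   multi-echo spin-lock (TSL 0/10/40/80 ms) and T2-prepared
   (TE 0/12.9/25.7/51.4 ms) image series following
   `S(t) = S0 * exp(-t / T)` plus noise.
2. **Relaxometry** — voxelwise mono-exponential Levenberg–Marquardt
   fitting of the registered echo series into quantitative maps (ms).
3. **Synthesis** — a 2D U-Net (8 convolutional layers, ReLU, batch
   normalization, skip connections) trained to map T2 slices to T1rho
   slices under the region-weighted loss

   `loss = 1.5 * L2(y_cart, yhat_cart) + L1(y_bg, yhat_bg)`

   with inputs clipped to [0, 150] ms, a subject-wise 65:15:20
   train/validation/test split, early stopping on validation loss,
   4-fold cross-validation and hyperparameter search utilities.
4. **Evaluation** — masked NMSE (`100 * sum(err^2) / sum(truth^2)`),
   PSNR (data range 150 ms), Gaussian-window SSIM, voxel and
   compartment-mean Pearson correlation, Bland–Altman bias and 1.96-SD
   limits of agreement, and a compartment-mean quantification-error
   rate compared against the 6.42% clinically-significant-change
   threshold — including an out-of-distribution stratum built by coil
   bias fields and SNR rescaling.

## Worked example

Thirty phantom subjects (8 slices of 64 x 64), maps fitted from their
noisy echo series, tiny U-Net preset, subject-wise split:

```r
library(qmapsynth)

spec   <- phantomSpec()                     # 30 subjects, 1% noise
cohort <- makeCohort(spec, AcquisitionSpec())
fitted <- lapply(cohort$truths, function(tr) list(
  T1rho = fitMonoexponential(simulateEchoes(tr, AcquisitionSpec(), "T1rho"))@map,
  T2    = fitMonoexponential(simulateEchoes(tr, AcquisitionSpec(), "T2"))@map))

split <- splitDataset(names(fitted), seed = 1)
pairsOf <- function(ids) unlist(lapply(ids, function(id)
  makeSlicePairs(fitted[[id]]$T2, fitted[[id]]$T1rho,
                 cohort$truths[[id]]@labels, id)), recursive = FALSE)

model <- buildModel(tinyUNetSpec(), seed = 11)
model <- trainModel(model, pairsOf(split$train), pairsOf(split$val),
                    trainConfig(maxEpochs = 75, earlyStopPatience = 15, seed = 1))

preds  <- lapply(split$test, function(id) predictMap(model, fitted[[id]]$T2))
names(preds) <- split$test
report <- evaluateCohort(preds,
                         lapply(cohort$truths[split$test], function(t) t@t1rho),
                         lapply(cohort$truths[split$test], function(t) t@labels))
```

On the held-out test subjects this prints (one fixed seed, ~8 min on
one CPU for the whole pipeline):

```
cartilage NMSE          1.72 %     # error energy, fraction of truth energy
compartment Pearson r   0.970      # truth vs predicted compartment means
Bland-Altman bias      -1.82 ms    # mean difference of compartment means
quantification error    7.34 %     # vs the 6.42 % clinical threshold
baseline NMSE           2.88 %     # T2 rescaled by the cartilage mean ratio
```

so the network recovers the cartilage T1rho structure of held-out
phantoms with error energy well under the no-learning baseline and
compartment means that track the truth closely. Applying a 10% coil
bias field with halved SNR to the same test subjects (the
out-of-distribution stratum) raises median cartilage NMSE from 1.78%
to 2.06% and |bias| from 1.82 to 1.99 ms — the expected degradation
direction under a scanner/coil change.

`runPipeline(runConfig(), "rundir")` performs the same stages with
per-stage persistence and resumability, and
`inst/cli/qmapsynth.R simulate|fit|train|predict|evaluate|run` exposes
them from a shell.

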