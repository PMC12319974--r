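# mebold

Multi-echo BOLD fMRI tooling for precision functional mapping on
volumetric grids: thermal-noise removal, T2\* mapping and optimal echo
combination, motion quality control, nuisance regression, functional
connectivity, and split-half reliability — together with a synthetic
multi-echo generator that provides ground truth for every stage.

## The problem

Precision functional mapping characterizes an individual's functional
brain networks from hours of within-subject resting-state fMRI. In
developmental populations (children and especially newborns) that much
low-motion data is hard to collect, so acquisition and processing choices
that squeeze more reliability out of each minute matter. Two such choices
are modeled here:

1. **Multi-echo (ME) acquisition.** The gradient-echo signal decays as
   S(TE) = S₀·exp(−TE/T2\*). Reading several echo times per excitation
   lets one estimate T2\* voxelwise (log-linear fit across echoes) and
   combine the echoes with the contrast-optimal weighting

   w_e ∝ TE_e · exp(−TE_e / T2\*),  normalized to Σw = 1.

   Because neonatal tissue has much longer and more variable T2\* than
   adult cortex (water content, incomplete myelination), the optimal
   weighting shifts toward late echoes in infants — an age-specific
   quantity this package computes, summarizes, and uses.

2. **NORDIC-style thermal denoising.** Complex-valued (magnitude + phase)
   echo series are cut into patches; each patch's Casorati matrix (patch
   voxels × frames) is SVD hard-thresholded at the level of the largest
   singular value of a pure-noise matrix of the same size (estimated by
   seeded Monte-Carlo from the thermal noise SD, itself measured from
   noise frames appended to the run). Components indistinguishable from
   zero-mean thermal noise are removed; everything above the noise edge is
   kept untouched, preserving spatial precision.

Downstream, the package implements the standard connectivity
preprocessing chain (framewise-displacement censoring with strict
0.2 / 0.3 mm thresholds, respiratory band-stop filtering of motion
parameters, the 36-parameter confound model, 0.009–0.08 Hz band-pass) and
quantifies data quality as temporal SNR and as permuted split-half
reliability of connectivity matrices versus the amount of data.

## Worked example

Simulate an infant five-echo run (echo times 14.2–113.12 ms, TR 1.761 s,
3 trailing noise frames), denoise it, map T2\*, and combine:

```r
library(mebold)

acq <- fiveEchoPreset(nFrames = 80, gridShape = c(16, 16, 16))
run <- simulateRun(acq, tissuePreset("infant"), seed = 1)
run$series
#> MultiEchoSeries: 5 echo(es), grid 16x16x16, 80 frames (+3 noise)
#>   TE (ms): 14.20, 38.93, 63.66, 88.39, 113.12 | TR 1.761 s | phase: yes

estimateNoiseSigma(run$series)
#> NoiseEstimate: sigma = 1 (source: noise_frames)

den   <- nordicDenoiseRun(run$series, seed = 2)
t2map <- fitT2Star(den, mask = run$truth$mask)
t2map
#> T2StarMap: 16x16x16 voxels, 1472 valid
#>   T2* (ms): median 96.76 [IQR 80.69-110.54], bounds [2, 500]

round(weightSummary(t2map, echoTimes(acq)), 3)
#>         t2star echo1 echo2 echo3 echo4 echo5
#> mean    95.162 0.094 0.190 0.233 0.245 0.239
#> median  96.763 0.086 0.184 0.232 0.250 0.248
#> sd      23.083 0.029 0.024 0.006 0.019 0.034
#> p05     55.114 0.073 0.166 0.225 0.215 0.176
#> p95    131.497 0.133 0.233 0.242 0.259 0.275

tsnrMap(optimalCombine(den, t2map), mask = run$truth$mask)
#> TsnrMap '': 16x16x16 voxels, 1472 defined, mean 76.40 (SD 15.01)
```

The recovered median T2\* (~97 ms) matches the infant preset's ground
truth, and the weight table shows the infant signature: the third to
fifth echoes carry the heaviest weights, whereas an adult T2\* of ~50 ms
puts the mass on echoes 2–3:

```r
round(weightsAtT2Star(c(14.2, 38.93, 63.66, 88.39, 113.12), 50.71), 3)
#> [1] 0.144 0.242 0.243 0.207 0.163
```

Comparing the denoised combination with combining the raw echoes, on the
same run:

```r
#> tSNR gain with denoising: 42.49%
```

The end-to-end experiment — four conditions (multi-echo vs single-echo ×
raw vs denoised), motion QC, cleaning, connectivity, tSNR averaging over
low-motion runs, and split-half reliability — is `runPipeline()`; a thin
command-line wrapper lives in `inst/scripts/mepfm.R`.

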