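# uteFascia

Image processing for **deep fascia, aponeurosis and tendon** in
dual-echo ultra-short echo time (UTE) MRI of the lower limb.

Collagen-rich connective tissue has T2\* relaxation times near or below
1 ms, so it is invisible at conventional echo times. A dual-echo UTE
acquisition collects one image at TE ≈ 0.05 ms (fascia still bright)
and one at a few ms (fascia gone, muscle and fat remain). With each
tissue modelled as S(TE) = S0·exp(−TE/T2\*), the scaled difference

    I_sub = a · I_UTE − I_shTE ,

with the factor *a* chosen so a non-target region's intensity
statistics match between echoes (*region-specific scaling*), isolates
the deep fascia as a thin bright annulus at the muscle periphery.
This package implements the full processing chain around that idea:

* **phantom** — synthetic dual-echo leg cross-section (fat / fascia /
  muscle / septum / bone) with mono-exponential decay, Rician noise,
  periodic stripe corruption, bias field, ground-truth label masks and
  synthetic pennate fascicle tracts, so every stage is testable without
  scanner data;
* **enhance** — region-specific scaling, echo subtraction,
  statistics-driven contrast adjustment, disk top-hat (radius 10 px),
  adaptive 20×20 Wiener filtering, SNR measurement;
* **segment** — FFT-domain periodic-noise spike suppression, K-means
  intensity clustering (k = 3, 10 replicates, minimum within-cluster
  sum of squares), distance-transform watershed (threshold 0.6,
  negated Euclidean distance map, background masked out);
* **measure** — skeleton-based thickness of thin structures (thin to
  the midline, measure to the inner and outer boundary at each
  skeleton point, average per slice and across slices), Dice/Jaccard
  agreement (J = D/(2−D)), muscle cross-sectional area and volume;
* **architecture** — fascicle length (arc length), tract length filter
  [5, 200] mm, pennation angle against the muscle line of action,
  PCSA = volume / mean fascicle length;
* **io / pipeline** — NIfTI in/out (RNifti), plain-text streamline
  tracts, a config-driven `runPipeline()`, and a thin `exec/fascia`
  command line.

Core containers are S4 classes with validity checks (`SliceImage`,
`DualEchoPair`, `LabelMask`, `StreamlineSet`, result records); standard
operations sit on EBImage, RNifti and base R.

## Worked example

```r
library(uteFascia)

# Synthetic dual-echo leg slice: 256 px at 0.5 mm, 1.5 mm fascia,
# Rician noise sigma 0.03 + stripe corruption (the defaults).
ph   <- makePhantom(phantomSpec(seed = 7))
pair <- dualEchoPair(ph@ute, ph@shte, ph@te1, ph@te2)

rs <- regionSpecificScale(pair)     # match muscle between echoes
rs$scaling
#> ScalingResult: factor 0.80203 (median-ratio)

sub <- subtractEchoes(pair, rs$scaledUte)   # fascia-bright image
fd  <- fftDenoise(sub)                      # stripe suppression
cr  <- kmeansIntensity(fd$image, k = 3, replicates = 10, seed = 11)
fm  <- fasciaMaskFromClusters(cr, fd$image)

diceJaccard(fm, labelMask(labels(ph@truth) == 2L))
#> Agreement: Dice 1, Jaccard 1

thicknessReport(list(fm), spacing = spacing(ph@ute))
#> ThicknessReport: 1 slice(s), overall mean 1.498 mm
```

The scaling factor (≈0.80) matches the muscle median between echoes so
muscle cancels on subtraction; at this noise level the recovered fascia
mask matches the ground truth pixel for pixel, and its measured
thickness (1.498 mm) sits well within half a pixel (0.25 mm) of the
true 1.5 mm.

Muscle architecture from synthetic pennate tracts:

```r
ts <- makePennateTracts(1000, 22.37, c(0, 0, 1), c(5, 200), seed = 17)
mean(pennationAngles(ts, c(0, 0, 1)))
#> [1] 22.37
```

## Command line

```sh
exec/fascia phantom    --out out/ph --seed 3
exec/fascia subtract   --ute out/ph/ute.nii.gz --shte out/ph/shte.nii.gz --out out/sub
exec/fascia fftdenoise --in out/sub/subtraction.nii.gz --out out/fft
exec/fascia kmeans     --in out/fft/fft.nii.gz --out out/km --seed 3
exec/fascia thickness  --mask out/km/fascia_mask.nii.gz --out out/th
```

or everything at once from a config: `exec/fascia pipeline --config
cfg.yaml --out out` (stages, per-stage parameters and seed; a
provenance JSON capturing every parameter is written alongside the
results).

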