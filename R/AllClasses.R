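#' @import methods
#' @importFrom stats median sd quantile rnorm runif kmeans cov
#' @importFrom utils head tail write.csv
NULL

## ---- core image containers ----------------------------------------------

#' Single axial MRI slice
#'
#' A 2D grayscale slice with its in-plane pixel spacing and slice
#' thickness. This is the atom every processing stage consumes and
#' produces. Pixels are stored as a numeric matrix indexed `[row, col]`;
#' physical position of a pixel centre is `index * spacing` (mm).
#'
#' @slot pixels numeric matrix of intensities (finite values only).
#' @slot spacing numeric(2), (row_mm, col_mm) pixel spacing, both > 0.
#' @slot sliceThickness numeric(1), through-plane thickness in mm.
#'
#' @seealso [sliceImage()], [dualEchoPair()]
#' @export
setClass("SliceImage",
  slots = c(pixels = "matrix", spacing = "numeric", sliceThickness = "numeric"),
  prototype = prototype(spacing = c(1, 1), sliceThickness = 1))

setValidity("SliceImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be a numeric matrix")
  else if (!all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite (no NaN/Inf)")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two strictly positive values (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive value (mm)")
  if (length(msg)) msg else TRUE
})

#' Co-registered dual-echo pair
#'
#' Holds the ultra-short echo (UTE) and the short-TE (shTE) slice of one
#' dual-echo acquisition together with their echo times. The two grids
#' must be identical in size and spacing; the pair is assumed
#' co-registered since both echoes come from a single acquisition.
#'
#' @slot ute [SliceImage-class] acquired at `te1` (ms).
#' @slot shte [SliceImage-class] acquired at `te2` (ms).
#' @slot te1,te2 echo times in ms, `te1 < te2`.
#' @export
setClass("DualEchoPair",
  slots = c(ute = "SliceImage", shte = "SliceImage",
            te1 = "numeric", te2 = "numeric"))

setValidity("DualEchoPair", function(object) {
  msg <- character()
  if (!(length(object@te1) == 1L && length(object@te2) == 1L &&
        is.finite(object@te1) && is.finite(object@te2)))
    msg <- c(msg, "te1 and te2 must be single finite numbers (ms)")
  else if (object@te1 >= object@te2)
    msg <- c(msg, "te1 must be strictly less than te2")
  if (!identical(dim(object@ute@pixels), dim(object@shte@pixels)))
    msg <- c(msg, "ute and shte grids differ in size")
  if (!isTRUE(all.equal(object@ute@spacing, object@shte@spacing)))
    msg <- c(msg, "ute and shte grids differ in spacing")
  if (length(msg)) msg else TRUE
})

#' Integer tissue label mask
#'
#' Per-pixel integer tissue labels sharing a [SliceImage-class] grid.
#' Label 0 is reserved for background; every nonzero label used in the
#' array must be named in the scheme.
#'
#' @slot labels integer matrix of labels.
#' @slot scheme named character vector mapping label codes (names) to
#'   tissue names, e.g. `c("1" = "fascia")`.
#' @export
setClass("LabelMask",
  slots = c(labels = "matrix", scheme = "character"))

setValidity("LabelMask", function(object) {
  msg <- character()
  if (!is.numeric(object@labels) || any(!is.finite(object@labels)) ||
      any(object@labels != round(object@labels)) || any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative integers")
  used <- setdiff(unique(as.vector(object@labels)), 0)
  if (length(used)) {
    codes <- suppressWarnings(as.integer(names(object@scheme)))
    missing <- setdiff(used, codes)
    if (length(missing))
      msg <- c(msg, paste0("labels absent from scheme: ",
                           paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Set of streamline tracts
#'
#' Polylines in physical mm coordinates representing muscle fascicle
#' tracts (e.g. from diffusion tractography). Each tract is an n x 3
#' matrix of ordered points with n >= 2.
#'
#' @slot tracts list of numeric matrices, one per tract, columns x/y/z (mm).
#' @export
setClass("StreamlineSet", slots = c(tracts = "list"))

setValidity("StreamlineSet", function(object) {
  for (i in seq_along(object@tracts)) {
    t <- object@tracts[[i]]
    if (!is.matrix(t) || ncol(t) != 3L)
      return(sprintf("tract %d is not an n x 3 matrix", i))
    if (nrow(t) < 2L)
      return(sprintf("tract %d has fewer than 2 points", i))
    if (!all(is.finite(t)))
      return(sprintf("tract %d contains non-finite coordinates", i))
  }
  TRUE
})

## ---- phantom -------------------------------------------------------------

#' Mono-exponential tissue signal model
#'
#' Signal of a tissue at echo time TE under effective transverse decay:
#' `S(TE) = S0 * exp(-TE / T2*)`. Collagen-rich tissues such as deep
#' fascia have T2* near or below 1 ms, so they retain signal only at
#' ultra-short echo times; this difference is the dual-echo subtraction
#' contrast mechanism.
#'
#' @slot s0 proton-density amplitude (arbitrary units, >= 0).
#' @slot t2star effective decay constant in ms (> 0).
#' @export
setClass("TissueSignalModel", slots = c(s0 = "numeric", t2star = "numeric"))

setValidity("TissueSignalModel", function(object) {
  if (length(object@s0) != 1L || !is.finite(object@s0) || object@s0 < 0)
    return("s0 must be a single non-negative number")
  if (length(object@t2star) != 1L || !is.finite(object@t2star) ||
      object@t2star <= 0)
    return("t2star must be a single positive number (ms)")
  TRUE
})

#' Synthetic leg-phantom specification
#'
#' Geometry, tissue signal models, corruption settings and seed for the
#' synthetic dual-echo lower-leg cross-section: concentric background /
#' subcutaneous fat / thin deep-fascia annulus / muscle (optionally split
#' by an aponeurosis-like septum) / bone.
#'
#' @slot gridSize pixels per side (>= 64).
#' @slot pixelSpacing mm per pixel (isotropic in-plane).
#' @slot legRadius,fatThickness,boneRadius geometry in mm.
#' @slot fasciaThickness mm; a scalar or a `function(theta)` of polar
#'   angle for non-uniform fascia.
#' @slot septumWidth mm; 0 disables the septum.
#' @slot tissueModels named list of [TissueSignalModel-class] for
#'   fat, fascia, muscle, bone, background.
#' @slot noiseSigma Rician noise scale (>= 0).
#' @slot periodicNoise `NULL` or `list(amplitude=, frequency=, orientation=)`
#'   (cycles/image, degrees).
#' @slot biasField `NULL` or numeric coefficients of a low-order 2D
#'   polynomial (see [makePhantom()]).
#' @slot te1,te2 echo times in ms.
#' @slot sliceThickness mm.
#' @slot seed RNG seed (integer).
#' @export
setClass("PhantomSpec",
  slots = c(gridSize = "integer", pixelSpacing = "numeric",
            legRadius = "numeric", fatThickness = "numeric",
            fasciaThickness = "ANY", septumWidth = "numeric",
            boneRadius = "numeric", tissueModels = "list",
            noiseSigma = "numeric", periodicNoise = "ANY",
            biasField = "ANY", te1 = "numeric", te2 = "numeric",
            sliceThickness = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@gridSize < 64L)
    msg <- c(msg, "gridSize must be >= 64")
  if (object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be > 0")
  ft <- object@fasciaThickness
  ftMax <- if (is.function(ft)) {
    max(vapply(seq(0, 2 * pi, length.out = 360), ft, numeric(1)))
  } else ft
  ftMin <- if (is.function(ft)) {
    min(vapply(seq(0, 2 * pi, length.out = 360), ft, numeric(1)))
  } else ft
  if (ftMin < 0 || object@fatThickness < 0 || object@septumWidth < 0 ||
      object@boneRadius < 0)
    msg <- c(msg, "all thicknesses and radii must be >= 0")
  if (object@boneRadius + ftMax + object@fatThickness >= object@legRadius)
    msg <- c(msg, paste0("geometry does not nest: require boneRadius + ",
                         "fasciaThickness + fatThickness < legRadius"))
  need <- c("fat", "fascia", "muscle", "bone", "background")
  if (!all(need %in% names(object@tissueModels)))
    msg <- c(msg, paste0("tissueModels must name: ",
                         paste(need, collapse = ", ")))
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (!is.null(object@periodicNoise) &&
      !all(c("amplitude", "frequency", "orientation") %in%
           names(object@periodicNoise)))
    msg <- c(msg, "periodicNoise must list amplitude, frequency, orientation")
  if (object@te1 >= object@te2)
    msg <- c(msg, "te1 must be < te2")
  if (length(msg)) msg else TRUE
})

#' Rendered phantom output
#'
#' @slot ute,shte [SliceImage-class] at the two echo times.
#' @slot truth [LabelMask-class] ground-truth tissue labels.
#' @slot trueThicknessMm scalar fascia thickness (mm), or per-angle profile.
#' @slot te1,te2 echo times (ms).
#' @slot spec the [PhantomSpec-class] that produced the output.
#' @export
setClass("PhantomOutput",
  slots = c(ute = "SliceImage", shte = "SliceImage", truth = "LabelMask",
            trueThicknessMm = "ANY", te1 = "numeric", te2 = "numeric",
            spec = "PhantomSpec"))

## ---- result records ------------------------------------------------------

#' Region-specific scaling result
#'
#' Records the factor applied to the UTE image so that a non-target
#' region's intensity statistics match the shTE image, optimising signal
#' cancellation of that region on subtraction.
#'
#' @slot factor positive scalar applied to the UTE image.
#' @slot method one of "median-ratio", "mean-ratio", "blended".
#' @slot roi the [LabelMask-class] region used for matching.
#' @slot preMatchStats,postMatchStats named numeric vectors with
#'   per-echo mean and median over the ROI.
#' @export
setClass("ScalingResult",
  slots = c(factor = "numeric", method = "character", roi = "LabelMask",
            preMatchStats = "numeric", postMatchStats = "numeric"))

setValidity("ScalingResult", function(object) {
  if (length(object@factor) != 1L || !is.finite(object@factor) ||
      object@factor <= 0)
    return("factor must be a single positive number")
  if (!object@method %in% c("median-ratio", "mean-ratio", "blended"))
    return("unknown method")
  if (object@method == "median-ratio") {
    r <- object@postMatchStats[["shteMedian"]] /
         object@postMatchStats[["uteMedian"]]
    if (abs(r - 1) > 1e-6)
      return("post-match ROI median ratio departs from 1 beyond 1e-6")
  }
  TRUE
})

#' Signal-to-noise measurement
#'
#' SNR defined as mean signal over a signal ROI divided by the standard
#' deviation over a background (air) ROI.
#' @slot signalRoiMean,backgroundRoiStd,snr numeric scalars.
#' @export
setClass("SnrMeasurement",
  slots = c(signalRoiMean = "numeric", backgroundRoiStd = "numeric",
            snr = "numeric"))

setValidity("SnrMeasurement", function(object) {
  if (object@backgroundRoiStd <= 0)
    return("backgroundRoiStd must be > 0")
  if (abs(object@snr - object@signalRoiMean / object@backgroundRoiStd) >
      1e-12 * max(1, abs(object@snr)))
    return("snr must equal signalRoiMean / backgroundRoiStd")
  TRUE
})

#' K-means intensity clustering result
#'
#' @slot labels [LabelMask-class] with k classes, relabelled so cluster 1
#'   has the lowest centroid.
#' @slot centroids numeric, ascending cluster centre intensities.
#' @slot wcss total within-cluster sum of squares of the best replicate.
#' @slot replicateSeeds integer seeds used for the replicates.
#' @export
setClass("ClusterResult",
  slots = c(labels = "LabelMask", centroids = "numeric", wcss = "numeric",
            replicateSeeds = "integer"))

setValidity("ClusterResult", function(object) {
  if (is.unsorted(object@centroids))
    return("centroids must be sorted ascending")
  if (any(object@labels@labels < 1))
    return("every pixel must be assigned to a cluster")
  TRUE
})

#' Watershed segmentation result
#'
#' Catchment regions of the negated distance transform of the binarized
#' foreground; 0 marks background and inter-region ridge pixels.
#' @slot labels [LabelMask-class] of regions.
#' @slot nRegions number of regions.
#' @slot thresholdUsed binarization threshold.
#' @export
setClass("WatershedResult",
  slots = c(labels = "LabelMask", nRegions = "integer",
            thresholdUsed = "numeric"))

#' Thickness report for a thin structure
#'
#' @slot perSliceMeanMm per-slice mean thickness (mm); `NA` for slices
#'   with an empty mask.
#' @slot overallMeanMm mean over slices with at least one skeleton point.
#' @slot nSkeletonPoints per-slice skeleton point counts.
#' @slot spacingMm in-plane spacing used.
#' @export
setClass("ThicknessReport",
  slots = c(perSliceMeanMm = "numeric", overallMeanMm = "numeric",
            nSkeletonPoints = "integer", spacingMm = "numeric"))

setValidity("ThicknessReport", function(object) {
  ok <- object@nSkeletonPoints > 0
  if (any(ok)) {
    m <- mean(object@perSliceMeanMm[ok])
    if (abs(m - object@overallMeanMm) > 1e-9 * max(1, abs(m)))
      return("overallMeanMm must be the mean over slices with skeleton points")
  }
  if (any(object@perSliceMeanMm[ok] < 0))
    return("thickness must be >= 0")
  TRUE
})

#' Segmentation agreement metrics
#'
#' Dice coefficient and Jaccard index; the two are linked by the set
#' identity J = D / (2 - D), asserted on construction.
#' @slot dice,jaccard overlap metrics in `[0, 1]`.
#' @export
setClass("AgreementMetrics", slots = c(dice = "numeric", jaccard = "numeric"))

setValidity("AgreementMetrics", function(object) {
  if (object@dice < 0 || object@dice > 1)
    return("dice must lie in [0, 1]")
  if (abs(object@jaccard - object@dice / (2 - object@dice)) > 1e-12)
    return("jaccard must equal dice / (2 - dice)")
  TRUE
})

#' Muscle architecture report
#'
#' Fascicle length and pennation statistics of a filtered tract set, the
#' muscle volume, and the physiological cross-sectional area
#' PCSA = volume / mean fascicle length.
#'
#' @slot nTractsIn,nTractsKept tract counts before/after length filtering.
#' @slot fascicleLengthMeanMm,fascicleLengthSdMm mm.
#' @slot pennationMeanDeg,pennationSdDeg degrees in `[0, 90]`.
#' @slot muscleVolumeMm3 mm^3.
#' @slot pcsaMm2 mm^2.
#' @slot lineOfAction unit 3-vector.
#' @export
setClass("ArchitectureReport",
  slots = c(nTractsIn = "integer", nTractsKept = "integer",
            fascicleLengthMeanMm = "numeric", fascicleLengthSdMm = "numeric",
            pennationMeanDeg = "numeric", pennationSdDeg = "numeric",
            muscleVolumeMm3 = "numeric", pcsaMm2 = "numeric",
            lineOfAction = "numeric"))

setValidity("ArchitectureReport", function(object) {
  if (abs(object@pcsaMm2 -
          object@muscleVolumeMm3 / object@fascicleLengthMeanMm) >
      1e-9 * max(1, object@pcsaMm2))
    return("pcsaMm2 must equal muscleVolumeMm3 / fascicleLengthMeanMm")
  if (object@pennationMeanDeg < 0 || object@pennationMeanDeg > 90)
    return("pennation angles must lie in [0, 90] degrees")
  if (abs(sqrt(sum(object@lineOfAction^2)) - 1) > 1e-6)
    return("lineOfAction must be a unit vector")
  TRUE
})

#' Frequency-domain filter settings
#'
#' Settings for FFT spike suppression: a protected central (low
#' frequency) disk, a z-score threshold on the log-magnitude spectrum for
#' spike detection, and an optional Gaussian low-pass.
#'
#' @slot protectRadiusFrac fraction of `min(dim)` kept untouched around
#'   the spectrum centre (0 < f < 0.5).
#' @slot spikeZ z-score threshold on log-magnitude for spike detection.
#' @slot lowpassFrac Gaussian low-pass cutoff as a fraction of Nyquist;
#'   `NA` disables the low-pass.
#' @export
setClass("FrequencyFilterSpec",
  slots = c(protectRadiusFrac = "numeric", spikeZ = "numeric",
            lowpassFrac = "numeric"))

setValidity("FrequencyFilterSpec", function(object) {
  if (object@protectRadiusFrac <= 0 || object@protectRadiusFrac >= 0.5)
    return("protectRadiusFrac must lie in (0, 0.5)")
  if (object@spikeZ <= 0)
    return("spikeZ must be > 0")
  TRUE
})
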