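#' @include AllGenerics.R
NULL

## ---- constructors --------------------------------------------------------

#' Create a SliceImage
#'
#' @param pixels numeric matrix of intensities, `[row, col]`.
#' @param spacing numeric(2) in-plane spacing in mm (a scalar is recycled).
#' @param sliceThickness through-plane thickness in mm.
#' @return a [SliceImage-class].
#' @examples
#' img <- sliceImage(matrix(runif(64), 8, 8), spacing = 0.5)
#' spacing(img)
#' @export
sliceImage <- function(pixels, spacing = c(1, 1), sliceThickness = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  storage.mode(pixels) <- "double"
  new("SliceImage", pixels = pixels, spacing = as.numeric(spacing),
      sliceThickness = as.numeric(sliceThickness))
}

#' Create a DualEchoPair
#'
#' @param ute,shte [SliceImage-class] objects on identical grids.
#' @param te1,te2 echo times in ms, `te1 < te2`.
#' @export
dualEchoPair <- function(ute, shte, te1, te2) {
  new("DualEchoPair", ute = ute, shte = shte,
      te1 = as.numeric(te1), te2 = as.numeric(te2))
}

#' Create a LabelMask
#'
#' @param labels integer (or logical) matrix; logical input becomes a
#'   binary 0/1 mask.
#' @param scheme named character vector mapping label codes to tissue
#'   names; defaults to `c("1" = "foreground")` for binary input.
#' @export
labelMask <- function(labels, scheme = NULL) {
  if (is.logical(labels)) {
    labels <- array(as.integer(labels), dim = dim(labels))
  }
  storage.mode(labels) <- "integer"
  if (is.null(scheme)) {
    used <- sort(setdiff(unique(as.vector(labels)), 0L))
    scheme <- if (identical(used, 1L)) c("1" = "foreground") else {
      stats::setNames(paste0("label", used), as.character(used))
    }
  }
  new("LabelMask", labels = labels, scheme = scheme)
}

#' Create a StreamlineSet
#'
#' @param tracts list of n x 3 numeric matrices (mm physical coordinates).
#' @export
streamlineSet <- function(tracts) {
  tracts <- lapply(tracts, function(t) {
    t <- as.matrix(t); storage.mode(t) <- "double"; t
  })
  new("StreamlineSet", tracts = tracts)
}

#' Create a TissueSignalModel
#'
#' @param s0 proton-density amplitude (>= 0).
#' @param t2star effective transverse decay constant in ms (> 0).
#' @export
tissueModel <- function(s0, t2star) {
  new("TissueSignalModel", s0 = as.numeric(s0), t2star = as.numeric(t2star))
}

#' Create an AgreementMetrics record from a Dice coefficient
#'
#' @param dice Dice coefficient in `[0, 1]`; the Jaccard index is
#'   derived through the set identity `J = D / (2 - D)`.
#' @export
agreementFromDice <- function(dice) {
  new("AgreementMetrics", dice = dice, jaccard = dice / (2 - dice))
}

## ---- accessors -----------------------------------------------------------

#' @rdname pixels
#' @export
setMethod("pixels", "SliceImage", function(object) object@pixels)

#' @rdname spacing
#' @export
setMethod("spacing", "SliceImage", function(object) object@spacing)

#' @rdname sliceThickness
#' @export
setMethod("sliceThickness", "SliceImage", function(object) object@sliceThickness)

#' @rdname labels
#' @export
setMethod("labels", "LabelMask", function(object, ...) object@labels)

#' @rdname scheme
#' @export
setMethod("scheme", "LabelMask", function(object) object@scheme)

#' @rdname tracts
#' @export
setMethod("tracts", "StreamlineSet", function(object) object@tracts)

#' @rdname nTracts
#' @export
setMethod("nTracts", "StreamlineSet", function(object) length(object@tracts))

#' @rdname signalAt
#' @export
setMethod("signalAt", "TissueSignalModel", function(object, te) {
  stopifnot(all(te >= 0))
  object@s0 * exp(-te / object@t2star)
})

## ---- show methods --------------------------------------------------------

setMethod("show", "SliceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SliceImage: %d x %d px, spacing %.3g x %.3g mm, slice %.3g mm\n",
              d[1], d[2], object@spacing[1], object@spacing[2],
              object@sliceThickness))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "DualEchoPair", function(object) {
  d <- dim(object@ute@pixels)
  cat(sprintf("DualEchoPair: %d x %d px, TE1 = %.4g ms (UTE), TE2 = %.4g ms (shTE)\n",
              d[1], d[2], object@te1, object@te2))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels[object@labels != 0],
                      levels = names(object@scheme)))
  cat(sprintf("LabelMask: %d x %d px\n", d[1], d[2]))
  for (code in names(object@scheme))
    cat(sprintf("  %s (%s): %d px\n", object@scheme[[code]], code,
                as.integer(tab[[code]])))
})

setMethod("show", "StreamlineSet", function(object) {
  n <- length(object@tracts)
  cat(sprintf("StreamlineSet: %d tracts\n", n))
  if (n) {
    len <- fascicleLengths(object)
    cat(sprintf("  arc length %.3g-%.3g mm (mean %.3g)\n",
                min(len), max(len), mean(len)))
  }
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d, wcss = %.6g\n",
              length(object@centroids), object@wcss))
  cat("  centroids:", paste(sprintf("%.4g", object@centroids),
                            collapse = ", "), "\n")
})

setMethod("show", "WatershedResult", function(object) {
  cat(sprintf("WatershedResult: %d regions at threshold %.3g\n",
              object@nRegions, object@thresholdUsed))
})

setMethod("show", "ScalingResult", function(object) {
  cat(sprintf("ScalingResult: factor %.6g (%s)\n",
              object@factor, object@method))
})

setMethod("show", "SnrMeasurement", function(object) {
  cat(sprintf("SNR = %.4g (signal mean %.4g / background sd %.4g)\n",
              object@snr, object@signalRoiMean, object@backgroundRoiStd))
})

setMethod("show", "ThicknessReport", function(object) {
  cat(sprintf("ThicknessReport: %d slice(s), overall mean %.4g mm\n",
              length(object@perSliceMeanMm), object@overallMeanMm))
})

setMethod("show", "AgreementMetrics", function(object) {
  cat(sprintf("Agreement: Dice %.4g, Jaccard %.4g\n",
              object@dice, object@jaccard))
})

setMethod("show", "ArchitectureReport", function(object) {
  cat(sprintf("ArchitectureReport: %d/%d tracts kept\n",
              object@nTractsKept, object@nTractsIn))
  cat(sprintf("  fascicle length %.4g +/- %.4g mm\n",
              object@fascicleLengthMeanMm, object@fascicleLengthSdMm))
  cat(sprintf("  pennation %.4g +/- %.4g deg\n",
              object@pennationMeanDeg, object@pennationSdDeg))
  cat(sprintf("  volume %.6g mm^3, PCSA %.6g mm^2\n",
              object@muscleVolumeMm3, object@pcsaMm2))
})

setMethod("show", "PhantomOutput", function(object) {
  d <- dim(object@ute@pixels)
  cat(sprintf("PhantomOutput: %d x %d px dual-echo pair, TE %.3g/%.3g ms\n",
              d[1], d[2], object@te1, object@te2))
  tt <- object@trueThicknessMm
  if (is.numeric(tt) && length(tt) == 1L)
    cat(sprintf("  true fascia thickness %.4g mm\n", tt))
})
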