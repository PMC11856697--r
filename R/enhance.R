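#' @include accessors.R
NULL

#' Statistics-driven contrast adjustment
#'
#' Linear intensity remap in the spirit of MATLAB's `imadjust` driven by
#' the image's own statistics: the input window is
#' `[mean - 2 sd, mean + 2 sd]` intersected with the observed range, and
#' is mapped affinely onto `[0, 1]` with saturation outside the window.
#' The +/- 2 sd window covers ~95 % of a Gaussian intensity histogram.
#'
#' @param img a [SliceImage-class].
#' @return a [SliceImage-class] with intensities in `[0, 1]`.
#' @export
contrastAdjust <- function(img) {
  stopIfNot2D(img)
  x <- img@pixels
  s <- sd(x)
  if (s == 0) {
    warning("constant image: contrast window undefined, rescaling by max")
    m <- max(x)
    out <- if (m > 0) x / m else x
    return(sliceImage(out, img@spacing, img@sliceThickness))
  }
  m <- mean(x)
  lo <- max(m - 2 * s, min(x))
  hi <- min(m + 2 * s, max(x))
  out <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  sliceImage(array(out, dim(x)), img@spacing, img@sliceThickness)
}

#' White top-hat filtering
#'
#' Image minus its morphological opening with a disk-shaped structuring
#' element, emphasising bright features narrower than the disk while
#' suppressing wider structures and smooth background. The default
#' radius of 10 px targets sub-millimeter fascia at typical UTE in-plane
#' resolutions.
#'
#' @param img a [SliceImage-class].
#' @param radiusPx disk radius in pixels (>= 1).
#' @return non-negative [SliceImage-class].
#' @export
topHat <- function(img, radiusPx = 10L) {
  stopIfNot2D(img)
  if (radiusPx < 1) stop("radiusPx must be >= 1")
  if (2L * radiusPx + 1L > min(dim(img@pixels)))
    stop("structuring element larger than image")
  out <- EBImage::whiteTopHat(img@pixels, discBrush(radiusPx))
  out <- pmax(as.matrix(out), 0)
  sliceImage(array(out, dim(img@pixels)), img@spacing, img@sliceThickness)
}

#' Locally adaptive Wiener denoising
#'
#' Pixelwise adaptive Wiener filter in the manner of MATLAB's `wiener2`:
#' with local mean `mu` and variance `s2` over the window and noise power
#' `nu` (estimated as the mean of the local variances when not given),
#' the output is `mu + max(s2 - nu, 0) / max(s2, nu) * (x - mu)`. The
#' filter smooths homogeneous regions strongly and leaves high-variance
#' structure (edges, thin fascia) nearly untouched, unlike erosion or
#' dilation which would alter thickness measurements.
#'
#' @param img a [SliceImage-class].
#' @param window integer window size `c(rows, cols)`; a scalar is
#'   recycled. Defaults to 20 x 20.
#' @param noisePower optional noise variance estimate.
#' @return a [SliceImage-class].
#' @export
wienerDenoise <- function(img, window = c(20L, 20L), noisePower = NULL) {
  stopIfNot2D(img)
  if (length(window) == 1L) window <- rep(window, 2L)
  window <- as.integer(window)
  if (any(window < 1)) stop("window dimensions must be >= 1")
  if (any(window > dim(img@pixels)))
    stop("window exceeds image dimensions")
  x <- img@pixels
  mu <- localBoxMean(x, window[1], window[2])
  s2 <- pmax(localBoxMean(x^2, window[1], window[2]) - mu^2, 0)
  nu <- if (is.null(noisePower)) mean(s2) else noisePower
  gain <- if (nu == 0) array(1, dim(x)) else pmax(s2 - nu, 0) / pmax(s2, nu)
  out <- mu + gain * (x - mu)
  sliceImage(array(out, dim(x)), img@spacing, img@sliceThickness)
}

#' Automatic muscle ROI estimate from the shTE image
#'
#' Region-specific scaling needs a non-target region whose signal should
#' cancel on subtraction. When the user supplies none, muscle is
#' estimated from the shTE image as the largest connected component of
#' pixels near the dominant tissue intensity: the image is normalized,
#' air is separated from tissue by Otsu's threshold, and the histogram
#' mode of the tissue pixels gives the muscle intensity (muscle is
#' ordinarily the largest tissue in a leg cross-section). The component
#' is eroded to stay clear of boundary partial-volume pixels.
#'
#' @param shte the shTE [SliceImage-class].
#' @param bandHalfWidth half-width of the intensity band around the
#'   tissue mode, as a fraction of the normalized intensity range.
#' @return binary [LabelMask-class].
#' @export
autoMuscleRoi <- function(shte, bandHalfWidth = 0.15) {
  stopIfNot2D(shte)
  x <- normalize01(shte@pixels)
  thr <- EBImage::otsu(EBImage::Image(x))
  fg <- x > thr
  if (!any(fg)) stop("no foreground found in shTE image")
  v <- x[fg]
  h <- graphics::hist(v, breaks = 64, plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  band <- fg & abs(x - mode) <= bandHalfWidth
  cc <- EBImage::bwlabel(array(as.numeric(band), dim(x)))
  if (max(cc) == 0) stop("no mid-intensity component found")
  sizes <- tabulate(cc[cc > 0])
  comp <- cc == which.max(sizes)
  comp <- EBImage::erode(array(as.numeric(comp), dim(x)), discBrush(3))
  if (!any(comp > 0)) stop("muscle ROI eroded to empty; supply an ROI")
  labelMask(array(as.matrix(comp) > 0, dim(x)), c("1" = "muscle"))
}

#' Region-specific intensity scaling of the UTE echo
#'
#' The UTE echo has lower SNR and a different intensity regime than the
#' shTE echo; subtracting the raw echoes leaves residual signal in
#' non-target tissue. This operation raises all UTE pixel values by a
#' factor chosen by comparing the mean and median of the two echoes over
#' a non-target ROI (muscle by default): the factor is the ROI median
#' ratio shTE/UTE; when the mean ratio disagrees with the median ratio by
#' more than 20 % (skew from a bias field or outliers) the two ratios
#' are averaged and the method is recorded as "blended".
#'
#' @param pair a [DualEchoPair-class].
#' @param roi non-target [LabelMask-class]; must exclude fascia. Default
#'   `NULL` uses [autoMuscleRoi()] on the shTE image.
#' @param blendTol relative mean/median discrepancy that triggers
#'   blending (default 0.2).
#' @return `list(scaledUte = SliceImage, scaling = ScalingResult)`.
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSigma = 0, periodicNoise = NULL))
#' pair <- dualEchoPair(ph@ute, ph@shte, ph@te1, ph@te2)
#' rs <- regionSpecificScale(pair)
#' rs$scaling
#' @export
regionSpecificScale <- function(pair, roi = NULL, blendTol = 0.2) {
  stopifnot(methods::is(pair, "DualEchoPair"))
  if (is.null(roi)) roi <- autoMuscleRoi(pair@shte)
  sel <- roi@labels != 0
  if (!any(sel)) stop("ROI is empty")
  u <- pair@ute@pixels[sel]
  s <- pair@shte@pixels[sel]
  medU <- median(u); medS <- median(s)
  meanU <- mean(u); meanS <- mean(s)
  if (medU <= 0) stop("degenerate ROI: UTE median is not positive")
  medRatio <- medS / medU
  meanRatio <- meanS / meanU
  if (abs(meanRatio - medRatio) / medRatio > blendTol) {
    factor <- (meanRatio + medRatio) / 2
    method <- "blended"
  } else {
    factor <- medRatio
    method <- "median-ratio"
  }
  scaled <- sliceImage(pair@ute@pixels * factor, pair@ute@spacing,
                       pair@ute@sliceThickness)
  res <- new("ScalingResult", factor = factor, method = method, roi = roi,
             preMatchStats = c(uteMean = meanU, uteMedian = medU,
                               shteMean = meanS, shteMedian = medS),
             postMatchStats = c(uteMean = meanU * factor,
                                uteMedian = medU * factor,
                                shteMean = meanS, shteMedian = medS))
  list(scaledUte = scaled, scaling = res)
}

#' Dual-echo subtraction
#'
#' Subtracts the shTE image from the (optionally region-scaled) UTE
#' image. Short-T2* tissue such as deep fascia survives with high signal
#' while longer-T2* tissue cancels. Negative residuals are clipped to 0
#' and the result is min-max normalized to `[0, 1]`, the intensity
#' convention assumed by the downstream binarization threshold.
#'
#' @param pair a [DualEchoPair-class].
#' @param scaledUte optional scaled UTE [SliceImage-class] from
#'   [regionSpecificScale()]; when `NULL` the raw UTE image is used.
#' @param verbose emit a message with the clipped-pixel count.
#' @return a [SliceImage-class] in `[0, 1]`.
#' @export
subtractEchoes <- function(pair, scaledUte = NULL, verbose = FALSE) {
  stopifnot(methods::is(pair, "DualEchoPair"))
  u <- if (is.null(scaledUte)) pair@ute@pixels else scaledUte@pixels
  if (!identical(dim(u), dim(pair@shte@pixels)))
    stop("image dimensions differ")
  d <- u - pair@shte@pixels
  nClip <- sum(d < 0)
  if (verbose) message(sprintf("subtraction clipped %d negative pixels", nClip))
  d <- pmax(d, 0)
  out <- normalize01(array(d, dim(u)))
  sliceImage(out, pair@ute@spacing, pair@ute@sliceThickness)
}

#' Signal-to-noise ratio of an image
#'
#' SNR defined as the mean over a signal ROI divided by the standard
#' deviation over a background (air) ROI.
#'
#' @param img a [SliceImage-class].
#' @param signalRoi,backgroundRoi disjoint nonempty [LabelMask-class]
#'   regions.
#' @return a [SnrMeasurement-class].
#' @export
measureSnr <- function(img, signalRoi, backgroundRoi) {
  stopIfNot2D(img)
  s <- signalRoi@labels != 0
  b <- backgroundRoi@labels != 0
  if (!any(s) || !any(b)) stop("both ROIs must be nonempty")
  if (any(s & b)) stop("signal and background ROIs must be disjoint")
  sm <- mean(img@pixels[s])
  bs <- sd(img@pixels[b])
  if (bs <= 0) stop("degenerate background ROI: zero standard deviation")
  new("SnrMeasurement", signalRoiMean = sm, backgroundRoiStd = bs,
      snr = sm / bs)
}
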