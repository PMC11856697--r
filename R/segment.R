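#' @include accessors.R
NULL

#' Construct frequency-filter settings
#'
#' @param protectRadiusFrac protected central disk radius as a fraction
#'   of `min(dim)` (default 0.08).
#' @param spikeZ z-score threshold on log-magnitude (default 3.5).
#' @param lowpassFrac Gaussian low-pass cutoff as a fraction of Nyquist;
#'   `NA` (the default) disables the low-pass. A cutoff of 0.3 is the
#'   conventional setting when heavier smoothing is wanted, at the cost
#'   of attenuating thin structures such as sub-millimeter fascia.
#' @return a [FrequencyFilterSpec-class].
#' @export
frequencyFilterSpec <- function(protectRadiusFrac = 0.08, spikeZ = 3.5,
                                lowpassFrac = NA_real_) {
  new("FrequencyFilterSpec", protectRadiusFrac = protectRadiusFrac,
      spikeZ = spikeZ, lowpassFrac = as.numeric(lowpassFrac))
}

#' FFT-domain periodic-noise suppression
#'
#' Periodic interference concentrates as bright, localized spikes in the
#' log-magnitude spectrum while anatomy lives in the low frequencies.
#' The image is transformed to the frequency domain and centre-shifted;
#' bins whose log-magnitude `log(1 + |F|)` exceeds
#' `mean + spikeZ * sd` (statistics over bins outside the protected
#' central disk) are flagged as spikes and zeroed together with their
#' conjugate mirrors, so the output stays real. An optional Gaussian
#' low-pass then attenuates remaining high-frequency content outside the
#' protected disk. The filtered spectrum is inverse-transformed, the real
#' part is taken and min-max normalized to `[0, 1]`.
#'
#' Spectral power never increases: bins are only zeroed or attenuated.
#'
#' @param img a [SliceImage-class].
#' @param spec a [FrequencyFilterSpec-class].
#' @param normalize min-max normalize the output to `[0, 1]` (the
#'   pipeline convention); set `FALSE` to keep the raw filtered
#'   intensities, e.g. for spectral comparisons.
#' @return `list(image = SliceImage, spikeCount = int)` where
#'   `spikeCount` is the number of bins flagged by the z-test (conjugate
#'   mirrors not double-counted).
#' @export
fftDenoise <- function(img, spec = frequencyFilterSpec(),
                       normalize = TRUE) {
  stopIfNot2D(img)
  methods::validObject(spec)
  x <- img@pixels
  n1 <- nrow(x); n2 <- ncol(x)
  FF <- stats::fft(x)
  logm <- log1p(Mod(fftshift2(FF)))

  c1 <- fftCenter(n1); c2 <- fftCenter(n2)
  rr <- matrix(seq_len(n1) - c1, n1, n2)
  cc <- matrix(seq_len(n2) - c2, n1, n2, byrow = TRUE)
  protect <- sqrt(rr^2 + cc^2) <= spec@protectRadiusFrac * min(n1, n2)

  outside <- logm[!protect]
  mu <- mean(outside); sig <- sd(outside)
  spikeShift <- if (sig > 0) (logm > mu + spec@spikeZ * sig) & !protect
                else matrix(FALSE, n1, n2)
  spikeCount <- sum(spikeShift)

  # back to unshifted ordering, add conjugate mirrors
  spike <- ifftshift2(spikeShift)
  idx <- which(spike, arr.ind = TRUE)
  if (nrow(idx)) {
    mir <- cbind(conjIndex(idx[, 1], n1), conjIndex(idx[, 2], n2))
    spike[mir] <- TRUE
  }
  FF[spike] <- 0

  if (!is.na(spec@lowpassFrac)) {
    # radial frequency as a fraction of Nyquist, on the shifted grid
    rho <- sqrt((rr / (n1 / 2))^2 + (cc / (n2 / 2))^2)
    H <- exp(-rho^2 / (2 * spec@lowpassFrac^2))
    H[protect] <- 1
    FF <- FF * ifftshift2(H)
  }

  out <- Re(stats::fft(FF, inverse = TRUE)) / (n1 * n2)
  out <- array(out, dim(x))
  if (normalize) out <- normalize01(out)
  list(image = sliceImage(out, img@spacing, img@sliceThickness),
       spikeCount = as.integer(spikeCount))
}

#' Gradient-magnitude edge map
#'
#' Central-difference gradient magnitude normalized to `[0, 1]`. Sharp
#' tissue boundaries (e.g. the two sides of the fascia annulus) appear
#' as ridge maxima aligned with the true boundaries.
#'
#' @param img a [SliceImage-class].
#' @return a [SliceImage-class].
#' @export
edgeMap <- function(img) {
  stopIfNot2D(img)
  x <- img@pixels
  n1 <- nrow(x); n2 <- ncol(x)
  gr <- (x[pmin(seq_len(n1) + 1L, n1), ] - x[pmax(seq_len(n1) - 1L, 1L), ]) / 2
  gc <- (x[, pmin(seq_len(n2) + 1L, n2)] - x[, pmax(seq_len(n2) - 1L, 1L)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  sliceImage(normalize01(array(mag, dim(x))), img@spacing,
             img@sliceThickness)
}

#' K-means clustering of pixel intensities
#'
#' Pixels are flattened to a one-dimensional intensity vector and
#' clustered with Lloyd's algorithm under Euclidean distance. Each
#' replicate starts from k distinct observed intensities sampled under a
#' seeded RNG; the replicate with the lowest within-cluster sum of
#' squares (WCSS) wins. Clusters are relabelled by ascending centroid so
#' cluster k is always the brightest class.
#'
#' @param img a [SliceImage-class].
#' @param k number of clusters (default 3: on a subtraction image these
#'   correspond primarily to background/muscle residual, fat residual,
#'   and fascia).
#' @param replicates number of seeded restarts (default 10).
#' @param seed RNG seed for the replicate initializations.
#' @param maxIter Lloyd iteration cap (default 300).
#' @return a [ClusterResult-class].
#' @export
kmeansIntensity <- function(img, k = 3L, replicates = 10L, seed = 1L,
                            maxIter = 300L) {
  stopIfNot2D(img)
  if (k < 2) stop("k must be >= 2")
  v <- as.vector(img@pixels)
  ux <- unique(v)
  if (length(ux) < k)
    stop("image has fewer distinct intensities than k")
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, replicates)
  best <- NULL
  for (i in seq_len(replicates)) {
    set.seed(repSeeds[i])
    init <- sample(ux, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(v, centers = init, iter.max = maxIter,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed in every replicate")
  ord <- order(best$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  lab <- array(relabel[best$cluster], dim = dim(img@pixels))
  mask <- labelMask(lab, stats::setNames(paste0("cluster", seq_len(k)),
                                         as.character(seq_len(k))))
  new("ClusterResult", labels = mask,
      centroids = as.numeric(best$centers[ord, 1]),
      wcss = best$tot.withinss, replicateSeeds = as.integer(repSeeds))
}

#' Watershed segmentation of the binarized foreground
#'
#' Reproduces the MATLAB-style marker-free watershed on a negated
#' Euclidean distance transform: the image (assumed normalized to
#' `[0, 1]`) is binarized at the threshold, the distance from each
#' foreground pixel to the nearest background pixel is computed, its
#' negation (with background held at -Inf, i.e. excluded from flooding)
#' is flooded with 8-connectivity, and catchment basins become regions.
#' Pixels on the 1-px ridge between adjacent regions and all background
#' pixels carry label 0.
#'
#' @param img a [SliceImage-class] with intensities in `[0, 1]`.
#' @param threshold binarization threshold (default 0.6).
#' @return a [WatershedResult-class].
#' @export
watershedSegment <- function(img, threshold = 0.6) {
  stopIfNot2D(img)
  x <- img@pixels
  bw <- x > threshold
  if (!any(bw)) {
    warning("empty foreground at threshold; no regions")
    return(new("WatershedResult",
               labels = labelMask(array(0L, dim(x)),
                                  c("1" = "region")),
               nRegions = 0L, thresholdUsed = threshold))
  }
  D <- EBImage::distmap(array(as.numeric(bw), dim(x)))
  ws <- EBImage::watershed(D)
  lab <- array(as.integer(as.matrix(ws)), dim(x))
  lab[!bw] <- 0L
  # 1-px ridge between adjacent regions, as in the MATLAB transform
  right <- cbind(lab[, -1L], 0L)
  down <- rbind(lab[-1L, ], 0L)
  diag1 <- rbind(cbind(lab[-1L, -1L], 0L), 0L)
  ridge <- (lab > 0 & right > 0 & lab != right) |
           (lab > 0 & down > 0 & lab != down) |
           (lab > 0 & diag1 > 0 & lab != diag1)
  lab[ridge] <- 0L
  keep <- sort(setdiff(unique(as.vector(lab)), 0L))
  relabel <- integer(max(lab, 1L)); relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  n <- length(keep)
  schemeNames <- if (n) stats::setNames(paste0("region", seq_len(n)),
                                        as.character(seq_len(n)))
                 else c("1" = "region")
  new("WatershedResult", labels = labelMask(lab, schemeNames),
      nRegions = as.integer(n), thresholdUsed = threshold)
}

#' Extract a fascia mask from an intensity clustering
#'
#' On a subtraction image the fascia is by construction the brightest
#' tissue, so the cluster with the highest centroid is the fascia
#' candidate. Stray bright speckles are removed by keeping only
#' candidate components that touch the band just outside the enclosed
#' muscle region (the interior connected component of non-candidate
#' pixels that does not touch the image border). When the annulus is
#' broken and no enclosed interior exists, components are kept by size
#' instead; no morphological closure is applied, so missing arcs are
#' never hallucinated.
#'
#' @param cr a [ClusterResult-class] computed on `subtractionImg`.
#' @param subtractionImg the subtraction [SliceImage-class].
#' @param bandWidthPx width (px) of the search band outside the muscle
#'   interior.
#' @return binary [LabelMask-class] (1 = fascia).
#' @export
fasciaMaskFromClusters <- function(cr, subtractionImg, bandWidthPx = 7L) {
  stopifnot(methods::is(cr, "ClusterResult"))
  k <- length(cr@centroids)
  cand <- cr@labels@labels == k
  if (!any(cand) || all(subtractionImg@pixels == 0)) {
    warning("no fascia candidate pixels; returning empty mask")
    return(labelMask(array(FALSE, dim(cand)), c("1" = "fascia")))
  }
  d <- dim(cand)
  comp <- EBImage::bwlabel(array(as.numeric(cand), d))
  comp <- array(as.integer(as.matrix(comp)), d)
  nComp <- max(comp)
  sizes <- tabulate(comp[comp > 0], nComp)

  inv <- !cand
  icc <- array(as.integer(as.matrix(EBImage::bwlabel(
    array(as.numeric(inv), d)))), d)
  borderIds <- unique(c(icc[1, ], icc[d[1], ], icc[, 1], icc[, d[2]]))
  interiorIds <- setdiff(seq_len(max(icc, 0L)), c(0L, borderIds))
  keepIds <- integer(0)
  if (length(interiorIds)) {
    isz <- tabulate(icc[icc > 0], max(icc))
    interior <- icc == interiorIds[which.max(isz[interiorIds])]
    band <- EBImage::dilate(array(as.numeric(interior), d),
                            discBrush(bandWidthPx))
    band <- as.matrix(band) > 0 & !interior
    keepIds <- setdiff(unique(comp[band & cand]), 0L)
  }
  if (!length(keepIds)) {
    # broken ring: keep components large enough to be fascia arcs
    keepIds <- which(sizes >= max(20, 0.1 * max(sizes)))
  }
  mask <- array(comp %in% keepIds, d)
  if (!any(mask)) warning("fascia mask is empty")
  labelMask(mask, c("1" = "fascia"))
}
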