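#' @include accessors.R
NULL

#' Filter tracts by arc length
#'
#' Keeps tracts whose arc length lies in the closed interval
#' `[minMm, maxMm]` (default 5-200 mm, the usual anatomical plausibility
#' window for lower-limb fascicle tracts), preserving order.
#'
#' @param ts a [StreamlineSet-class].
#' @param minMm,maxMm length bounds in mm, `minMm < maxMm`.
#' @return a filtered [StreamlineSet-class].
#' @export
filterTracts <- function(ts, minMm = 5, maxMm = 200) {
  if (minMm >= maxMm) stop("minMm must be < maxMm")
  len <- fascicleLengths(ts)
  streamlineSet(ts@tracts[len >= minMm & len <= maxMm])
}

#' Arc lengths of streamline tracts
#'
#' Per tract, the sum of consecutive-point Euclidean distances (mm).
#'
#' @param ts a [StreamlineSet-class].
#' @return numeric vector of lengths in mm.
#' @examples
#' ts <- streamlineSet(list(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))))
#' fascicleLengths(ts)  # 7
#' @export
fascicleLengths <- function(ts) {
  vapply(ts@tracts, function(t) {
    sum(sqrt(rowSums((t[-1L, , drop = FALSE] -
                        t[-nrow(t), , drop = FALSE])^2)))
  }, numeric(1))
}

#' Pennation angles of tracts against a line of action
#'
#' The fascicle vector is the end-to-end chord of each tract; the
#' pennation angle is the angle between that chord and the muscle's line
#' of action, folded to `[0, 90]` degrees via the absolute dot product
#' since fibre orientation is direction-agnostic. Zero-length chords are
#' skipped with a warning.
#'
#' @param ts a [StreamlineSet-class].
#' @param lineOfAction nonzero 3-vector.
#' @return numeric vector of angles in degrees (one per usable tract).
#' @export
pennationAngles <- function(ts, lineOfAction) {
  if (sum(lineOfAction^2) == 0) stop("line of action must be nonzero")
  if (!length(ts@tracts)) stop("streamline set is empty")
  loa <- lineOfAction / sqrt(sum(lineOfAction^2))
  chords <- t(vapply(ts@tracts, function(t) t[nrow(t), ] - t[1L, ],
                     numeric(3)))
  nrm <- sqrt(rowSums(chords^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sprintf("%d zero-length chord(s) skipped", sum(zero)))
    chords <- chords[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
  }
  cosang <- pmin(abs(chords %*% loa) / nrm, 1)
  as.numeric(acos(cosang) * 180 / pi)
}

#' Estimate a muscle's line of action from its mask stack
#'
#' Principal eigenvector of the covariance of foreground voxel physical
#' coordinates, sign-fixed to a positive through-plane component. For an
#' elongated muscle this is the long axis. A user-supplied vector should
#' be preferred when the muscle's mechanical line of action differs from
#' its geometric axis.
#'
#' @param masks list of binary [LabelMask-class] slices (>= 2 slices
#'   with foreground).
#' @param spacing in-plane spacing (mm).
#' @param sliceThickness through-plane spacing (mm).
#' @return unit 3-vector `(x, y, z)` = (col, row, slice) in mm space.
#' @export
lineOfActionEstimate <- function(masks, spacing = c(1, 1),
                                 sliceThickness = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  pts <- do.call(rbind, lapply(seq_along(masks), function(i) {
    idx <- which(asBinaryMatrix(masks[[i]]) != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    cbind(x = idx[, 2] * spacing[2], y = idx[, 1] * spacing[1],
          z = i * sliceThickness)
  }))
  if (is.null(pts) || !nrow(pts)) stop("mask stack has no foreground")
  if (length(unique(pts[, 3])) < 2L)
    stop(paste0("through-plane covariance is rank-deficient (single ",
                "slice); supply a line of action"))
  ev <- eigen(cov(pts), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[3] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Muscle architecture report
#'
#' Applies the tract length filter, computes fascicle lengths and
#' pennation angles, measures the muscle volume from the mask stack, and
#' derives the physiological cross-sectional area
#' `PCSA = volume / mean fascicle length` - the force-capacity proxy for
#' pennate muscle. The PCSA identity is re-asserted on the constructed
#' report.
#'
#' @param ts a [StreamlineSet-class].
#' @param masks list of binary [LabelMask-class] slices of the muscle.
#' @param spacing in-plane spacing (mm).
#' @param sliceThickness through-plane spacing (mm).
#' @param lineOfAction optional unit 3-vector; estimated with
#'   [lineOfActionEstimate()] when absent.
#' @param minMm,maxMm tract length filter bounds (mm).
#' @return an [ArchitectureReport-class].
#' @export
architectureReport <- function(ts, masks, spacing = c(1, 1),
                               sliceThickness = 1, lineOfAction = NULL,
                               minMm = 5, maxMm = 200) {
  nIn <- length(ts@tracts)
  kept <- filterTracts(ts, minMm, maxMm)
  if (!length(kept@tracts))
    stop("no tracts remain after length filtering")
  if (is.null(lineOfAction))
    lineOfAction <- lineOfActionEstimate(masks, spacing, sliceThickness)
  loa <- lineOfAction / sqrt(sum(lineOfAction^2))
  len <- fascicleLengths(kept)
  ang <- pennationAngles(kept, loa)
  vol <- muscleSize(masks, spacing, sliceThickness)$volumeMm3
  new("ArchitectureReport",
      nTractsIn = as.integer(nIn), nTractsKept = length(kept@tracts),
      fascicleLengthMeanMm = mean(len), fascicleLengthSdMm = sd(len),
      pennationMeanDeg = mean(ang), pennationSdDeg = sd(ang),
      muscleVolumeMm3 = vol, pcsaMm2 = vol / mean(len),
      lineOfAction = loa)
}
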