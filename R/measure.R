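#' @include accessors.R
NULL

## ---- skeletonization -----------------------------------------------------

# 8-neighbourhood maps in the order N, NE, E, SE, S, SW, W, NW around
# each pixel (zero-padded borders).
neighborStack <- function(m) {
  list(n  = shiftMat(m, -1L,  0L), ne = shiftMat(m, -1L,  1L),
       e  = shiftMat(m,  0L,  1L), se = shiftMat(m,  1L,  1L),
       s  = shiftMat(m,  1L,  0L), sw = shiftMat(m,  1L, -1L),
       w  = shiftMat(m,  0L, -1L), nw = shiftMat(m, -1L, -1L))
}

#' Morphological thinning to a 1-px skeleton
#'
#' Zhang-Suen iterative thinning of a binary mask down to its 1-pixel
#' midline while preserving topology (a closed annulus thins to a closed
#' loop). Used as the midline for skeleton-based thickness measurement.
#'
#' @param mask binary [LabelMask-class] or logical/0-1 matrix.
#' @return logical matrix of skeleton pixels.
#' @export
thinMask <- function(mask) {
  p <- asBinaryMatrix(mask)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- neighborStack(p)
      B <- Reduce(`+`, nb)
      seq8 <- nb[c("n", "ne", "e", "se", "s", "sw", "w", "nw", "n")]
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (seq8[[i]] == 0) * (seq8[[i + 1]] == 1)
      }))
      if (pass == 1) {
        cond <- nb$n * nb$e * nb$s == 0 & nb$e * nb$s * nb$w == 0
      } else {
        cond <- nb$n * nb$e * nb$w == 0 & nb$n * nb$s * nb$w == 0
      }
      del <- p == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        p[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p == 1
}

#' Prune short spur branches from a skeleton
#'
#' Iteratively removes endpoint pixels (pixels with at most one
#' 8-neighbour) up to `len` times, trimming thinning artifacts shorter
#' than `len` pixels. Closed loops have no endpoints and are untouched.
#' If pruning would empty the skeleton entirely, the unpruned skeleton
#' is returned with a warning.
#'
#' @param skeleton logical matrix from [thinMask()].
#' @param len spur length in pixels (default 5).
#' @return logical matrix.
#' @export
pruneSpurs <- function(skeleton, len = 5L) {
  p0 <- array(as.numeric(skeleton), dim(skeleton))
  p <- p0
  for (i in seq_len(len)) {
    nb <- neighborStack(p)
    B <- Reduce(`+`, nb)
    endpoint <- p == 1 & B <= 1
    if (!any(endpoint)) break
    p[endpoint] <- 0
  }
  if (!any(p == 1)) {
    warning("pruning removed the whole skeleton; returning unpruned")
    return(p0 == 1)
  }
  p == 1
}

# Local tangent directions at skeleton pixels via second moments of
# neighbouring skeleton offsets in a 5x5 window. Returns an n x 2 matrix
# of unit tangents (dr, dc); rows are NA where no tangent is defined.
skeletonTangents <- function(skel) {
  d <- dim(skel)
  s <- array(as.numeric(skel), d)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  Srr <- Scc <- Src <- Nn <- array(0, d)
  for (i in seq_len(nrow(offs))) {
    sh <- shiftMat(s, offs$dr[i], offs$dc[i])
    Srr <- Srr + sh * offs$dr[i]^2
    Scc <- Scc + sh * offs$dc[i]^2
    Src <- Src + sh * offs$dr[i] * offs$dc[i]
    Nn <- Nn + sh
  }
  idx <- which(skel)
  phi <- 0.5 * atan2(2 * Src[idx], Srr[idx] - Scc[idx])
  tang <- cbind(cos(phi), sin(phi))
  tang[Nn[idx] < 2, ] <- NA_real_
  tang
}

# March from each skeleton pixel along +/- the local normal until the
# first sample outside the mask; the boundary is placed midway between
# the last inside and first outside sample. Returns per-pixel thickness
# in px (NA where the tangent was undefined).
normalRayThickness <- function(mask, skel, maxHalfPx, step = 0.25) {
  d <- dim(mask)
  idx <- which(skel, arr.ind = TRUE)
  tang <- skeletonTangents(skel)
  nrm <- cbind(-tang[, 2], tang[, 1])
  n <- nrow(idx)
  out <- rep(NA_real_, n)
  ok <- which(!is.na(nrm[, 1]))
  if (!length(ok)) return(out)
  kMax <- ceiling((maxHalfPx + 2) / step)
  castOne <- function(sgn) {
    dist <- rep(NA_real_, length(ok))
    alive <- rep(TRUE, length(ok))
    for (k in seq_len(kMax)) {
      if (!any(alive)) break
      r <- round(idx[ok, 1] + sgn * k * step * nrm[ok, 1])
      c <- round(idx[ok, 2] + sgn * k * step * nrm[ok, 2])
      inside <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
      inMask <- rep(FALSE, length(ok))
      inMask[inside] <- mask[cbind(r[inside], c[inside])] != 0
      left <- alive & !inMask
      dist[left] <- (k - 0.5) * step
      alive <- alive & inMask
    }
    dist
  }
  dPlus <- castOne(+1)
  dMinus <- castOne(-1)
  out[ok] <- dPlus + dMinus
  out
}

#' Skeleton-based thickness of a thin binary structure
#'
#' Realizes the midline thickness measurement for thin segmented tissue:
#' the mask is thinned to its 1-px skeleton (midline), short spurs are
#' pruned, and at each skeleton pixel the distance from the midline to
#' the inner and to the outer boundary is measured along the local
#' midline normal with sub-pixel boundary localization; the two
#' distances are summed and converted to mm. The slice thickness is the
#' average over all skeleton pixels. Skeleton pixels without a usable
#' tangent (isolated points) fall back to twice the Euclidean distance
#' transform minus one pixel.
#'
#' Requires isotropic in-plane spacing (row/col spacing within 1 %).
#'
#' @param mask binary [LabelMask-class] with nonempty foreground.
#' @param spacing in-plane pixel spacing in mm, numeric(2) or scalar.
#' @param pruneLen spur-pruning length in px (default 5).
#' @return `list(sliceMeanMm, skeleton, perPixelMm)` where `skeleton`
#'   is a binary [LabelMask-class] of midline pixels.
#' @examples
#' bar <- matrix(0L, 32, 40); bar[14:18, 5:36] <- 1L
#' skeletonThickness(labelMask(bar), spacing = 0.5)$sliceMeanMm  # ~2.5
#' @export
skeletonThickness <- function(mask, spacing = c(1, 1), pruneLen = 5L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (abs(spacing[1] - spacing[2]) > 0.01 * spacing[1])
    stop("anisotropic in-plane spacing is unsupported")
  m <- asBinaryMatrix(mask)
  if (!any(m != 0)) stop("mask has no foreground")
  skel <- pruneSpurs(thinMask(m), pruneLen)
  edt <- as.matrix(EBImage::distmap(m))
  thickPx <- normalRayThickness(m, skel, maxHalfPx = max(edt))
  # fallback for degenerate skeleton pixels: doubled EDT convention
  # (distance between pixel centres overshoots the boundary by 1/2 px
  # on each side, hence the -1)
  fb <- is.na(thickPx)
  if (any(fb)) {
    idx <- which(skel, arr.ind = TRUE)
    thickPx[fb] <- 2 * edt[idx[fb, , drop = FALSE]] - 1
  }
  thickMm <- thickPx * mean(spacing)
  list(sliceMeanMm = mean(thickMm),
       skeleton = labelMask(skel, c("1" = "skeleton")),
       perPixelMm = thickMm)
}

#' Thickness report over a slice stack
#'
#' Applies [skeletonThickness()] slice by slice and averages across
#' slices. Slices with an empty mask contribute no measurements: they
#' are recorded with a skeleton point count of 0 and excluded from the
#' overall mean.
#'
#' @param masks list of binary [LabelMask-class] objects, one per slice.
#' @param spacing in-plane spacing (mm).
#' @param pruneLen spur-pruning length (px).
#' @return a [ThicknessReport-class].
#' @export
thicknessReport <- function(masks, spacing = c(1, 1), pruneLen = 5L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  perSlice <- rep(NA_real_, length(masks))
  nPts <- integer(length(masks))
  for (i in seq_along(masks)) {
    m <- asBinaryMatrix(masks[[i]])
    if (!any(m != 0)) next
    st <- skeletonThickness(masks[[i]], spacing, pruneLen)
    perSlice[i] <- st$sliceMeanMm
    nPts[i] <- sum(st$skeleton@labels)
  }
  if (!any(nPts > 0)) stop("all slices are empty")
  new("ThicknessReport", perSliceMeanMm = perSlice,
      overallMeanMm = mean(perSlice[nPts > 0]),
      nSkeletonPoints = nPts, spacingMm = spacing)
}

#' Dice coefficient and Jaccard index of two binary masks
#'
#' `dice = 2|A & B| / (|A| + |B|)`, `jaccard = |A & B| / |A | B|`; the
#' set identity `jaccard = dice / (2 - dice)` is asserted on the result.
#'
#' @param a,b binary [LabelMask-class] objects of the same shape.
#' @return an [AgreementMetrics-class].
#' @examples
#' m <- labelMask(matrix(c(1L, 1L, 0L, 0L), 2, 2))
#' diceJaccard(m, m)   # dice 1, jaccard 1
#' @export
diceJaccard <- function(a, b) {
  A <- asBinaryMatrix(a) != 0
  B <- asBinaryMatrix(b) != 0
  if (!identical(dim(A), dim(B))) stop("mask shapes differ")
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0) stop("both masks are empty: metrics undefined")
  inter <- sum(A & B)
  dice <- 2 * inter / (nA + nB)
  jac <- inter / (nA + nB - inter)
  stopifnot(abs(jac - dice / (2 - dice)) <= 1e-12)
  new("AgreementMetrics", dice = dice, jaccard = jac)
}

#' Muscle cross-sectional area and volume
#'
#' Per-slice cross-sectional area = foreground pixel count times pixel
#' area; volume = sum of CSA times slice thickness.
#'
#' @param masks list of binary [LabelMask-class] objects (slices).
#' @param spacing in-plane spacing (mm), numeric(2) or scalar.
#' @param sliceThickness through-plane thickness (mm).
#' @return `list(csaPerSliceMm2, volumeMm3)`.
#' @export
muscleSize <- function(masks, spacing = c(1, 1), sliceThickness = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  pixArea <- spacing[1] * spacing[2]
  csa <- vapply(masks, function(m) sum(asBinaryMatrix(m) != 0) * pixArea,
                numeric(1))
  list(csaPerSliceMm2 = csa, volumeMm3 = sum(csa) * sliceThickness)
}
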