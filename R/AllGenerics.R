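#' @include AllClasses.R
NULL

#' Pixel matrix of an image-like object
#' @param object a [SliceImage-class].
#' @return numeric matrix `[row, col]`.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' In-plane pixel spacing in mm
#' @param object a [SliceImage-class].
#' @return numeric(2), (row_mm, col_mm).
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' Through-plane slice thickness in mm
#' @param object a [SliceImage-class].
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))

#' Label matrix of a mask
#' @param object a [LabelMask-class].
#' @param ... ignored.
#' @export
setGeneric("labels")

#' Label-to-tissue-name scheme of a mask
#' @param object a [LabelMask-class].
#' @export
setGeneric("scheme", function(object) standardGeneric("scheme"))

#' List of tract polylines
#' @param object a [StreamlineSet-class].
#' @return list of n x 3 matrices (mm).
#' @export
setGeneric("tracts", function(object) standardGeneric("tracts"))

#' Number of tracts in a streamline set
#' @param object a [StreamlineSet-class].
#' @export
setGeneric("nTracts", function(object) standardGeneric("nTracts"))

#' Tissue signal at a given echo time
#'
#' Evaluates the mono-exponential decay `S0 * exp(-TE / T2*)`.
#' @param object a [TissueSignalModel-class].
#' @param te echo time(s) in ms (>= 0).
#' @return signal amplitude(s), strictly positive and strictly
#'   decreasing in `te` when `s0 > 0`.
#' @examples
#' m <- tissueModel(s0 = 1, t2star = 1)
#' signalAt(m, 0.05)   # ~ 0.951
#' signalAt(m, 5)      # ~ 0.0067
#' @export
setGeneric("signalAt", function(object, te) standardGeneric("signalAt"))
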