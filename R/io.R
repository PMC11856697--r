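#' @include accessors.R
NULL

#' Load a slice stack from a NIfTI volume
#'
#' Reads a 2D or 3D NIfTI file into an ordered list of
#' [SliceImage-class] objects. Slices come back in through-plane order
#' as stored; in-plane spacing and slice thickness are taken from the
#' header `pixdim`, and intensities are returned as stored (RNifti
#' applies the scale slope/intercept on read).
#'
#' @param path file path.
#' @param format `"nifti"` (the only supported on-disk format; DICOM
#'   series must be converted to NIfTI first).
#' @return list of [SliceImage-class].
#' @export
loadVolume <- function(path, format = c("nifti", "dicom-series")) {
  format <- match.arg(format)
  if (format == "dicom-series")
    stop(paste0("DICOM series reading is not supported; convert the ",
                "series to NIfTI (e.g. with dcm2niix) and load that"))
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0))
    stop("non-positive pixel spacing in NIfTI header of '", path, "'")
  thick <- if (length(pd) >= 3 && is.finite(pd[3]) && pd[3] > 0) pd[3] else 1
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (!all(is.finite(a))) stop("non-finite voxel values in '", path, "'")
  lapply(seq_len(dim(a)[3]), function(k) {
    sliceImage(a[, , k], spacing = pd[1:2], sliceThickness = thick)
  })
}

#' Save a SliceImage (or stack) as NIfTI
#'
#' @param img a [SliceImage-class] or list of them (identical grids).
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype on-disk datatype; `"double"` round-trips losslessly,
#'   `"float"` is the compact choice for stage outputs.
#' @return the path, invisibly.
#' @note NIfTI stores through-plane spacing only for stacks of two or
#'   more slices; a single-slice file is written 2D and reloads with the
#'   default slice thickness.
#' @export
saveSlice <- function(img, path, datatype = "double") {
  if (methods::is(img, "SliceImage")) img <- list(img)
  a <- array(0, c(dim(img[[1]]@pixels), length(img)))
  for (k in seq_along(img)) a[, , k] <- img[[k]]@pixels
  nii <- niftiWithSpacing(a, img[[1]]@spacing, img[[1]]@sliceThickness)
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

# Build a niftiImage with explicit spatial pixdim, keeping singleton
# third dimensions (asNifti alone drops them, losing the spacing).
niftiWithSpacing <- function(a, spacing, thickness) {
  d <- dim(a)
  hdr <- RNifti::niftiHeader(list(
    dim = c(length(d), d, rep(1L, 7 - length(d))),
    pixdim = c(-1, spacing, thickness, rep(1, 4)),
    xyzt_units = 2L))   # mm
  RNifti::asNifti(a, reference = hdr)
}

#' Save a label mask as uint8 NIfTI with a JSON scheme sidecar
#'
#' The mask is validated before writing; the label scheme goes to
#' `<path>.json` so a reload reproduces labels and tissue names exactly.
#'
#' @param mask a [LabelMask-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing optional in-plane spacing to record in the header.
#' @return the path, invisibly.
#' @export
saveMask <- function(mask, path, spacing = c(1, 1)) {
  methods::validObject(mask)
  if (max(mask@labels) > 255L) stop("labels exceed uint8 range")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  nii <- niftiWithSpacing(array(mask@labels, dim(mask@labels)),
                          spacing, 1)
  RNifti::writeNifti(nii, path, datatype = "uint8")
  jsonlite::write_json(as.list(mask@scheme), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load a label mask saved by [saveMask()]
#'
#' @param path NIfTI path; the `<path>.json` sidecar is read when
#'   present, otherwise a generic scheme is derived from the labels.
#' @return a [LabelMask-class].
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  a <- matrix(as.integer(a), nrow = dim(a)[1])
  side <- paste0(path, ".json")
  scheme <- if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    stats::setNames(as.character(unlist(s)), names(s))
  } else NULL
  labelMask(a, scheme)
}

#' Write a phantom to an output directory
#'
#' Emits one NIfTI volume per echo (lossless float64), the uint8 label
#' mask, and a JSON sidecar recording the generating parameters, the
#' true fascia thickness, and the seed - enough provenance to re-render
#' the identical phantom.
#'
#' @param ph a [PhantomOutput-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveSlice(ph@ute, file.path(dir, "ute.nii.gz"))
  saveSlice(ph@shte, file.path(dir, "shte.nii.gz"))
  saveMask(ph@truth, file.path(dir, "truth.nii.gz"),
           spacing = ph@ute@spacing)
  spec <- ph@spec
  side <- list(
    gridSize = spec@gridSize, pixelSpacing = spec@pixelSpacing,
    legRadius = spec@legRadius, fatThickness = spec@fatThickness,
    fasciaThickness = if (is.function(spec@fasciaThickness))
      "function(theta)" else spec@fasciaThickness,
    septumWidth = spec@septumWidth, boneRadius = spec@boneRadius,
    noiseSigma = spec@noiseSigma, periodicNoise = spec@periodicNoise,
    biasField = spec@biasField, te1 = spec@te1, te2 = spec@te2,
    sliceThickness = spec@sliceThickness, seed = spec@seed,
    trueThicknessMm = ph@trueThicknessMm,
    tissueModels = lapply(spec@tissueModels, function(m)
      list(s0 = m@s0, t2star = m@t2star)))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write streamline tracts as plain text
#'
#' One tract per block: a header line `track <i> <npoints>` followed by
#' one `x y z` line per point (mm), blocks separated by blank lines.
#'
#' @param ts a [StreamlineSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTracts <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# streamline tracts, physical mm coordinates", con)
  for (i in seq_along(ts@tracts)) {
    t <- ts@tracts[[i]]
    writeLines(sprintf("track %d %d", i, nrow(t)), con)
    writeLines(apply(t, 1, function(p)
      paste(format(p, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read streamline tracts written by [writeTracts()]
#'
#' @param path input path.
#' @return a [StreamlineSet-class].
#' @export
readTracts <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ln <- trimws(readLines(path))
  ln <- ln[!startsWith(ln, "#")]
  tracts <- list()
  cur <- NULL
  for (l in ln) {
    if (startsWith(l, "track")) {
      if (!is.null(cur) && length(cur)) tracts <- c(tracts, list(cur))
      cur <- character(0)
    } else if (nzchar(l)) {
      cur <- c(cur, l)
    }
  }
  if (!is.null(cur) && length(cur)) tracts <- c(tracts, list(cur))
  streamlineSet(lapply(tracts, function(block) {
    do.call(rbind, lapply(strsplit(block, "[[:space:]]+"), as.numeric))
  }))
}
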