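#' @include accessors.R
NULL

pipelineStageOrder <- c(subtract = 1, enhance = 2, fft = 3, kmeans = 4,
                        watershed = 4, thickness = 5)

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

#' Run the fascia imaging pipeline
#'
#' Executes the two-phase workflow on a dual-echo pair: the image
#' enhancement / noise-removal phase (region-specific scaling +
#' subtraction, then contrast / top-hat / Wiener enhancement), followed
#' by the segmentation phase (FFT periodic-noise suppression, then
#' K-means clustering or watershed), and finally thickness measurement
#' of the extracted fascia mask. Every intermediate image, the masks,
#' the thickness report, and a provenance log with all parameters and
#' seeds are written to the output directory.
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   \describe{
#'     \item{input}{either `list(phantom = list(...))` with
#'       [phantomSpec()] arguments, or `list(ute =, shte =, te1 =, te2 =)`
#'       NIfTI paths and echo times.}
#'     \item{stages}{character vector drawn from `subtract`, `enhance`,
#'       `fft`, `kmeans`, `watershed`, `thickness`, in pipeline order.}
#'     \item{params}{optional per-stage parameter lists, e.g.
#'       `params$kmeans$k`.}
#'     \item{seed}{RNG seed (default 1).}
#'   }
#' @param out output directory.
#' @return invisibly, a list with the final mask, thickness report (if
#'   measured), and the provenance record.
#' @export
runPipeline <- function(config, out) {
  config <- readPipelineConfig(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% character(0)
  known <- names(pipelineStageOrder)
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  ord <- pipelineStageOrder[stages]
  if (any(diff(ord) < 0))
    stop("stage-order violation: stages must follow ",
         "subtract < enhance < fft < {kmeans|watershed} < thickness")
  if (all(c("kmeans", "watershed") %in% stages))
    stop("choose one of kmeans or watershed, not both")
  seed <- config$seed %||% 1L
  params <- config$params %||% list()

  ## ---- input -------------------------------------------------------------
  inp <- config$input
  if (!is.null(inp$phantom)) {
    spec <- do.call(phantomSpec, inp$phantom)
    ph <- makePhantom(spec)
    pair <- dualEchoPair(ph@ute, ph@shte, ph@te1, ph@te2)
    writePhantom(ph, file.path(out, "phantom"))
  } else if (!is.null(inp$ute)) {
    ute <- loadVolume(inp$ute)[[1]]
    shte <- loadVolume(inp$shte)[[1]]
    pair <- dualEchoPair(ute, shte, inp$te1 %||% 0.05, inp$te2 %||% 5.19)
  } else stop("config$input must give a phantom spec or ute/shte paths")

  prov <- list(stages = stages, seed = seed, params = params,
               input = if (!is.null(inp$phantom)) "phantom" else
                 list(ute = inp$ute, shte = inp$shte),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  current <- subtractEchoes(pair)   # starting point if no subtract stage
  mask <- NULL
  report <- NULL

  if (!length(stages)) {
    warning("empty stage list: input subtraction copied to output")
    saveSlice(current, file.path(out, "output.nii.gz"), datatype = "float")
  }

  for (st in stages) {
    if (st == "subtract") {
      p <- params$subtract %||% list()
      if (identical(p$scale %||% "region", "region")) {
        roi <- if (!is.null(p$roi)) loadMask(p$roi) else NULL
        rs <- regionSpecificScale(pair, roi)
        prov$scaling <- list(factor = rs$scaling@factor,
                             method = rs$scaling@method)
        current <- subtractEchoes(pair, rs$scaledUte)
      } else {
        current <- subtractEchoes(pair)
      }
    } else if (st == "enhance") {
      p <- params$enhance %||% list()
      if (isTRUE(p$contrast %||% TRUE)) current <- contrastAdjust(current)
      if (!is.null(p$tophatRadius))
        current <- topHat(current, p$tophatRadius)
      if (!is.null(p$wiener))
        current <- wienerDenoise(current, p$wiener)
    } else if (st == "fft") {
      p <- params$fft %||% list()
      fs <- frequencyFilterSpec(p$protectRadiusFrac %||% 0.08,
                                p$spikeZ %||% 3.5,
                                p$lowpassFrac %||% NA_real_)
      fd <- fftDenoise(current, fs)
      prov$fft <- list(spikeCount = fd$spikeCount)
      current <- fd$image
    } else if (st == "kmeans") {
      p <- params$kmeans %||% list()
      cr <- kmeansIntensity(current, p$k %||% 3L,
                            p$replicates %||% 10L, seed)
      prov$kmeans <- list(k = length(cr@centroids), wcss = cr@wcss,
                          centroids = cr@centroids)
      mask <- fasciaMaskFromClusters(cr, current)
      saveMask(cr@labels, file.path(out, "clusters.nii.gz"),
               spacing = current@spacing)
    } else if (st == "watershed") {
      p <- params$watershed %||% list()
      ws <- watershedSegment(current, p$threshold %||% 0.6)
      prov$watershed <- list(nRegions = ws@nRegions,
                             threshold = ws@thresholdUsed)
      mask <- labelMask(ws@labels@labels != 0, c("1" = "fascia"))
      saveMask(ws@labels, file.path(out, "watershed.nii.gz"),
               spacing = current@spacing)
    } else if (st == "thickness") {
      if (is.null(mask)) stop("thickness stage requires a segmentation")
      report <- thicknessReport(list(mask), spacing = current@spacing)
      df <- data.frame(slice_index = seq_along(report@perSliceMeanMm),
                       n_skeleton_points = report@nSkeletonPoints,
                       mean_thickness_mm = report@perSliceMeanMm)
      write.csv(df, file.path(out, "thickness.csv"), row.names = FALSE)
      prov$thickness <- list(overallMeanMm = report@overallMeanMm)
    }
    if (st %in% c("subtract", "enhance", "fft"))
      saveSlice(current, file.path(out, paste0(st, ".nii.gz")),
                datatype = "float")
  }
  if (!is.null(mask))
    saveMask(mask, file.path(out, "fascia_mask.nii.gz"),
             spacing = current@spacing)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mask = mask, report = report, provenance = prov,
                 image = current))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
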