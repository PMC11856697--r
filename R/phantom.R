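#' @include accessors.R
NULL

#' Default tissue signal models for the leg phantom
#'
#' Amplitudes and T2* values chosen to reproduce the qualitative
#' dual-echo contrast ordering of a lower leg: fascia retains signal only
#' at ultra-short TE (T2* ~ 1 ms), muscle and fat persist at the second
#' echo, cortical bone decays almost immediately, background is air.
#'
#' @return named list of [TissueSignalModel-class].
#' @export
defaultTissueModels <- function() {
  list(fat        = tissueModel(0.9, 15),
       fascia     = tissueModel(0.8, 1.2),
       muscle     = tissueModel(1.0, 25),
       bone       = tissueModel(0.3, 0.4),
       background = tissueModel(0.0, 1))
}

#' Default multiplicative bias-field coefficients
#'
#' Coefficients of the low-order 2D polynomial used by [makePhantom()]
#' when a smooth coil-shading field is wanted: `exp(c1 u + c2 v + c3 u^2 +
#' c4 v^2 + c5 u v)` over normalized coordinates `u, v` in `[-1, 1]`,
#' normalized to mean 1. The default set produces ~ +/-30 % shading,
#' comparable to surface-coil inhomogeneity.
#' @export
defaultBiasField <- function() c(0.3, -0.2, 0.15, 0.1, -0.1)

#' Specify a synthetic dual-echo leg phantom
#'
#' Builds a validated [PhantomSpec-class] describing a lower-leg axial
#' cross-section: concentric background / subcutaneous fat / thin
#' deep-fascia annulus / muscle (optionally split by an aponeurosis-like
#' septum) / bone, with per-tissue mono-exponential T2* decay evaluated
#' at two echo times, Rician noise, optional sinusoidal periodic noise
#' and an optional smooth multiplicative bias field.
#'
#' Default echo times 0.05/5.19 ms and 0.5 mm spacing mirror a spiral
#' dual-echo UTE protocol. Default corruptions are a Rician sigma of 0.03
#' (SNR ~ 33 relative to unit muscle signal) and a stripe artifact of
#' amplitude 0.08 at 32 cycles/image, 30 degrees - the kind of structured
#' periodic interference the FFT stage is designed to remove. The
#' periodic-noise wave vector is quantized to integer DFT bins so the
#' corruption occupies exactly two conjugate frequency bins.
#'
#' @param gridSize pixels per side (>= 64).
#' @param pixelSpacing mm per pixel.
#' @param legRadius,fatThickness,boneRadius geometry (mm).
#' @param fasciaThickness fascia annulus thickness in mm; scalar or
#'   `function(theta)` of polar angle.
#' @param septumWidth width (mm) of a vertical septum through the
#'   muscle; 0 disables it.
#' @param tissueModels named list of [TissueSignalModel-class]; see
#'   [defaultTissueModels()].
#' @param noiseSigma Rician noise scale (>= 0).
#' @param periodicNoise `NULL` or `list(amplitude=, frequency=,
#'   orientation=)` with frequency in cycles/image and orientation in
#'   degrees.
#' @param biasField `NULL` or polynomial coefficients (see
#'   [defaultBiasField()]).
#' @param te1,te2 echo times (ms).
#' @param sliceThickness mm.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noiseSigma = 0, periodicNoise = NULL)
#' ph <- makePhantom(spec)
#' ph
#' @export
phantomSpec <- function(gridSize = 256L, pixelSpacing = 0.5,
                        legRadius = 50, fatThickness = 6,
                        fasciaThickness = 1.5, septumWidth = 0,
                        boneRadius = 10,
                        tissueModels = defaultTissueModels(),
                        noiseSigma = 0.03,
                        periodicNoise = list(amplitude = 0.08,
                                             frequency = 32,
                                             orientation = 30),
                        biasField = NULL,
                        te1 = 0.05, te2 = 5.19,
                        sliceThickness = 5, seed = 1L) {
  new("PhantomSpec", gridSize = as.integer(gridSize),
      pixelSpacing = pixelSpacing, legRadius = legRadius,
      fatThickness = fatThickness, fasciaThickness = fasciaThickness,
      septumWidth = septumWidth, boneRadius = boneRadius,
      tissueModels = tissueModels, noiseSigma = noiseSigma,
      periodicNoise = periodicNoise, biasField = biasField,
      te1 = te1, te2 = te2, sliceThickness = sliceThickness,
      seed = as.integer(seed))
}

#' Tissue label codes used by the phantom
#'
#' 0 background, 1 fat, 2 fascia, 3 muscle, 4 bone, 5 septum (the septum
#' carries the fascia signal model but its own label so the fascia
#' annulus ground truth stays clean).
#' @export
phantomScheme <- function() {
  c("1" = "fat", "2" = "fascia", "3" = "muscle", "4" = "bone",
    "5" = "septum")
}

# Quantize a (frequency, orientation) pair to integer DFT bin offsets.
periodicWaveVector <- function(frequency, orientationDeg) {
  th <- orientationDeg * pi / 180
  c(kr = round(frequency * sin(th)), kc = round(frequency * cos(th)))
}

#' Render a synthetic dual-echo leg phantom
#'
#' Renders the concentric geometry of a [PhantomSpec-class] by per-pixel
#' radial classification at pixel centres (no anti-aliasing, so the
#' ground-truth thickness is exact in pixel units), evaluates each
#' tissue's signal at the two echo times, then applies the corruptions in
#' physically meaningful order: multiplicative bias field, additive
#' periodic noise (both echoes), and per-echo independent Rician noise
#' (magnitude of signal plus complex Gaussian).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomOutput-class] with the dual-echo pair, ground-truth
#'   [LabelMask-class], and the true fascia thickness in mm.
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSigma = 0, periodicNoise = NULL))
#' # fascia is bright at the first echo and gone at the second:
#' f <- labels(ph@truth) == 2
#' mean(pixels(ph@ute)[f]) > mean(pixels(ph@shte)[f])
#' @export
makePhantom <- function(spec) {
  methods::validObject(spec)
  n <- spec@gridSize
  sp <- spec@pixelSpacing
  ctr <- (n + 1) / 2
  rowMm <- (seq_len(n) - ctr) * sp
  colMm <- (seq_len(n) - ctr) * sp
  R <- sqrt(outer(rowMm^2, colMm^2, "+"))
  theta <- atan2(matrix(rowMm, n, n), matrix(colMm, n, n, byrow = TRUE))

  ft <- spec@fasciaThickness
  ftMat <- if (is.function(ft)) {
    array(vapply(as.vector(theta), ft, numeric(1)), dim = c(n, n))
  } else matrix(ft, n, n)
  fasciaOuter <- spec@legRadius - spec@fatThickness
  fasciaInner <- fasciaOuter - ftMat

  lab <- matrix(0L, n, n)
  lab[R <= spec@legRadius] <- 1L                       # fat
  lab[R <= fasciaOuter & R > fasciaInner] <- 2L        # fascia annulus
  lab[R <= fasciaInner] <- 3L                          # muscle
  if (spec@septumWidth > 0) {
    half <- spec@septumWidth / 2
    septum <- abs(matrix(colMm, n, n, byrow = TRUE)) <= half &
      R <= fasciaInner & R > spec@boneRadius
    lab[septum] <- 5L
  }
  lab[R <= spec@boneRadius] <- 4L                      # bone

  tm <- spec@tissueModels
  sigFor <- function(te) {
    s <- c(signalAt(tm$background, te), signalAt(tm$fat, te),
           signalAt(tm$fascia, te), signalAt(tm$muscle, te),
           signalAt(tm$bone, te), signalAt(tm$fascia, te))
    array(s[lab + 1L], dim = c(n, n))
  }
  ute <- sigFor(spec@te1)
  shte <- sigFor(spec@te2)

  if (!is.null(spec@biasField) && length(spec@biasField)) {
    cf <- c(spec@biasField, rep(0, 5))[1:5]
    u <- matrix((seq_len(n) - ctr) / (n / 2), n, n)         # rows
    v <- matrix((seq_len(n) - ctr) / (n / 2), n, n, byrow = TRUE)
    field <- exp(cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * v^2 +
                   cf[5] * u * v)
    field <- field / mean(field)
    ute <- ute * field
    shte <- shte * field
  }

  if (!is.null(spec@periodicNoise)) {
    pn <- spec@periodicNoise
    k <- periodicWaveVector(pn$frequency, pn$orientation)
    ri <- matrix(seq_len(n) - 1L, n, n)
    ci <- matrix(seq_len(n) - 1L, n, n, byrow = TRUE)
    stripe <- pn$amplitude * sin(2 * pi * (k["kr"] * ri + k["kc"] * ci) / n)
    ute <- ute + stripe
    shte <- shte + stripe
  }

  if (spec@noiseSigma > 0) {
    set.seed(spec@seed)
    rician <- function(s) {
      sqrt((s + rnorm(length(s), sd = spec@noiseSigma))^2 +
             rnorm(length(s), sd = spec@noiseSigma)^2) |>
        array(dim = dim(s))
    }
    ute <- rician(ute)
    shte <- rician(shte)
  }

  trueTh <- if (is.function(ft)) {
    vapply(seq(0, 2 * pi, length.out = 361)[-361], ft, numeric(1))
  } else ft

  new("PhantomOutput",
      ute = sliceImage(ute, c(sp, sp), spec@sliceThickness),
      shte = sliceImage(shte, c(sp, sp), spec@sliceThickness),
      truth = new("LabelMask", labels = lab, scheme = phantomScheme()),
      trueThicknessMm = trueTh, te1 = spec@te1, te2 = spec@te2,
      spec = spec)
}

#' Generate synthetic pennate fascicle tracts
#'
#' Produces straight streamline tracts whose end-to-end chords all make
#' exactly the requested pennation angle with a given muscle line of
#' action; the azimuth of each chord around the line of action and the
#' tract lengths are randomized. Serves as ground truth for the
#' architecture metrics: the recovered mean pennation must equal the set
#' angle up to numerical precision.
#'
#' @param nTracts number of tracts (>= 1).
#' @param pennationDeg pennation angle in degrees, `0 <= angle < 90`.
#' @param lineOfAction 3-vector (normalized internally).
#' @param lengthRangeMm `c(min, max)` tract length range in mm; lengths
#'   are drawn uniformly.
#' @param seed RNG seed.
#' @param nPointsPerTract vertices per (straight) polyline, >= 2.
#' @return a [StreamlineSet-class].
#' @examples
#' ts <- makePennateTracts(100, 22.37, c(0, 0, 1), c(5, 200), seed = 7)
#' mean(pennationAngles(ts, c(0, 0, 1)))   # 22.37
#' @export
makePennateTracts <- function(nTracts, pennationDeg,
                              lineOfAction = c(0, 0, 1),
                              lengthRangeMm = c(5, 200), seed = 1L,
                              nPointsPerTract = 2L) {
  if (pennationDeg < 0 || pennationDeg >= 90)
    stop("pennationDeg must satisfy 0 <= angle < 90")
  if (lengthRangeMm[1] > lengthRangeMm[2])
    stop("lengthRangeMm must be increasing")
  if (nTracts < 1)
    stop("nTracts must be >= 1")
  loa <- lineOfAction / sqrt(sum(lineOfAction^2))
  # orthonormal basis perpendicular to the line of action
  ref <- if (abs(loa[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * loa) * loa
  u <- u / sqrt(sum(u^2))
  v <- c(loa[2] * u[3] - loa[3] * u[2],
         loa[3] * u[1] - loa[1] * u[3],
         loa[1] * u[2] - loa[2] * u[1])
  a <- pennationDeg * pi / 180
  set.seed(seed)
  phi <- runif(nTracts, 0, 2 * pi)
  len <- runif(nTracts, lengthRangeMm[1], lengthRangeMm[2])
  starts <- matrix(runif(3 * nTracts, -50, 50), ncol = 3)
  tl <- lapply(seq_len(nTracts), function(i) {
    d <- cos(a) * loa + sin(a) * (cos(phi[i]) * u + sin(phi[i]) * v)
    s <- seq(0, len[i], length.out = max(2L, nPointsPerTract))
    sweep(outer(s, d), 2, starts[i, ], "+")
  })
  streamlineSet(tl)
}
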