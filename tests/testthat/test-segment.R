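test_that("FFT denoising removes stripe bins and spares clean images", {
  ph <- noisyPhantom()           # default Rician + stripe corruption
  fd <- fftDenoise(ph@ute)
  expect_gt(fd$spikeCount, 0)
  n <- nrow(pixels(ph@ute))
  k <- uteFascia:::periodicWaveVector(32, 30)
  binPower <- function(m) {
    P <- Mod(stats::fft(m))^2
    P[k[1] + 1, k[2] + 1] + P[n - k[1] + 1, n - k[2] + 1]
  }
  before <- binPower(norm01(pixels(ph@ute)))
  after <- binPower(pixels(fd$image))
  expect_lt(after / before, 0.1)       # >= 90 % stripe power removed

  clean <- cleanPhantom()
  fc <- fftDenoise(clean@ute)
  x0 <- norm01(pixels(clean@ute))
  rel <- sqrt(sum((pixels(fc$image) - x0)^2) / sum(x0^2))
  expect_lt(rel, 0.05)

  const <- sliceImage(matrix(0.3, 32, 32))
  out <- fftDenoise(const)
  expect_equal(pixels(out$image), pixels(const))
  expect_equal(out$spikeCount, 0L)
})

test_that("FFT filtering never increases spectral power in any bin", {
  ph <- noisyPhantom()
  for (sp in list(frequencyFilterSpec(),
                  frequencyFilterSpec(lowpassFrac = 0.3))) {
    fd <- fftDenoise(ph@ute, sp, normalize = FALSE)
    Pin <- Mod(stats::fft(pixels(ph@ute)))
    Pout <- Mod(stats::fft(pixels(fd$image)))
    expect_true(all(Pout <= Pin + 1e-6 * max(Pin)))
    expect_lte(sum(Pout^2), sum(Pin^2) * (1 + 1e-12))
  }
})

test_that("edge map responds at steps and tissue boundaries", {
  expect_true(all(pixels(edgeMap(sliceImage(matrix(1, 16, 16)))) == 0))

  step <- matrix(0, 32, 32); step[, 17:32] <- 1
  e <- pixels(edgeMap(sliceImage(step)))
  expect_setequal(which(e[16, ] == max(e[16, ])), c(16, 17))

  ph <- cleanPhantom()
  pair <- phantomPair(ph)
  sub <- subtractEchoes(pair, regionSpecificScale(pair)$scaledUte)
  e2 <- pixels(edgeMap(sub))
  lab <- labels(ph@truth)
  mid <- nrow(lab) %/% 2 + 1          # row through the centre
  left <- min(which(lab[mid, ] == 2)) # outer fascia boundary column
  win <- (left - 3):(left + 1)   # outer-boundary side only
  ridge <- win[which.max(e2[mid, win])]
  expect_lte(abs(ridge - left), 1)
})

test_that("intensity k-means separates delta populations exactly", {
  v <- rep(c(0.1, 0.5, 0.9), times = c(30, 40, 30))
  img <- sliceImage(matrix(v, 10, 10))
  cr <- kmeansIntensity(img, k = 3, replicates = 10, seed = 1)
  expect_equal(cr@centroids, c(0.1, 0.5, 0.9), tolerance = 1e-12)
  expect_equal(cr@wcss, 0)
  cr2 <- kmeansIntensity(img, k = 3, replicates = 10, seed = 1)
  expect_identical(labels(cr2@labels), labels(cr@labels))
  expect_identical(cr2@wcss, cr@wcss)
  expect_error(kmeansIntensity(sliceImage(matrix(0.5, 4, 4)), k = 3),
               "distinct")
})

test_that("k-means matches the exhaustive-partition oracle on tiny images", {
  set.seed(9)
  for (case in 1:10) {
    v <- round(runif(12), 3)
    cr <- kmeansIntensity(sliceImage(matrix(v, 3, 4)), k = 2,
                          replicates = 10, seed = case)
    expect_equal(cr@wcss, bruteForceWcss2(v), tolerance = 1e-9)
  }
})

test_that("highest-intensity cluster recalls the fascia annulus", {
  ph <- noisyPhantom()
  pair <- phantomPair(ph)
  sub <- subtractEchoes(pair, regionSpecificScale(pair)$scaledUte)
  cr <- kmeansIntensity(sub, k = 3, replicates = 10, seed = 11)
  top <- labels(cr@labels) == 3
  truth <- labels(ph@truth) == 2
  expect_gt(sum(top & truth) / sum(truth), 0.8)
})

test_that("watershed splits touching blobs and labels ridges 0", {
  img <- matrix(0, 64, 64)
  img[10:20, 10:20] <- 1; img[40:50, 40:50] <- 1
  ws <- watershedSegment(sliceImage(img), 0.6)
  expect_equal(ws@nRegions, 2L)
  # each region congruent to its blob
  expect_equal(sum(labels(ws@labels) > 0), sum(img > 0.6))

  r <- matrix(1:64, 64, 64); c <- t(r)
  dumb <- sqrt((r - 32)^2 + (c - 22)^2) <= 12 |
          sqrt((r - 32)^2 + (c - 42)^2) <= 12
  wd <- watershedSegment(sliceImage(array(as.numeric(dumb), c(64, 64))),
                         0.5)
  expect_equal(wd@nRegions, 2L)
  ridgeCols <- which(apply(labels(wd@labels) == 0 & dumb, 2, any))
  expect_true(all(abs(ridgeCols - 32) <= 1))   # split at the neck

  expect_warning(we <- watershedSegment(sliceImage(matrix(0, 16, 16))),
                 "empty foreground")
  expect_equal(we@nRegions, 0L)
})

test_that("fascia mask extraction reaches Dice >= 0.8 and never closes gaps", {
  ph <- noisyPhantom()
  pair <- phantomPair(ph)
  sub <- subtractEchoes(pair, regionSpecificScale(pair)$scaledUte)
  cr <- kmeansIntensity(sub, k = 3, replicates = 10, seed = 11)
  fm <- fasciaMaskFromClusters(cr, sub)
  expect_gt(diceJaccard(fm, truthFascia(ph))@dice, 0.8)

  # zeroed sector: no pixels may be hallucinated there
  x <- pixels(sub)
  n <- nrow(x)
  r <- matrix(1:n, n, n); c <- t(r)
  ctr <- (n + 1) / 2
  sector <- atan2(r - ctr, c - ctr) > 0 & atan2(r - ctr, c - ctr) < pi / 3
  x[sector] <- 0
  subBroken <- sliceImage(x, spacing(sub))
  crB <- kmeansIntensity(subBroken, k = 3, replicates = 10, seed = 11)
  fmB <- fasciaMaskFromClusters(crB, subBroken)
  expect_equal(sum(labels(fmB)[sector]), 0)
  expect_gt(sum(labels(fmB)), 0)

  zero <- sliceImage(matrix(0, 32, 32))
  crZ <- list()
  expect_warning(fmZ <- fasciaMaskFromClusters(cr, zero), "empty mask|no fascia")
})

test_that("FFT before K-means does not degrade fascia Dice", {
  ph <- noisyPhantom()
  pair <- phantomPair(ph)
  sub <- subtractEchoes(pair, regionSpecificScale(pair)$scaledUte)
  truth <- truthFascia(ph)
  crA <- kmeansIntensity(sub, k = 3, replicates = 10, seed = 11)
  dAlone <- diceJaccard(fasciaMaskFromClusters(crA, sub), truth)@dice
  fd <- fftDenoise(sub)
  crF <- kmeansIntensity(fd$image, k = 3, replicates = 10, seed = 11)
  dFft <- diceJaccard(fasciaMaskFromClusters(crF, fd$image), truth)@dice
  expect_gte(dFft, dAlone)
})
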