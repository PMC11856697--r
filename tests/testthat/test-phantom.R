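test_that("tissue signal follows mono-exponential decay", {
  m <- tissueModel(s0 = 1, t2star = 1)
  expect_equal(signalAt(m, 0), 1)
  expect_equal(signalAt(m, 0.05), exp(-0.05), tolerance = 1e-12)
  expect_equal(signalAt(m, 5), exp(-5), tolerance = 1e-12)
  te <- seq(0, 10, by = 0.5)
  s <- signalAt(m, te)
  expect_true(all(s > 0))
  expect_true(all(diff(s) < 0))
})

test_that("noiseless phantom renders the stated fascia intensities", {
  tm <- defaultTissueModels()
  tm$fascia <- tissueModel(1, 1)
  ph <- makePhantom(phantomSpec(noiseSigma = 0, periodicNoise = NULL,
                                tissueModels = tm, te1 = 0.05, te2 = 5))
  f <- labels(ph@truth) == 2
  expect_equal(unique(pixels(ph@ute)[f]), exp(-0.05), tolerance = 1e-12)
  expect_equal(unique(pixels(ph@shte)[f]), exp(-5), tolerance = 1e-12)
})

test_that("geometry violations and degenerate fascia are handled", {
  expect_error(phantomSpec(legRadius = 10, fatThickness = 6,
                           fasciaThickness = 2, boneRadius = 5),
               "nest")
  ph <- makePhantom(phantomSpec(fasciaThickness = 0, noiseSigma = 0,
                                periodicNoise = NULL))
  expect_false(any(labels(ph@truth) == 2))
  d <- pixels(ph@ute) - pixels(ph@shte)
  # no bright ring: the maximal subtraction value sits in fat, not at a
  # thin annulus (fascia model absent from the rendered geometry)
  expect_lt(max(d), signalAt(defaultTissueModels()$fascia, 0.05))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- makePhantom(phantomSpec(seed = 3))
  b <- makePhantom(phantomSpec(seed = 3))
  expect_identical(pixels(a@ute), pixels(b@ute))
  expect_identical(pixels(a@shte), pixels(b@shte))
  c <- makePhantom(phantomSpec(seed = 4))
  expect_false(identical(pixels(a@ute), pixels(c@ute)))
})

test_that("scaled subtraction contrast peaks on the fascia annulus", {
  ph <- cleanPhantom()
  pair <- phantomPair(ph)
  sub <- subtractEchoes(pair, regionSpecificScale(pair)$scaledUte)
  lab <- labels(ph@truth)
  mFascia <- mean(pixels(sub)[lab == 2])
  expect_gt(mFascia, mean(pixels(sub)[lab == 3]))  # muscle
  expect_gt(mFascia, mean(pixels(sub)[lab == 1]))  # fat
})

test_that("Rician noise preserves the mean of a high-SNR region", {
  spec <- phantomSpec(noiseSigma = 0.03, periodicNoise = NULL, seed = 21)
  ph <- makePhantom(spec)
  muscle <- labels(ph@truth) == 3
  expect_gt(sum(muscle), 1e4)
  truthVal <- signalAt(defaultTissueModels()$muscle, spec@te1)
  se <- sd(pixels(ph@ute)[muscle]) / sqrt(sum(muscle))
  expect_lt(abs(mean(pixels(ph@ute)[muscle]) - truthVal), 3 * se)
})

test_that("periodic corruption occupies exactly its two conjugate bins", {
  base <- phantomSpec(noiseSigma = 0, periodicNoise = NULL)
  striped <- phantomSpec(noiseSigma = 0,
                         periodicNoise = list(amplitude = 0.1,
                                              frequency = 32,
                                              orientation = 30))
  d <- pixels(makePhantom(striped)@ute) - pixels(makePhantom(base)@ute)
  P <- Mod(stats::fft(d))^2
  n <- nrow(d)
  k <- uteFascia:::periodicWaveVector(32, 30)
  hot <- c(P[k[1] + 1, k[2] + 1], P[n - k[1] + 1, n - k[2] + 1])
  expect_gt(min(hot) / sum(P), 0.499)   # each conjugate bin holds half
})

test_that("pennate generator puts every chord at the requested angle", {
  ts0 <- makePennateTracts(50, 0, c(0, 0, 1), c(5, 200), seed = 2)
  expect_equal(max(pennationAngles(ts0, c(0, 0, 1))), 0, tolerance = 1e-9)

  loa <- c(1, 2, 2) / 3
  ts <- makePennateTracts(200, 22.37, loa, c(5, 200), seed = 5)
  # independent per-chord oracle: arccos of the normalized dot product
  ang <- vapply(tracts(ts), function(t) {
    ch <- t[nrow(t), ] - t[1, ]
    acos(abs(sum(ch * loa)) / sqrt(sum(ch^2))) * 180 / pi
  }, numeric(1))
  expect_equal(mean(ang), 22.37, tolerance = 1e-9)
  expect_lt(max(abs(ang - 22.37)), 1e-9)

  len <- fascicleLengths(ts)
  expect_true(all(len >= 5 & len <= 200))
  expect_error(makePennateTracts(10, 95, c(0, 0, 1)), "pennationDeg")
})
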