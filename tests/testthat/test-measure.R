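test_that("bar thickness is recovered within discretization bounds", {
  for (tPx in c(2, 3, 5, 8)) {
    for (ang in c(0, 45, 90)) {
      st <- skeletonThickness(barMask(96, tPx, ang), spacing = 1)
      tol <- if (ang == 45) 1 else 0.5
      expect_lt(abs(st$sliceMeanMm - barTruthPx(tPx, ang)), tol + 1e-9)
    }
  }
  # the worked example: 5-px bar at 0.5 mm spacing is 2.5 mm thick
  st <- skeletonThickness(barMask(96, 5, 0), spacing = 0.5)
  expect_lt(abs(st$sliceMeanMm - 2.5), 0.25)
})

test_that("a 1-px line measures one pixel within the bias bound", {
  m <- matrix(0L, 48, 48); m[24, 8:40] <- 1L
  st <- skeletonThickness(labelMask(m), spacing = 1)
  expect_lt(abs(st$sliceMeanMm - 1), 0.5)
})

test_that("thickness is translation invariant and scales with spacing", {
  base <- matrix(0L, 64, 64); base[20:24, 10:54] <- 1L
  shifted <- matrix(0L, 64, 64); shifted[32:36, 8:52] <- 1L
  t1 <- skeletonThickness(labelMask(base), spacing = 1)$sliceMeanMm
  t2 <- skeletonThickness(labelMask(shifted), spacing = 1)$sliceMeanMm
  expect_equal(t1, t2, tolerance = 1e-12)
  t3 <- skeletonThickness(labelMask(base), spacing = 0.3)$sliceMeanMm
  expect_equal(t3, 0.3 * t1, tolerance = 1e-12)
  expect_error(skeletonThickness(labelMask(base), spacing = c(0.3, 0.5)),
               "anisotropic")
  expect_error(skeletonThickness(labelMask(matrix(0L, 8, 8))),
               "no foreground")
})

test_that("phantom annulus thickness lands within half a pixel", {
  ph <- cleanPhantom()   # 1.5 mm fascia at 0.5 mm spacing = 3 px
  st <- skeletonThickness(truthFascia(ph), spacing(ph@ute))
  expect_lt(abs(st$sliceMeanMm - 1.5), 0.25)
})

test_that("multi-slice reports average nonempty slices only", {
  bars <- lapply(c(3, 5), function(t) barMask(64, t, 0))
  empty <- labelMask(matrix(0L, 64, 64))
  rep3 <- thicknessReport(c(bars, list(empty)), spacing = 1)
  expect_equal(rep3@nSkeletonPoints[3], 0L)
  expect_equal(rep3@overallMeanMm, mean(rep3@perSliceMeanMm[1:2]))
  single <- vapply(bars, function(b)
    skeletonThickness(b, 1)$sliceMeanMm, numeric(1))
  expect_equal(rep3@perSliceMeanMm[1:2], single)
  expect_error(thicknessReport(list(empty), spacing = 1), "empty")
})

test_that("Dice and Jaccard follow their set identities", {
  m <- matrix(FALSE, 40, 40); m[5:20, 5:20] <- TRUE
  a <- labelMask(m)
  expect_equal(diceJaccard(a, a)@dice, 1)
  expect_equal(diceJaccard(a, a)@jaccard, 1)
  n <- matrix(FALSE, 40, 40); n[30:35, 30:35] <- TRUE
  expect_equal(diceJaccard(a, labelMask(n))@dice, 0)
  expect_error(diceJaccard(labelMask(matrix(FALSE, 4, 4)),
                           labelMask(matrix(FALSE, 4, 4))), "undefined")
  # the published inter-observer pair: dice 0.904 implies jaccard 0.825
  A <- matrix(FALSE, 40, 40); A[seq_len(500)] <- TRUE
  B <- matrix(FALSE, 40, 40); B[48 + seq_len(500)] <- TRUE  # overlap 452
  dj <- diceJaccard(labelMask(A), labelMask(B))
  expect_equal(dj@dice, 0.904, tolerance = 1e-9)
  expect_equal(round(dj@jaccard, 3), 0.825)
  expect_equal(dj@jaccard, dj@dice / (2 - dj@dice), tolerance = 1e-15)
})

test_that("muscle size follows count-times-area and is additive", {
  m <- matrix(FALSE, 20, 20); m[seq_len(100)] <- TRUE
  ms <- muscleSize(list(labelMask(m)), spacing = 0.5)
  expect_equal(ms$csaPerSliceMm2, 25)
  two <- muscleSize(list(labelMask(m), labelMask(m)), spacing = 0.5,
                    sliceThickness = 4)
  expect_equal(two$volumeMm3, 200)

  a <- matrix(FALSE, 20, 20); a[1:5, ] <- TRUE
  b <- matrix(FALSE, 20, 20); b[10:15, ] <- TRUE
  vu <- muscleSize(list(labelMask(a | b)), 1, 2)$volumeMm3
  va <- muscleSize(list(labelMask(a)), 1, 2)$volumeMm3
  vb <- muscleSize(list(labelMask(b)), 1, 2)$volumeMm3
  expect_equal(vu, va + vb)

  ph <- cleanPhantom()
  leg <- labelMask(labels(ph@truth) != 0L)
  csa <- muscleSize(list(leg), spacing(ph@ute))$csaPerSliceMm2
  spec <- ph@spec
  expect_lt(abs(csa - pi * spec@legRadius^2) / (pi * spec@legRadius^2),
            0.02)
})
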