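test_that("contrast adjustment maps the two-level image to full range", {
  x <- matrix(rep(c(0.2, 0.8), each = 5000), 100, 100)
  out <- pixels(contrastAdjust(sliceImage(x)))
  # window [mean - 2 sd, mean + 2 sd] = [-0.1, 1.1] clipped to [0.2, 0.8]
  expect_equal(sort(unique(round(as.vector(out), 10))), c(0, 1))
  expect_equal(out[x == 0.2][1], 0)
  expect_equal(out[x == 0.8][1], 1)
})

test_that("contrast adjustment is monotone and handles constant images", {
  set.seed(1)
  x <- matrix(runif(400), 20, 20)
  out <- pixels(contrastAdjust(sliceImage(x)))
  unsat <- out > 0 & out < 1
  expect_equal(order(x[unsat]), order(out[unsat]))
  expect_warning(cc <- contrastAdjust(sliceImage(matrix(0.4, 8, 8))),
                 "constant")
  expect_true(all(pixels(cc) == 1))
})

test_that("top-hat keeps narrow ridges and removes wide structures", {
  flat <- sliceImage(matrix(0.7, 64, 64))
  expect_true(all(pixels(topHat(flat)) == 0))

  ridge <- matrix(0, 64, 64); ridge[31:33, ] <- 1
  th <- pixels(topHat(sliceImage(ridge), 10))
  expect_equal(th[32, 32], 1)            # 3-px ridge survives intact
  expect_true(all(th >= 0))

  r <- matrix(1:101, 101, 101); c <- t(r)
  disk <- array(as.numeric(sqrt((r - 51)^2 + (c - 51)^2) <= 30), dim(r))
  td <- pixels(topHat(sliceImage(disk), 10))
  expect_lt(max(td[sqrt((r - 51)^2 + (c - 51)^2) <= 15]), 1e-9)
  expect_error(topHat(sliceImage(matrix(0, 10, 10)), 10), "larger")
})

test_that("Wiener filter denoises without disturbing means or edges", {
  const <- sliceImage(matrix(0.5, 40, 40))
  expect_equal(pixels(wienerDenoise(const)), pixels(const))

  set.seed(3)
  noisy <- matrix(0.5 + rnorm(128^2, sd = 0.05), 128, 128)
  out <- pixels(wienerDenoise(sliceImage(noisy)))
  expect_lt(var(as.vector(out)), var(as.vector(noisy)))
  expect_lt(abs(mean(out) - 0.5), 0.005)

  edge <- matrix(0, 64, 64); edge[, 33:64] <- 1
  eout <- pixels(wienerDenoise(sliceImage(edge), c(21, 21)))
  crossIn <- min(which(edge[32, ] >= 0.5))
  crossOut <- min(which(eout[32, ] >= 0.5))
  expect_lte(abs(crossIn - crossOut), 1)
  expect_error(wienerDenoise(sliceImage(matrix(0, 8, 8)), c(20, 20)),
               "exceeds")
})

test_that("region-specific scaling matches ROI statistics exactly", {
  set.seed(5)
  shte <- matrix(runif(64^2, 0.4, 0.9), 64, 64)
  ute <- shte * 0.5
  pair <- dualEchoPair(sliceImage(ute), sliceImage(shte), 0.05, 5.19)
  roi <- labelMask(matrix(TRUE, 64, 64))
  rs <- regionSpecificScale(pair, roi)
  expect_equal(rs$scaling@factor, 2, tolerance = 1e-12)
  expect_equal(rs$scaling@method, "median-ratio")
  post <- rs$scaling@postMatchStats
  expect_equal(post[["shteMedian"]] / post[["uteMedian"]], 1,
               tolerance = 1e-12)

  same <- dualEchoPair(sliceImage(shte), sliceImage(shte), 0.05, 5.19)
  rs2 <- regionSpecificScale(same, roi)
  expect_equal(rs2$scaling@factor, 1)
  expect_true(all(pixels(subtractEchoes(same, rs2$scaledUte)) == 0))

  zero <- dualEchoPair(sliceImage(matrix(0, 8, 8)),
                       sliceImage(matrix(1, 8, 8)), 0.05, 5.19)
  expect_error(regionSpecificScale(zero, labelMask(matrix(TRUE, 8, 8))),
               "degenerate ROI")
})

test_that("scaling residual in muscle stays below the fascia signal", {
  ph <- cleanPhantom()
  pair <- phantomPair(ph)
  roi <- labelMask(labels(ph@truth) == 3L)   # bias-free muscle ROI
  rs <- regionSpecificScale(pair, roi)
  d <- pixels(rs$scaledUte) - pixels(ph@shte)
  lab <- labels(ph@truth)
  expect_lt(abs(median(d[lab == 3])), median(d[lab == 2]))
})

test_that("subtraction clips negatives and normalizes to [0, 1]", {
  u <- matrix(c(0.2, 0.8), 4, 4)
  s <- matrix(0.5, 4, 4)
  pair <- dualEchoPair(sliceImage(u), sliceImage(s), 0.05, 5.19)
  out <- pixels(subtractEchoes(pair))
  expect_equal(range(out), c(0, 1))
  expect_true(all(out[u == 0.2] == 0))   # negative residuals clipped

  bad <- sliceImage(matrix(0.5, 6, 6))
  expect_error(subtractEchoes(pair, bad), "dimensions differ")
})

test_that("SNR follows its definition", {
  img <- matrix(0, 10, 10)
  img[1:5, 1] <- 1.56            # signal ROI, mean 1.56
  img[1:3, 10] <- c(-1, 0, 1)    # background ROI, sd exactly 1
  sig <- matrix(FALSE, 10, 10); sig[1:5, 1] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[1:3, 10] <- TRUE
  m <- measureSnr(sliceImage(img), labelMask(sig), labelMask(bg))
  expect_equal(m@snr, 1.56, tolerance = 1e-12)
  expect_error(measureSnr(sliceImage(img), labelMask(sig), labelMask(sig)),
               "disjoint")
})
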