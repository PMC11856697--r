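# Shared fixtures, cached so the phantom is rendered once per test run.
.fix <- new.env(parent = emptyenv())

# Noiseless, corruption-free phantom: the analytic reference.
cleanPhantom <- function() {
  if (is.null(.fix$clean))
    .fix$clean <- makePhantom(phantomSpec(noiseSigma = 0,
                                          periodicNoise = NULL))
  .fix$clean
}

# Phantom under the default study corruptions (Rician + stripes).
noisyPhantom <- function(seed = 7L) {
  key <- paste0("noisy", seed)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- makePhantom(phantomSpec(seed = seed))
  .fix[[key]]
}

phantomPair <- function(ph) dualEchoPair(ph@ute, ph@shte, ph@te1, ph@te2)

truthFascia <- function(ph) labelMask(labels(ph@truth) == 2L)

# Straight bar mask of nominal thickness tPx at a given orientation.
# The band centre is placed on a pixel centre (odd tPx) or between two
# pixel centres (even tPx) so axis-aligned bars have exactly tPx rows.
barMask <- function(n, tPx, angleDeg) {
  ctr <- if (tPx %% 2 == 1) floor(n / 2) else floor(n / 2) + 0.5
  r <- matrix(seq_len(n), n, n)
  c <- t(r)
  th <- angleDeg * pi / 180
  d <- abs((r - ctr) * cos(th) - (c - ctr) * sin(th))
  along <- (r - ctr) * sin(th) + (c - ctr) * cos(th)
  labelMask(d < tPx / 2 & abs(along) <= 0.4 * n)
}

# Effective thickness of the discrete bar: row count for axis-aligned
# bars; (number of occupied diagonals) / sqrt(2) for 45 degrees.
barTruthPx <- function(tPx, angleDeg) {
  if (angleDeg %in% c(0, 90)) {
    ctr <- if (tPx %% 2 == 1) 0 else 0.5
    sum(abs(seq(-tPx - 2, tPx + 2) - ctr) < tPx / 2)
  } else {
    # occupied diagonals have perpendicular offset k/sqrt(2), k integer
    ks <- seq(-3 * tPx, 3 * tPx)
    sum(abs(ks) / sqrt(2) < tPx / 2) / sqrt(2)
  }
}

# Brute-force 1D 2-means oracle: minimum WCSS over all 2-part
# assignments of the values.
bruteForceWcss2 <- function(v) {
  n <- length(v)
  best <- Inf
  for (m in seq_len(2^n - 1)) {
    a <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    if (all(a) || !any(a)) next
    w <- sum((v[a] - mean(v[a]))^2) + sum((v[!a] - mean(v[!a]))^2)
    if (w < best) best <- w
  }
  best
}

norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
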