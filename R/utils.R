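## Internal numerical helpers shared across modules.

# Min-max normalization to [0,1]; a constant image is returned unchanged.
normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(x)
  (x - rng[1]) / (rng[2] - rng[1])
}

# Centre index of the zero-frequency bin after fftshift (1-based).
fftCenter <- function(n) floor(n / 2) + 1L

# Swap quadrants so that the DC bin sits at fftCenter().
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2))]
}

# Conjugate-mirror index for 1-based unshifted DFT indices.
conjIndex <- function(j, n) (n - (j - 1L)) %% n + 1L

# Odd-sized disc structuring element of the given pixel radius.
discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Local windowed mean with replicate padding; supports even window sizes
# using the MATLAB convention (floor((w-1)/2) pixels before the centre).
localBoxMean <- function(x, wr, wc) {
  nr <- nrow(x); nc <- ncol(x)
  br <- (wr - 1L) %/% 2L; ar <- wr - 1L - br
  bc <- (wc - 1L) %/% 2L; ac <- wc - 1L - bc
  xp <- x[c(rep(1L, br), seq_len(nr), rep(nr, ar)),
          c(rep(1L, bc), seq_len(nc), rep(nc, ac)), drop = FALSE]
  # summed-area table with a zero border row/col
  s <- matrix(0, nrow(xp) + 1L, ncol(xp) + 1L)
  s[-1L, -1L] <- apply(apply(xp, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (s[r1 + wr, c1 + wc, drop = FALSE] - s[r1, c1 + wc, drop = FALSE] -
     s[r1 + wr, c1, drop = FALSE] + s[r1, c1, drop = FALSE]) / (wr * wc)
}

# Shift a matrix by (dr, dc), zero-filling exposed borders.
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Binary matrix from a LabelMask or logical/numeric matrix.
asBinaryMatrix <- function(mask) {
  m <- if (methods::is(mask, "LabelMask")) mask@labels else mask
  array(as.numeric(m != 0), dim = dim(m))
}

stopIfNot2D <- function(img) {
  stopifnot(methods::is(img, "SliceImage"), length(dim(img@pixels)) == 2L)
}
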