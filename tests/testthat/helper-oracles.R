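# Independent brute-force oracles used to validate the fast implementations.
# They deliberately take the O(n^2) full-matrix route rather than reusing any
# package internals.

# Ripley K via the full distance matrix: V * #{ordered pairs with d <= r} / n^2
oracle_ripley_k <- function(points, radii, volume) {
  n <- nrow(points)
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  vapply(radii, function(r) volume * sum(dm <= r) / n^2, numeric(1))
}

# per-source-row nearest distance to target rows via the full matrix
oracle_nearest <- function(src, tgt, exclude_self = FALSE) {
  dm <- matrix(NA_real_, nrow(src), nrow(tgt))
  for (i in seq_len(nrow(src))) {
    for (j in seq_len(nrow(tgt))) {
      dm[i, j] <- sqrt(sum((src[i, ] - tgt[j, ])^2))
    }
  }
  if (exclude_self) diag(dm) <- Inf
  apply(dm, 1, min)
}

# random rigid rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# filled-disc mask of radius r px centred in a (2r + 21)^2 image
disc_mask <- function(radius) {
  side <- 2 * radius + 21
  centre <- (side + 1) / 2
  ix <- matrix(seq_len(side), side, side)
  iy <- t(ix)
  matrix(as.integer((ix - centre)^2 + (iy - centre)^2 <= radius^2),
         side, side)
}

make_tempdir <- function() {
  d <- tempfile("ecdnaspatial_test_")
  dir.create(d)
  d
}

# irregular connected blob: union of overlapping discs
blob_mask <- function(seed = 1, side = 151) {
  set.seed(seed)
  ix <- matrix(seq_len(side), side, side)
  iy <- t(ix)
  m <- matrix(0L, side, side)
  cx <- side / 2 + stats::runif(4, -15, 15)
  cy <- side / 2 + stats::runif(4, -15, 15)
  rr <- stats::runif(4, 20, 40)
  for (k in 1:4) {
    m[(ix - cx[k])^2 + (iy - cy[k])^2 <= rr[k]^2] <- 1L
  }
  m
}
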