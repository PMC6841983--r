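# Independent oracles and fixture builders shared across tests.

# Exhaustive single-origin box counter: loops over every grid box and scans
# its pixels. Deliberately naive and independent of the package's
# unique-cell-index implementation.
bf_box_count <- function(pixels, eps) {
  d <- dim(pixels)
  n <- 0L
  for (r0 in seq(1, d[1], by = eps)) {
    for (c0 in seq(1, d[2], by = eps)) {
      blk <- pixels[r0:min(r0 + eps - 1, d[1]), c0:min(c0 + eps - 1, d[2])]
      if (any(blk)) n <- n + 1L
    }
  }
  n
}

# Faster exhaustive check via band sums (still touches every pixel); used
# for the larger fixtures where the double loop would crawl.
band_box_count <- function(pixels, eps) {
  d <- dim(pixels)
  rg <- rep(seq_len(ceiling(d[1] / eps)), each = eps, length.out = d[1])
  cg <- rep(seq_len(ceiling(d[2] / eps)), each = eps, length.out = d[2])
  sums <- rowsum(t(rowsum(pixels + 0, rg)), cg)
  sum(sums > 0)
}

# Straight bar of given (odd) width through the image centre at
# `angle_deg`, drawn from the point-to-line distance (no package code).
make_bar <- function(width, angle_deg, size = 65) {
  ctr <- (size - 1) / 2
  th <- angle_deg * pi / 180
  nvec <- c(cos(th), -sin(th))  # unit normal of the bar axis
  idx <- seq_len(size) - 1
  dist <- outer(idx - ctr, idx - ctr, function(r, c) r * nvec[1] + c * nvec[2])
  binary_mask(abs(dist) < width / 2,
              name = sprintf("bar_w%d_a%d", width, angle_deg))
}

# Brute-force caliber oracle: scans every background pixel for the nearest
# one to the centreline point (independent of the package's distance
# transform), and converts the centre-to-centre clearance to a width.
bf_caliber <- function(pixels, point) {
  bg <- which(!pixels, arr.ind = TRUE) - 1L
  d <- sqrt(min((bg[, 1] - point[1])^2 + (bg[, 2] - point[2])^2))
  max(1, 2 * d - 1)
}

# ep x ep checkerboard over an n x n window
make_checkerboard <- function(n = 64, ep = 8) {
  idx <- seq_len(n) - 1
  binary_mask(outer(idx, idx, function(r, c) ((r %/% ep) + (c %/% ep)) %% 2 == 0),
              name = "checkerboard")
}

# handful of box sizes for oracle comparisons, spanning small to 45% max
sample_box_sizes_for_test <- function(dims) {
  smax <- floor(0.45 * min(dims))
  sz <- unique(c(2, 3, 5, 7, smax %/% 2, smax))
  sz[sz >= 2 & sz <= smax]
}

# small simulated tree used by several suites
test_tree_params <- function(seed, window = 512) {
  tree_sim_params(seed = seed, window = window, segment_length = c(40, 12),
                  root_caliber = 14)
}
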