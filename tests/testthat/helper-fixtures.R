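# Fixture builders and small independent oracles used across tests.
# Oracles are deliberately naive re-implementations (brute force /
# flood fill) kept separate from the package's own code paths.

# logical matrix with a rasterised disk (pixel-centre rule)
disk_mask <- function(radius_px, dim = ceiling(2 * radius_px) + 5,
                      center = (dim + 1) / 2) {
  m <- matrix(FALSE, dim, dim)
  for (r in 1:dim)
    m[r, ] <- (r - center)^2 + ((1:dim) - center)^2 <= radius_px^2
  m
}

# union of disks at given (row, col) centres (px)
disks_mask <- function(centers, radius_px, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  for (k in seq_len(nrow(centers)))
    for (r in 1:nrow) {
      d2 <- (r - centers[k, 1])^2 + ((1:ncol) - centers[k, 2])^2
      m[r, ] <- m[r, ] | d2 <= radius_px^2
    }
  m
}

rect_mask <- function(h, w, pad = 3) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + (1:h), pad + (1:w)] <- TRUE
  m
}

# naive queue-based flood fill component count, 8-connected --
# independent of the package's union-find labelling
flood_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (s in which(mask & !seen)) {
    if (seen[s]) next
    n <- n + 1L
    q <- s
    seen[s] <- TRUE
    nr <- nrow(mask)
    while (length(q)) {
      p <- q[[1]]
      q <- q[-1]
      pr <- (p - 1) %% nr + 1
      pc <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- pr + dr; c2 <- pc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(mask)) next
        i <- (c2 - 1) * nr + r2
        if (mask[i] && !seen[i]) {
          seen[i] <- TRUE
          q <- c(q, i)
        }
      }
    }
  }
  n
}

# turn a plain logical mask into a one-blob set via the package detector
single_blob <- function(mask, optics = optics_model()) {
  bs <- detect_blobs(mask, optics, min_area_um2 = 0)
  stopifnot(length(bs$blobs) == 1)
  bs$blobs[[1]]
}

# quiet noise-free test configuration
quiet_config <- function(...) {
  op <- optics_model(noise_sd = 0)
  run_config(optics = op,
             stream = stream_model(frame_height = op$frame_height),
             ...)
}
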