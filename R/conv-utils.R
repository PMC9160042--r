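# Small dense 2-D filtering helpers shared by the phantom generator and the
# aggregation stage. Borders use symmetric (edge-replicating) reflection so
# filter mass never leaks off the image.

# pad a matrix by reflecting rows/cols about the edge (edge pixel duplicated)
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(pmin(pmax(k:1, 1L), nr), seq_len(nr),
            pmin(pmax(nr - seq_len(k) + 1L, 1L), nr))
  cidx <- c(pmin(pmax(k:1, 1L), nc), seq_len(nc),
            pmin(pmax(nc - seq_len(k) + 1L, 1L), nc))
  m[ridx, cidx, drop = FALSE]
}

# dense cross-correlation of `m` with a (2k+1)x(2k+1) kernel, reflect borders,
# output the same shape as `m`
filter2_reflect <- function(m, kernel) {
  k <- (nrow(kernel) - 1L) %/% 2L
  stopifnot(nrow(kernel) == ncol(kernel), nrow(kernel) == 2L * k + 1L)
  p <- pad_reflect(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      w <- kernel[a, b]
      if (w != 0) {
        out <- out + w * p[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
      }
    }
  }
  out
}

# separable Gaussian blur, kernel truncated at radius ceiling(3*sigma),
# reflect borders; preserves constants exactly (kernel normalized)
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  r <- as.integer(ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- pad_reflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # rows pass
  tmp <- matrix(0, nr, ncol(p))
  for (a in seq_along(g)) {
    tmp <- tmp + g[a] * p[(a - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (b in seq_along(g)) {
    out <- out + g[b] * tmp[, (b - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}
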