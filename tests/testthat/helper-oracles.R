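# Independent brute-force oracles, written against the metric definitions
# directly with explicit element loops. They deliberately share no code with
# the package implementations they check.

random_uint8 <- function(m, n = m) {
  gray_image(matrix(sample(0:255, m * n, replace = TRUE), m, n), "uint8")
}

oracle_ssim <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  xv <- as.numeric(x); yv <- as.numeric(y)
  n <- length(xv)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + xv[i]; my <- my + yv[i] }
  mx <- mx / n; my <- my / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (xv[i] - mx)^2
    vy <- vy + (yv[i] - my)^2
    cxy <- cxy + (xv[i] - mx) * (yv[i] - my)
  }
  vx <- vx / n; vy <- vy / n; cxy <- cxy / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

oracle_psnr <- function(x, y) {
  m <- nrow(x); n <- ncol(x)
  mse <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) mse <- mse + (x[i, j] - y[i, j])^2
  mse <- mse / (m * n)
  if (mse == 0) Inf else 20 * log10(255 / sqrt(mse))
}

oracle_histogram <- function(x) {
  h <- numeric(256)
  for (v in as.numeric(x)) h[v + 1] <- h[v + 1] + 1
  h / length(x)
}

oracle_kl <- function(p, q, eps = 1e-10) {
  ps <- p + eps; qs <- q + eps
  ps <- ps / sum(ps); qs <- qs / sum(qs)
  total <- 0
  for (i in 1:256) total <- total + ps[i] * log(ps[i] / qs[i])
  total
}

oracle_sd <- function(x, y) {
  m <- nrow(x); n <- ncol(x)
  gr <- function(f, i, j) {
    fi <- function(a, b) f[max(a, 1), max(b, 1)]   # replicate border
    2 * fi(i, j) - fi(i - 1, j) - fi(i, j - 1)
  }
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- acc + abs(gr(x, i, j) - gr(y, i, j))
  }
  nabla <- acc / (m * n)
  if (nabla == 0) Inf else 10 * log10(255^2 / nabla)
}

# --- aggregation oracle: naive per-pixel re-implementation -------------------

oracle_sobel <- function(img) {
  m <- unclass(img)
  nr <- nrow(m); nc <- ncol(m)
  # reflect (edge-duplicating) border lookup
  at <- function(i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      gx <- gx + kx[a + 2, b + 2] * at(i + a, j + b)
      gy <- gy + ky[a + 2, b + 2] * at(i + a, j + b)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_gaussian <- function(edges, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  off <- -r:r
  kern <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  kern <- kern / sum(kern)
  nr <- nrow(edges); nc <- ncol(edges)
  # symmetric (edge-duplicating) mirror, matching the documented border rule
  mir <- function(i, n) { if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i }
  at <- function(i, j) edges[mir(i, nr), mir(j, nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in off) for (b in off) {
      acc <- acc + kern[a + r + 1, b + r + 1] * at(i + a, j + b)
    }
    out[i, j] <- acc
  }
  out
}

# the whole fusion, pixel by pixel
oracle_aggregate <- function(images, scores, metric, sigma) {
  ord <- order(scores, -seq_along(scores), decreasing = TRUE)[1:2]
  i1 <- images[[ord[1]]]; i2 <- images[[ord[2]]]
  m <- scores[ord]
  if (any(is.infinite(m))) m <- c(2, 1)
  if (metric == "ssim") {
    m <- pmax(m, 0); if (sum(m) == 0) m <- c(1, 1)
  }
  g1 <- oracle_gaussian(oracle_sobel(i1), sigma)
  g2 <- oracle_gaussian(oracle_sobel(i2), sigma)
  nr <- nrow(i1); nc <- ncol(i1)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    den <- g1[i, j] * m[1] + g2[i, j] * m[2]
    w1 <- if (den > 0) g1[i, j] * m[1] / den else m[1] / (m[1] + m[2])
    out[i, j] <- floor(w1 * i1[i, j] + (1 - w1) * i2[i, j] + 0.5)
  }
  gray_image(out, "uint8")
}
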