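#' Structural similarity (global form)
#'
#' Computes the single-window SSIM of two uint8 images from whole-image
#' statistics,
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'                   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with population (1/N) variance and covariance. Identical images score
#' exactly 1. The stabilizing constants default to the conventional
#' `(0.01 * 255)^2` and `(0.03 * 255)^2`; they only guard against weak
#' denominators.
#'
#' A mean-of-local-windows variant is available through `window`; the global
#' form is the default and is what the rest of the pipeline uses.
#'
#' @param x,y uint8 [gray_image]s of the same shape.
#' @param c1,c2 positive stabilizing constants.
#' @param window optional odd window side; if given, SSIM is the mean of the
#'   global formula over all fully interior `window x window` patches.
#' @return SSIM in \[-1, 1\]; symmetric in `x` and `y`.
#' @export
compute_ssim <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                         window = NULL) {
  assert_image(x, "uint8", "x"); assert_image(y, "uint8", "y")
  assert_same_shape(x, y)
  stopifnot(c1 > 0, c2 > 0)
  if (is.null(window)) {
    return(ssim_stat(as.vector(x), as.vector(y), c1, c2))
  }
  w <- as.integer(window)
  stopifnot(w >= 2, w <= nrow(x), w <= ncol(x))
  vals <- c()
  for (i in seq_len(nrow(x) - w + 1L)) {
    for (j in seq_len(ncol(x) - w + 1L)) {
      vals <- c(vals, ssim_stat(
        as.vector(x[i:(i + w - 1L), j:(j + w - 1L)]),
        as.vector(y[i:(i + w - 1L), j:(j + w - 1L)]), c1, c2
      ))
    }
  }
  mean(vals)
}

ssim_stat <- function(xv, yv, c1, c2) {
  n <- length(xv)
  mx <- mean(xv); my <- mean(yv)
  vx <- sum((xv - mx)^2) / n
  vy <- sum((yv - my)^2) / n
  cxy <- sum((xv - mx) * (yv - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Peak signal-to-noise ratio
#'
#' \eqn{PSNR = 20 \log_{10}(255 / \sqrt{MSE})} in decibels, with
#' \eqn{MSE = \frac{1}{mn}\sum (f - g)^2}. Identical images (MSE = 0) return
#' `Inf`.
#'
#' @inheritParams compute_ssim
#' @return PSNR in dB, or `Inf`.
#' @export
compute_psnr <- function(x, y) {
  assert_image(x, "uint8", "x"); assert_image(y, "uint8", "y")
  assert_same_shape(x, y)
  mse <- mean((unclass(x) - unclass(y))^2)
  if (mse == 0) return(Inf)
  20 * log10(255 / sqrt(mse))
}

#' Intensity histogram of a uint8 image
#'
#' One bin per intensity level 0..255, normalized to probabilities.
#'
#' @param x a uint8 [gray_image].
#' @return A numeric vector of 256 probabilities summing to 1.
#' @export
image_histogram <- function(x) {
  assert_image(x, "uint8", "x")
  tabulate(as.vector(unclass(x)) + 1L, nbins = 256L) / length(x)
}

#' Kullback-Leibler divergence of two intensity histograms
#'
#' \eqn{KL(P \| Q) = \sum_x P(x) \log(P(x)/Q(x))} in nats. Image histograms
#' routinely have empty bins, where the formula is undefined, so `eps` is
#' added to every bin of both histograms before renormalization. The result
#' is nonnegative (Gibbs inequality) and asymmetric.
#'
#' @param p,q histograms from [image_histogram()] (256 nonnegative values
#'   summing to 1).
#' @param eps additive smoothing applied to every bin.
#' @return KL divergence in nats, `>= 0`.
#' @export
compute_kl <- function(p, q, eps = 1e-10) {
  stopifnot(length(p) == 256L, length(q) == 256L, eps > 0,
            all(p >= 0), all(q >= 0),
            abs(sum(p) - 1) < 1e-9, abs(sum(q) - 1) < 1e-9)
  ps <- (p + eps) / sum(p + eps)
  qs <- (q + eps) / sum(q + eps)
  sum(ps * log(ps / qs))
}

#' Sharpness difference between two images
#'
#' Compares the discrete gradients
#' \eqn{\Delta f(i,j) = 2 f(i,j) - f(i-1,j) - f(i,j-1)} of the two images:
#' \eqn{\nabla} is the mean absolute gradient difference over all pixels and
#' \eqn{SD = 10 \log_{10}(255^2 / \nabla)} in decibels. Out-of-grid
#' neighbours on the first row/column are supplied by replicating the edge,
#' so the mean runs over the full grid. \eqn{\nabla = 0} (e.g. two constant
#' images) returns `Inf`.
#'
#' @inheritParams compute_ssim
#' @return SD in dB, or `Inf`.
#' @export
compute_sd <- function(x, y) {
  assert_image(x, "uint8", "x"); assert_image(y, "uint8", "y")
  assert_same_shape(x, y)
  gd <- mean(abs(grad2(unclass(x)) - grad2(unclass(y))))
  if (gd == 0) return(Inf)
  10 * log10(255^2 / gd)
}

# 2f(i,j) - f(i-1,j) - f(i,j-1) with replicate-edge extension at i=1 / j=1
grad2 <- function(m) {
  up   <- m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
  left <- m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
  2 * m - up - left
}

#' Four-metric quality report of a generated image
#'
#' Bundles [compute_ssim()], [compute_psnr()], [compute_kl()] (on the two
#' images' 256-bin histograms) and [compute_sd()] against a reference image.
#' Identical inputs yield `ssim = 1`, `kl = 0` and the `Inf` sentinel for
#' PSNR and SD.
#'
#' @param generated,reference uint8 [gray_image]s of the same shape.
#' @return A one-row tibble with columns `ssim`, `psnr`, `kl`, `sd`.
#' @examples
#' a <- make_phantom(phantom_spec(size = 32, seed = 1))
#' b <- make_phantom(phantom_spec(size = 32, seed = 2))
#' evaluate_image(a, b)
#' @export
evaluate_image <- function(generated, reference) {
  assert_same_shape(generated, reference)
  tibble::tibble(
    ssim = compute_ssim(generated, reference),
    psnr = compute_psnr(generated, reference),
    kl   = compute_kl(image_histogram(generated), image_histogram(reference)),
    sd   = compute_sd(generated, reference)
  )
}
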