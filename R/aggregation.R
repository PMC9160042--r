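#' Sobel edge-magnitude map
#'
#' Applies the standard 3x3 Sobel kernels in both directions (reflect border
#' handling) and returns the gradient magnitude \eqn{\sqrt{G_x^2 + G_y^2}} as
#' a nonnegative matrix of the same shape.
#'
#' @param img a uint8 [gray_image].
#' @return A numeric matrix of edge magnitudes (an edge map).
#' @export
sobel_edge_map <- function(img) {
  assert_image(img, "uint8")
  m <- unclass(img)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- filter2_reflect(m, kx)      # column-direction gradient
  gy <- filter2_reflect(m, t(kx))   # row-direction gradient
  sqrt(gx^2 + gy^2)
}

#' Gaussian value of an edge map
#'
#' Smooths the Sobel magnitudes with a truncated Gaussian kernel (radius
#' `ceiling(3 * sigma)`, reflect borders), spreading each edge's priority to
#' its neighbourhood. Output is nonnegative and linear in the input.
#'
#' @param edges an edge map from [sobel_edge_map()].
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return A smoothed nonnegative matrix of the same shape.
#' @export
gaussian_edge_value <- function(edges, sigma = 1) {
  stopifnot(is.matrix(edges), all(edges >= 0), sigma > 0)
  gaussian_blur(edges, sigma)
}

#' Candidate set for aggregation
#'
#' Holds the three base-GAN outputs for one reference image together with
#' their image-level metric scores against that reference.
#'
#' @param images list of exactly 3 uint8 [gray_image]s of equal shape.
#' @param scores numeric vector of 3 metric values (finite or `Inf`).
#' @param metric which metric produced the scores: `"ssim"` or `"psnr"`.
#' @return A `candidate_set` object.
#' @export
candidate_set <- function(images, scores, metric = c("ssim", "psnr")) {
  metric <- match.arg(metric)
  if (length(images) != 3L || length(scores) != 3L) {
    stop("a candidate set holds exactly 3 images and 3 scores", call. = FALSE)
  }
  lapply(images, assert_image, domain = "uint8")
  assert_same_shape(images[[1]], images[[2]])
  assert_same_shape(images[[1]], images[[3]])
  if (any(is.na(scores))) stop("scores must not be NA", call. = FALSE)
  structure(list(images = images, scores = as.numeric(scores),
                 metric = metric), class = "candidate_set")
}

#' Select the best two of three candidates
#'
#' Returns the indices of the two highest-scoring candidates, ordered by
#' descending score; ties break deterministically toward the lower index.
#'
#' @param cands a [candidate_set()].
#' @return An integer vector of length 2.
#' @examples
#' select_top_two_scores(c(0.40, 0.68, 0.62))
#' @export
select_top_two <- function(cands) {
  stopifnot(inherits(cands, "candidate_set"))
  select_top_two_scores(cands$scores)
}

#' @rdname select_top_two
#' @param scores numeric vector of exactly 3 scores.
#' @export
select_top_two_scores <- function(scores) {
  if (length(scores) != 3L) {
    stop("exactly 3 candidate scores are required", call. = FALSE)
  }
  order(scores, seq_along(scores) * -1, decreasing = TRUE)[1:2]
}

#' Per-pixel blend weights from edge maps and metric scores
#'
#' The weight of image 1 at each pixel is
#' \deqn{w_1(x,y) = \frac{g_1(x,y) m_1}{g_1(x,y) m_1 + g_2(x,y) m_2}}
#' where \eqn{g_i} are Gaussian-smoothed edge values and \eqn{m_i} the
#' image-level metric scores, so pixels near strong edges of the
#' better-scoring image dominate the blend. Where both weighted edge values
#' vanish the weights fall back to the metric-proportional split
#' \eqn{m_1 / (m_1 + m_2)}. Weights always sum to 1 pixel-wise.
#'
#' @param g1,g2 smoothed edge maps of equal shape ([gaussian_edge_value()]).
#' @param m1,m2 nonnegative metric scores, not both zero.
#' @return A list with matrices `w1` and `w2` (`w1 + w2 == 1` everywhere).
#' @export
assign_weights <- function(g1, g2, m1, m2) {
  stopifnot(is.matrix(g1), is.matrix(g2), identical(dim(g1), dim(g2)))
  if (m1 < 0 || m2 < 0) stop("metric scores must be >= 0", call. = FALSE)
  if (m1 == 0 && m2 == 0) {
    stop("at least one metric score must be positive", call. = FALSE)
  }
  a <- g1 * m1
  denom <- a + g2 * m2
  w1 <- matrix(m1 / (m1 + m2), nrow(g1), ncol(g1))
  pos <- denom > 0
  w1[pos] <- a[pos] / denom[pos]
  list(w1 = w1, w2 = 1 - w1)
}

#' Pixel-wise weighted blend of two images
#'
#' `out = round(w1 * img1 + w2 * img2)` with half-up rounding; every output
#' pixel is a convex combination of the two input pixels, so it lies within
#' their \[min, max\] range.
#'
#' @param img1,img2 uint8 [gray_image]s of equal shape.
#' @param w weight maps from [assign_weights()].
#' @return A uint8 [gray_image].
#' @export
blend_images <- function(img1, img2, w) {
  assert_image(img1, "uint8", "img1"); assert_image(img2, "uint8", "img2")
  assert_same_shape(img1, img2)
  stopifnot(is.list(w), identical(dim(w$w1), dim(img1)))
  if (max(abs(w$w1 + w$w2 - 1)) > 1e-9 || min(w$w1) < -1e-12 ||
      max(w$w1) > 1 + 1e-12) {
    stop("weight maps must lie in [0,1] and sum to 1 pixel-wise",
         call. = FALSE)
  }
  out <- floor(w$w1 * unclass(img1) + w$w2 * unclass(img2) + 0.5)
  gray_image(out, "uint8")
}

#' Edge-priority aggregation of a candidate set
#'
#' The full fusion step: select the two best candidates by their metric
#' score, compute each one's Sobel edge map, smooth both with a Gaussian, turn
#' the smoothed edge values and the metric scores into per-pixel weights, and
#' blend. Deterministic given its inputs. When the metric is PSNR and any
#' selected score is infinite (a candidate identical to the reference), the
#' two scores are rank-transformed (2 for the better, 1 for the other) so the
#' weights stay finite.
#'
#' @param cands a [candidate_set()].
#' @param sigma Gaussian smoothing bandwidth for the edge maps, in pixels.
#' @return The fused uint8 [gray_image].
#' @examples
#' ref <- make_phantom(phantom_spec(size = 32, seed = 0))
#' imgs <- make_phantom_dataset(3, phantom_spec(size = 32), 0.15, seed = 2)
#' sc <- vapply(imgs, compute_ssim, numeric(1), y = ref)
#' fused <- aggregate_candidates(candidate_set(imgs, sc, "ssim"))
#' @export
aggregate_candidates <- function(cands, sigma = 1) {
  stopifnot(inherits(cands, "candidate_set"))
  sel <- select_top_two(cands)
  i1 <- cands$images[[sel[1]]]
  i2 <- cands$images[[sel[2]]]
  m <- cands$scores[sel]
  if (any(is.infinite(m))) {
    m <- c(2, 1)   # rank transform keeps weights finite
  }
  if (cands$metric == "ssim") {
    m <- pmax(m, 0)  # SSIM can be negative; weights need nonnegative scores
    if (sum(m) == 0) m <- c(1, 1)
  }
  g1 <- gaussian_edge_value(sobel_edge_map(i1), sigma)
  g2 <- gaussian_edge_value(sobel_edge_map(i2), sigma)
  w <- assign_weights(g1, g2, m[1], m[2])
  blend_images(i1, i2, w)
}
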