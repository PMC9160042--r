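test_that("Sobel edge maps match kernel geometry and a brute-force oracle", {
  flat <- gray_image(matrix(77, 6, 6), "uint8")
  expect_true(all(sobel_edge_map(flat) == 0))
  # vertical step edge: maxima on the two columns astride the step,
  # zero far away
  step <- gray_image(cbind(matrix(0, 8, 4), matrix(255, 8, 4)), "uint8")
  e <- sobel_edge_map(step)
  expect_true(all(e[, 4:5] > 0))
  expect_true(all(e[, c(1, 2, 7, 8)] == 0))
  # hand-filled 4x4 against the explicit convolution oracle
  withr::local_seed(10)
  img <- random_uint8(4)
  expect_equal(sobel_edge_map(img), oracle_sobel(img), tolerance = 1e-9)
})

test_that("Gaussian edge smoothing is linear, normalized and a semigroup", {
  z <- matrix(0, 9, 9)
  expect_true(all(gaussian_edge_value(z, 1) == 0))
  # unit impulse: centre equals the normalized kernel's centre weight
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  g <- gaussian_edge_value(imp, 1)
  k1 <- exp(-(-3:3)^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(g[5, 5], k1[4]^2, tolerance = 1e-12)
  # smoothing twice with sigma ~ once with sigma * sqrt(2) (interior);
  # the 3-sigma kernel truncation leaves ~0.3% tail mass, which bounds how
  # closely the exact-Gaussian semigroup identity can hold
  withr::local_seed(11)
  e <- abs(matrix(rnorm(33 * 33), 33, 33))
  twice <- gaussian_edge_value(gaussian_edge_value(e, 1), 1)
  once <- gaussian_edge_value(e, sqrt(2))
  inner <- 13:21
  expect_equal(twice[inner, inner], once[inner, inner], tolerance = 2e-3)
})

test_that("top-two selection orders by score with index tie-breaks", {
  expect_identical(select_top_two_scores(c(0.40, 0.68, 0.62)), c(2L, 3L))
  expect_identical(select_top_two_scores(c(0.5, 0.5, 0.1)), c(1L, 2L))
  expect_identical(select_top_two_scores(c(0.3, 0.3, 0.3)), c(1L, 2L))
  expect_identical(select_top_two_scores(c(0.1, Inf, 0.5)), c(2L, 3L))
  expect_error(select_top_two_scores(c(1, 2)), "3 candidate scores")
})

test_that("weight assignment follows the edge-times-metric rule", {
  g <- matrix(1, 4, 4)
  w <- assign_weights(g, g, 0.5, 0.5)
  expect_true(all(w$w1 == 0.5) && all(w$w2 == 0.5))
  # degenerate dominance: only image 1 has edges
  w <- assign_weights(matrix(2, 4, 4), matrix(0, 4, 4), 0.5, 0.5)
  expect_true(all(w$w1 == 1))
  # stated scalar example: g1=2, g2=1, m1=0.6, m2=0.4 -> w1 = 1.2/1.6
  w <- assign_weights(matrix(2, 2, 2), matrix(1, 2, 2), 0.6, 0.4)
  expect_equal(w$w1[1, 1], 0.75, tolerance = 1e-12)
  # zero-edge pixels fall back to the metric-proportional split
  g1 <- matrix(0, 2, 2); g1[1, 1] <- 3
  w <- assign_weights(g1, matrix(0, 2, 2), 0.6, 0.2)
  expect_equal(w$w1[1, 1], 1)
  expect_equal(w$w1[2, 2], 0.75)
  expect_error(assign_weights(g, g, 0, 0), "positive")
})

test_that("weights always sum to one pixel-wise", {
  withr::local_seed(12)
  for (i in 1:20) {
    g1 <- matrix(abs(rnorm(36)), 6, 6) * rbinom(36, 1, 0.7)
    g2 <- matrix(abs(rnorm(36)), 6, 6) * rbinom(36, 1, 0.7)
    m <- runif(2)
    w <- assign_weights(g1, g2, m[1], m[2])
    expect_lt(max(abs(w$w1 + w$w2 - 1)), 1e-9)
    expect_true(all(w$w1 >= 0 & w$w1 <= 1))
  }
})

test_that("blending is idempotent, selective and convex", {
  withr::local_seed(13)
  a <- random_uint8(6); b <- random_uint8(6)
  g <- matrix(runif(36), 6, 6)
  w <- list(w1 = g, w2 = 1 - g)
  expect_identical(unclass(blend_images(a, a, w)), unclass(a))
  sel <- list(w1 = matrix(1, 6, 6), w2 = matrix(0, 6, 6))
  expect_identical(unclass(blend_images(a, b, sel)), unclass(a))
  # stated half-weight example: all pixels land on 128
  x1 <- gray_image(matrix(c(0, 255, 255, 0), 2, 2), "uint8")
  x2 <- gray_image(matrix(c(255, 0, 0, 255), 2, 2), "uint8")
  half <- list(w1 = matrix(0.5, 2, 2), w2 = matrix(0.5, 2, 2))
  expect_true(all(unclass(blend_images(x1, x2, half)) == 128))
  # convexity: output bounded by the two inputs pixel-wise
  out <- blend_images(a, b, w)
  expect_true(all(unclass(out) >= pmin(unclass(a), unclass(b))))
  expect_true(all(unclass(out) <= pmax(unclass(a), unclass(b))))
})

test_that("aggregation is deterministic, idempotent and reference-seeking", {
  withr::local_seed(14)
  ref <- make_phantom(phantom_spec(size = 16, seed = 1))
  same <- candidate_set(list(ref, ref, ref), c(1, 1, 1), "ssim")
  expect_identical(unclass(aggregate_candidates(same)), unclass(ref))
  # a candidate equal to the reference always wins selection under SSIM
  others <- make_phantom_dataset(2, phantom_spec(size = 16), 0.15, seed = 2)
  imgs <- list(others[[1]], ref, others[[2]])
  sc <- vapply(imgs, compute_ssim, numeric(1), y = ref)
  expect_identical(select_top_two_scores(sc)[1], 2L)
  cs <- candidate_set(imgs, sc, "ssim")
  out1 <- aggregate_candidates(cs, sigma = 1)
  out2 <- aggregate_candidates(cs, sigma = 1)
  expect_identical(unclass(out1), unclass(out2))   # bit-identical reruns
})

test_that("swapping the two selected images leaves the blend unchanged", {
  withr::local_seed(15)
  i1 <- random_uint8(8); i2 <- random_uint8(8)
  g1 <- gaussian_edge_value(sobel_edge_map(i1), 1)
  g2 <- gaussian_edge_value(sobel_edge_map(i2), 1)
  w12 <- assign_weights(g1, g2, 0.7, 0.3)
  w21 <- assign_weights(g2, g1, 0.3, 0.7)
  a <- blend_images(i1, i2, w12)
  b <- blend_images(i2, i1, w21)
  expect_identical(unclass(a), unclass(b))
})

test_that("full aggregation agrees bit-exactly with the naive reference", {
  withr::local_seed(16)
  ref <- random_uint8(8)
  for (metric in c("ssim", "psnr")) {
    for (i in 1:5) {
      imgs <- list(random_uint8(8), random_uint8(8), random_uint8(8))
      sc <- if (metric == "ssim") {
        vapply(imgs, compute_ssim, numeric(1), y = ref)
      } else {
        vapply(imgs, compute_psnr, numeric(1), y = ref)
      }
      got <- aggregate_candidates(candidate_set(imgs, sc, metric), sigma = 1)
      want <- oracle_aggregate(imgs, sc, metric, sigma = 1)
      expect_identical(unclass(got), unclass(want))
    }
  }
})

test_that("PSNR-infinite candidates are handled by rank transformation", {
  withr::local_seed(17)
  ref <- random_uint8(8)
  imgs <- list(ref, random_uint8(8), random_uint8(8))
  sc <- vapply(imgs, compute_psnr, numeric(1), y = ref)
  expect_identical(sc[1], Inf)
  out <- aggregate_candidates(candidate_set(imgs, sc, "psnr"))
  expect_s3_class(out, "gray_image")   # finite weights despite the sentinel
})
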