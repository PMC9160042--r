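test_that("Gram matrices match their definition and are symmetric PSD", {
  expect_identical(gram_matrix(matrix(0, 3, 5)), matrix(0, 3, 3))
  expect_identical(gram_matrix(diag(2)), diag(2))   # orthonormal rows
  withr::local_seed(41)
  f <- matrix(rnorm(15), 3, 5)
  expect_equal(gram_matrix(f), f %*% t(f), tolerance = 1e-12)
  for (i in 1:10) {
    g <- gram_matrix(matrix(rnorm(8 * 20), 8, 20))
    expect_equal(g, t(g), tolerance = 1e-12)
    expect_gte(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("content loss is half the squared distance, quadratic in scale", {
  f <- c(1, 2); p <- c(0, 0)
  expect_equal(content_loss(f, p), 2.5)
  expect_identical(content_loss(f, f), 0)
  expect_equal(content_loss(2 * f, 2 * p), 4 * content_loss(f, p))
  expect_error(content_loss(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("style loss follows the weighted Gram-mismatch formula", {
  # one layer, A = B = 1, G = 2, H = 0, w = 1 -> (1/4) * 4 = 1
  expect_equal(
    style_loss(list(l = matrix(2)), list(l = matrix(0)),
               list(l = c(1, 1)), w_l = 1),
    1
  )
  withr::local_seed(42)
  f <- matrix(rnorm(12), 3, 4)
  g <- list(a = gram_matrix(f))
  expect_identical(style_loss(g, g, list(a = c(3, 4))), 0)
  # spatial permutation invariance of the Gram summary
  fp <- f[, sample(ncol(f))]
  expect_equal(gram_matrix(fp), gram_matrix(f), tolerance = 1e-12)
})

test_that("total-variation loss counts squared neighbour jumps", {
  expect_identical(tv_loss(matrix(5, 6, 6)), 0)
  expect_identical(tv_loss(matrix(c(0, 1), 1, 2)), 1)
  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(tv_loss(checker), 4)
})

test_that("total loss is the weighted sum with the reference coefficients", {
  cfg <- style_config()
  expect_equal(total_loss(list(content = 1, style = 1, tv = 1), cfg), 105.001)
  expect_identical(total_loss(list(content = 0, style = 0, tv = 0), cfg), 0)
  # linear in each part with its coefficient
  base <- total_loss(list(content = 1, style = 2, tv = 3), cfg)
  expect_equal(total_loss(list(content = 2, style = 2, tv = 3), cfg) - base,
               cfg$w_cont)
  expect_equal(total_loss(list(content = 1, style = 3, tv = 3), cfg) - base,
               cfg$w_sty)
  expect_equal(total_loss(list(content = 1, style = 2, tv = 4), cfg) - base,
               cfg$w_tv)
})

test_that("the extractor yields the six contracted feature stacks", {
  ex <- feature_extractor(seed = 5)
  img <- make_phantom(phantom_spec(size = 64, seed = 6))
  layers <- c("1_1", "2_1", "3_1", "4_1", "5_1", "4_2")
  feats <- extract_features(ex, img, layers)
  expect_identical(sort(names(feats)), sort(layers))
  # block b sees the image after b-1 poolings
  expect_identical(ncol(feats[["1_1"]]), 64L * 64L)
  expect_identical(ncol(feats[["5_1"]]), 4L * 4L)
  expect_identical(nrow(feats[["4_2"]]), ex$channels[4])
  expect_error(extract_features(ex, img, "9_9"), "unknown")
})

test_that("style-transfer pixel gradients match finite differences", {
  ex <- feature_extractor(seed = 7)
  cfg <- style_config(iterations = 1)
  sty <- make_phantom(phantom_spec(size = 32, seed = 8))
  cont <- make_phantom(phantom_spec(size = 32, seed = 9))
  grams <- lapply(
    aggrgan:::extractor_forward(ex, unclass(convert_image(sty, "unit")),
                                cfg$style_layers)$features,
    gram_matrix
  )
  cfeat <- aggrgan:::extractor_forward(
    ex, unclass(convert_image(cont, "unit")), cfg$content_layer
  )$features[[cfg$content_layer]]
  layers <- unique(c(cfg$style_layers, cfg$content_layer))
  withr::local_seed(43)
  x <- matrix(runif(32 * 32), 32, 32)
  ev <- aggrgan:::st_loss_and_grad(x, ex, layers, grams, cfeat, cfg)
  h <- 1e-6
  for (idx in c(1L, 257L, 700L, 1024L)) {
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    num <- (aggrgan:::st_loss_and_grad(xp, ex, layers, grams, cfeat, cfg)$value -
            aggrgan:::st_loss_and_grad(xm, ex, layers, grams, cfeat, cfg)$value) /
      (2 * h)
    expect_equal(ev$grad[idx], num, tolerance = 1e-5)
  }
})

test_that("zero iterations is the identity and self-style starts at zero", {
  ex <- feature_extractor(seed = 10)
  cont <- make_phantom(phantom_spec(size = 32, seed = 11))
  sty <- make_phantom(phantom_spec(size = 32, seed = 12))
  st0 <- run_style_transfer(cont, sty, ex, style_config(iterations = 0))
  expect_identical(unclass(st0$image), unclass(cont))
  stc <- run_style_transfer(cont, cont, ex,
                            style_config(w_tv = 0, iterations = 5))
  expect_identical(stc$initial_loss, 0)
  expect_identical(unclass(stc$image), unclass(cont))
})

test_that("the optimizer descends on phantom content/style pairs", {
  ex <- feature_extractor(seed = 13)
  cfg <- style_config(iterations = 25)
  for (seed in 1:3) {
    cont <- make_phantom(phantom_spec(size = 32, seed = 100 + seed))
    sty <- make_phantom(phantom_spec(size = 32, seed = 200 + seed))
    st <- run_style_transfer(cont, sty, ex, cfg)
    expect_lte(st$final_loss, st$initial_loss)
    expect_lt(st$final_loss, st$initial_loss)  # strict on these fixtures
    expect_true(all(unclass(st$image) >= 0 & unclass(st$image) <= 255))
    g <- glance(st)
    expect_true(all(c(g$content, g$style, g$tv) >= 0))
  }
})
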