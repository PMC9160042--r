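test_that("generators honour shape, range and determinism contracts", {
  for (v in c("dcgan1", "dcgan2", "wgan_div")) {
    gen <- build_generator(gan_spec(v, image_size = 32), seed = 5)
    z <- matrix(rnorm(100 * 4), 100, 4)
    out <- generate(gen, z)
    expect_identical(dim(out), c(1L, 32L, 32L, 4L))
    expect_true(all(out >= -1 & out <= 1))
    gen2 <- build_generator(gan_spec(v, image_size = 32), seed = 5)
    expect_identical(generate(gen2, z), out)   # same seed, same map
  }
})

test_that("the two DCGAN variants differ in parameter count and upsampling", {
  g1 <- build_generator(gan_spec("dcgan1"), seed = 1)
  g2 <- build_generator(gan_spec("dcgan2"), seed = 1)
  expect_false(n_parameters(g1) == n_parameters(g2))
  types1 <- vapply(g1$net, `[[`, "", "type")
  types2 <- vapply(g2$net, `[[`, "", "type")
  expect_true("upsample2" %in% types1 && !"tconv" %in% types1)
  expect_true("tconv" %in% types2 && !"upsample2" %in% types2)
  # the WGAN generator is fully connected
  gw <- build_generator(gan_spec("wgan_div"), seed = 1)
  expect_false(any(vapply(gw$net, `[[`, "", "type") %in%
                     c("conv", "tconv", "upsample2")))
})

test_that("discriminators are sigmoid-bounded, the critic unbounded", {
  withr::local_seed(21)
  x <- array(runif(32 * 32 * 4, -1, 1), c(1, 32, 32, 4))
  d <- build_discriminator(gan_spec("dcgan1"), seed = 2)
  s <- discriminate(d, x)
  expect_length(s, 4)
  expect_true(all(s > 0 & s < 1))
  cr <- build_discriminator(gan_spec("wgan_div"), seed = 2)
  # scale an input up: a linear read-out can leave (0, 1)
  f <- discriminate(cr, x * 1e4)
  expect_true(any(f < 0 | f > 1))
})

test_that("vanilla GAN losses match their closed forms", {
  at_half <- vanilla_gan_loss(rep(0.5, 4), rep(0.5, 4))
  expect_equal(at_half$d_loss, 2 * log(2), tolerance = 1e-12)
  near_perfect <- vanilla_gan_loss(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_lt(near_perfect$d_loss, 1e-6)
  hand <- vanilla_gan_loss(c(0.9, 0.8), 0.1)
  expect_equal(hand$d_loss, -mean(log(c(0.9, 0.8))) - log(0.9),
               tolerance = 1e-12)
  expect_equal(hand$g_loss, -log(0.1), tolerance = 1e-12)
  expect_equal(hand$g_loss_minimax, log(0.9), tolerance = 1e-12)
})

test_that("the Wasserstein-divergence objective matches scalar arithmetic", {
  expect_equal(wgan_div_loss(c(1, 1), c(0, 0), c(1, 1), k = 2, p = 6), 3)
  expect_equal(wgan_div_loss(c(0.3, 0.7), c(0.3, 0.7), c(0, 0)), 0)
  withr::local_seed(22)
  for (i in 1:20) {
    fr <- rnorm(8); ff <- rnorm(8); gn <- abs(rnorm(8))
    k <- runif(1, 0.5, 5); p <- runif(1, 1, 8)
    expect_equal(wgan_div_loss(fr, ff, gn, k, p),
                 mean(fr) - mean(ff) + k * mean(gn^p), tolerance = 1e-9)
  }
  # monotone in every gradient norm
  base <- wgan_div_loss(c(0, 0), c(0, 0), c(1, 1), k = 2, p = 6)
  expect_gt(wgan_div_loss(c(0, 0), c(0, 0), c(1.5, 1), k = 2, p = 6), base)
  expect_error(wgan_div_loss(1, 1, 1, k = -1), "positive")
})

test_that("the critic's analytic input gradient matches finite differences", {
  # the gradient-penalty backprop rests on this per-sample input gradient
  withr::local_seed(23)
  spec <- gan_spec("wgan_div", image_size = 16)
  d <- build_discriminator(spec, seed = 3)
  x <- array(runif(16 * 16 * 2, -1, 1), c(1, 16, 16, 2))
  fw <- aggrgan:::nn_forward(d$net, x, training = FALSE)
  g <- aggrgan:::nn_backward(d$net, fw$caches, matrix(1, 1, 2))$dx
  h <- 1e-6
  for (probe in list(c(1, 3, 5, 1), c(1, 10, 2, 2))) {
    xp <- x; xp[probe[1], probe[2], probe[3], probe[4]] <-
      xp[probe[1], probe[2], probe[3], probe[4]] + h
    xm <- x; xm[probe[1], probe[2], probe[3], probe[4]] <-
      xm[probe[1], probe[2], probe[3], probe[4]] - h
    num <- (discriminate(d, xp)[probe[4]] - discriminate(d, xm)[probe[4]]) /
      (2 * h)
    expect_equal(g[probe[1], probe[2], probe[3], probe[4]], num,
                 tolerance = 1e-4)
  }
})

test_that("gradient-penalty parameter gradients match finite differences", {
  withr::local_seed(24)
  spec <- gan_spec("wgan_div", image_size = 16)
  d <- build_discriminator(spec, seed = 4)
  x <- array(runif(16 * 16 * 3, -1, 1), c(1, 16, 16, 3))
  k <- 2; p <- 6
  pen_value <- function(net) {
    fw <- aggrgan:::nn_forward(net, x, training = FALSE)
    aggrgan:::wgan_penalty(net, fw$caches, k, p)$value
  }
  fw <- aggrgan:::nn_forward(d$net, x, training = FALSE)
  pen <- aggrgan:::wgan_penalty(d$net, fw$caches, k, p)
  h <- 1e-6
  for (li in c(2L, 4L, 6L)) {
    for (probe in c(1L, 5L)) {
      net_p <- d$net; net_p[[li]]$params$W[probe] <-
        net_p[[li]]$params$W[probe] + h
      net_m <- d$net; net_m[[li]]$params$W[probe] <-
        net_m[[li]]$params$W[probe] - h
      num <- (pen_value(net_p) - pen_value(net_m)) / (2 * h)
      expect_equal(pen$grads[[li]]$W[probe], num, tolerance = 1e-3)
    }
  }
})

test_that("training is deterministic, finite and bookkeeps its log", {
  data <- make_phantom_dataset(16, phantom_spec(size = 32), 0.1, seed = 30)
  cfg <- train_config("wgan_div", epochs = 3, batch_size = 8, seed = 31)
  fit1 <- train_gan(gan_spec("wgan_div"), cfg, data)
  fit2 <- train_gan(gan_spec("wgan_div"), cfg, data)
  expect_identical(fit1$log, fit2$log)
  expect_identical(nrow(fit1$log), 3L * 2L)   # epochs x ceil(16/8) batches
  expect_true(all(is.finite(fit1$log$g_loss)))
  expect_true(all(is.finite(fit1$log$d_loss)))
  expect_identical(tidy(fit1), fit1$log)
  expect_identical(glance(fit1)$steps, 6L)
})

test_that("zero-epoch training returns an untrained generator and empty log", {
  data <- make_phantom_dataset(4, phantom_spec(size = 32), 0.1, seed = 32)
  fit <- train_gan(gan_spec("dcgan2"),
                   train_config("dcgan2", epochs = 0, seed = 33), data)
  expect_identical(nrow(fit$log), 0L)
  fresh <- build_generator(gan_spec("dcgan2"), seed = 33)
  z <- matrix(rnorm(100 * 2), 100, 2)
  expect_identical(generate(fit$generator, z), generate(fresh, z))
  expect_error(train_gan(gan_spec("dcgan2"),
                         train_config("dcgan2", epochs = 1), list()),
               "nonempty")
})

test_that("sampled images satisfy the image contract and depend on the seed", {
  gen <- build_generator(gan_spec("dcgan2"), seed = 40)
  s1 <- sample_images(gen, 3, seed = 7)
  s2 <- sample_images(gen, 3, seed = 7)
  expect_identical(lapply(s1, unclass), lapply(s2, unclass))
  expect_true(all(vapply(s1, function(im) {
    image_domain(im) == "uint8" && all(unclass(im) >= 0 & unclass(im) <= 255)
  }, logical(1))))
  s3 <- sample_images(gen, 3, seed = 8)
  expect_false(identical(lapply(s1, unclass), lapply(s3, unclass)))
})
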