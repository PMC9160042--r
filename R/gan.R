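#' Architecture specification for a base generator/discriminator pair
#'
#' Three variants are supported, differing mainly in how the generator
#' upsamples the latent vector:
#'
#' * `"dcgan1"` — convolutional generator that grows the map with nearest-
#'   neighbour upsampling followed by 4x4 convolutions (the deeper of the two
#'   DCGAN variants); convolutional discriminator with strided 4x4 filters,
#'   LeakyReLU, per-layer dropout and a sigmoid read-out.
#' * `"dcgan2"` — same family but the generator upsamples with strided 4x4
#'   transposed convolutions; same discriminator.
#' * `"wgan_div"` — fully connected generator and critic; the critic has no
#'   terminal squashing and is trained with the Wasserstein-divergence
#'   objective (gradient-norm penalty at interpolated points).
#'
#' @param variant `"dcgan1"`, `"dcgan2"` or `"wgan_div"`.
#' @param latent_dim latent (noise) dimension; 100 by DCGAN convention.
#' @param image_size square image side; must be a power of 2, at least 16.
#' @param filter_size convolution filter side (4 throughout).
#' @param leaky_slope LeakyReLU negative slope.
#' @param dropout discriminator dropout rate (DCGAN variants).
#' @param nf base channel width of the convolutional networks.
#' @return A `gan_spec` list.
#' @export
gan_spec <- function(variant = c("dcgan1", "dcgan2", "wgan_div"),
                     latent_dim = 100L, image_size = 32L, filter_size = 4L,
                     leaky_slope = 0.2, dropout = 0.25, nf = 16L) {
  variant <- match.arg(variant)
  image_size <- as.integer(image_size)
  if (image_size < 16L || bitwAnd(image_size, image_size - 1L) != 0L) {
    stop("`image_size` must be a power of 2 and >= 16", call. = FALSE)
  }
  structure(list(
    variant = variant, latent_dim = as.integer(latent_dim),
    image_size = image_size, filter_size = as.integer(filter_size),
    leaky_slope = leaky_slope, dropout = dropout, nf = as.integer(nf)
  ), class = "gan_spec")
}

#' Training hyperparameters for one GAN variant
#'
#' The `"full"` profile carries the full-scale settings (batch 64 / lr 2e-4 /
#' 1000 epochs for dcgan1; batch 128 / lr 2e-4 / 650 epochs for dcgan2; batch
#' 32 / lr 1e-3 / 1000 epochs for wgan_div). The `"desk"` profile keeps each
#' variant's batch size and learning rate but caps epochs at 50 so the suite
#' trains in seconds on one CPU; it is the default for tests and the pipeline.
#'
#' @param variant which GAN variant the config is for.
#' @param profile `"desk"` (default) or `"full"`.
#' @param epochs,batch_size,learning_rate optional overrides.
#' @param k,p Wasserstein-divergence penalty coefficient and exponent
#'   (`wgan_div` only); the conventional k = 2, p = 6.
#' @param seed RNG seed controlling initialization, batching, latent draws
#'   and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(variant = c("dcgan1", "dcgan2", "wgan_div"),
                         profile = c("desk", "full"),
                         epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, k = 2, p = 6, seed = 42L) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  base <- switch(variant,
    dcgan1   = list(batch_size = 64L,  learning_rate = 2e-4, epochs = 1000L),
    dcgan2   = list(batch_size = 128L, learning_rate = 2e-4, epochs = 650L),
    wgan_div = list(batch_size = 32L,  learning_rate = 1e-3, epochs = 1000L)
  )
  if (profile == "desk") {
    base$epochs <- 50L
    base$batch_size <- min(base$batch_size, 32L)
  }
  if (!is.null(epochs)) base$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) base$batch_size <- as.integer(batch_size)
  if (!is.null(learning_rate)) base$learning_rate <- learning_rate
  stopifnot(base$epochs >= 0, base$batch_size >= 1, base$learning_rate > 0,
            k > 0, p > 0)
  structure(list(
    variant = variant, profile = profile, batch_size = base$batch_size,
    learning_rate = base$learning_rate, epochs = base$epochs,
    optimizer = "adam", k = k, p = p, seed = as.integer(seed)
  ), class = "train_config")
}

# --- network builders --------------------------------------------------------

# generator network layers for a spec; draws weights from the current RNG
generator_net <- function(spec) {
  s <- spec$image_size; nf <- spec$nf; k <- spec$filter_size
  al <- spec$leaky_slope
  switch(spec$variant,
    dcgan1 = {
      n_up <- as.integer(log2(s / 4))
      ch <- c(nf * 2^(n_up - 1), nf * 2^(seq.int(n_up - 2, 0)), 1L)
      net <- list(
        layer_dense(spec$latent_dim, ch[1] * 16L),
        layer_reshape(c(ch[1], 4L, 4L)),
        layer_batchnorm(ch[1]), layer_lrelu(al)
      )
      for (i in seq_len(n_up)) {
        net <- c(net, list(layer_upsample2(),
                           layer_conv(ch[i], ch[i + 1], k = k, stride = 1L,
                                      pad = 2L),
                           layer_crop_br(1L)))
        if (i < n_up) {
          net <- c(net, list(layer_batchnorm(ch[i + 1]), layer_lrelu(al)))
        }
      }
      c(net, list(layer_tanh()))
    },
    dcgan2 = {
      n_up <- as.integer(log2(s / 8))
      ch <- c(nf * 2^(seq.int(n_up - 1, 0, by = -1)), 1L)
      net <- list(
        layer_dense(spec$latent_dim, ch[1] * 64L),
        layer_reshape(c(ch[1], 8L, 8L)),
        layer_batchnorm(ch[1]), layer_lrelu(al)
      )
      for (i in seq_len(n_up)) {
        net <- c(net, list(layer_tconv(ch[i], ch[i + 1], k = k, stride = 2L,
                                       pad = 1L)))
        if (i < n_up) {
          net <- c(net, list(layer_batchnorm(ch[i + 1]), layer_lrelu(al)))
        }
      }
      c(net, list(layer_tanh()))
    },
    wgan_div = list(
      layer_dense(spec$latent_dim, 128L), layer_lrelu(al),
      layer_dense(128L, 256L), layer_lrelu(al),
      layer_dense(256L, s * s), layer_tanh(),
      layer_reshape(c(1L, s, s))
    )
  )
}

discriminator_net <- function(spec) {
  s <- spec$image_size; nf <- spec$nf; k <- spec$filter_size
  al <- spec$leaky_slope
  if (spec$variant == "wgan_div") {
    # fully connected critic, unbounded output; its fixed 3-dense topology is
    # what the analytic gradient-penalty backprop assumes
    return(list(
      layer_flatten(),
      layer_dense(s * s, 256L), layer_lrelu(al),
      layer_dense(256L, 128L), layer_lrelu(al),
      layer_dense(128L, 1L)
    ))
  }
  list(
    layer_conv(1L, nf, k = k, stride = 2L, pad = 1L), layer_lrelu(al),
    layer_dropout(spec$dropout),
    layer_conv(nf, 2L * nf, k = k, stride = 2L, pad = 1L), layer_lrelu(al),
    layer_dropout(spec$dropout),
    layer_flatten(),
    layer_dense(2L * nf * (s %/% 4L)^2, 1L),
    layer_sigmoid()
  )
}

#' Build an (untrained) generator
#'
#' Constructs the generator network for a spec with seeded random weights.
#' The returned object maps standard-normal latent vectors to signed-domain
#' images; use [generate()] for raw batches or [sample_images()] for uint8
#' images.
#'
#' @param spec a [gan_spec()].
#' @param seed integer seed for the weight initialization.
#' @return A `gan_generator` object.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gan_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  structure(list(net = generator_net(spec), spec = spec),
            class = "gan_generator")
}

#' Build an (untrained) discriminator / critic
#'
#' For the DCGAN variants the output is a sigmoid probability in (0, 1); for
#' `wgan_div` it is an unbounded critic score.
#'
#' @inheritParams build_generator
#' @return A `gan_discriminator` object.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gan_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  structure(list(net = discriminator_net(spec), spec = spec),
            class = "gan_discriminator")
}

#' Map latent vectors through a generator
#'
#' @param generator a `gan_generator`.
#' @param z latent matrix, `latent_dim x n` (one column per image).
#' @return An array of signed-domain images, dim `(1, size, size, n)`, all
#'   values in \[-1, 1\].
#' @export
generate <- function(generator, z) {
  stopifnot(inherits(generator, "gan_generator"), is.matrix(z),
            nrow(z) == generator$spec$latent_dim)
  nn_forward(generator$net, z, training = FALSE)$out
}

#' Score an image batch with a discriminator / critic
#'
#' @param discriminator a `gan_discriminator`.
#' @param x image batch, array of dim `(1, size, size, n)` in the signed
#'   domain.
#' @return A numeric vector of n scores.
#' @export
discriminate <- function(discriminator, x) {
  stopifnot(inherits(discriminator, "gan_discriminator"))
  as.numeric(nn_forward(discriminator$net, x, training = FALSE)$out)
}

#' Number of trainable parameters
#' @param x a `gan_generator` or `gan_discriminator`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  stopifnot(inherits(x, c("gan_generator", "gan_discriminator")))
  nn_n_params(x$net)
}

# --- losses ------------------------------------------------------------------

#' Vanilla (minimax) GAN losses
#'
#' For discriminator probabilities on real and fake batches:
#' `d_loss = -mean(log d_real) - mean(log(1 - d_fake))`. The generator loss is
#' the non-saturating form `-mean(log d_fake)` (the generator maximizes the
#' probability of the discriminator being fooled); the pure minimax generator
#' term `mean(log(1 - d_fake))` is returned alongside for completeness.
#' Values at exactly 0 or 1 are clamped by `eps` before the logarithm. At the
#' uninformative point D = 0.5 everywhere, `d_loss = 2 log 2`.
#'
#' @param d_real,d_fake discriminator outputs in (0, 1).
#' @param eps clamping constant.
#' @return A list with `g_loss`, `d_loss` and `g_loss_minimax`.
#' @export
vanilla_gan_loss <- function(d_real, d_fake, eps = 1e-7) {
  stopifnot(all(d_real >= 0 & d_real <= 1), all(d_fake >= 0 & d_fake <= 1))
  dr <- pmin(pmax(d_real, eps), 1 - eps)
  df <- pmin(pmax(d_fake, eps), 1 - eps)
  list(
    g_loss = -mean(log(df)),
    d_loss = -mean(log(dr)) - mean(log(1 - df)),
    g_loss_minimax = mean(log(1 - df))
  )
}

#' Wasserstein-divergence critic objective
#'
#' `mean(f_real) - mean(f_fake) + k * mean(grad_norms^p)`, where `grad_norms`
#' are the norms of the critic's input gradients at points interpolated
#' between real and fake samples.
#'
#' @param f_real,f_fake critic scores on real and fake batches.
#' @param grad_norms critic input-gradient norms at interpolated points.
#' @param k penalty coefficient, `> 0`.
#' @param p penalty exponent, `> 0`.
#' @return The scalar objective value.
#' @export
wgan_div_loss <- function(f_real, f_fake, grad_norms, k = 2, p = 6) {
  if (k <= 0 || p <= 0) stop("`k` and `p` must be positive", call. = FALSE)
  stopifnot(all(grad_norms >= 0))
  mean(f_real) - mean(f_fake) + k * mean(grad_norms^p)
}

# --- training ----------------------------------------------------------------

#' Train a base GAN on a set of grayscale images
#'
#' Alternating optimization: one discriminator/critic step then one generator
#' step per batch, Adam throughout (beta1 = 0.5). DCGAN variants use the
#' non-saturating vanilla losses; `wgan_div` trains the critic on
#' `mean(f_fake) - mean(f_real) + k mean(||grad||^p)` with the gradient
#' penalty evaluated at per-pair uniform convex combinations of real and fake
#' samples, and the generator on `-mean(f_fake)`. Fully deterministic given
#' `config$seed`.
#'
#' @param spec a [gan_spec()].
#' @param config a [train_config()] for the same variant.
#' @param dataset nonempty list of [gray_image]s, each `image_size` square
#'   (any domain; converted to signed internally).
#' @return A `gan_fit` with elements `generator` (a `gan_generator`),
#'   `discriminator`, `log` (tibble of per-step losses), `spec`, `config`.
#' @examples
#' \donttest{
#' data <- make_phantom_dataset(16, phantom_spec(size = 32), 0.1, seed = 1)
#' fit <- train_gan(gan_spec("wgan_div"), train_config("wgan_div", epochs = 2),
#'                  data)
#' }
#' @export
train_gan <- function(spec, config, dataset) {
  stopifnot(inherits(spec, "gan_spec"), inherits(config, "train_config"))
  if (config$variant != spec$variant) {
    stop("`spec` and `config` are for different variants", call. = FALSE)
  }
  if (length(dataset) == 0) stop("`dataset` must be nonempty", call. = FALSE)
  s <- spec$image_size
  X <- dataset_to_array(dataset, s)
  n <- dim(X)[4]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  g_net <- generator_net(spec)
  d_net <- discriminator_net(spec)
  g_state <- adam_init(g_net)
  d_state <- adam_init(d_net)
  lr <- config$learning_rate
  bs <- config$batch_size
  n_batches <- ceiling(n / bs)
  log_rows <- vector("list", config$epochs * n_batches)
  t_g <- 0L; t_d <- 0L; row <- 0L

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    for (b in seq_len(n_batches)) {
      take <- idx[((b - 1L) * bs + 1L):min(b * bs, n)]
      x_real <- X[, , , take, drop = FALSE]
      m <- length(take)

      if (spec$variant == "wgan_div") {
        step <- wgan_step(g_net, d_net, x_real, spec, config, lr,
                          g_state, d_state, t_g, t_d)
      } else {
        step <- dcgan_step(g_net, d_net, x_real, spec, config, lr,
                           g_state, d_state, t_g, t_d)
      }
      g_net <- step$g_net; d_net <- step$d_net
      g_state <- step$g_state; d_state <- step$d_state
      t_g <- step$t_g; t_d <- step$t_d
      if (!is.finite(step$g_loss) || !is.finite(step$d_loss)) {
        stop(sprintf(
          "training diverged at epoch %d batch %d (g_loss=%g, d_loss=%g)",
          epoch, b, step$g_loss, step$d_loss
        ), call. = FALSE)
      }
      row <- row + 1L
      gl <- step$g_loss; dl <- step$d_loss
      log_rows[[row]] <- tibble::tibble(
        step = row, epoch = epoch, batch = b, g_loss = gl, d_loss = dl
      )
    }
  }

  log <- if (row > 0) dplyr::bind_rows(log_rows[seq_len(row)]) else
    tibble::tibble(step = integer(), epoch = integer(), batch = integer(),
                   g_loss = numeric(), d_loss = numeric())
  structure(list(
    generator = structure(list(net = g_net, spec = spec),
                          class = "gan_generator"),
    discriminator = structure(list(net = d_net, spec = spec),
                              class = "gan_discriminator"),
    log = log, spec = spec, config = config
  ), class = "gan_fit")
}

dataset_to_array <- function(dataset, s) {
  X <- array(0, c(1L, s, s, length(dataset)))
  for (i in seq_along(dataset)) {
    img <- convert_image(dataset[[i]], "signed")
    if (nrow(img) != s || ncol(img) != s) {
      stop(sprintf("dataset image %d is %d x %d, expected %d x %d",
                   i, nrow(img), ncol(img), s, s), call. = FALSE)
    }
    X[1L, , , i] <- unclass(img)
  }
  X
}

# one adversarial step for the DCGAN variants (vanilla losses)
dcgan_step <- function(g_net, d_net, x_real, spec, config, lr,
                       g_state, d_state, t_g, t_d) {
  m <- dim(x_real)[4]
  eps <- 1e-7

  # --- discriminator update
  z <- matrix(stats::rnorm(spec$latent_dim * m), spec$latent_dim, m)
  gf <- nn_forward(g_net, z, training = TRUE)
  g_net <- gf$net
  x_fake <- gf$out

  fr <- nn_forward(d_net, x_real, training = TRUE)
  d_net <- fr$net
  s_real <- pmin(pmax(as.numeric(fr$out), eps), 1 - eps)
  ff <- nn_forward(d_net, x_fake, training = TRUE)
  d_net <- ff$net
  s_fake <- pmin(pmax(as.numeric(ff$out), eps), 1 - eps)

  losses <- vanilla_gan_loss(s_real, s_fake, eps)

  d_real_grad <- matrix(-1 / (m * s_real), 1L, m)
  d_fake_grad <- matrix(1 / (m * (1 - s_fake)), 1L, m)
  bw_r <- nn_backward(d_net, fr$caches, d_real_grad)
  bw_f <- nn_backward(d_net, ff$caches, d_fake_grad)
  d_grads <- nn_add_grads(bw_r$grads, bw_f$grads)
  t_d <- t_d + 1L
  upd <- adam_step(d_net, d_grads, d_state, lr, t_d)
  d_net <- upd$net; d_state <- upd$state

  # --- generator update (non-saturating loss through the updated D)
  z2 <- matrix(stats::rnorm(spec$latent_dim * m), spec$latent_dim, m)
  gf2 <- nn_forward(g_net, z2, training = TRUE)
  g_net <- gf2$net
  df2 <- nn_forward(d_net, gf2$out, training = TRUE)
  s2 <- pmin(pmax(as.numeric(df2$out), eps), 1 - eps)
  g_out_grad <- matrix(-1 / (m * s2), 1L, m)
  bw_d <- nn_backward(df2$net, df2$caches, g_out_grad)
  bw_g <- nn_backward(g_net, gf2$caches, bw_d$dx)
  t_g <- t_g + 1L
  upd <- adam_step(g_net, bw_g$grads, g_state, lr, t_g)
  g_net <- upd$net; g_state <- upd$state

  g_loss <- -mean(log(s2))
  list(g_net = g_net, d_net = d_net, g_state = g_state, d_state = d_state,
       t_g = t_g, t_d = t_d, g_loss = g_loss, d_loss = losses$d_loss)
}

# one adversarial step for the Wasserstein-divergence variant
wgan_step <- function(g_net, d_net, x_real, spec, config, lr,
                      g_state, d_state, t_g, t_d) {
  m <- dim(x_real)[4]
  k <- config$k; p <- config$p

  # --- critic update
  z <- matrix(stats::rnorm(spec$latent_dim * m), spec$latent_dim, m)
  gf <- nn_forward(g_net, z, training = TRUE)
  g_net <- gf$net
  x_fake <- gf$out

  fr <- nn_forward(d_net, x_real, training = FALSE)
  f_real <- as.numeric(fr$out)
  ff <- nn_forward(d_net, x_fake, training = FALSE)
  f_fake <- as.numeric(ff$out)

  # interpolates: one uniform convex combination per real/fake pair
  epsm <- stats::runif(m)
  x_hat <- x_real
  for (i in seq_len(m)) {
    x_hat[, , , i] <- epsm[i] * x_real[, , , i] + (1 - epsm[i]) * x_fake[, , , i]
  }
  fh <- nn_forward(d_net, x_hat, training = FALSE)
  pen <- wgan_penalty(d_net, fh$caches, k, p)

  # critic minimizes mean(f_fake) - mean(f_real) + penalty
  bw_r <- nn_backward(d_net, fr$caches, matrix(-1 / m, 1L, m))
  bw_f <- nn_backward(d_net, ff$caches, matrix(1 / m, 1L, m))
  d_grads <- nn_add_grads(nn_add_grads(bw_r$grads, bw_f$grads), pen$grads)
  t_d <- t_d + 1L
  upd <- adam_step(d_net, d_grads, d_state, lr, t_d)
  d_net <- upd$net; d_state <- upd$state
  d_loss <- mean(f_fake) - mean(f_real) + pen$value

  # --- generator update: minimize -mean(f_fake)
  z2 <- matrix(stats::rnorm(spec$latent_dim * m), spec$latent_dim, m)
  gf2 <- nn_forward(g_net, z2, training = TRUE)
  g_net <- gf2$net
  ff2 <- nn_forward(d_net, gf2$out, training = FALSE)
  bw_d <- nn_backward(d_net, ff2$caches, matrix(-1 / m, 1L, m))
  bw_g <- nn_backward(g_net, gf2$caches, bw_d$dx)
  t_g <- t_g + 1L
  upd <- adam_step(g_net, bw_g$grads, g_state, lr, t_g)
  g_net <- upd$net; g_state <- upd$state
  g_loss <- -mean(as.numeric(ff2$out))

  list(g_net = g_net, d_net = d_net, g_state = g_state, d_state = d_state,
       t_g = t_g, t_d = t_d, g_loss = g_loss, d_loss = d_loss)
}

# Gradient penalty k * mean(||grad_x f(x_hat)||^p) for the fully connected
# critic, with analytic gradients w.r.t. the critic's dense weights. The
# LeakyReLU masks are treated as locally constant (exact almost everywhere).
# Critic topology: flatten, dense, lrelu, dense, lrelu, dense.
wgan_penalty <- function(d_net, caches, k, p) {
  types <- vapply(d_net, `[[`, "", "type")
  stopifnot(identical(types,
    c("flatten", "dense", "lrelu", "dense", "lrelu", "dense")))
  W1 <- d_net[[2]]$params$W   # h1 x d
  W2 <- d_net[[4]]$params$W   # h2 x h1
  W3 <- d_net[[6]]$params$W   # 1 x h2
  m1 <- caches[[3]]$mask      # h1 x B
  m2 <- caches[[5]]$mask      # h2 x B
  B <- ncol(m1)

  u <- m2 * as.numeric(W3)          # h2 x B
  v <- crossprod(W2, u)             # h1 x B
  tt <- m1 * v                      # h1 x B
  g <- crossprod(W1, tt)            # d x B, per-sample input gradients
  norms2 <- colSums(g * g)
  value <- k * mean(norms2^(p / 2))

  coef <- (k / B) * p * ifelse(norms2 > 0, norms2^(p / 2 - 1), 0)
  r <- t(t(g) * coef)               # d x B
  dW1 <- tt %*% t(r)                # h1 x d
  q <- W1 %*% r                     # h1 x B
  sv <- m1 * q                      # h1 x B
  dW2 <- u %*% t(sv)                # h2 x h1
  dW3 <- matrix(rowSums(m2 * (W2 %*% sv)), 1L)

  grads <- vector("list", length(d_net))
  grads[[2]] <- list(W = dW1, b = numeric(nrow(W1)))
  grads[[4]] <- list(W = dW2, b = numeric(nrow(W2)))
  grads[[6]] <- list(W = dW3, b = 0)
  list(value = value, grads = grads, norms = sqrt(norms2))
}

#' Sample uint8 images from a generator
#'
#' Draws `n` standard-normal latent vectors with the given seed, maps them
#' through the generator in inference mode (batch-norm running statistics)
#' and converts each signed-domain output to a uint8 [gray_image].
#'
#' @param generator a `gan_generator` (possibly from [train_gan()]).
#' @param n number of images.
#' @param seed latent-draw seed.
#' @return A list of `n` uint8 [gray_image]s.
#' @export
sample_images <- function(generator, n, seed = 1L) {
  stopifnot(inherits(generator, "gan_generator"), n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(generator$spec$latent_dim * n),
              generator$spec$latent_dim, n)
  out <- generate(generator, z)
  lapply(seq_len(n), function(i) {
    convert_image(gray_image(out[1L, , , i], "signed"), "uint8")
  })
}

# --- broom-style accessors ---------------------------------------------------

#' @export
print.gan_fit <- function(x, ...) {
  cat(sprintf(
    "<gan_fit> %s, %d epochs, %d training steps; final g_loss %.4f, d_loss %.4f\n",
    x$spec$variant, x$config$epochs, nrow(x$log),
    if (nrow(x$log)) x$log$g_loss[nrow(x$log)] else NA_real_,
    if (nrow(x$log)) x$log$d_loss[nrow(x$log)] else NA_real_
  ))
  invisible(x)
}

#' Tidy the training log of a GAN fit
#' @param x a `gan_fit`.
#' @param ... unused.
#' @return The per-step loss tibble (`step`, `epoch`, `batch`, `g_loss`,
#'   `d_loss`).
#' @export
tidy.gan_fit <- function(x, ...) x$log

#' One-row summary of a GAN fit
#' @param x a `gan_fit`.
#' @param ... unused.
#' @return A one-row tibble: variant, epochs, steps, final/mean losses,
#'   generator parameter count.
#' @export
glance.gan_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    epochs = x$config$epochs,
    steps = nrow(x$log),
    final_g_loss = if (nrow(x$log)) x$log$g_loss[nrow(x$log)] else NA_real_,
    final_d_loss = if (nrow(x$log)) x$log$d_loss[nrow(x$log)] else NA_real_,
    mean_g_loss = if (nrow(x$log)) mean(x$log$g_loss) else NA_real_,
    mean_d_loss = if (nrow(x$log)) mean(x$log$d_loss) else NA_real_,
    n_params_generator = n_parameters(x$generator)
  )
}

#' Loss-curve plot for a GAN fit
#' @param object a `gan_fit`.
#' @param ... unused.
#' @return A ggplot object with generator and discriminator loss traces.
#' @export
autoplot.gan_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("g_loss", "d_loss"),
                            names_to = "network", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("%s training losses", object$spec$variant),
      x = "training step", y = "loss", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
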