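#' Gram matrix of a layer's feature stack
#'
#' For a feature stack `F` with `A` filters (rows) and `B` spatial positions
#' (columns), the Gram matrix is \eqn{G_{i_1 i_2} = \sum_k F_{i_1 k} F_{i_2 k}}
#' — the matrix of inner products between vectorized filter maps. It is
#' symmetric positive semidefinite and invariant to spatial permutation, which
#' is what makes it a style (rather than content) summary.
#'
#' @param features numeric matrix, filters x positions.
#' @return An `A x A` symmetric PSD matrix.
#' @export
gram_matrix <- function(features) {
  stopifnot(is.matrix(features))
  tcrossprod(features)
}

#' Content loss between two feature stacks
#'
#' Half the squared Euclidean distance \eqn{\frac{1}{2}\sum (F - P)^2} between
#' the content image's features `F` and the generated image's features `P` at
#' the content layer.
#'
#' @param f,p numeric arrays/matrices of identical shape.
#' @return Nonnegative scalar; 0 iff `f == p`.
#' @export
content_loss <- function(f, p) {
  if (!identical(dim(f), dim(p)) || length(f) != length(p)) {
    stop("content feature shapes differ", call. = FALSE)
  }
  0.5 * sum((f - p)^2)
}

#' Multi-layer style loss between Gram matrices
#'
#' \deqn{L_{sty} = \sum_l w_l \frac{1}{4 A_l^2 B_l^2}
#'       \sum_{i_1,i_2} (G^l_{i_1 i_2} - H^l_{i_1 i_2})^2}
#' where `G` are the style image's Gram matrices, `H` the generated image's,
#' `A_l` the filter count and `B_l` the feature-map size of layer `l`.
#'
#' @param style_grams,gen_grams named lists of Gram matrices over the same
#'   layer set.
#' @param dims named list of `c(A, B)` per layer.
#' @param w_l per-layer weights (default uniform, summing to 1).
#' @return Nonnegative scalar; 0 iff all Gram pairs are equal.
#' @export
style_loss <- function(style_grams, gen_grams, dims,
                       w_l = rep(1 / length(style_grams),
                                 length(style_grams))) {
  if (!identical(sort(names(style_grams)), sort(names(gen_grams)))) {
    stop("style and generated Gram layer sets differ", call. = FALSE)
  }
  total <- 0
  for (i in seq_along(style_grams)) {
    nm <- names(style_grams)[i]
    A <- dims[[nm]][1]; B <- dims[[nm]][2]
    total <- total + w_l[i] / (4 * A^2 * B^2) *
      sum((style_grams[[nm]] - gen_grams[[nm]])^2)
  }
  total
}

#' Total-variation loss of an image
#'
#' Sum of squared horizontal and vertical neighbour differences; zero exactly
#' for constant images. Penalizing it smooths the synthesized image.
#'
#' @param img numeric matrix (any intensity domain).
#' @return Nonnegative scalar.
#' @export
tv_loss <- function(img) {
  m <- unclass(img)
  h <- if (ncol(m) > 1) sum((m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])^2) else 0
  v <- if (nrow(m) > 1) sum((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2) else 0
  h + v
}

#' Style-transfer configuration
#'
#' Defaults follow the reference settings: content/style/total-variation
#' weights 5 / 100 / 0.001, uniform per-layer style weights 1/5, style layers
#' `1_1 ... 5_1` (first convolution of each block), content layer `4_2`, and
#' an L-BFGS budget of 2000 iterations. Tests and the desk pipeline use far
#' fewer iterations; the loss decreases monotonically regardless of budget.
#'
#' @param w_cont,w_sty,w_tv loss weights.
#' @param style_layers,content_layer feature-extractor layer names.
#' @param iterations L-BFGS outer-iteration budget.
#' @return A `style_config` list.
#' @export
style_config <- function(w_cont = 5, w_sty = 100, w_tv = 0.001,
                         style_layers = c("1_1", "2_1", "3_1", "4_1", "5_1"),
                         content_layer = "4_2", iterations = 2000L) {
  stopifnot(w_cont >= 0, w_sty >= 0, w_tv >= 0, iterations >= 0)
  structure(list(
    w_cont = w_cont, w_sty = w_sty, w_tv = w_tv,
    style_layers = style_layers, content_layer = content_layer,
    w_l = rep(1 / length(style_layers), length(style_layers)),
    iterations = as.integer(iterations), optimizer = "lbfgs"
  ), class = "style_config")
}

#' Weighted total style-transfer loss
#'
#' `w_cont * content + w_sty * style + w_tv * tv`. At the reference weights
#' (5, 100, 0.001), unit part losses give 105.001.
#'
#' @param parts numeric vector or list with elements `content`, `style`, `tv`
#'   (all nonnegative).
#' @param config a [style_config()].
#' @return The weighted sum.
#' @export
total_loss <- function(parts, config = style_config()) {
  parts <- as.list(parts)
  stopifnot(parts$content >= 0, parts$style >= 0, parts$tv >= 0)
  config$w_cont * parts$content + config$w_sty * parts$style +
    config$w_tv * parts$tv
}

# --- feature extractor -------------------------------------------------------

#' Multi-layer convolutional feature extractor
#'
#' A five-block convolutional stack patterned after the VGG-19 layer layout
#' used for style transfer: each block holds two 3x3 convolutions (named
#' `"<block>_1"`, `"<block>_2"`) followed by ReLU, with 2x2 average pooling
#' between blocks. Features are taken post-activation. The weights are
#' seeded random draws (He-scaled), which keeps the extractor deterministic
#' and dependency-free; a pretrained network can be substituted by anything
#' honouring the same layer-name contract.
#'
#' @param channels per-block channel widths.
#' @param seed weight-initialization seed.
#' @return A `feature_extractor` object.
#' @export
feature_extractor <- function(channels = c(4L, 8L, 12L, 16L, 16L),
                              seed = 1L) {
  stopifnot(length(channels) == 5L, all(channels >= 1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  ops <- list()
  names_out <- character()
  c_in <- 1L
  for (blk in 1:5) {
    for (lay in 1:2) {
      fan_in <- c_in * 9L
      ops <- c(ops, list(layer_conv(c_in, channels[blk], k = 3L, stride = 1L,
                                    pad = 1L, w_sd = sqrt(2 / fan_in))),
               list(layer_relu()))
      names_out <- c(names_out, "", sprintf("%d_%d", blk, lay))
      c_in <- channels[blk]
    }
    if (blk < 5) {
      ops <- c(ops, list(layer_avgpool2()))
      names_out <- c(names_out, "")
    }
  }
  structure(list(ops = ops, tap_names = names_out, channels = channels,
                 seed = as.integer(seed)),
            class = "feature_extractor")
}

# forward pass collecting post-activation feature stacks at the named taps;
# x is a unit-domain matrix. Returns features (filters x positions matrices)
# and, if keep_caches, everything needed for backprop.
extractor_forward <- function(extractor, x, layers, keep_caches = FALSE) {
  a <- array(unclass(x), c(1L, nrow(x), ncol(x), 1L))
  feats <- list()
  dims <- list()
  caches <- if (keep_caches) vector("list", length(extractor$ops)) else NULL
  for (i in seq_along(extractor$ops)) {
    step <- layer_forward(extractor$ops[[i]], a, training = FALSE)
    a <- step$out
    if (keep_caches) caches[[i]] <- step$cache
    nm <- extractor$tap_names[i]
    if (nzchar(nm) && nm %in% layers) {
      d <- dim(a)
      f <- a; dim(f) <- c(d[1], d[2] * d[3])
      feats[[nm]] <- f
      dims[[nm]] <- c(d[1], d[2] * d[3])
    }
  }
  list(features = feats, dims = dims, caches = caches)
}

#' Extract named feature stacks from an image
#'
#' @param extractor a [feature_extractor()].
#' @param img a [gray_image] (converted to the unit domain internally).
#' @param layers character vector of layer names, e.g. `c("1_1", "4_2")`.
#' @return A named list of filters-x-positions feature matrices.
#' @export
extract_features <- function(extractor, img, layers) {
  stopifnot(inherits(extractor, "feature_extractor"))
  u <- convert_image(img, "unit")
  missing <- setdiff(layers, extractor$tap_names)
  if (length(missing)) {
    stop("unknown extractor layers: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extractor_forward(extractor, unclass(u), layers)$features
}

# --- the optimization --------------------------------------------------------

#' Refine an image by multi-layer style transfer
#'
#' Starting from the content image (so a zero-iteration budget is the
#' identity), minimizes
#' `w_cont * L_content + w_sty * L_style + w_tv * L_tv` over the pixels with
#' box-constrained L-BFGS in the unit domain. The style targets are the
#' Gram matrices of the style image at the five style layers; the content
#' target is the content image's feature stack at the content layer.
#' Gradients are exact backpropagation through the extractor. The returned
#' final loss never exceeds the initial loss.
#'
#' @param content the content image (the aggregated/generated image).
#' @param style the style image (a raw reference image), same shape.
#' @param extractor a [feature_extractor()] accepting the image size (five
#'   pooling stages need side >= 16; side 64 is comfortable).
#' @param config a [style_config()].
#' @return A `style_transfer` object: `image` (uint8 [gray_image]),
#'   `initial_loss`, `final_loss`, `parts` (final loss components),
#'   `iterations`, `config`.
#' @examples
#' \donttest{
#' cont <- make_phantom(phantom_spec(seed = 1))
#' sty <- make_phantom(phantom_spec(seed = 2))
#' st <- run_style_transfer(cont, sty, feature_extractor(),
#'                          style_config(iterations = 10))
#' }
#' @export
run_style_transfer <- function(content, style, extractor = feature_extractor(),
                               config = style_config()) {
  assert_image(content, arg = "content"); assert_image(style, arg = "style")
  assert_same_shape(content, style)
  stopifnot(inherits(extractor, "feature_extractor"),
            inherits(config, "style_config"))
  if (nrow(content) != ncol(content) || nrow(content) %% 16L != 0L) {
    stop("images must be square with side a multiple of 16 (5-block extractor)",
         call. = FALSE)
  }
  layers_all <- unique(c(config$style_layers, config$content_layer))

  style_u <- unclass(convert_image(style, "unit"))
  content_u <- unclass(convert_image(content, "unit"))
  sf <- extractor_forward(extractor, style_u, config$style_layers)
  style_grams <- lapply(sf$features, gram_matrix)
  cf <- extractor_forward(extractor, content_u, config$content_layer)
  content_feat <- cf$features[[config$content_layer]]

  objective <- function(par) {
    x <- matrix(par, nrow(content), ncol(content))
    st_loss_and_grad(x, extractor, layers_all, style_grams, content_feat,
                     config)
  }

  init <- as.vector(content_u)
  ev0 <- objective(init)

  if (config$iterations == 0L) {
    out_img <- convert_image(gray_image(content_u, "unit"), "uint8")
    return(structure(list(
      image = out_img, initial_loss = ev0$value, final_loss = ev0$value,
      parts = ev0$parts, iterations = 0L, config = config
    ), class = "style_transfer"))
  }

  opt <- stats::optim(
    par = init,
    fn = function(par) objective(par)$value,
    gr = function(par) objective(par)$grad,
    method = "L-BFGS-B", lower = 0, upper = 1,
    control = list(maxit = config$iterations)
  )
  if (!is.finite(opt$value)) {
    stop("style transfer produced a non-finite loss", call. = FALSE)
  }
  evf <- objective(opt$par)
  final <- matrix(pmin(pmax(opt$par, 0), 1), nrow(content), ncol(content))
  structure(list(
    image = convert_image(gray_image(final, "unit"), "uint8"),
    initial_loss = ev0$value, final_loss = opt$value, parts = evf$parts,
    iterations = config$iterations, config = config
  ), class = "style_transfer")
}

# total loss and its exact pixel gradient for the current iterate x (unit
# domain matrix)
st_loss_and_grad <- function(x, extractor, layers_all, style_grams,
                             content_feat, config) {
  fw <- extractor_forward(extractor, x, layers_all, keep_caches = TRUE)
  feats <- fw$features; dims <- fw$dims

  # loss parts
  gen_grams <- lapply(feats[config$style_layers], gram_matrix)
  l_sty <- style_loss(style_grams, gen_grams,
                      dims[config$style_layers], config$w_l)
  l_cont <- content_loss(content_feat, feats[[config$content_layer]])
  l_tv <- tv_loss(x)
  value <- config$w_cont * l_cont + config$w_sty * l_sty + config$w_tv * l_tv

  # per-tap feature gradients (of the *weighted* total loss)
  inject <- list()
  for (i in seq_along(config$style_layers)) {
    nm <- config$style_layers[i]
    A <- dims[[nm]][1]; B <- dims[[nm]][2]
    dH <- config$w_sty * config$w_l[i] / (2 * A^2 * B^2) *
      (gen_grams[[nm]] - style_grams[[nm]])
    inject[[nm]] <- 2 * dH %*% feats[[nm]]   # d/dF of sum over Gram entries
  }
  cl <- config$content_layer
  dcont <- config$w_cont * (feats[[cl]] - content_feat)
  inject[[cl]] <- (inject[[cl]] %||% 0) + dcont

  # backward through the extractor, injecting at each tap
  da <- NULL
  for (i in rev(seq_along(extractor$ops))) {
    nm <- extractor$tap_names[i]
    if (nzchar(nm) && !is.null(inject[[nm]])) {
      d <- dims[[nm]]
      add <- inject[[nm]]
      # feature matrices are (filters x positions); restore the array shape
      hw <- d[2]
      side <- as.integer(sqrt(hw))
      dim(add) <- c(d[1], side, side, 1L)
      da <- if (is.null(da)) add else da + add
    }
    if (!is.null(da)) {
      da <- layer_backward(extractor$ops[[i]], fw$caches[[i]], da)$dx
    }
  }
  grad <- matrix(da[1L, , , 1L], nrow(x), ncol(x))

  # total-variation gradient
  if (config$w_tv > 0) {
    gtv <- matrix(0, nrow(x), ncol(x))
    dh <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
    gtv[, -1] <- gtv[, -1] + 2 * dh
    gtv[, -ncol(x)] <- gtv[, -ncol(x)] - 2 * dh
    dv <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
    gtv[-1, ] <- gtv[-1, ] + 2 * dv
    gtv[-nrow(x), ] <- gtv[-nrow(x), ] - 2 * dv
    grad <- grad + config$w_tv * gtv
  }

  list(value = value, grad = as.vector(grad),
       parts = list(content = l_cont, style = l_sty, tv = l_tv))
}

#' @export
print.style_transfer <- function(x, ...) {
  cat(sprintf(
    "<style_transfer> %d iterations; loss %.6g -> %.6g\n",
    x$iterations, x$initial_loss, x$final_loss
  ))
  invisible(x)
}

#' One-row summary of a style-transfer run
#' @param x a `style_transfer` object.
#' @param ... unused.
#' @return A one-row tibble with initial/final losses and the final loss
#'   decomposition.
#' @export
glance.style_transfer <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    initial_loss = x$initial_loss,
    final_loss = x$final_loss,
    content = x$parts$content,
    style = x$parts$style,
    tv = x$parts$tv
  )
}
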