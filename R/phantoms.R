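#' Specification of a brain-like phantom image
#'
#' The phantom emulates the gross statistical structure of an axial
#' brain-tumor MRI slice: dark background, a mid-gray elliptical "head" with
#' smooth low-frequency tissue texture, and a bright circular "tumor" blob.
#' It provides edges, plateaus and a multimodal histogram — the features the
#' metrics, aggregation and style-transfer stages react to — without claiming
#' anatomical realism.
#'
#' @param size image side length in pixels (square image).
#' @param head_axes vertical/horizontal semi-axes of the head ellipse, as
#'   fractions of `size`.
#' @param tumor_center tumor centre `(row, col)` as fractions of `size`.
#' @param tumor_radius tumor radius as a fraction of `size`; 0 removes the
#'   tumor.
#' @param texture_scale standard deviation (intensity levels) of the smooth
#'   tissue texture; 0 gives a flat plateau.
#' @param noise_sd standard deviation (intensity levels) of additive Gaussian
#'   pixel noise, clipped to \[0, 255\].
#' @param seed integer seed making the phantom fully deterministic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 64L,
                         head_axes = c(0.42, 0.36),
                         tumor_center = c(0.42, 0.60),
                         tumor_radius = 0.11,
                         texture_scale = 10,
                         noise_sd = 4,
                         seed = 1L) {
  stopifnot(size >= 8, length(head_axes) == 2, length(tumor_center) == 2)
  if (any(head_axes <= 0 | head_axes >= 0.5)) {
    stop("`head_axes` fractions must lie in (0, 0.5)", call. = FALSE)
  }
  if (tumor_radius < 0) stop("`tumor_radius` must be >= 0", call. = FALSE)
  spec <- list(
    size = as.integer(size), head_axes = head_axes,
    tumor_center = tumor_center, tumor_radius = tumor_radius,
    texture_scale = texture_scale, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  # the tumor disc must sit fully inside the head ellipse:
  # scale tumor offsets by the ellipse axes and check the inflated radius
  dr <- (tumor_center[1] - 0.5) / head_axes[1]
  dc <- (tumor_center[2] - 0.5) / head_axes[2]
  margin <- tumor_radius / min(head_axes)
  if (tumor_radius > 0 && sqrt(dr^2 + dc^2) + margin > 1) {
    stop("tumor disc extends outside the head ellipse", call. = FALSE)
  }
  spec
}

# intensity plateaus of the piecewise-constant skeleton
PHANTOM_BG     <- 0
PHANTOM_TISSUE <- 120
PHANTOM_TUMOR  <- 230

#' Generate one phantom image
#'
#' Deterministic given the spec (including its seed). With
#' `texture_scale = 0` and `noise_sd = 0` the image has exactly three
#' intensity plateaus (background 0, tissue 120, tumor 230).
#'
#' @param spec a [phantom_spec()].
#' @return A uint8 [gray_image] of side `spec$size`.
#' @examples
#' img <- make_phantom(phantom_spec(size = 32, seed = 7))
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  rc <- (seq_len(n) - 0.5) / n   # pixel-centre coordinates in [0,1]
  rows <- matrix(rc, n, n)
  cols <- matrix(rc, n, n, byrow = TRUE)

  in_head <- ((rows - 0.5) / spec$head_axes[1])^2 +
             ((cols - 0.5) / spec$head_axes[2])^2 <= 1
  img <- matrix(PHANTOM_BG, n, n)
  img[in_head] <- PHANTOM_TISSUE

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  if (spec$texture_scale > 0) {
    # band-limited texture: white noise blurred at ~size/8, rescaled to the
    # requested sd, applied to tissue only
    tex <- matrix(stats::rnorm(n * n), n, n)
    tex <- gaussian_blur(tex, sigma = n / 8)
    s <- stats::sd(as.vector(tex))
    if (s > 0) tex <- tex / s * spec$texture_scale
    img[in_head] <- img[in_head] + tex[in_head]
  }

  if (spec$tumor_radius > 0) {
    in_tumor <- (rows - spec$tumor_center[1])^2 +
                (cols - spec$tumor_center[2])^2 <= spec$tumor_radius^2
    img[in_tumor] <- PHANTOM_TUMOR
  }

  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
  }
  gray_image(pmin(pmax(round(img), 0), 255), "uint8")
}

#' Generate a jittered phantom dataset
#'
#' Produces `n` phantoms whose tumor position, radius and texture/noise
#' realizations are jittered around a base spec. With `jitter = 0` all images
#' are bit-identical copies of `make_phantom(base)`.
#'
#' @param n number of images.
#' @param base the base [phantom_spec()].
#' @param jitter relative jitter amplitude (uniform in +/- `jitter`) applied
#'   to the tumor centre and radius.
#' @param seed dataset-level seed.
#' @return A list of `n` uint8 [gray_image]s.
#' @export
make_phantom_dataset <- function(n, base = phantom_spec(), jitter = 0.1,
                                 seed = 1L) {
  stopifnot(n >= 1, jitter >= 0)
  if (jitter == 0) {
    img <- make_phantom(base)
    return(rep(list(img), n))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- matrix(stats::runif(n * 3, -jitter, jitter), n, 3)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    sp <- base
    sp$tumor_center <- pmin(pmax(base$tumor_center * (1 + draws[i, 1:2]),
                                 0.05), 0.95)
    sp$tumor_radius <- max(base$tumor_radius * (1 + draws[i, 3]), 0)
    sp$seed <- seeds[i]
    # rebuild through the constructor so the inside-the-head invariant holds
    sp <- phantom_spec(
      size = sp$size, head_axes = sp$head_axes,
      tumor_center = sp$tumor_center, tumor_radius = sp$tumor_radius,
      texture_scale = sp$texture_scale, noise_sd = sp$noise_sd, seed = sp$seed
    )
    make_phantom(sp)
  })
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
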