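#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix (rows are image rows, row 1 at the
#' top; 0-based pixel coordinates in the docs map to R's 1-based indices) with
#' a `domain` attribute declaring the intensity convention:
#'
#' * `"uint8"` — integers in \[0, 255\]; the convention all quality metrics use
#'   (peak intensity 255).
#' * `"unit"`  — reals in \[0, 1\]; the style-transfer optimization domain.
#' * `"signed"` — reals in \[-1, 1\]; the GAN training domain (Tanh output).
#'
#' @param pixels numeric matrix, at least 2 x 2 (the sharpness-difference
#'   gradient needs both an upper and a left neighbour).
#' @param domain one of `"uint8"`, `"unit"`, `"signed"`.
#' @return A `gray_image` object.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), "uint8")
#' dim(img)
#' @export
gray_image <- function(pixels, domain = c("uint8", "unit", "signed")) {
  domain <- match.arg(domain)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("a gray_image must be at least 2 x 2", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all pixel values must be finite", call. = FALSE)
  }
  rng <- switch(domain,
    uint8  = c(0, 255),
    unit   = c(0, 1),
    signed = c(-1, 1)
  )
  if (min(pixels) < rng[1] - 1e-9 || max(pixels) > rng[2] + 1e-9) {
    stop(sprintf(
      "pixel values outside the declared '%s' domain [%g, %g]",
      domain, rng[1], rng[2]
    ), call. = FALSE)
  }
  if (domain == "uint8" && any(abs(pixels - round(pixels)) > 1e-9)) {
    stop("'uint8' images must hold integer intensity levels", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(pixels, domain = domain, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, domain '%s', range [%g, %g]\n",
    nrow(x), ncol(x), image_domain(x), min(x), max(x)
  ))
  invisible(x)
}

#' Intensity domain of an image
#' @param img a [gray_image].
#' @return `"uint8"`, `"unit"` or `"signed"`.
#' @export
image_domain <- function(img) {
  attr(img, "domain") %||% "uint8"
}

is_gray_image <- function(x) inherits(x, "gray_image")

assert_image <- function(img, domain = NULL, arg = "img") {
  if (!is_gray_image(img)) {
    stop(sprintf("`%s` must be a gray_image", arg), call. = FALSE)
  }
  if (!is.null(domain) && image_domain(img) != domain) {
    stop(sprintf(
      "`%s` must be in the '%s' domain (got '%s'); see convert_image()",
      arg, domain, image_domain(img)
    ), call. = FALSE)
  }
  invisible(img)
}

assert_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y))) {
    stop(sprintf(
      "image shapes differ: %d x %d vs %d x %d",
      nrow(x), ncol(x), nrow(y), ncol(y)
    ), call. = FALSE)
  }
  invisible(NULL)
}

#' Convert an image between intensity domains
#'
#' Affine re-mapping between the three pipeline conventions. Converting to the
#' current domain is the identity. uint8 endpoints map exactly: 0 -> -1 and
#' 255 -> +1 in the signed domain. A uint8 -> signed -> uint8 round trip
#' changes no pixel by more than one intensity level (rounding).
#'
#' @param img a [gray_image].
#' @param target destination domain tag.
#' @return A [gray_image] in the target domain.
#' @examples
#' u <- gray_image(matrix(c(0, 255, 128, 64), 2, 2), "uint8")
#' convert_image(u, "signed")
#' @export
convert_image <- function(img, target = c("uint8", "unit", "signed")) {
  target <- match.arg(target)
  assert_image(img)
  from <- image_domain(img)
  if (from == target) return(img)
  # go through unit [0,1]
  u <- switch(from,
    uint8  = unclass(img) / 255,
    unit   = unclass(img),
    signed = (unclass(img) + 1) / 2
  )
  out <- switch(target,
    uint8  = round(u * 255),
    unit   = u,
    signed = u * 2 - 1
  )
  out <- pmin(pmax(out, switch(target, uint8 = 0, unit = 0, signed = -1)),
              switch(target, uint8 = 255, unit = 1, signed = 1))
  attr(out, "domain") <- NULL
  gray_image(out, target)
}

#' Read a grayscale image from an 8-bit PNG
#'
#' Colour PNGs are collapsed to luminance (Rec. 601 weights); an alpha channel
#' is ignored. The result is always a uint8 image.
#'
#' @param path path to a PNG file.
#' @return A [gray_image] with domain `"uint8"`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  arr <- tryCatch(png::readPNG(path),
    error = function(e) {
      stop(sprintf("cannot decode '%s' as PNG: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(round(arr * 255), "uint8")
}

#' Write a grayscale image to an 8-bit PNG
#'
#' Round trips losslessly with [load_image()] for uint8 images.
#'
#' @param img a [gray_image]; converted to uint8 first if needed.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- convert_image(img, "uint8")
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' Extract 2-D slices from a NIfTI volume
#'
#' Reads a NIfTI-1 volume (requires the RNifti package), takes the requested
#' slices along one axis and min-max rescales each slice independently to
#' uint8. A constant-valued slice (min == max) maps to all zeros.
#'
#' @param volume_path path to a `.nii` / `.nii.gz` file.
#' @param axis axis to slice along (1, 2 or 3).
#' @param indices 1-based slice indices along `axis`.
#' @return A list of uint8 [gray_image]s, one per index.
#' @export
extract_slices <- function(volume_path, axis = 3L, indices) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI support requires the 'RNifti' package", call. = FALSE)
  }
  vol <- tryCatch(as.array(RNifti::readNifti(volume_path)),
    error = function(e) {
      stop(sprintf("cannot read '%s' as a NIfTI volume: %s",
                   volume_path, conditionMessage(e)), call. = FALSE)
    })
  if (length(dim(vol)) != 3L) {
    stop("expected a 3-D volume", call. = FALSE)
  }
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3", call. = FALSE)
  depth <- dim(vol)[axis]
  if (any(indices < 1L | indices > depth)) {
    stop(sprintf("slice index out of bounds (axis %d has depth %d)",
                 axis, depth), call. = FALSE)
  }
  lapply(indices, function(i) {
    sl <- switch(axis, vol[i, , ], vol[, i, ], vol[, , i])
    rescale_to_uint8(sl)
  })
}

# min-max rescale any numeric matrix to a uint8 gray_image;
# constant input maps to all zeros by convention
rescale_to_uint8 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi > lo) m <- (m - lo) / (hi - lo) else m <- m * 0
  gray_image(round(m * 255), "uint8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
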