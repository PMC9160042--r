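#' Configuration of a full synthesis-and-evaluation run
#'
#' Describes one end-to-end experiment: train the three base GANs on a
#' phantom (or user-supplied) dataset, sample images from each, fuse the best
#' two per reference with the edge-priority aggregation under both SSIM and
#' PSNR selection, refine every generated image by style transfer against its
#' reference, and score all eight method variants with the four-metric suite.
#'
#' @param dataset either `NULL` (a jittered phantom dataset is generated) or
#'   a list of uint8 [gray_image]s, all `image_size` square.
#' @param image_size square image side (power of 2, >= 16).
#' @param n_train training-set size when phantoms are generated.
#' @param epochs training epochs for every variant (desk profile).
#' @param n_generated generated images per method.
#' @param sigma Gaussian bandwidth of the aggregation edge smoothing.
#' @param style style-transfer settings; a [style_config()].
#' @param extractor feature extractor for style transfer.
#' @param seed global seed; every stage derives its randomness from it.
#' @return A `run_config` list.
#' @export
run_config <- function(dataset = NULL, image_size = 32L, n_train = 64L,
                       epochs = 15L, n_generated = 4L, sigma = 1,
                       style = style_config(iterations = 40L),
                       extractor = feature_extractor(), seed = 1L) {
  stopifnot(n_generated >= 1, n_train >= 1, sigma > 0,
            inherits(style, "style_config"),
            inherits(extractor, "feature_extractor"))
  structure(list(
    dataset = dataset, image_size = as.integer(image_size),
    n_train = as.integer(n_train), epochs = as.integer(epochs),
    n_generated = as.integer(n_generated), sigma = sigma,
    style = style, extractor = extractor, seed = as.integer(seed)
  ), class = "run_config")
}

METHOD_NAMES <- c("dcgan1", "dcgan2", "wgan_div",
                  "dcgan1+style", "dcgan2+style", "wgan_div+style",
                  "aggrgan_ssim", "aggrgan_psnr")

#' Run the full aggregation pipeline
#'
#' Orchestrates every stage and returns the eight-method evaluation table:
#' the three base GANs, each base GAN refined by style transfer, and the
#' aggregated image under SSIM- and PSNR-driven selection (both refined by
#' style transfer, as in the reference procedure). Each generated image is
#' scored against the raw reference image that served as its selection and
#' style target. Fully reproducible for a given `config$seed`.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return An `aggrgan_run` with `table` (8 methods x mean metrics, plus the
#'   per-method maxima of SSIM), `per_image` (per-image scores), `images`
#'   (named list of generated image lists), `fits` (the three `gan_fit`s) and
#'   `config`.
#' @examples
#' \donttest{
#' run <- run_aggrgan(run_config(epochs = 2, n_generated = 2,
#'                    style = style_config(iterations = 5)))
#' run$table
#' }
#' @export
run_aggrgan <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  s <- config$image_size

  # --- data
  dataset <- config$dataset
  if (is.null(dataset)) {
    dataset <- make_phantom_dataset(
      config$n_train, phantom_spec(size = s, seed = config$seed),
      jitter = 0.1, seed = config$seed
    )
  } else {
    lapply(dataset, assert_image, domain = "uint8")
  }

  # --- train the three base GANs
  variants <- c("dcgan1", "dcgan2", "wgan_div")
  fits <- list()
  for (i in seq_along(variants)) {
    v <- variants[i]
    say("training %s ...", v)
    fits[[v]] <- train_gan(
      gan_spec(v, image_size = s),
      train_config(v, profile = "desk", epochs = config$epochs,
                   seed = config$seed + i),
      dataset
    )
  }

  # --- generate, aggregate, stylize, evaluate
  refs <- dataset[((seq_len(config$n_generated) - 1L) %% length(dataset)) + 1L]
  images <- stats::setNames(
    lapply(METHOD_NAMES, function(m) vector("list", config$n_generated)),
    METHOD_NAMES
  )
  rows <- list()
  for (j in seq_len(config$n_generated)) {
    ref <- refs[[j]]
    base <- lapply(seq_along(variants), function(i) {
      sample_images(fits[[variants[i]]]$generator, 1L,
                    seed = config$seed * 1000L + j * 10L + i)[[1]]
    })
    ssim_scores <- vapply(base, compute_ssim, numeric(1), y = ref)
    psnr_scores <- vapply(base, compute_psnr, numeric(1), y = ref)
    agg_ssim <- aggregate_candidates(
      candidate_set(base, ssim_scores, "ssim"), sigma = config$sigma)
    agg_psnr <- aggregate_candidates(
      candidate_set(base, psnr_scores, "psnr"), sigma = config$sigma)

    say("stylizing image set %d/%d ...", j, config$n_generated)
    stylize <- function(img) {
      run_style_transfer(img, ref, config$extractor, config$style)$image
    }
    out <- c(
      base,
      lapply(base, stylize),
      list(stylize(agg_ssim), stylize(agg_psnr))
    )
    for (m in seq_along(METHOD_NAMES)) {
      images[[m]][[j]] <- out[[m]]
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(method = METHOD_NAMES[m], image = j),
        evaluate_image(out[[m]], ref)
      )
    }
  }
  per_image <- dplyr::bind_rows(rows)

  table <- per_image |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      ssim = mean(.data$ssim), psnr = mean(.data$psnr),
      kl = mean(.data$kl), sd = mean(.data$sd),
      max_ssim = max(.data$ssim), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$method, METHOD_NAMES))

  structure(list(table = table, per_image = per_image, images = images,
                 fits = fits, config = config),
            class = "aggrgan_run")
}

#' @export
print.aggrgan_run <- function(x, ...) {
  cat(sprintf("<aggrgan_run> %d methods x %d generated images\n",
              nrow(x$table), x$config$n_generated))
  print(x$table)
  invisible(x)
}

#' Write an evaluation table to CSV
#'
#' Fixed column order `method, ssim, psnr, kl, sd`; infinite sentinels are
#' serialized as the string `"inf"`. [read_report()] round-trips the values.
#'
#' @param table the `table` tibble of an [run_aggrgan()] result (or any tibble
#'   with those columns).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  cols <- c("method", "ssim", "psnr", "kl", "sd")
  stopifnot(all(cols %in% names(table)))
  df <- as.data.frame(table)[, cols, drop = FALSE]
  for (cc in cols[-1]) {
    v <- df[[cc]]
    df[[cc]] <- ifelse(is.infinite(v), "inf",
                       trimws(formatC(v, digits = 15, format = "g")))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write report to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read an evaluation table written by [write_report()]
#' @param path CSV path.
#' @return A tibble with `"inf"` cells restored to `Inf`.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cc in setdiff(names(df), "method")) {
    df[[cc]] <- ifelse(df[[cc]] == "inf", Inf, as.numeric(df[[cc]]))
  }
  tibble::as_tibble(df)
}

# --- plotting ----------------------------------------------------------------

#' Plot a grayscale image
#' @param object a [gray_image].
#' @param ... unused.
#' @return A ggplot raster plot (row 1 at the top).
#' @export
autoplot.gray_image <- function(object, ...) {
  u <- convert_image(object, "unit")
  df <- tidyr::expand_grid(row = seq_len(nrow(u)), col = seq_len(ncol(u)))
  df$intensity <- as.vector(t(unclass(u)))  # expand_grid varies col fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Metric comparison plot for a pipeline run
#' @param object an `aggrgan_run`.
#' @param ... unused.
#' @return A ggplot faceted by metric; infinite sentinels are dropped with a
#'   note.
#' @export
autoplot.aggrgan_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_image, c("ssim", "psnr", "kl", "sd"),
                            names_to = "metric", values_to = "value")
  n_inf <- sum(is.infinite(df$value))
  if (n_inf > 0) {
    message(n_inf, " infinite sentinel value(s) omitted from the plot")
    df <- df[is.finite(df$value), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
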