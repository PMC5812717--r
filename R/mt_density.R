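#' Sum a fluorescence image stack
#'
#' Pixelwise sum of all frames (typically the 10 intra-myofibrillar planes
#' of a fiber) into one 2-D image. The accumulator is double precision, so
#' no saturation can occur whatever the input bit depth.
#'
#' @param stack An `image_stack` (see [generate_filament_image()]) or a
#'   3-D numeric array (rows x cols x frames).
#' @return 2-D numeric matrix of summed intensities.
#' @export
sum_stack <- function(stack) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (length(dim(frames)) != 3L || dim(frames)[3L] < 1L) {
    stop("stack must be a non-empty 3-D array.", call. = FALSE)
  }
  if (any(frames < 0)) stop("intensities must be non-negative.", call. = FALSE)
  rowSums(frames, dims = 2L)
}

#' Binarize a summed image and measure foreground density
#'
#' Thresholds the image (Otsu by default, or a fixed threshold) and reports
#' the fraction of above-threshold pixels — the microtubule density measure
#' used on summed fiber stacks.
#'
#' @param image 2-D numeric matrix (summed intensities).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"` (same scale as
#'   `image`).
#' @return A `density_result`: `density` in [0, 1], `threshold` used,
#'   `method`.
#' @export
binarize_and_density <- function(image, method = c("otsu", "fixed"),
                                 threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix.", call. = FALSE)
  }
  rng <- range(image)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      stop("constant image: Otsu thresholding is undefined; use method = \"fixed\".",
           call. = FALSE)
    }
    # Otsu operates on the image's own intensity range, making the density
    # invariant to positive rescaling of the intensities.
    scaled <- (image - rng[1L]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    threshold <- rng[1L] + th01 * diff(rng)
  } else if (is.null(threshold) || !is.numeric(threshold)) {
    stop("`threshold` is required for method = \"fixed\".", call. = FALSE)
  }
  structure(list(density = mean(image > threshold),
                 threshold = unname(threshold), method = method),
            class = "density_result")
}

#' Microtubule density of an image stack
#'
#' Convenience wrapper: sum the stack, then binarize and measure the
#' foreground pixel fraction.
#'
#' @inheritParams sum_stack
#' @inheritParams binarize_and_density
#' @return A `density_result`.
#' @export
mt_density <- function(stack, method = c("otsu", "fixed"), threshold = NULL) {
  binarize_and_density(sum_stack(stack), method = method, threshold = threshold)
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Density: %.4f of pixels above threshold %.4g (%s)\n",
              x$density, x$threshold, x$method))
  invisible(x)
}
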