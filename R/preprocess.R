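# Image rescaling and the three enhancement transforms compared by the
# pipeline: contrast normalization (quantile stretch), histogram
# equalization and histogram matching.

#' Rescale an RGB image
#'
#' Bilinear down/up-sampling. Native TMA cores are around 6000 x 6000
#' pixels; the pipeline default is a factor of 0.25, giving roughly
#' 1500 x 1500 and a large saving in compute at negligible cost to the
#' superpixel-level texture statistics.
#'
#' @param image `H x W x 3` array, intensities in `[0, 255]`.
#' @param factor Scale factor in `(0, 1]`; output dimensions are
#'   `max(1, round(dim * factor))`.
#' @return Rescaled integer image array.
#' @export
rescale <- function(image, factor) {
  check_rgb_image(image)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor > 1)
    stop("`factor` must be a single value in (0, 1]", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  nh <- max(1L, round_half_up(h * factor))
  nw <- max(1L, round_half_up(w * factor))
  if (nh == h && nw == w) return(image)
  out <- array(0L, c(nh, nw, 3L))
  for (ch in 1:3) {
    res <- EBImage::resize(EBImage::Image(t(image[, , ch] / 255)),
                           w = nw, h = nh, filter = "bilinear")
    out[, , ch] <- clamp255(round_half_up(t(as.matrix(res)) * 255))
  }
  as_int_image(out)
}

# Type-1 (inverse-ECDF) quantile of integer intensities: the smallest
# observed value v with F(v) >= p. Using this definition makes the
# contrast stretch exactly idempotent.
quantile_type1 <- function(x, p) {
  sx <- sort(x)
  sx[max(1L, ceiling(p * length(sx)))]
}

#' Contrast normalization by quantile stretch
#'
#' Linear stretch mapping the `(saturation, 1 - saturation)` intensity
#' quantiles to `(0, 255)`, clipping outside. This mirrors the classic
#' "enhance contrast with saturated pixels" normalization used in
#' interactive image-analysis toolchains.
#'
#' @param image `H x W x 3` array.
#' @param saturation Fraction of pixels saturated at each end,
#'   `0 <= saturation < 0.5`. Default 0.0035 (0.35%).
#' @param per_channel Stretch each channel independently (default) or use
#'   the pooled histogram of all three channels.
#' @return Normalized integer image.
#' @export
normalize_image <- function(image, saturation = 0.0035, per_channel = TRUE) {
  check_rgb_image(image)
  if (saturation < 0 || saturation >= 0.5)
    stop("`saturation` must be in [0, 0.5)", call. = FALSE)
  out <- image
  stretch <- function(v, lo, hi) {
    clamp255(round_half_up((v - lo) / (hi - lo) * 255))
  }
  if (per_channel) {
    for (ch in 1:3) {
      v <- as.vector(image[, , ch])
      lo <- quantile_type1(v, saturation)
      hi <- quantile_type1(v, 1 - saturation)
      if (lo == hi) {
        warning("channel ", c("R", "G", "B")[ch],
                " is constant; left unchanged", call. = FALSE)
        next
      }
      out[, , ch] <- stretch(image[, , ch], lo, hi)
    }
  } else {
    v <- as.vector(image)
    lo <- quantile_type1(v, saturation)
    hi <- quantile_type1(v, 1 - saturation)
    if (lo == hi) {
      warning("image is constant; left unchanged", call. = FALSE)
      return(image)
    }
    for (ch in 1:3) out[, , ch] <- stretch(image[, , ch], lo, hi)
  }
  as_int_image(out)
}

# Equalization mapping for one integer channel (256 bins):
# out(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * 255), cdf_min the
# smallest nonzero cumulative count. Returns a 256-entry lookup table.
equalize_lut <- function(v) {
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- cdf[256L]
  cdf_min <- cdf[match(TRUE, cdf > 0)]
  if (n == cdf_min) return(0:255)  # constant channel: identity
  clamp255(round_half_up((cdf - cdf_min) / (n - cdf_min) * 255))
}

#' Histogram equalization
#'
#' Per-channel 256-bin equalization spreading intensities over the full
#' 8-bit range so the cumulative histogram is approximately uniform.
#' Unlike normalization and matching, equalization acts on each image
#' independently of the rest of the data set.
#'
#' @param image `H x W x 3` array.
#' @param luminance_only If `TRUE`, derive one mapping from the rounded
#'   channel-mean luminance and apply it to all three channels (preserves
#'   hue better); default `FALSE` equalizes each channel independently.
#' @return Equalized integer image.
#' @export
equalize_histogram <- function(image, luminance_only = FALSE) {
  check_rgb_image(image)
  out <- image
  if (luminance_only) {
    lum <- round_half_up((image[, , 1] + image[, , 2] + image[, , 3]) / 3)
    lut <- equalize_lut(as.vector(lum))
    for (ch in 1:3) out[, , ch] <- matrix(lut[image[, , ch] + 1L],
                                          dim(image)[1], dim(image)[2])
  } else {
    for (ch in 1:3) {
      lut <- equalize_lut(as.vector(image[, , ch]))
      out[, , ch] <- matrix(lut[image[, , ch] + 1L],
                            dim(image)[1], dim(image)[2])
    }
  }
  as_int_image(out)
}

# Matching LUT for one channel: m(v) = G^{-1}(F(v)) with F, G empirical
# CDFs of source and reference and G^{-1}(t) the smallest intensity whose
# CDF reaches t.
match_lut <- function(src, ref) {
  f <- cumsum(tabulate(src + 1L, nbins = 256L)) / length(src)
  g <- cumsum(tabulate(ref + 1L, nbins = 256L)) / length(ref)
  vapply(0:255, function(v) {
    which(g >= f[v + 1L] - 1e-12)[1L] - 1L
  }, integer(1))
}

#' Histogram matching
#'
#' Monotone per-channel remapping of `source` so that its intensity CDF is
#' as close as possible (in sup distance, among monotone integer maps) to
#' that of `reference`.
#'
#' @param source `H x W x 3` array to be remapped.
#' @param reference `H x W x 3` array supplying the target histogram.
#' @return Matched integer image, same dimensions as `source`.
#' @export
match_histogram <- function(source, reference) {
  check_rgb_image(source, "source")
  check_rgb_image(reference, "reference")
  out <- source
  for (ch in 1:3) {
    lut <- match_lut(as.vector(source[, , ch]),
                     as.vector(reference[, , ch]))
    out[, , ch] <- matrix(lut[source[, , ch] + 1L],
                          dim(source)[1], dim(source)[2])
  }
  as_int_image(out)
}

#' Apply one of the enhancement transforms
#'
#' Dispatcher over the enhancement kinds compared by the pipeline.
#'
#' @param image `H x W x 3` array.
#' @param kind One of `"none"`, `"normalize"`, `"equalize"`, `"match"`.
#' @param reference Reference image, required when `kind = "match"`.
#' @param ... Passed on to the underlying transform
#'   ([normalize_image()] or [equalize_histogram()]).
#' @return Enhanced integer image.
#' @export
enhance <- function(image, kind = c("none", "normalize", "equalize", "match"),
                    reference = NULL, ...) {
  kind <- match.arg(kind)
  switch(kind,
         none = {
           check_rgb_image(image)
           image
         },
         normalize = normalize_image(image, ...),
         equalize = equalize_histogram(image, ...),
         match = {
           if (is.null(reference))
             stop("`reference` image is required for kind = \"match\"",
                  call. = FALSE)
           match_histogram(image, reference)
         })
}
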