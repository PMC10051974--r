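# Synthetic TMA generator: square images with a circular tissue disc on a
# light-gray background and irregular tumor blobs inside the disc, plus
# the exact paired label image. Every pipeline stage is testable on these
# without external data.

#' Parameters of the synthetic TMA generator
#'
#' Defaults emulate a digitized TMA core: a light-gray background
#' (`background_gray` with a small shared luminance noise, so background
#' stays achromatic), a circular tissue disc, smooth pinkish non-tumor
#' tissue and brown, strongly speckled tumor regions. The tumor/non-tumor
#' color and noise contrasts are chosen so that first-order statistics
#' alone separate the classes.
#'
#' @param size Image side length in pixels (default 512).
#' @param disc_radius_fraction Disc radius as a fraction of `size`
#'   (default 0.45).
#' @param n_tumor_blobs Number of tumor seed blobs (default 4); 0 disables
#'   tumor entirely.
#' @param tumor_fraction_target Target fraction of disc pixels that are
#'   tumor (default 0.35).
#' @param background_gray Background gray level (default 220).
#' @param background_noise_sd Shared-luminance background noise SD
#'   (default 3).
#' @param tumor_base_color RGB of tumor tissue (default `c(150, 100, 60)`).
#' @param tumor_noise_sd Per-pixel, per-channel tumor speckle SD
#'   (default 35).
#' @param nontumor_base_color RGB of non-tumor tissue
#'   (default `c(205, 165, 175)`).
#' @param nontumor_noise_sd Smooth non-tumor noise SD (default 8).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(size = 512L, disc_radius_fraction = 0.45,
                             n_tumor_blobs = 4L,
                             tumor_fraction_target = 0.35,
                             background_gray = 220,
                             background_noise_sd = 3,
                             tumor_base_color = c(150, 100, 60),
                             tumor_noise_sd = 35,
                             nontumor_base_color = c(205, 165, 175),
                             nontumor_noise_sd = 8,
                             seed = 1L) {
  stopifnot(size >= 32L, disc_radius_fraction > 0,
            disc_radius_fraction <= 0.5, n_tumor_blobs >= 0L,
            tumor_fraction_target > 0, tumor_fraction_target < 1,
            length(tumor_base_color) == 3L,
            length(nontumor_base_color) == 3L)
  structure(list(size = as.integer(size),
                 disc_radius_fraction = disc_radius_fraction,
                 n_tumor_blobs = as.integer(n_tumor_blobs),
                 tumor_fraction_target = tumor_fraction_target,
                 background_gray = background_gray,
                 background_noise_sd = background_noise_sd,
                 tumor_base_color = tumor_base_color,
                 tumor_noise_sd = tumor_noise_sd,
                 nontumor_base_color = nontumor_base_color,
                 nontumor_noise_sd = nontumor_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

# Gaussian-smoothed white noise rescaled to unit SD.
smooth_noise <- function(h, w, sigma) {
  n <- matrix(stats::rnorm(h * w), h, w)
  sm <- t(as.matrix(EBImage::gblur(EBImage::Image(t(n)), sigma = sigma)))
  sm / stats::sd(sm)
}

#' Generate one synthetic TMA image with its exact label image
#'
#' The tumor region is the super-level set of a smoothed random field
#' (plus Gaussian bumps at `n_tumor_blobs` random sites inside the disc),
#' thresholded at the in-disc quantile that yields the target tumor
#' fraction, so tumor boundaries are irregular and the achieved fraction
#' is within sampling ties of the target. Labels are exact by
#' construction.
#'
#' @param params [synthetic_params()] object.
#' @return List with `image` (`H x W x 3` integer array), `labels`
#'   (integer matrix over `{0, 2, 3}`) and `tumor_fraction` (achieved
#'   fraction of disc pixels labeled tumor).
#' @export
generate_tma <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  s <- params$size
  with_seed(params$seed, {
    ctr <- (s + 1) / 2
    rr <- matrix(seq_len(s), s, s) - ctr
    cc <- matrix(seq_len(s), s, s, byrow = TRUE) - ctr
    dist2 <- rr^2 + cc^2
    radius <- params$disc_radius_fraction * s
    disc <- dist2 <= radius^2

    tumor <- matrix(FALSE, s, s)
    if (params$n_tumor_blobs > 0L) {
      field <- smooth_noise(s, s, sigma = s / 12)
      for (b in seq_len(params$n_tumor_blobs)) {
        # seed site uniform within 80% of the disc radius
        a <- stats::runif(1, 0, 2 * pi)
        d <- sqrt(stats::runif(1)) * 0.8 * radius
        br <- ctr + d * sin(a); bc <- ctr + d * cos(a)
        bw <- stats::runif(1, 0.05, 0.12) * s
        field <- field + 1.5 * exp(-((rr + ctr - br)^2 +
                                     (cc + ctr - bc)^2) / (2 * bw^2))
      }
      thr <- stats::quantile(field[disc], 1 - params$tumor_fraction_target,
                             names = FALSE, type = 7)
      tumor <- disc & (field >= thr)
    }
    nontumor <- disc & !tumor

    labels <- matrix(0L, s, s)
    labels[tumor] <- 2L
    labels[nontumor] <- 3L

    img <- array(0, c(s, s, 3L))
    bg_noise <- matrix(stats::rnorm(s * s, sd = params$background_noise_sd),
                       s, s)  # shared across channels: background stays gray
    nt_noise <- lapply(1:3, function(ch)
      smooth_noise(s, s, sigma = s / 64) * params$nontumor_noise_sd)
    for (ch in 1:3) {
      plane <- params$background_gray + bg_noise
      plane[nontumor] <- params$nontumor_base_color[ch] +
        nt_noise[[ch]][nontumor]
      if (any(tumor))
        plane[tumor] <- params$tumor_base_color[ch] +
          stats::rnorm(sum(tumor), sd = params$tumor_noise_sd)
      img[, , ch] <- clamp255(round_half_up(plane))
    }
    list(image = as_int_image(img), labels = labels,
         tumor_fraction = if (any(disc)) sum(tumor) / sum(disc) else 0)
  })
}

#' Generate a synthetic TMA data set
#'
#' Generates `n_images` image/label pairs; image `i` uses seed
#' `base_seed + i - 1`, so the whole set is reproducible from `base_seed`.
#'
#' @param n_images Number of images (>= 1).
#' @param base_seed Seed of the first image.
#' @param params [synthetic_params()] template (its `seed` is overridden
#'   per image).
#' @param out_dir Optional directory; when given, each pair is written as
#'   `image_<i>.png` / `labels_<i>.png`.
#' @return Named list (`image_1`, ...) of [generate_tma()] results.
#' @export
generate_dataset <- function(n_images, base_seed = 42L,
                             params = synthetic_params(), out_dir = NULL) {
  stopifnot(n_images >= 1L)
  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    p <- params
    p$seed <- as.integer(base_seed + i - 1L)
    out[[i]] <- generate_tma(p)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_image(out[[i]]$image,
                  file.path(out_dir, sprintf("image_%02d.png", i)))
      write_label_image(out[[i]]$labels,
                        file.path(out_dir, sprintf("labels_%02d.png", i)))
    }
  }
  names(out) <- sprintf("image_%02d", seq_len(n_images))
  out
}
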