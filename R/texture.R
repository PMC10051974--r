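# Per-superpixel texture description: 17 first-order histogram statistics
# and 6 Tamura features, computed on each RGB channel, for a 69-value
# descriptor per superpixel.

FIRST_ORDER_NAMES <- c("mean", "variance", "sd", "skewness", "kurtosis",
                       "energy", "rms", "entropy", "min", "max", "median",
                       "range", "mad", "p25", "p75", "iqr", "cv")

TAMURA_NAMES <- c("coarseness", "contrast", "directionality",
                  "linelikeness", "regularity", "roughness")

#' The fixed 69-feature name registry
#'
#' Feature columns are named `<channel>_<feature>` for channel in
#' `R, G, B` and feature one of the 17 first-order statistics followed by
#' the 6 Tamura features. The order is frozen so feature tables are
#' comparable across runs and machines.
#'
#' @return Character vector of length 69.
#' @export
tma_feature_names <- function() {
  as.vector(vapply(c("R", "G", "B"), function(ch)
    paste(ch, c(FIRST_ORDER_NAMES, TAMURA_NAMES), sep = "_"),
    character(23L)))
}

#' Split an RGB image into channel rasters
#'
#' @param image `H x W x 3` array.
#' @return Named list of three `H x W` matrices (`R`, `G`, `B`).
#' @export
split_channels <- function(image) {
  check_rgb_image(image)
  list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
}

#' First-order (histogram) statistics of a pixel region
#'
#' Computes the 17 first-order texture statistics of an intensity multiset:
#' mean, population variance, standard deviation, skewness, excess
#' kurtosis, energy (mean squared intensity), root mean square, Shannon
#' entropy (base 2, 256 bins), minimum, maximum, median, range, mean
#' absolute deviation, 25th and 75th percentiles, interquartile range and
#' coefficient of variation. Skewness and kurtosis are 0 for constant
#' regions; the coefficient of variation is 0 when the mean is 0.
#'
#' @param pixels Numeric vector of intensities in `[0, 255]` (at least 1).
#' @return Named numeric vector of length 17.
#' @export
first_order_stats <- function(pixels) {
  if (!length(pixels)) stop("empty pixel region", call. = FALSE)
  x <- as.numeric(pixels)
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n            # population variance
  s <- sqrt(v)
  if (v > 0) {
    skew <- sum((x - mu)^3) / n / s^3
    kurt <- sum((x - mu)^4) / n / v^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  energy <- mean(x^2)
  counts <- tabulate(round(x) + 1L, nbins = 256L)
  p <- counts[counts > 0] / n
  entropy <- -sum(p * log2(p))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mu, variance = v, sd = s, skewness = skew, kurtosis = kurt,
    energy = energy, rms = sqrt(energy), entropy = entropy,
    min = min(x), max = max(x), median = q[2], range = max(x) - min(x),
    mad = mean(abs(x - mu)), p25 = q[1], p75 = q[3], iqr = q[3] - q[1],
    cv = if (mu == 0) 0 else s / mu)
}

# Box mean over a 2^k x 2^k window "centered" at each pixel (rows
# [i - h, i + h - 1], h = 2^(k-1)); windows are clamped at the borders and
# divided by the actual pixel count.
box_mean_pow2 <- function(M, k) {
  h <- nrow(M); w <- ncol(M)
  half <- 2^(k - 1)
  I <- apply(M, 2, cumsum)
  I <- t(apply(I, 1, cumsum))
  I <- rbind(0, cbind(0, I))  # zero-padded integral image
  r1 <- pmax(1L, seq_len(h) - half); r2 <- pmin(h, seq_len(h) + half - 1L)
  c1 <- pmax(1L, seq_len(w) - half); c2 <- pmin(w, seq_len(w) + half - 1L)
  B <- I[r2 + 1L, c2 + 1L] - I[r1, c2 + 1L] - I[r2 + 1L, c1] + I[r1, c1]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  B / area
}

shift_rows <- function(M, d) {  # clamped row shift: M[i + d, j]
  h <- nrow(M)
  M[pmin(h, pmax(1L, seq_len(h) + d)), , drop = FALSE]
}

shift_cols <- function(M, d) {
  w <- ncol(M)
  M[, pmin(w, pmax(1L, seq_len(w) + d)), drop = FALSE]
}

# Coarseness, contrast, directionality and line-likeness of a filled crop,
# restricted to `mask` for the coarseness/directionality averages.
tamura_core <- function(crop, mask) {
  h <- nrow(crop); w <- ncol(crop)
  # --- coarseness: best scale 2^k per pixel from difference-of-averages
  kmax <- 0L
  while (2^(kmax + 1L) <= min(h, w) / 2) kmax <- kmax + 1L
  if (kmax == 0L) {
    coars <- 1
  } else {
    best_e <- matrix(-Inf, h, w)
    best_s <- matrix(1, h, w)
    for (k in seq_len(kmax)) {
      A <- box_mean_pow2(crop, k)
      half <- 2^(k - 1)
      ekv <- abs(shift_rows(A, half) - shift_rows(A, -half))
      ekh <- abs(shift_cols(A, half) - shift_cols(A, -half))
      e <- pmax(ekv, ekh)
      upd <- e > best_e  # strict: ties keep the smaller scale
      best_s[upd] <- 2^k
      best_e[upd] <- e[upd]
    }
    coars <- mean(best_s[mask])
  }
  # --- contrast: sigma / kurtosis^(1/4) on the filled crop
  x <- as.vector(crop)
  mu <- mean(x)
  v <- sum((x - mu)^2) / length(x)
  if (v > 0) {
    a4 <- (sum((x - mu)^4) / length(x)) / v^2
    contr <- sqrt(v) / a4^0.25
  } else contr <- 0
  # --- directionality: 16-bin gradient-orientation histogram entropy
  dh <- (shift_cols(crop, 1L) - shift_cols(crop, -1L)) / 2
  dv <- (shift_rows(crop, 1L) - shift_rows(crop, -1L)) / 2
  mag <- sqrt(dh^2 + dv^2)
  theta <- atan2(dv, dh) %% pi
  thr <- stats::median(mag[mask])
  sel <- mask & (mag > thr)
  nbin <- 16L
  if (!any(sel)) {
    dir <- 0
    lin <- 0
  } else {
    # bin centers at j * pi/16 so axis-aligned orientations sit at centers
    bins <- floor(((theta[sel] + pi / (2 * nbin)) %% pi) / (pi / nbin)) + 1L
    hst <- tabulate(bins, nbins = nbin)
    p <- hst[hst > 0] / sum(hst)
    dir <- 1 + sum(p * log2(p)) / log2(nbin)  # 1 - normalized entropy
    # --- line-likeness: orientation agreement at distance 4 along the
    # gradient direction, double-angle cosine to respect the pi-wrap
    d <- 4
    si <- which(sel)
    r <- ((si - 1L) %% h) + 1L; c <- ((si - 1L) %/% h) + 1L
    th <- theta[si]
    r2 <- r + round(d * sin(th)); c2 <- c + round(d * cos(th))
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    if (!any(ok)) {
      lin <- 0
    } else {
      pi2 <- (c2[ok] - 1L) * h + r2[ok]
      lin <- mean(cos(2 * (th[ok] - theta[pi2])))
    }
  }
  c(coarseness = coars, contrast = contr, directionality = dir,
    linelikeness = lin)
}

#' Tamura texture features of a masked region
#'
#' Computes the six Tamura features (coarseness, contrast, directionality,
#' line-likeness, regularity, roughness) of the region selected by `mask`.
#' The computation runs on the mask's bounding-box crop with non-mask
#' pixels filled by the mask mean, so texture from neighboring regions
#' cannot leak in. Regularity is 1 minus the normalized dispersion of the
#' first four features over a 2 x 2 sub-block partition of the crop (0 when
#' the crop is smaller than 8 x 8); roughness is coarseness + contrast.
#'
#' @param channel `H x W` numeric matrix (one image channel).
#' @param mask `H x W` logical matrix selecting the region (non-empty).
#' @return Named numeric vector of length 6.
#' @export
tamura_features <- function(channel, mask) {
  if (!is.matrix(channel) || !is.matrix(mask) ||
      !all(dim(channel) == dim(mask)))
    stop("`channel` and `mask` must be matrices of equal dimension",
         call. = FALSE)
  idx <- which(mask)
  if (!length(idx)) stop("empty mask", call. = FALSE)
  h <- nrow(channel)
  r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
  r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
  crop <- channel[r0:r1, c0:c1, drop = FALSE]
  mcrop <- mask[r0:r1, c0:c1, drop = FALSE]
  fill <- mean(channel[idx])
  crop[!mcrop] <- fill
  core <- tamura_core(crop, mcrop)
  # regularity over the 2 x 2 quadrant partition
  ch <- nrow(crop); cw <- ncol(crop)
  if (min(ch, cw) < 8L) {
    reg <- 0
  } else {
    rh <- ch %/% 2L; cwh <- cw %/% 2L
    blocks <- list(crop[1:rh, 1:cwh], crop[1:rh, (cwh + 1L):cw],
                   crop[(rh + 1L):ch, 1:cwh],
                   crop[(rh + 1L):ch, (cwh + 1L):cw])
    bf <- vapply(blocks, function(b)
      tamura_core(b, matrix(TRUE, nrow(b), ncol(b))), numeric(4L))
    disp <- vapply(seq_len(4L), function(i) {
      s <- stats::sd(bf[i, ])
      m <- mean(abs(bf[i, ]))
      min(1, s / (m + 1e-9))
    }, numeric(1))
    reg <- 1 - mean(disp)
  }
  c(core[1:4], regularity = reg,
    roughness = unname(core["coarseness"] + core["contrast"]))
}

#' Extract the per-superpixel feature table
#'
#' For every superpixel, computes the 17 first-order statistics of its
#' member pixels and the 6 Tamura features of its mask, on each RGB
#' channel, giving 69 feature values per row. Identifier columns carry the
#' image id, the superpixel id and the superpixel centroid (mean row/col);
#' classifiers must ignore them (and [train_classifier()] does).
#'
#' @param image `H x W x 3` array.
#' @param map `superpixel_map` with matching dimensions.
#' @param image_id Identifier stored in the `image_id` column.
#' @param labels Optional label image; when given, a `class` column is
#'   added via [assign_classes()] majority vote.
#' @return Data frame with `K` rows: `image_id`, `superpixel_id`, `row`,
#'   `col`, the 69 features, and optionally `class`.
#' @export
extract_feature_table <- function(image, map, image_id = "image",
                                  labels = NULL) {
  check_rgb_image(image)
  stopifnot(inherits(map, "superpixel_map"))
  a <- map$assignment
  if (!all(dim(image)[1:2] == dim(a)))
    stop("image and superpixel map dimensions differ", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  channels <- split_channels(image)
  px <- split(seq_len(h * w), as.vector(a))
  K <- map$K
  feats <- matrix(NA_real_, K, 69L,
                  dimnames = list(NULL, tma_feature_names()))
  cent_r <- numeric(K); cent_c <- numeric(K)
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(K)) {
    idx <- px[[as.character(k)]]
    r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
    cent_r[k] <- mean(r); cent_c[k] <- mean(c)
    mask[idx] <- TRUE
    row <- numeric(0)
    for (ch in channels) {
      fo <- first_order_stats(ch[idx])
      tm <- tamura_features(ch, mask)
      row <- c(row, fo, tm)
    }
    feats[k, ] <- row
    mask[idx] <- FALSE
  }
  out <- data.frame(image_id = image_id, superpixel_id = seq_len(K),
                    row = cent_r, col = cent_c, feats,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    cls <- assign_classes(map, labels)
    out$class <- cls$class[match(out$superpixel_id, cls$superpixel_id)]
  }
  out
}
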