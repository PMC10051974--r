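# Ground-truth construction: turn expert tumor polygons into three-class
# label images, and assign each superpixel a class by pixel majority vote.

# Even-odd polygon rasterization, boundary inclusive. `poly` uses ImageJ
# coordinates (x = column, y = row, 0-based); pixel (r, c) corresponds to
# the point (c - 1, r - 1). Returns a logical H x W matrix.
polygon_mask <- function(poly, h, w) {
  x <- as.numeric(poly$x); y <- as.numeric(poly$y)
  n <- length(x)
  if (n < 3L) stop("polygon needs >= 3 vertices", call. = FALSE)
  r0 <- max(1L, floor(min(y)) + 1L); r1 <- min(h, ceiling(max(y)) + 1L)
  c0 <- max(1L, floor(min(x)) + 1L); c1 <- min(w, ceiling(max(x)) + 1L)
  if (r0 > r1 || c0 > c1) return(matrix(FALSE, h, w))
  py <- (r0:r1) - 1  # point rows
  px <- (c0:c1) - 1  # point cols
  nr <- length(py); nc <- length(px)
  inside <- matrix(FALSE, nr, nc)
  onedge <- matrix(FALSE, nr, nc)
  PX <- matrix(px, nr, nc, byrow = TRUE)
  PY <- matrix(py, nr, nc)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- x[i]; y1 <- y[i]; x2 <- x[j]; y2 <- y[j]
    # crossing-number toggle (half-open rule in y avoids double counting)
    crosses <- ((y1 > PY) != (y2 > PY))
    if (any(crosses)) {
      xi <- x1 + (PY - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (PX < xi))
    }
    # boundary inclusion: point on the closed segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      onedge <- onedge | (abs(PX - x1) < eps & abs(PY - y1) < eps)
    } else {
      t <- ((PX - x1) * dx + (PY - y1) * dy) / len2
      cross <- (PX - x1) * dy - (PY - y1) * dx
      onedge <- onedge | (abs(cross) < eps * sqrt(len2) &
                          t >= -eps & t <= 1 + eps)
    }
  }
  out <- matrix(FALSE, h, w)
  out[r0:r1, c0:c1] <- inside | onedge
  out
}

# Otsu threshold (256-bin) of a numeric vector of 0..255 intensities.
otsu_threshold <- function(v) {
  counts <- tabulate(round(v) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  which.max(sigma_b) - 1L
}

#' Rasterize tumor polygons into a three-class label image
#'
#' Background is detected photometrically: pixels brighter (in grayscale
#' mean) than an Otsu threshold computed on the image *and* with channel
#' spread `max - min < 20` (i.e. light gray, low chroma). Non-background
#' pixels inside any tumor polygon (even-odd fill, boundary inclusive)
#' become tumor (code 2); the background rule takes precedence inside
#' polygons. Everything else is non-tumor tissue (code 3).
#'
#' @param image `H x W x 3` array.
#' @param tumor_rois List of polygons (as from [read_imagej_roi()] /
#'   [read_roi_set()]); may be empty.
#' @param chroma_max Channel-spread bound for the light-gray background
#'   rule (default 20).
#' @return Integer label matrix over `{0, 2, 3}`; the Otsu threshold used
#'   is attached as `attr(x, "otsu")`.
#' @export
rasterize_labels <- function(image, tumor_rois = list(), chroma_max = 20) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  thr <- otsu_threshold(as.vector(gray))
  spread <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  background <- (gray > thr) & (spread < chroma_max)
  tumor <- matrix(FALSE, h, w)
  for (poly in tumor_rois) tumor <- tumor | polygon_mask(poly, h, w)
  out <- matrix(3L, h, w)
  out[tumor] <- 2L
  out[background] <- 0L  # background rule wins inside polygons
  attr(out, "otsu") <- thr
  out
}

#' Assign a class to every superpixel by pixel majority vote
#'
#' For each superpixel, member pixels vote with their label-image class;
#' the superpixel receives the class with the most votes. Ties are broken
#' by a fixed priority (default tumor 2 > non-tumor 3 > background 0,
#' biasing toward sensitivity in a diagnostic-support setting).
#'
#' @param map `superpixel_map` object.
#' @param labels Integer label matrix over `{0, 2, 3}`, same dimensions.
#' @param tie_priority Integer vector ordering the codes for tie-breaking,
#'   highest priority first.
#' @return Data frame with one row per superpixel: `superpixel_id`,
#'   `class`, `n_pixels` and vote fractions `frac_0`, `frac_2`, `frac_3`
#'   (summing to 1 per row).
#' @export
assign_classes <- function(map, labels, tie_priority = c(2L, 3L, 0L)) {
  stopifnot(inherits(map, "superpixel_map"))
  check_label_image(labels)
  a <- map$assignment
  if (!all(dim(a) == dim(labels)))
    stop("superpixel map and label image dimensions differ", call. = FALSE)
  if (!setequal(tie_priority, LABEL_CODES))
    stop("`tie_priority` must be a permutation of {0, 2, 3}", call. = FALSE)
  av <- as.vector(a)
  counts <- vapply(tie_priority, function(code)
    tabulate(av[as.vector(labels) == code], nbins = map$K), integer(map$K))
  counts <- matrix(counts, nrow = map$K)  # columns in priority order
  n <- rowSums(counts)
  win <- max.col(counts, ties.method = "first")  # first = highest priority
  cls <- tie_priority[win]
  frac <- counts / n
  out <- data.frame(superpixel_id = seq_len(map$K), class = cls,
                    n_pixels = n)
  for (code in LABEL_CODES)
    out[[paste0("frac_", code)]] <- frac[, match(code, tie_priority)]
  out
}

#' Superpixel-resolution label image
#'
#' Replaces every pixel's label by the majority class of its superpixel.
#' This is the ground truth at the resolution the classifier actually
#' works at, used for scoring reconstructed segmentations.
#'
#' @inheritParams assign_classes
#' @return Integer label matrix over `{0, 2, 3}`.
#' @export
quantized_label_image <- function(map, labels, tie_priority = c(2L, 3L, 0L)) {
  cls <- assign_classes(map, labels, tie_priority)
  lut <- integer(map$K)
  lut[cls$superpixel_id] <- cls$class
  matrix(lut[map$assignment], nrow(labels), ncol(labels))
}
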