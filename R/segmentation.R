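# Reassembling classified superpixels into a segmented image and scoring
# it against ground truth.

#' Reconstruct a segmented label image from superpixel classes
#'
#' Places every superpixel back at its image position and paints it with
#' its predicted class, producing a label image over `{0, 2, 3}`.
#'
#' @param map `superpixel_map` object.
#' @param classes Data frame with columns `superpixel_id` and `class`
#'   (e.g. from [assign_classes()] or classifier predictions); every id in
#'   the map must be present.
#' @return Integer label matrix.
#' @export
reconstruct_segmentation <- function(map, classes) {
  stopifnot(inherits(map, "superpixel_map"))
  ids <- seq_len(map$K)
  pos <- match(ids, classes$superpixel_id)
  if (anyNA(pos))
    stop("no class for superpixel id(s): ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  cls <- as.integer(classes$class[pos])
  bad <- setdiff(unique(cls), LABEL_CODES)
  if (length(bad))
    stop("classes outside {0,2,3}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  matrix(cls[map$assignment], nrow(map$assignment), ncol(map$assignment))
}

#' Colorize a label image for display
#'
#' Maps background (0) to white, tumor (2) to red and non-tumor (3) to
#' green. The colorized preview is a display artifact only; scoring always
#' uses the code raster.
#'
#' @param labels Integer label matrix over `{0, 2, 3}`.
#' @return `H x W x 3` integer array.
#' @export
colorize_labels <- function(labels) {
  check_label_image(labels)
  cls <- tissue_classes()
  h <- nrow(labels); w <- ncol(labels)
  out <- array(0L, c(h, w, 3L))
  for (code in rownames(cls$colors)) {
    m <- labels == as.integer(code)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[m] <- cls$colors[code, ch]
      out[, , ch] <- plane
    }
  }
  as_int_image(out)
}

#' Pixel-level segmentation score
#'
#' Flattens the predicted and ground-truth label images and computes the
#' multiclass metrics of [compute_metrics()] at pixel level.
#'
#' @param predicted Integer label matrix over `{0, 2, 3}`.
#' @param truth Integer label matrix, same dimensions.
#' @return Metrics list as from [compute_metrics()].
#' @export
pixel_score <- function(predicted, truth) {
  check_label_image(predicted, "predicted")
  check_label_image(truth, "truth")
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth dimensions differ", call. = FALSE)
  compute_metrics(as.vector(truth), as.vector(predicted))
}
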