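# Internal helpers shared across modules.

# Rounding convention used package-wide when quantizing intensities:
# half-up (0.5 rounds away from zero toward +Inf for the non-negative
# values handled here), unlike base round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

clamp255 <- function(x) pmin(255, pmax(0, x))

#' Tissue class codes and display colors
#'
#' The three tissue classes are encoded as 0 (background, white),
#' 2 (tumor, red) and 3 (non-tumor, green). Code 1 is deliberately unused;
#' the three-code set is preserved verbatim from the labeling convention
#' of the source data.
#'
#' @return Named list with `codes` (integer vector) and `colors`
#'   (3-column matrix of RGB values, one row per code).
#' @export
tissue_classes <- function() {
  list(
    codes = c(background = 0L, tumor = 2L, nontumor = 3L),
    colors = matrix(c(255, 255, 255,
                      255, 0, 0,
                      0, 255, 0),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("0", "2", "3"), c("R", "G", "B")))
  )
}

LABEL_CODES <- c(0L, 2L, 3L)

# Validate an RGB image array (H x W x 3, values 0..255).
check_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop(sprintf("`%s` must have intensities in [0, 255]", arg), call. = FALSE)
  invisible(image)
}

# Validate a label image (H x W matrix over {0,2,3}).
check_label_image <- function(labels, arg = "labels") {
  if (!is.matrix(labels))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad))
    stop(sprintf("`%s` contains values outside {0,2,3}: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(labels)
}

as_int_image <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# EBImage stores rasters as (x = width, y = height); the package convention
# is matrix (row = y, col = x). These two adapters do the transposition.
ebi_to_array <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

array_to_ebi <- function(a) {
  if (length(dim(a)) == 2L) {
    EBImage::Image(t(a))
  } else {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  }
}

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
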