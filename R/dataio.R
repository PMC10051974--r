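# Reading and writing of the external artifacts the pipeline consumes and
# produces: RGB rasters, 8-bit label images, ImageJ polygon ROI files,
# CSV feature tables and flat run configuration files.

#' Read an RGB image
#'
#' Reads an 8-bit JPEG/PNG/TIFF raster into an `H x W x 3` integer array
#' with intensities in `[0, 255]`. Grayscale inputs are replicated to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to the image file.
#' @return Integer array of dimension `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  a <- ebi_to_array(img)
  v <- a * 255
  if (max(abs(v - round(v))) > 1e-6)
    stop("unsupported format (deeper than 8 bits per sample): ", path,
         call. = FALSE)
  v <- round(v)
  d <- dim(v)
  if (is.na(d[3]) || length(d) == 2L) {
    v <- array(v, c(d[1], d[2], 3L))
  } else if (d[3] == 1L) {
    v <- array(v[, , 1L], c(d[1], d[2], 3L))
  } else if (d[3] == 2L) {
    v <- array(v[, , 1L], c(d[1], d[2], 3L))  # gray + alpha
  } else if (d[3] > 3L) {
    v <- v[, , 1:3, drop = FALSE]             # drop alpha
  }
  as_int_image(v)
}

#' Write an RGB image as lossless PNG (or TIFF)
#'
#' @param image `H x W x 3` array with intensities in `[0, 255]`.
#' @param path Output path; the extension selects the format. PNG is the
#'   package default because pipeline artifacts must survive round trips
#'   bit-exactly.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  EBImage::writeImage(array_to_ebi(image / 255), path)
  invisible(path)
}

#' Read an 8-bit label image
#'
#' Accepts either a single-channel raster whose values are the class codes
#' `{0, 2, 3}`, or a color-coded raster using exactly white `(255,255,255)`
#' for background, red `(255,0,0)` for tumor and green `(0,255,0)` for
#' non-tumor.
#'
#' @param path Path to the label raster.
#' @param strict If `TRUE` (default) any single-channel value outside
#'   `{0,2,3}` is an error; if `FALSE`, offending pixels are remapped to the
#'   nearest allowed code (ties toward the smaller code) with a warning.
#' @return Integer matrix over `{0, 2, 3}`.
#' @export
read_label_image <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read label image ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  a <- round(ebi_to_array(img) * 255)
  d <- dim(a)
  if (length(d) == 3L && d[3] >= 3L) {
    return(decode_label_colors(as_int_image(a[, , 1:3])))
  }
  if (length(d) == 3L) a <- a[, , 1L]
  vals <- unique(as.vector(a))
  bad <- setdiff(vals, LABEL_CODES)
  if (length(bad)) {
    if (strict)
      stop("label image ", path, " contains values outside {0,2,3}: ",
           paste(sort(bad), collapse = ", "), call. = FALSE)
    # nearest allowed code, ties toward the smaller code
    lut <- vapply(0:255, function(v) {
      d2 <- abs(LABEL_CODES - v)
      LABEL_CODES[which.min(d2)]  # which.min takes first, codes sorted asc
    }, integer(1))
    n_bad <- sum(!(a %in% LABEL_CODES))
    a <- matrix(lut[a + 1L], nrow(a), ncol(a))
    warning(sprintf("remapped %d pixel(s) with out-of-set values in %s",
                    n_bad, path), call. = FALSE)
  }
  as_int_image(a)
}

# Decode a white/red/green color-coded label raster by exact color match.
decode_label_colors <- function(image) {
  check_rgb_image(image)
  cls <- tissue_classes()
  h <- dim(image)[1]; w <- dim(image)[2]
  key <- image[, , 1] * 65536L + image[, , 2] * 256L + image[, , 3]
  keys <- cls$colors[, 1] * 65536L + cls$colors[, 2] * 256L + cls$colors[, 3]
  out <- matrix(NA_integer_, h, w)
  for (i in seq_along(keys))
    out[key == keys[i]] <- as.integer(rownames(cls$colors)[i])
  if (anyNA(out))
    stop("color-coded label image contains colors other than ",
         "white/red/green", call. = FALSE)
  out
}

#' Write a label image as an 8-bit PNG
#'
#' Stores the raw class codes `{0,2,3}` as gray levels so that
#' `read_label_image()` recovers them bit-exactly.
#'
#' @param labels Integer matrix over `{0, 2, 3}`.
#' @param path Output path (PNG recommended).
#' @return Invisibly, `path`.
#' @export
write_label_image <- function(labels, path) {
  check_label_image(labels)
  EBImage::writeImage(array_to_ebi(labels / 255), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ImageJ ".roi" polygon files. Binary layout: 64-byte big-endian header
# starting with the magic "Iout"; ROI type byte at offset 6 (0 = polygon);
# bounding box top/left/bottom/right as 16-bit ints at offsets 8..15;
# n_coordinates at offset 16; after the header, n x-coordinates then n
# y-coordinates, 16-bit ints relative to (left, top).

ROI_TYPE_POLYGON <- 0L

#' Read an ImageJ polygon ROI file
#'
#' Parses the binary ImageJ `.roi` format (polygon subtype only) and returns
#' the polygon in absolute pixel coordinates (the stored bounding-box offset
#' is applied). Coordinates follow the ImageJ convention: `x` is the column
#' and `y` the row, 0-based.
#'
#' @param path Path to a `.roi` file.
#' @return List with integer vectors `x` and `y` (absolute vertices) and
#'   `n` (vertex count).
#' @export
read_imagej_roi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file (bad magic): ", path, call. = FALSE)
  type <- as.integer(raw[7])
  if (type != ROI_TYPE_POLYGON)
    stop("unsupported ROI type ", type, " (only polygon = 0 is supported): ",
         path, call. = FALSE)
  rd16 <- function(off) {  # signed big-endian 16-bit at 0-based offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  }
  top <- rd16(8); left <- rd16(10)
  n <- rd16(16)
  if (n < 3L) stop("polygon ROI with fewer than 3 vertices: ", path,
                   call. = FALSE)
  need <- 64L + 4L * n
  if (length(raw) < need) stop("truncated ROI file: ", path, call. = FALSE)
  xs <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                endian = "big")
  ys <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n, size = 2,
                endian = "big")
  list(x = xs + left, y = ys + top, n = n)
}

#' Write an ImageJ polygon ROI file
#'
#' Inverse of [read_imagej_roi()]; useful for exporting markings and for
#' round-trip testing.
#'
#' @param poly List with integer vectors `x` and `y` (absolute 0-based
#'   vertices, at least 3).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_imagej_roi <- function(poly, path) {
  x <- as.integer(poly$x); y <- as.integer(poly$y)
  if (length(x) < 3L || length(x) != length(y))
    stop("polygon needs >= 3 (x, y) vertex pairs", call. = FALSE)
  left <- min(x); top <- min(y)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(227L, con, size = 2, endian = "big")          # version
  writeBin(as.raw(c(ROI_TYPE_POLYGON, 0L)), con)         # type byte + pad
  writeBin(c(top, left, max(y) + 1L, max(x) + 1L), con, size = 2,
           endian = "big")                               # bounding box
  writeBin(length(x), con, size = 2, endian = "big")     # n_coordinates
  writeBin(raw(64L - 18L), con)                          # rest of header
  writeBin(x - left, con, size = 2, endian = "big")
  writeBin(y - top, con, size = 2, endian = "big")
  invisible(path)
}

#' Read all polygon ROIs for one image
#'
#' An image's tumor marking may be split over several `.roi` files; this
#' reads every `.roi` file in a directory and returns the list of polygons
#' (their union is the tumor region).
#'
#' @param dir Directory containing `.roi` files.
#' @return List of polygons as returned by [read_imagej_roi()].
#' @export
read_roi_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.roi$", full.names = TRUE))
  lapply(files, read_imagej_roi)
}

# ---------------------------------------------------------------------------
# Feature tables (CSV with header).

FEATURE_KEY_COLUMNS <- c("image_id", "superpixel_id", "row", "col")

#' Write a per-superpixel feature table to CSV
#'
#' @param table Data frame as produced by [extract_feature_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-superpixel feature table from CSV
#'
#' Validates the schema: the identifier columns and all 69 feature columns
#' must be present and feature columns must be numeric. The `class` column
#' is optional (absent for unlabeled tables).
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Data frame; `attr(x, "has_class")` records whether a class
#'   column was present.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(FEATURE_KEY_COLUMNS, tma_feature_names())
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("feature table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (fc in tma_feature_names())
    if (!is.numeric(tab[[fc]]))
      stop("non-numeric values in feature column `", fc, "` of ", path,
           call. = FALSE)
  attr(tab, "has_class") <- "class" %in% names(tab)
  tab
}

#' Read a flat key = value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric, `true`/`false` become logical, and
#' comma-separated values become character vectors.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    key <- kv[2]; val <- trimws(kv[3])
    val <- gsub('^"|"$', "", val)
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (tolower(val) %in% c("true", "false")) {
      val <- as.logical(val)
    } else if (grepl("^-?[0-9.]+([eE]-?[0-9]+)?$", val)) {
      val <- as.numeric(val)
    }
    out[[key]] <- val
  }
  out
}
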