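# SLIC superpixels: localized k-means over combined color + position,
# governed by an initial grid size S and a regularization r in [0, 1]
# ("very elastic" superpixels at 0, almost square at 1).

#' SLIC parameters
#'
#' @param grid_size Initial average superpixel side length `S` in pixels
#'   (default 30).
#' @param regularization `r` in `[0, 1]`: 0 gives very elastic superpixels,
#'   1 almost square ones (default 0.20). Internally mapped to a SLIC
#'   compactness `m = compactness_max * r`.
#' @param max_iterations Fixed number of assign/update sweeps (default 10).
#' @param enforce_connectivity Merge stray fragments smaller than `S^2 / 4`
#'   into their largest adjacent superpixel (default `TRUE`).
#' @param color_space `"opponent"` (default) computes color distances in an
#'   opponent color space derived from RGB by a fixed orthonormal
#'   transform; `"rgb"` uses plain RGB distances.
#' @param compactness_max Compactness reached at `r = 1` on 0-255
#'   intensities (default 40).
#' @return Object of class `slic_params`.
#' @export
slic_params <- function(grid_size = 30L, regularization = 0.20,
                        max_iterations = 10L, enforce_connectivity = TRUE,
                        color_space = c("opponent", "rgb"),
                        compactness_max = 40) {
  if (grid_size < 2L) stop("`grid_size` must be >= 2", call. = FALSE)
  if (regularization < 0 || regularization > 1)
    stop("`regularization` must be in [0, 1]", call. = FALSE)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1",
                                call. = FALSE)
  structure(list(grid_size = as.integer(grid_size),
                 regularization = regularization,
                 max_iterations = as.integer(max_iterations),
                 enforce_connectivity = isTRUE(enforce_connectivity),
                 color_space = match.arg(color_space),
                 compactness_max = compactness_max),
            class = "slic_params")
}

# Orthonormal opponent transform of RGB (rows: intensity, red-green,
# yellow-blue). Orthonormality preserves the Euclidean scale of 8-bit data.
OPPONENT_MATRIX <- matrix(c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3),
                            1 / sqrt(2), -1 / sqrt(2), 0,
                            1 / sqrt(6), 1 / sqrt(6), -2 / sqrt(6)),
                          nrow = 3, byrow = TRUE)

slic_color_planes <- function(image, color_space) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  if (color_space == "rgb") return(list(r, g, b))
  M <- OPPONENT_MATRIX
  list(M[1, 1] * r + M[1, 2] * g + M[1, 3] * b,
       M[2, 1] * r + M[2, 2] * g + M[2, 3] * b,
       M[3, 1] * r + M[3, 2] * g + M[3, 3] * b)
}

#' Partition an image into SLIC superpixels
#'
#' Cluster centers are initialized on a regular grid of
#' `ceiling(H/S) x ceiling(W/S)` sites; each pixel is assigned to the
#' nearest center within a `2S x 2S` search window under the distance
#' `D = d_color + (m / S) * d_xy` with `m = compactness_max * r`; centers
#' are then updated to their cluster means. After the fixed number of
#' iterations, connectivity is optionally enforced. The procedure has no
#' random component: identical inputs give identical maps.
#'
#' @param image `H x W x 3` array, intensities in `[0, 255]`.
#' @param params [slic_params()] object.
#' @return Object of class `superpixel_map`: list with `assignment`
#'   (`H x W` integer matrix of ids `1..K`), `K`, and `params`.
#' @export
slic <- function(image, params = slic_params()) {
  check_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (min(h, w) < 2L) stop("image must be at least 2 x 2", call. = FALSE)
  S <- params$grid_size
  if (S > min(h, w)) {
    warning("grid_size exceeds the smallest image dimension; ",
            "returning a single superpixel", call. = FALSE)
    return(structure(list(assignment = matrix(1L, h, w), K = 1L,
                          params = params), class = "superpixel_map"))
  }
  planes <- slic_color_planes(image, params$color_space)
  m <- params$compactness_max * params$regularization
  wxy <- m / S

  nr <- ceiling(h / S); nc <- ceiling(w / S)
  cr <- (seq_len(nr) - 0.5) * h / nr  # center rows
  cc <- (seq_len(nc) - 0.5) * w / nc  # center cols
  centers <- cbind(row = rep(cr, times = nc), col = rep(cc, each = nr))
  K <- nrow(centers)
  cfeat <- sapply(planes, function(p) {
    p[cbind(pmin(h, pmax(1, round(centers[, 1]))),
            pmin(w, pmax(1, round(centers[, 2]))))]
  })
  cfeat <- matrix(cfeat, nrow = K)

  rows_mat <- matrix(seq_len(h), h, w)
  cols_mat <- matrix(seq_len(w), h, w, byrow = TRUE)
  assignment <- matrix(0L, h, w)

  for (iter in seq_len(params$max_iterations)) {
    best <- matrix(Inf, h, w)
    assignment[] <- 0L
    for (k in seq_len(K)) {
      r0 <- max(1L, floor(centers[k, 1] - S)); r1 <- min(h, ceiling(centers[k, 1] + S))
      c0 <- max(1L, floor(centers[k, 2] - S)); c1 <- min(w, ceiling(centers[k, 2] + S))
      ri <- r0:r1; ci <- c0:c1
      dcol <- sqrt((planes[[1]][ri, ci] - cfeat[k, 1])^2 +
                   (planes[[2]][ri, ci] - cfeat[k, 2])^2 +
                   (planes[[3]][ri, ci] - cfeat[k, 3])^2)
      dxy <- sqrt((rows_mat[ri, ci] - centers[k, 1])^2 +
                  (cols_mat[ri, ci] - centers[k, 2])^2)
      d <- dcol + wxy * dxy
      upd <- d < best[ri, ci]
      if (any(upd)) {
        bsub <- best[ri, ci]; asub <- assignment[ri, ci]
        bsub[upd] <- d[upd]; asub[upd] <- k
        best[ri, ci] <- bsub; assignment[ri, ci] <- asub
      }
    }
    # pixels outside every search window (cannot happen with the grid
    # spacing used, kept as a safety net): nearest center by position
    if (any(assignment == 0L)) {
      miss <- which(assignment == 0L)
      mr <- rows_mat[miss]; mc <- cols_mat[miss]
      for (i in seq_along(miss)) {
        assignment[miss[i]] <-
          which.min((centers[, 1] - mr[i])^2 + (centers[, 2] - mc[i])^2)
      }
    }
    # update step: centers move to their cluster means
    av <- as.vector(assignment)
    cnt <- tabulate(av, nbins = K)
    nz <- cnt > 0L
    sums_r <- rowsum(as.vector(rows_mat), av)
    sums_c <- rowsum(as.vector(cols_mat), av)
    ids <- as.integer(rownames(sums_r))
    centers[ids, 1] <- sums_r[, 1] / cnt[ids]
    centers[ids, 2] <- sums_c[, 1] / cnt[ids]
    for (p in 1:3) {
      sp <- rowsum(as.vector(planes[[p]]), av)
      cfeat[ids, p] <- sp[, 1] / cnt[ids]
    }
  }

  if (params$enforce_connectivity) {
    assignment <- enforce_connectivity(assignment, S)
  } else {
    assignment <- relabel_contiguous(assignment)
  }
  structure(list(assignment = assignment, K = max(assignment),
                 params = params), class = "superpixel_map")
}

# Relabel ids to the contiguous range 1..K preserving first-appearance
# order in column-major scan.
relabel_contiguous <- function(assignment) {
  u <- unique(as.vector(assignment))
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  matrix(lut[assignment], nrow(assignment), ncol(assignment))
}

# 4-connected component labeling of a logical matrix by vectorized BFS.
label_components_4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      r <- ((frontier - 1L) %% h) + 1L
      up    <- frontier[r > 1L] - 1L
      down  <- frontier[r < h] + 1L
      left  <- frontier[frontier > h] - h
      right <- frontier[frontier <= h * (w - 1L)] + h
      nb <- c(up, down, left, right)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# Merge 4-connected fragments smaller than S^2/4 into their largest
# adjacent superpixel; larger detached fragments become superpixels of
# their own. Returns a relabeled assignment with contiguous ids.
enforce_connectivity <- function(assignment, S) {
  h <- nrow(assignment); w <- ncol(assignment)
  min_size <- S^2 / 4
  K <- max(assignment)
  # split every id into its 4-connected components (work on bounding boxes)
  comp <- matrix(0L, h, w)
  ncomp <- 0L
  comp_id <- integer(0)   # original superpixel id per component
  comp_px <- list()
  for (k in seq_len(K)) {
    idx <- which(assignment == k)
    if (!length(idx)) next
    r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
    r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
    sub <- assignment[r0:r1, c0:c1, drop = FALSE] == k
    lab <- label_components_4(sub)
    for (j in seq_len(max(lab))) {
      ncomp <- ncomp + 1L
      li <- which(lab == j)
      lr <- ((li - 1L) %% nrow(lab)) + r0
      lc <- ((li - 1L) %/% nrow(lab)) + c0
      comp_px[[ncomp]] <- (lc - 1L) * h + lr
      comp[comp_px[[ncomp]]] <- ncomp
      comp_id[ncomp] <- k
    }
  }
  sizes <- lengths(comp_px)
  # the largest component of each id keeps that id; detached components of
  # at least min_size become superpixels of their own; smaller orphans are
  # merged into the largest adjacent *superpixel* (never into another
  # orphan), peeling inward until every orphan touches a superpixel
  keep <- rep(FALSE, ncomp)
  for (k in unique(comp_id)) {
    members <- which(comp_id == k)
    keep[members[which.max(sizes[members])]] <- TRUE
  }
  keep <- keep | (sizes >= min_size)
  out <- matrix(0L, h, w)
  sp_size <- integer(ncomp)
  for (ci in which(keep)) {
    out[comp_px[[ci]]] <- ci
    sp_size[ci] <- sizes[ci]
  }
  pending <- which(!keep)
  while (length(pending)) {
    progress <- FALSE
    deferred <- integer(0)
    for (ci in pending[order(sizes[pending])]) {
      px <- comp_px[[ci]]
      r <- ((px - 1L) %% h) + 1L
      nb <- c(px[r > 1L] - 1L, px[r < h] + 1L,
              px[px > h] - h, px[px <= h * (w - 1L)] + h)
      nb_sp <- unique(out[nb])
      nb_sp <- nb_sp[nb_sp > 0L]
      if (!length(nb_sp)) {
        deferred <- c(deferred, ci)
        next
      }
      tgt <- nb_sp[which.max(sp_size[nb_sp])]
      out[px] <- tgt
      sp_size[tgt] <- sp_size[tgt] + sizes[ci]
      progress <- TRUE
    }
    if (!progress && length(deferred)) {
      # an island made only of orphans: promote its largest fragment
      big <- deferred[which.max(sizes[deferred])]
      out[comp_px[[big]]] <- big
      sp_size[big] <- sizes[big]
      deferred <- setdiff(deferred, big)
    }
    pending <- deferred
  }
  relabel_contiguous(out)
}

#' Superpixel pixel counts
#'
#' @param map `superpixel_map` object.
#' @return Data frame with columns `superpixel_id` and `pixel_count`;
#'   counts sum to `H * W`.
#' @export
superpixel_sizes <- function(map) {
  stopifnot(inherits(map, "superpixel_map"))
  cnt <- tabulate(map$assignment, nbins = map$K)
  data.frame(superpixel_id = seq_len(map$K), pixel_count = cnt)
}

#' Overlay superpixel boundaries on an image
#'
#' Pixels 4-adjacent to a pixel with a different superpixel id are painted
#' yellow `(255, 255, 0)`, the usual display convention for superpixel
#' limits.
#'
#' @param image `H x W x 3` array.
#' @param map `superpixel_map` with matching dimensions.
#' @return Copy of `image` with boundary pixels painted yellow.
#' @export
boundary_overlay <- function(image, map) {
  check_rgb_image(image)
  stopifnot(inherits(map, "superpixel_map"))
  a <- map$assignment
  if (!all(dim(image)[1:2] == dim(a)))
    stop("image and superpixel map dimensions differ", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  b <- matrix(FALSE, h, w)
  b[-h, ] <- b[-h, ] | (a[-h, ] != a[-1, ])
  b[-1, ] <- b[-1, ] | (a[-1, ] != a[-h, ])
  b[, -w] <- b[, -w] | (a[, -w] != a[, -1])
  b[, -1] <- b[, -1] | (a[, -1] != a[, -w])
  out <- image
  idx <- which(b)
  hw <- h * w
  out[idx] <- 255L
  out[idx + hw] <- 255L
  out[idx + 2L * hw] <- 0L
  out
}
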