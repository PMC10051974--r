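# Shared fixtures and independent oracles. Oracles are deliberately coded
# from the definitions (sorted lists, explicit counting), not by calling
# the package functions they check.

# --- independent ImageJ .roi encoder -------------------------------------
# Builds the binary polygon ROI layout byte by byte: 64-byte big-endian
# header ("Iout", version, type byte 0 at offset 6, bounding box at 8..15,
# n at 16), then relative x then y vertex shorts.
encode_roi_bytes <- function(x, y, type = 0L) {
  be16 <- function(v) {
    v <- as.integer(v)
    v <- ifelse(v < 0, v + 65536L, v)
    as.raw(c(v %/% 256L, v %% 256L))
  }
  left <- min(x); top <- min(y)
  header <- c(charToRaw("Iout"),
              be16(227),                     # version
              as.raw(c(type, 0)),            # roi type + pad
              be16(top), be16(left), be16(max(y) + 1), be16(max(x) + 1),
              be16(length(x)))
  header <- c(header, raw(64 - length(header)))
  body <- c(unlist(lapply(x - left, be16)), unlist(lapply(y - top, be16)))
  c(header, body)
}

write_roi_fixture <- function(path, x, y, type = 0L) {
  writeBin(encode_roi_bytes(x, y, type), path)
  path
}

# --- brute-force classification-metrics oracle ---------------------------
# Direct one-vs-rest counting with explicit loops.
oracle_metrics <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  n <- length(truth)
  out <- list()
  f1s <- numeric(0)
  for (cl in classes) {
    tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
    for (i in seq_len(n)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1L
      else if (truth[i] != cl && pred[i] == cl) fp <- fp + 1L
      else if (truth[i] == cl && pred[i] != cl) fn <- fn + 1L
      else tn <- tn + 1L
    }
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    f1s <- c(f1s, f1)
    out[[as.character(cl)]] <- c(TP = tp, FP = fp, FN = fn, TN = tn,
                                 PPV = ppv, TPR = tpr, F1 = f1)
  }
  list(per_class = out,
       accuracy = sum(truth == pred) / n,
       macro_f1 = mean(f1s))
}

# --- brute-force first-order statistics oracle ---------------------------
oracle_first_order <- function(x) {
  x <- as.numeric(x); n <- length(x); s <- sort(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  sdv <- sqrt(v)
  counts <- table(round(x))
  p <- as.numeric(counts) / n
  qt <- function(prob) {  # type-7 quantile, explicit
    h <- (n - 1) * prob
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(n, lo + 2)] - s[lo + 1])
  }
  c(mean = mu, variance = v, sd = sdv,
    skewness = if (v > 0) sum((x - mu)^3) / n / sdv^3 else 0,
    kurtosis = if (v > 0) sum((x - mu)^4) / n / v^2 - 3 else 0,
    energy = sum(x^2) / n, rms = sqrt(sum(x^2) / n),
    entropy = -sum(p * log2(p)),
    min = s[1], max = s[n], median = qt(0.5), range = s[n] - s[1],
    mad = sum(abs(x - mu)) / n, p25 = qt(0.25), p75 = qt(0.75),
    iqr = qt(0.75) - qt(0.25),
    cv = if (mu == 0) 0 else sdv / mu)
}

# --- brute-force superpixel vote counter ---------------------------------
oracle_assign <- function(assignment, labels, priority = c(2L, 3L, 0L)) {
  K <- max(assignment)
  res <- integer(K)
  for (k in seq_len(K)) {
    lv <- labels[assignment == k]
    cnt <- vapply(priority, function(code) sum(lv == code), integer(1))
    res[k] <- priority[which.max(cnt)]  # first max = highest priority
  }
  res
}

# --- random (map, labels) fixtures ---------------------------------------
# A valid superpixel map from a random Voronoi partition, plus random
# labels, both deterministic given the seed.
random_map_labels <- function(h = 24, w = 24, K = 6, seed = 1) {
  set.seed(seed)
  cr <- runif(K, 1, h); cc <- runif(K, 1, w)
  a <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    a[i, j] <- which.min((cr - i)^2 + (cc - j)^2)
  u <- unique(as.vector(a))
  a <- matrix(match(a, u), h, w)
  map <- structure(list(assignment = a, K = max(a), params = NULL),
                   class = "superpixel_map")
  labels <- matrix(sample(c(0L, 2L, 3L), h * w, replace = TRUE), h, w)
  list(map = map, labels = labels)
}

# --- separable synthetic feature tables ----------------------------------
# Valid feature tables with class-dependent feature means; used where the
# learning machinery is under test rather than feature extraction.
make_feature_table <- function(n_per_class = 20, seed = 1, image_id = "img",
                               shift = 3, shuffle_classes = FALSE) {
  set.seed(seed)
  feats <- tma_feature_names()
  classes <- rep(c(0L, 2L, 3L), each = n_per_class)
  n <- length(classes)
  X <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, feats))
  offs <- match(classes, c(0L, 2L, 3L)) * shift
  X[, 1:12] <- X[, 1:12] + offs   # class signal in a feature subset
  tab <- data.frame(image_id = image_id, superpixel_id = seq_len(n),
                    row = runif(n, 1, 100), col = runif(n, 1, 100),
                    X, check.names = FALSE, stringsAsFactors = FALSE)
  tab$class <- if (shuffle_classes) sample(classes) else classes
  tab
}
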