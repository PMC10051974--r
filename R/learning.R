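# Supervised superpixel classification: five classifier families, the
# per-class precision/recall/F1 + accuracy metrics, image-level
# cross-validation and the enhancement x classifier comparison grid.

CLASSIFIER_FAMILIES <- c("random_forest", "svm", "logit_boost", "c45_tree",
                         "bayes_net")

#' Specify a classifier
#'
#' The five families mirror the classical Weka line-up used in superpixel
#' classification studies: bagged randomized trees (random forest), an
#' SMO-style support vector machine, additive logistic regression with
#' decision stumps (LogitBoost), an entropy-split pruned decision tree
#' (C4.5 style) and naive Bayes with Gaussian conditionals (the minimal
#' Bayesian network). They are analogues, not bit-compatible replicas, of
#' the Weka implementations.
#'
#' @param family One of `"random_forest"`, `"svm"`, `"logit_boost"`,
#'   `"c45_tree"`, `"bayes_net"`.
#' @param seed Integer seed; all training randomness flows from it.
#' @param num_trees Trees in the random forest (default 100).
#' @param svm_kernel `"radial"` (default) or `"linear"`.
#' @param svm_cost SVM cost parameter (default 1).
#' @param boost_iter LogitBoost iterations (default 30).
#' @param tree_cp Complexity-pruning parameter for the decision tree
#'   (default 0.01).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = CLASSIFIER_FAMILIES, seed = 1L,
                            num_trees = 100L,
                            svm_kernel = c("radial", "linear"), svm_cost = 1,
                            boost_iter = 30L, tree_cp = 0.01) {
  family <- match.arg(family)
  structure(list(family = family, seed = as.integer(seed),
                 num_trees = as.integer(num_trees),
                 svm_kernel = match.arg(svm_kernel), svm_cost = svm_cost,
                 boost_iter = as.integer(boost_iter), tree_cp = tree_cp),
            class = "classifier_spec")
}

# Predictor matrix: the 69 feature columns only. Identifier/position
# columns (image_id, superpixel_id, row, col) are never used as
# predictors; they exist to place each superpixel back in the image.
feature_matrix <- function(table) {
  feats <- tma_feature_names()
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("feature table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(table[, feats])
  storage.mode(X) <- "double"
  X
}

#' Train a superpixel classifier
#'
#' @param table Feature table with a `class` column (codes in
#'   `{0, 2, 3}`); at least two classes must be present and features must
#'   be finite.
#' @param spec [classifier_spec()] object.
#' @return Object of class `tma_model` with a [predict][predict.tma_model]
#'   method.
#' @export
train_classifier <- function(table, spec = classifier_spec("random_forest")) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(table$class)) stop("feature table has no `class` column",
                                 call. = FALSE)
  X <- feature_matrix(table)
  if (any(!is.finite(X))) stop("non-finite feature values in training table",
                               call. = FALSE)
  y <- factor(table$class)
  if (nlevels(y) < 2L) stop("training table contains a single class",
                            call. = FALSE)
  fit <- with_seed(spec$seed, switch(
    spec$family,
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = spec$num_trees,
      mtry = floor(sqrt(ncol(X))), seed = spec$seed, num.threads = 1L),
    svm = e1071::svm(x = X, y = y, kernel = spec$svm_kernel,
                     cost = spec$svm_cost, scale = TRUE),
    logit_boost = logitboost_train(X, y, iter = spec$boost_iter),
    c45_tree = {
      df <- data.frame(.class = y, X, check.names = TRUE)
      rpart::rpart(.class ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = spec$tree_cp))
    },
    bayes_net = e1071::naiveBayes(x = as.data.frame(X), y = y)))
  structure(list(family = spec$family, fit = fit, levels = levels(y),
                 spec = spec), class = "tma_model")
}

#' Predict superpixel classes
#'
#' @param object `tma_model` from [train_classifier()].
#' @param newdata Feature table (class column not required).
#' @param ... Unused.
#' @return Integer vector of class codes, one per row of `newdata`.
#' @export
predict.tma_model <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  pred <- switch(
    object$family,
    random_forest = as.character(
      stats::predict(object$fit, data = X, num.threads = 1L)$predictions),
    svm = as.character(stats::predict(object$fit, newdata = X)),
    logit_boost = logitboost_predict(object$fit, X),
    c45_tree = {
      df <- as.data.frame(X, check.names = TRUE)
      as.character(stats::predict(object$fit, newdata = df, type = "class"))
    },
    bayes_net = as.character(
      stats::predict(object$fit, newdata = as.data.frame(X))))
  as.integer(pred)
}

# ---------------------------------------------------------------------------
# LogitBoost with depth-1 regression stumps (additive logistic
# regression), one-vs-rest for multiclass. No installed package provides
# this family, so it is implemented here.

# Weighted least-squares stump: split on the feature/threshold minimizing
# weighted SSE of the working response, constant prediction on each side.
fit_stump <- function(X, z, w) {
  n <- nrow(X); p <- ncol(X)
  tot_w <- sum(w); tot_wz <- sum(w * z)
  base_sse <- sum(w * z^2) - tot_wz^2 / tot_w
  best <- list(sse = base_sse, feature = 0L, threshold = 0,
               left = tot_wz / tot_w, right = tot_wz / tot_w)
  for (j in seq_len(p)) {
    o <- order(X[, j])
    xs <- X[o, j]; ws <- w[o]; zs <- z[o]
    cw <- cumsum(ws); cwz <- cumsum(ws * zs); cwz2 <- cumsum(ws * zs^2)
    # candidate splits between distinct consecutive values
    cand <- which(diff(xs) > 0)
    if (!length(cand)) next
    lw <- cw[cand]; lwz <- cwz[cand]
    rw <- tot_w - lw; rwz <- tot_wz - lwz
    sse <- (cwz2[n] - lwz^2 / lw) - rwz^2 / rw
    bi <- which.min(sse)
    if (sse[bi] < best$sse - 1e-12) {
      i <- cand[bi]
      best <- list(sse = sse[bi], feature = j,
                   threshold = (xs[i] + xs[i + 1]) / 2,
                   left = lwz[bi] / lw[bi], right = rwz[bi] / rw[bi])
    }
  }
  best
}

stump_predict <- function(stump, X) {
  if (stump$feature == 0L) return(rep(stump$left, nrow(X)))
  ifelse(X[, stump$feature] <= stump$threshold, stump$left, stump$right)
}

logitboost_train <- function(X, y, iter = 30L, z_max = 4) {
  lv <- levels(y)
  models <- lapply(lv, function(cl) {
    yy <- as.numeric(y == cl)
    Fv <- rep(0, nrow(X))
    stumps <- vector("list", iter)
    for (m in seq_len(iter)) {
      p <- 1 / (1 + exp(-Fv))
      w <- pmax(p * (1 - p), 1e-5)
      z <- pmin(z_max, pmax(-z_max, (yy - p) / w))
      st <- fit_stump(X, z, w)
      stumps[[m]] <- st
      Fv <- Fv + 0.5 * stump_predict(st, X)
    }
    stumps
  })
  list(levels = lv, models = models, iter = iter)
}

logitboost_predict <- function(fit, X) {
  scores <- vapply(fit$models, function(stumps) {
    Fv <- rep(0, nrow(X))
    for (st in stumps) Fv <- Fv + 0.5 * stump_predict(st, X)
    Fv
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  fit$levels[max.col(scores, ties.method = "first")]
}

# ---------------------------------------------------------------------------
# Metrics

#' Per-class confusion counts and classification metrics
#'
#' One-vs-rest TP/FP/FN/TN per class, per-class precision
#' `PPV = TP / (TP + FP)`, recall `TPR = TP / (TP + FN)`, and
#' `F1 = 2 TP / (2 TP + FP + FN)` (each 0 when its denominator is 0);
#' multiclass accuracy `ACC = correct / N`; macro F1 is the unweighted
#' mean of per-class F1, weighted F1 the support-weighted mean.
#'
#' @param truth Vector of true class codes.
#' @param predicted Vector of predicted class codes, same length.
#' @return List with `confusion` (data frame of per-class counts),
#'   `per_class` (data frame of PPV/TPR/F1/support), `accuracy`,
#'   `macro_f1`, `weighted_f1` and `n`.
#' @export
compute_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || !length(truth))
    stop("`truth` and `predicted` must be non-empty and of equal length",
         call. = FALSE)
  truth <- as.vector(truth); predicted <- as.vector(predicted)
  classes <- sort(unique(c(truth, predicted)))
  n <- length(truth)
  conf <- data.frame(class = classes, TP = 0L, FP = 0L, FN = 0L, TN = 0L,
                     support = 0L)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    conf$TP[i] <- tp; conf$FP[i] <- fp; conf$FN[i] <- fn
    conf$TN[i] <- n - tp - fp - fn
    conf$support[i] <- tp + fn
  }
  ppv <- ifelse(conf$TP + conf$FP > 0, conf$TP / (conf$TP + conf$FP), 0)
  tpr <- ifelse(conf$TP + conf$FN > 0, conf$TP / (conf$TP + conf$FN), 0)
  f1 <- ifelse(2 * conf$TP + conf$FP + conf$FN > 0,
               2 * conf$TP / (2 * conf$TP + conf$FP + conf$FN), 0)
  per_class <- data.frame(class = classes, PPV = ppv, TPR = tpr, F1 = f1,
                          support = conf$support)
  list(confusion = conf, per_class = per_class,
       accuracy = sum(truth == predicted) / n,
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * conf$support) / n,
       n = n)
}

#' Image-level (leave-one-image-out) cross-validation
#'
#' One fold per image: the classifier is trained on the superpixels of all
#' other images and tested on the held-out image, preventing within-image
#' leakage. With 10 images this is the classical 10-fold protocol where
#' each training set holds 9 images.
#'
#' @param tables Named list of per-image feature tables, each with a
#'   `class` column (at least 2 images).
#' @param spec [classifier_spec()] object.
#' @return Object of class `cv_report`: list with `per_image` (data frame
#'   of per-fold accuracy and macro F1), `mean_accuracy`, `mean_macro_f1`,
#'   `folds` (held-out image per fold, with its training images) and
#'   `spec`.
#' @export
cross_validate <- function(tables, spec = classifier_spec("random_forest")) {
  if (length(tables) < 2L) stop("cross-validation needs >= 2 images",
                                call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("image_", seq_along(tables))
  res <- vector("list", length(tables))
  folds <- vector("list", length(tables))
  for (i in seq_along(tables)) {
    train_tab <- do.call(rbind, tables[-i])
    model <- train_classifier(train_tab, spec)
    pred <- predict(model, tables[[i]])
    m <- compute_metrics(tables[[i]]$class, pred)
    res[[i]] <- data.frame(image = names(tables)[i],
                           accuracy = m$accuracy, macro_f1 = m$macro_f1,
                           weighted_f1 = m$weighted_f1,
                           n_superpixels = m$n)
    folds[[i]] <- list(test = names(tables)[i],
                       train = names(tables)[-i])
  }
  per_image <- do.call(rbind, res)
  rownames(per_image) <- NULL
  structure(list(per_image = per_image,
                 mean_accuracy = mean(per_image$accuracy),
                 mean_macro_f1 = mean(per_image$macro_f1),
                 folds = folds, spec = spec),
            class = "cv_report")
}

ENHANCEMENT_ORDER <- c("equalize", "match", "normalize", "none")

#' Compare classifiers across enhancement methods
#'
#' Runs [cross_validate()] for every (enhancement, classifier) pair and
#' tabulates mean accuracy and mean macro F1. The best pair maximizes mean
#' accuracy, with ties broken by macro F1 and then by a fixed enhancement
#' order (equalize, match, normalize, none).
#'
#' @param image_sets Named list: enhancement name -> list of per-image
#'   feature tables with classes.
#' @param specs List of [classifier_spec()] objects.
#' @return Data frame with one row per pair (`enhancement`, `family`,
#'   `mean_accuracy`, `mean_macro_f1`), ranked best first;
#'   `attr(x, "reports")` holds the underlying `cv_report`s.
#' @export
compare_grid <- function(image_sets, specs) {
  if (!length(image_sets) || !length(specs))
    stop("`image_sets` and `specs` must be non-empty", call. = FALSE)
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  rows <- list(); reports <- list()
  for (enh in names(image_sets)) {
    for (spec in specs) {
      cv <- cross_validate(image_sets[[enh]], spec)
      key <- paste(enh, spec$family, sep = ":")
      reports[[key]] <- cv
      rows[[key]] <- data.frame(enhancement = enh, family = spec$family,
                                mean_accuracy = cv$mean_accuracy,
                                mean_macro_f1 = cv$mean_macro_f1)
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  enh_rank <- match(grid$enhancement, ENHANCEMENT_ORDER,
                    nomatch = length(ENHANCEMENT_ORDER) + 1L)
  o <- order(-grid$mean_accuracy, -grid$mean_macro_f1, enh_rank)
  grid <- grid[o, , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "reports") <- reports
  grid
}
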