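test_that("metrics match hand-computed binary counts", {
  # class "a": TP=8, FP=2, FN=2 -> PPV = TPR = F1 = 0.8
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), "b", "b", "a", "a", rep("b", 8))
  m <- compute_metrics(truth, pred)
  a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(a$PPV, 0.8)
  expect_equal(a$TPR, 0.8)
  expect_equal(a$F1, 0.8)
  expect_equal(m$accuracy, 16 / 20)
})

test_that("perfect and degenerate predictions hit the F1 extremes", {
  truth <- c(0, 2, 3, 0, 2, 3)
  m <- compute_metrics(truth, truth)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$F1 == 1))
  expect_equal(m$macro_f1, 1)
  pred <- c(2, 3, 0, 2, 3, 0)   # every case wrong
  m2 <- compute_metrics(truth, pred)
  expect_equal(m2$accuracy, 0)
  expect_true(all(m2$per_class$F1 == 0))
})

test_that("metrics equal the brute-force oracle on random 3-class vectors", {
  set.seed(51)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    truth <- sample(c(0L, 2L, 3L), n, TRUE)
    pred <- sample(c(0L, 2L, 3L), n, TRUE)
    got <- compute_metrics(truth, pred)
    want <- oracle_metrics(truth, pred)
    expect_identical(got$accuracy, want$accuracy)
    expect_identical(got$macro_f1, want$macro_f1)
    for (cl in names(want$per_class)) {
      row <- got$confusion[got$confusion$class == as.integer(cl), ]
      expect_equal(unname(unlist(row[c("TP", "FP", "FN", "TN")])),
                   unname(want$per_class[[cl]][c("TP", "FP", "FN", "TN")]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("confusion counts satisfy the structural identities", {
  set.seed(52)
  truth <- sample(c(0L, 2L, 3L), 60, TRUE)
  pred <- sample(c(0L, 2L, 3L), 60, TRUE)
  m <- compute_metrics(truth, pred)
  expect_true(all(m$confusion$TP + m$confusion$FP + m$confusion$FN +
                    m$confusion$TN == m$n))
  expect_equal(m$confusion$TP + m$confusion$FN, m$confusion$support)
  expect_equal(sum(m$confusion$support), m$n)
  expect_equal(sum(m$confusion$TP), sum(truth == pred))
})

test_that("accuracy and macro F1 are invariant to class relabeling", {
  set.seed(53)
  truth <- sample(c(0L, 2L, 3L), 50, TRUE)
  pred <- sample(c(0L, 2L, 3L), 50, TRUE)
  perm <- c(`0` = 3L, `2` = 0L, `3` = 2L)
  m1 <- compute_metrics(truth, pred)
  m2 <- compute_metrics(perm[as.character(truth)], perm[as.character(pred)])
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$macro_f1, m2$macro_f1)
})

test_that("metrics reject malformed inputs", {
  expect_error(compute_metrics(1:3, 1:4), "equal length")
  expect_error(compute_metrics(integer(0), integer(0)), "non-empty")
})

test_that("every classifier family separates well-separated classes", {
  tab <- make_feature_table(n_per_class = 30, seed = 61, shift = 4)
  for (fam in c("random_forest", "svm", "logit_boost", "c45_tree",
                "bayes_net")) {
    model <- train_classifier(tab, classifier_spec(fam, seed = 1))
    pred <- predict(model, tab)
    acc <- mean(pred == tab$class)
    expect_gte(acc, 0.99)
  }
})

test_that("training is deterministic given the seed", {
  tab <- make_feature_table(n_per_class = 25, seed = 62, shift = 1)
  for (fam in c("random_forest", "logit_boost")) {
    m1 <- train_classifier(tab, classifier_spec(fam, seed = 9))
    m2 <- train_classifier(tab, classifier_spec(fam, seed = 9))
    expect_identical(predict(m1, tab), predict(m2, tab))
  }
})

test_that("degenerate training tables are rejected", {
  tab <- make_feature_table(n_per_class = 10, seed = 63)
  single <- tab[tab$class == 2L, ]
  expect_error(train_classifier(single, classifier_spec("random_forest")),
               "single class")
  bad <- tab
  bad$R_mean[3] <- NaN
  expect_error(train_classifier(bad, classifier_spec("random_forest")),
               "non-finite")
})

test_that("identifier columns are not used as predictors", {
  # class perfectly encoded in superpixel_id ordering but features pure
  # noise: a classifier that saw the id would be perfect, one that does
  # not stays near chance
  tab <- make_feature_table(n_per_class = 40, seed = 64, shift = 0)
  tab <- tab[order(tab$class), ]
  tab$superpixel_id <- seq_len(nrow(tab))
  tab$row <- as.numeric(tab$class) * 100
  model <- train_classifier(tab, classifier_spec("c45_tree", seed = 2))
  acc <- mean(predict(model, tab) == tab$class)
  expect_lt(acc, 0.85)
})

test_that("cross-validation builds one fold per image training on the rest", {
  tabs <- lapply(1:10, function(i)
    make_feature_table(n_per_class = 8, seed = 70 + i,
                       image_id = paste0("img", i)))
  names(tabs) <- paste0("img", 1:10)
  cv <- cross_validate(tabs, classifier_spec("c45_tree", seed = 1))
  expect_equal(nrow(cv$per_image), 10L)
  expect_length(cv$folds, 10L)
  for (i in 1:10) {
    expect_equal(cv$folds[[i]]$test, paste0("img", i))
    expect_length(cv$folds[[i]]$train, 9L)
    expect_false(cv$folds[[i]]$test %in% cv$folds[[i]]$train)
  }
  expect_equal(cv$mean_accuracy, mean(cv$per_image$accuracy))
  expect_equal(cv$mean_macro_f1, mean(cv$per_image$macro_f1))
})

test_that("two identical separable images cross-validate near perfectly", {
  tabs <- list(a = make_feature_table(n_per_class = 25, seed = 81, shift = 4),
               b = make_feature_table(n_per_class = 25, seed = 81, shift = 4))
  cv <- cross_validate(tabs, classifier_spec("random_forest", seed = 5))
  expect_true(all(cv$per_image$accuracy >= 0.99))
})

test_that("cross-validation requires at least two images", {
  expect_error(cross_validate(list(a = make_feature_table(5, 1))), ">= 2")
})

test_that("the comparison grid enumerates pairs and demotes shuffled labels", {
  sets <- list(
    equalize = list(a = make_feature_table(12, seed = 91, shift = 4),
                    b = make_feature_table(12, seed = 92, shift = 4)),
    normalize = list(a = make_feature_table(12, seed = 93, shift = 4),
                     b = make_feature_table(12, seed = 94, shift = 4)),
    match = list(a = make_feature_table(12, seed = 95, shift = 4,
                                        shuffle_classes = TRUE),
                 b = make_feature_table(12, seed = 96, shift = 4,
                                        shuffle_classes = TRUE)))
  specs <- lapply(c("c45_tree", "bayes_net"), classifier_spec, seed = 1)
  grid <- compare_grid(sets, specs)
  expect_equal(nrow(grid), 6L)
  expect_setequal(grid$enhancement, c("equalize", "normalize", "match"))
  # the label-shuffled set can never rank first
  expect_false(grid$enhancement[1] == "match")
  best <- select_best(grid)
  expect_true(best$enhancement %in% c("equalize", "normalize"))
})

test_that("best-pair selection breaks ties by F1 then enhancement order", {
  grid <- data.frame(
    enhancement = c("normalize", "equalize", "match"),
    family = c("svm", "svm", "svm"),
    mean_accuracy = c(0.9, 0.9, 0.9),
    mean_macro_f1 = c(0.80, 0.85, 0.85))
  best <- select_best(grid)
  expect_equal(best$enhancement, "equalize")  # F1 tie -> fixed order
  expect_error(select_best(grid[0, ]), "empty")
})
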