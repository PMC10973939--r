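make_labeled <- function(n_pos, n_neg, seed = 1) {
  generate_dataset(tiny_generator(n_pos, n_neg, seed = seed))
}

test_that("stratified 8:2 split reproduces the benchmark arithmetic", {
  recs <- make_labeled(859, 859, seed = 2)
  sp <- dataset_split(recs, test_fraction = 0.2, seed = 7)
  expect_identical(unname(sp$counts["train", ]), c(688L, 688L))
  expect_identical(unname(sp$counts["test", ]), c(171L, 171L))
  expect_identical(nrow(sp$train), 1376L)
  expect_identical(nrow(sp$test), 342L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
})

test_that("split is seed-deterministic and per-class floor-rounded", {
  recs <- make_labeled(10, 10, seed = 3)
  sp <- dataset_split(recs, 0.2, seed = 5)
  expect_identical(unname(sp$counts["train", ]), c(8L, 8L))
  expect_identical(unname(sp$counts["test", ]), c(2L, 2L))
  sp2 <- dataset_split(recs, 0.2, seed = 5)
  expect_identical(sp$test$id, sp2$test$id)
  sp3 <- dataset_split(recs, 0.2, seed = 6)
  expect_false(identical(sp$test$id, sp3$test$id))
  one_class <- recs[recs$label == 1, ]
  expect_error(dataset_split(one_class, 0.2, 1), "both classes")
})

test_that("k-fold indices partition, balance and stratify", {
  labels <- c(rep(1L, 5), rep(0L, 5))
  folds <- kfold_indices(labels, k = 5, seed = 1)
  val <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(val) == 2L))
  expect_identical(sort(unlist(val)), 1:10)
  for (f in folds)
    expect_identical(sort(c(f$train, f$validation)), 1:10)
  # stratification on a larger unbalanced-fold-prone case
  labels2 <- c(rep(1L, 31), rep(0L, 29))
  folds2 <- kfold_indices(labels2, k = 5, seed = 2)
  sizes <- lengths(lapply(folds2, `[[`, "validation"))
  expect_lte(diff(range(sizes)), 1L)
  global_ratio <- 31 / 60
  for (f in folds2) {
    nv <- length(f$validation)
    npos <- sum(labels2[f$validation] == 1)
    expect_lte(abs(npos - global_ratio * nv), 1)
  }
  expect_error(kfold_indices(c(1L, 0L), k = 5), "cannot make")
})

test_that("metrics match hand-computed confusion arithmetic", {
  perfect <- compute_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$Sn, 1)
  expect_equal(perfect$Sp, 1)
  expect_equal(perfect$MCC, 1)

  m <- compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$ACC, 0.7)
  expect_equal(m$Sn, 0.6)
  expect_equal(m$Sp, 0.8)
  expect_equal(m$MCC, 10 / sqrt(600))

  # degenerate: everything predicted positive on balanced data
  deg <- compute_metrics(list(tp = 5, tn = 0, fp = 5, fn = 0))
  expect_equal(deg$Sn, 1)
  expect_equal(deg$Sp, 0)
  expect_equal(deg$MCC, 0)
  expect_true("MCC" %in% deg$undefined)

  # zero-denominator sensitivity is flagged, not silently zero
  nd <- compute_metrics(list(tp = 0, tn = 4, fp = 1, fn = 0))
  expect_true(is.na(nd$Sn))
  expect_true("Sn" %in% nd$undefined)
})

test_that("compute_metrics agrees with an independent tally of predictions", {
  set.seed(71)
  for (rep in 1:5) {
    actual <- rbinom(40, 1, 0.5)
    predicted <- rbinom(40, 1, 0.5)
    cc <- confusion_counts(predicted, actual)
    expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 40L)
    m <- compute_metrics(cc)
    expect_equal(m$ACC, mean(predicted == actual))
    tab <- table(factor(predicted, 0:1), factor(actual, 0:1))
    expect_identical(cc$tp, tab["1", "1"][[1]])
    expect_identical(cc$tn, tab["0", "0"][[1]])
  }
})

test_that("MCC is symmetric under swapping the class convention", {
  set.seed(72)
  for (rep in 1:10) {
    c4 <- as.list(sample(0:20, 4, replace = TRUE))
    names(c4) <- c("tp", "tn", "fp", "fn")
    swapped <- list(tp = c4$tn, tn = c4$tp, fp = c4$fn, fn = c4$fp)
    expect_equal(compute_metrics(c4)$MCC, compute_metrics(swapped)$MCC)
  }
})

test_that("AUC equals exhaustive pair counting and has forced extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(73)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)  # force ties sometimes
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(scores, labels)$auc, mean(pairs))
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(74)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qlogis(scores), labels)$auc, base)
  expect_equal(roc_auc(scores^3, labels)$auc, base)
})

test_that("AUC and ROC agree with an independent package implementation", {
  library(pROC)
  set.seed(75)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  ours <- roc_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
  expect_equal(ours$curve$fpr[1], 0)
  expect_equal(ours$curve$tpr[1], 0)
  expect_equal(tail(ours$curve$fpr, 1), 1)
  expect_equal(tail(ours$curve$tpr, 1), 1)
  expect_true(all(diff(ours$curve$fpr) >= 0))
  expect_true(all(diff(ours$curve$tpr) >= 0))
})

test_that("training is seed-reproducible and evaluation is consistent on balanced data", {
  recs <- make_labeled(30, 30, seed = 8)
  mc <- tiny_model_config(seed = 2)
  tc <- train_config(epochs = 2, batch_size = 16, folds = 5, seed = 9)
  fit1 <- train_model(recs, mc, tc)
  fit2 <- train_model(recs, mc, tc)
  expect_identical(sapply(fit1$fold_metrics, `[[`, "ACC"),
                   sapply(fit2$fold_metrics, `[[`, "ACC"))
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(nrow(fit1$cv_summary), 5L)
  # on an exactly balanced test set ACC = (Sn + Sp) / 2
  ev <- evaluate_model(fit1$model, recs)
  expect_equal(ev$ACC, (ev$Sn + ev$Sp) / 2, tolerance = 1e-12)
  expect_false(is.null(ev$AUC))
})

test_that("randomly permuted labels give near-chance fold AUC", {
  recs <- make_labeled(100, 100, seed = 10)
  set.seed(11)
  recs$label <- sample(recs$label)
  mc <- tiny_model_config(seed = 2)
  tc <- train_config(epochs = 2, batch_size = 32, folds = 5, seed = 12)
  fit <- train_model(recs, mc, tc)
  aucs <- sapply(fit$fold_metrics, `[[`, "AUC")
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("metrics report files are written with all five metrics", {
  m <- metrics <- compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
  m$AUC <- 0.9
  m$roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  path <- tempfile(fileext = ".txt")
  write_metrics_report(m, path, extra = list(seed = 42))
  lines <- readLines(path)
  for (key in c("ACC", "Sn", "Sp", "MCC", "AUC", "seed", "tp"))
    expect_true(any(startsWith(lines, paste0(key, ":"))),
                label = paste("report contains", key))
  expect_true(file.exists(paste0(tools::file_path_sans_ext(path),
                                 ".roc.tsv")))
})
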