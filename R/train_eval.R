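# Dataset splitting, five-fold cross-validation training, and the metric
# suite (ACC, Sn, Sp, MCC, AUC/ROC).

#' Training configuration
#'
#' @param epochs Training epochs per fit, default 30.
#' @param lr Adam learning rate, default 1e-3.
#' @param batch_size Minibatch size, default 64.
#' @param folds Cross-validation folds, default 5.
#' @param seed Seed governing shuffling, fold assignment, dropout masks.
#' @param loss Loss name; only \code{"cross_entropy"} is implemented
#'   (softmax output implies it).
#' @return List of class \code{train_config}.
#' @export
train_config <- function(epochs = 30L, lr = 1e-3, batch_size = 64L,
                         folds = 5L, seed = 1L, loss = "cross_entropy") {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!identical(loss, "cross_entropy"))
    stop("unsupported loss: ", loss)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds), seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Splits a labeled dataset per class: each class contributes exactly
#' \code{floor(test_fraction * class size)} records to the test set, so
#' 859 + 859 records at fraction 0.2 give 688/688 training and 171/171
#' test records.  Membership is governed entirely by the seed.
#'
#' @param records Labeled peptide data.frame.
#' @param test_fraction Fraction held out, default 0.2.
#' @param seed Integer seed.
#' @return List of class \code{dataset_split}: \code{train}, \code{test},
#'   \code{counts} (per class and subset), \code{test_fraction},
#'   \code{seed}.
#' @export
dataset_split <- function(records, test_fraction = 0.2, seed = 1L) {
  if (anyNA(records$label)) stop("all records must be labeled")
  classes <- sort(unique(records$label))
  if (length(classes) < 2L)
    stop("stratification requires both classes, found only: ",
         paste(classes, collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in classes) {
    idx <- which(records$label == cl)
    n_test <- floor(test_fraction * length(idx))
    test_idx <- c(test_idx, sample(idx)[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  train <- records[-test_idx, , drop = FALSE]
  test <- records[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  counts <- rbind(train = table(factor(train$label, levels = classes)),
                  test = table(factor(test$label, levels = classes)))
  structure(list(train = train, test = test, counts = counts,
                 test_fraction = test_fraction, seed = seed),
            class = "dataset_split")
}

#' Stratified k-fold indices
#'
#' Partitions record indices into k folds whose sizes differ by at most
#' one, keeping each fold's class ratio within one sample of the global
#' ratio (continuous round-robin assignment across classes).
#'
#' @param labels Binary label vector.
#' @param k Number of folds, default 5.
#' @param seed Integer seed.
#' @return List of k elements, each \code{list(train =, validation =)}.
#' @export
kfold_indices <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("cannot make ", k, " folds from ", n, " records")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  cum <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((cum + seq_along(idx) - 1L) %% k) + 1L
    cum <- cum + length(idx)
  }
  lapply(seq_len(k), function(i)
    list(train = which(fold != i), validation = which(fold == i)))
}

## ---- metrics ---------------------------------------------------------------

#' Confusion counts from predictions
#'
#' @param predicted,actual Binary vectors (1 = ACP positive class).
#' @return List of class \code{confusion_counts}: tp, tn, fp, fn.
#' @export
confusion_counts <- function(predicted, actual) {
  structure(list(tp = sum(predicted == 1 & actual == 1),
                 tn = sum(predicted == 0 & actual == 0),
                 fp = sum(predicted == 1 & actual == 0),
                 fn = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/total; Sn = TP/(TP+FN); Sp = TN/(TN+FP);
#' MCC = (TP TN - FP FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A zero denominator in Sn or Sp yields NA plus an entry in
#' \code{undefined}; a zero MCC denominator yields 0 (standard convention)
#' and is flagged likewise.
#'
#' @param counts A [confusion_counts()] or list with tp, tn, fp, fn.
#' @return List of class \code{metrics_report}: ACC, Sn, Sp, MCC,
#'   \code{counts}, \code{undefined} (character vector of flagged metrics).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated samples")
  undefined <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "Sn"); NA_real_
  }
  sp <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "Sp"); NA_real_
  }
  denom <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else {
    undefined <- c(undefined, "MCC"); 0
  }
  structure(list(ACC = (tp + tn) / total, Sn = sn, Sp = sp, MCC = mcc,
                 counts = counts, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  Sn %.4f  Sp %.4f  MCC %.4f", x$ACC, x$Sn, x$Sp,
              x$MCC))
  if (!is.null(x$AUC)) cat(sprintf("  AUC %.4f", x$AUC))
  cat("\n")
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney probability that a random positive scores above
#' a random negative, with ties counted half (computed from ranks).  The
#' curve runs monotonically from (0,0) to (1,1), one point per distinct
#' score threshold.
#'
#' @param scores Positive-class scores/probabilities.
#' @param labels Binary labels (1 = positive).
#' @return List with \code{auc} and \code{curve} (data.frame fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- cumsum(l == 1)[keep] / n1
  fpr <- cumsum(l == 0)[keep] / n0
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

# Metrics (incl. AUC) from positive-class probabilities at threshold 0.5.
metrics_from_scores <- function(scores, labels) {
  m <- compute_metrics(confusion_counts(as.integer(scores >= 0.5), labels))
  roc <- roc_auc(scores, labels)
  m$AUC <- roc$auc
  m$roc <- roc$curve
  m
}

## ---- training --------------------------------------------------------------

# One full fit of the network on encoded data.  y: binary labels; class
# index 1 = ACP, 2 = non-ACP.  Returns the trained model and epoch losses.
fit_model <- function(x, y, mconfig, tconfig, seed_offset = 0L) {
  model <- build_model(mconfig)
  opt <- adam_init(model$params)
  n <- dim(x)[1]
  yidx <- ifelse(y == 1, 1L, 2L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(tconfig$seed + seed_offset)
  losses <- numeric(tconfig$epochs)
  for (ep in seq_len(tconfig$epochs)) {
    ord <- sample(n)
    bl <- numeric(0)
    for (start in seq(1L, n, by = tconfig$batch_size)) {
      idx <- ord[start:min(start + tconfig$batch_size - 1L, n)]
      if (length(idx) < 2L) next  # batch-norm needs > 1 row
      fw <- model_forward_batch(model$params, mconfig, model$dims,
                                x[idx, , , drop = FALSE], training = TRUE)
      model$params <- fw$params
      ce <- softmax_xent(fw$logits, yidx[idx])
      if (!is.finite(ce$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      grads <- model_backward_batch(model$params, mconfig, model$dims,
                                    fw, ce$dlogits)
      step <- adam_step(model$params, grads, opt, lr = tconfig$lr)
      model$params <- step$params
      opt <- step$state
      bl <- c(bl, ce$loss)
    }
    losses[ep] <- mean(bl)
  }
  list(model = model, losses = losses)
}

#' Train with five-fold cross-validation, then retrain on everything
#'
#' Partitions the training records into stratified folds, fits one model
#' per fold and evaluates it on the held-out fold, then retrains a final
#' model on the full training set.  All randomness (fold assignment,
#' initialisation, shuffling, dropout) is governed by the two config seeds.
#'
#' @param records Labeled peptide data.frame.
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param alphabet Alphabet for encoding.
#' @param verbose Print per-fold progress.
#' @return List of class \code{acpflow_fit}: \code{model} (final, trained
#'   on all records), \code{fold_metrics} (list of metrics_report),
#'   \code{cv_summary} (mean and sd per metric across folds),
#'   \code{losses} (final-fit epoch losses).
#' @export
train_model <- function(records, mconfig = model_config(),
                        tconfig = train_config(),
                        alphabet = aa_alphabet(), verbose = FALSE) {
  if (anyNA(records$label)) stop("all training records must be labeled")
  if (length(unique(records$label)) < 2L)
    stop("training requires both classes")
  x <- encode_dataset(records, alphabet, mconfig$max_len)
  y <- records$label
  folds <- kfold_indices(y, k = tconfig$folds, seed = tconfig$seed)
  fold_metrics <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    fit <- fit_model(x[f$train, , , drop = FALSE], y[f$train],
                     mconfig, tconfig, seed_offset = i)
    scores <- model_probs(fit$model, x[f$validation, , , drop = FALSE])[, 1]
    fold_metrics[[i]] <- metrics_from_scores(scores, y[f$validation])
    if (verbose)
      message(sprintf("fold %d/%d: ACC %.3f AUC %.3f (final loss %.4f)",
                      i, length(folds), fold_metrics[[i]]$ACC,
                      fold_metrics[[i]]$AUC, tail(fit$losses, 1)))
  }
  final <- fit_model(x, y, mconfig, tconfig, seed_offset = 0L)
  vals <- sapply(fold_metrics, function(m)
    c(ACC = m$ACC, Sn = m$Sn, Sp = m$Sp, MCC = m$MCC, AUC = m$AUC))
  cv_summary <- data.frame(metric = rownames(vals),
                           mean = rowMeans(vals),
                           sd = apply(vals, 1, sd))
  rownames(cv_summary) <- NULL
  structure(list(model = final$model, fold_metrics = fold_metrics,
                 cv_summary = cv_summary, losses = final$losses),
            class = "acpflow_fit")
}

#' Evaluate a trained model on labeled records
#'
#' Thresholds the ACP probability at 0.5 (argmax) for the confusion
#' counts; AUC uses the raw probabilities.
#'
#' @param model An \code{acpflow_model}.
#' @param records Labeled peptide data.frame.
#' @param alphabet Alphabet for encoding.
#' @return \code{metrics_report} with ACC, Sn, Sp, MCC, AUC, counts and
#'   ROC curve points.
#' @export
evaluate_model <- function(model, records, alphabet = aa_alphabet()) {
  if (anyNA(records$label) || is.null(records$label))
    stop("evaluation requires labeled records")
  x <- encode_dataset(records, alphabet, model$config$max_len)
  scores <- model_probs(model, x)[, 1]
  metrics_from_scores(scores, records$label)
}

## ---- report files ----------------------------------------------------------

#' Write a metrics report as key-value lines
#'
#' @param metrics A \code{metrics_report}.
#' @param path Output path; ROC points go to \code{path} with extension
#'   \code{.roc.tsv} when a curve is present.
#' @param extra Named list of extra keys (seed, config hash, ...).
#' @export
write_metrics_report <- function(metrics, path, extra = list()) {
  kv <- c(report_version = "1",
          ACC = metrics$ACC, Sn = metrics$Sn, Sp = metrics$Sp,
          MCC = metrics$MCC)
  if (!is.null(metrics$AUC)) kv <- c(kv, AUC = metrics$AUC)
  if (!is.null(metrics$counts))
    kv <- c(kv, tp = metrics$counts$tp, tn = metrics$counts$tn,
            fp = metrics$counts$fp, fn = metrics$counts$fn)
  if (length(metrics$undefined))
    kv <- c(kv, undefined = paste(metrics$undefined, collapse = ","))
  for (k in names(extra)) kv[k] <- as.character(extra[[k]])
  writeLines(paste0(names(kv), ": ", kv), path)
  if (!is.null(metrics$roc))
    write.table(metrics$roc, paste0(tools::file_path_sans_ext(path),
                                    ".roc.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
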