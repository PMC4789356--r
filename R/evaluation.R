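#' Confusion counts for a binary prediction
#'
#' @param truth,predicted Vectors of +1/-1 labels (same length/order).
#' @return Named integer vector with elements `TP`, `FN`, `FP`, `TN`.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.numeric(truth); predicted <- as.numeric(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(-1, 1)), all(predicted %in% c(-1, 1)))
  c(TP = sum(truth == 1 & predicted == 1),
    FN = sum(truth == 1 & predicted == -1),
    FP = sum(truth == -1 & predicted == 1),
    TN = sum(truth == -1 & predicted == -1))
}

#' Threshold performance metrics from confusion counts
#'
#' Standard binary-classification measures on the percentage scale:
#' `ACC = 100 (TP+TN) / (TP+TN+FP+FN)`, `SN = 100 TP / (TP+FN)`,
#' `SP = 100 TN / (TN+FP)`, `FPR = 100 FP / (FP+TN)`, and the Matthews
#' correlation coefficient
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` in
#' \[-1, 1\]. A metric whose denominator is zero is reported as `NA` with a
#' warning, never silently as 0.
#'
#' @param counts Named vector/list with elements `TP`, `FN`, `FP`, `TN`
#'   (e.g. from [confusionCounts()]).
#' @return Named numeric vector `ACC`, `SN`, `SP`, `FPR`, `MCC`.
#' @examples
#' computeMetrics(c(TP = 90, FN = 10, FP = 20, TN = 80))
#' @export
computeMetrics <- function(counts) {
  counts <- as.list(counts)
  TP <- as.numeric(counts$TP); FN <- as.numeric(counts$FN)
  FP <- as.numeric(counts$FP); TN <- as.numeric(counts$TN)
  stopifnot(all(c(TP, FN, FP, TN) >= 0))
  total <- TP + TN + FP + FN
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- 100 * safe(TP + TN, total, "ACC")
  sn <- 100 * safe(TP, TP + FN, "SN")
  sp <- 100 * safe(TN, TN + FP, "SP")
  fpr <- 100 * safe(FP, FP + TN, "FPR")
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) {
    warning("MCC undefined (zero denominator)", call. = FALSE)
    NA_real_
  } else (TP * TN - FP * FN) / mccDen
  c(ACC = acc, SN = sn, SP = sp, FPR = fpr, MCC = mcc)
}

#' Assign examples to k cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one. With `stratifyBy`, assignment is round-robin per class
#' through a shared fold pointer, keeping both the overall fold sizes and
#' the per-class balance.
#'
#' @param ids Character vector of example ids.
#' @param k Number of folds (2 <= k <= length(ids)).
#' @param seed Integer RNG seed; the same seed reproduces the assignment.
#' @param stratifyBy Optional vector (or named map over `ids`) of class
#'   labels to stratify on.
#' @return Named integer vector of fold indices in 1..k.
#' @export
kfoldSplit <- function(ids, k, seed = 1L, stratifyBy = NULL) {
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of examples (", n, ")")
  if (anyDuplicated(ids)) stop("ids must be unique")
  fold <- setNames(integer(n), ids)
  .withSeed(seed, {
    if (is.null(stratifyBy)) {
      fold[sample(n)] <- rep_len(seq_len(k), n)
    } else {
      if (!is.null(names(stratifyBy))) stratifyBy <- stratifyBy[ids]
      stopifnot(length(stratifyBy) == n)
      ptr <- 0L
      for (cl in sort(unique(as.character(stratifyBy)))) {
        idx <- which(stratifyBy == cl)
        idx <- if (length(idx) > 1L) sample(idx) else idx
        fold[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
        ptr <- ptr + length(idx)
      }
    }
  })
  fold
}

#' k-fold cross-validation of an RBF-SVM
#'
#' Trains k models, each on k-1 folds, scores the held-out fold, and reports
#' per-fold metrics, the mean and sample standard deviation (n-1
#' denominator) of fold accuracies, and metrics on the pooled confusion
#' counts over all held-out predictions. Stratified fold assignment is the
#' default so small classes are represented in every training fold.
#'
#' @param features Numeric feature matrix with rownames (ids).
#' @param labels Vector of +1/-1 labels (aligned with rows, or named by id).
#' @param gamma,cost SVM hyperparameters, see [trainSVM()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param stratify Stratify the split by label (default TRUE).
#' @param scheme Scheme tag passed through to [trainSVM()].
#' @return A list of class `"hblCV"`: `folds` (per-fold metric data.frame),
#'   `pooled` (metrics on pooled counts), `pooledCounts`, `meanACC`,
#'   `sdACC`, `scores` (data.frame id/fold/truth/score/predicted) and
#'   `assignment`.
#' @export
crossValidate <- function(features, labels, gamma, cost, k = 5L, seed = 1L,
                          stratify = TRUE, scheme = "custom") {
  features <- as.matrix(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- as.numeric(labels)
  stopifnot(length(labels) == nrow(features))
  fold <- kfoldSplit(ids, k, seed = seed,
                     stratifyBy = if (stratify) labels else NULL)
  perFold <- vector("list", k)
  scoreTab <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(labels[train])) < 2L)
      stop("training fold ", f, " contains a single class; ",
           "use stratify = TRUE or fewer folds")
    model <- trainSVM(features[train, , drop = FALSE], labels[train],
                      gamma = gamma, cost = cost, scheme = scheme,
                      seed = seed)
    sc <- decisionScore(model, features[test, , drop = FALSE])
    pred <- ifelse(sc >= model@threshold, 1, -1)
    cc <- confusionCounts(labels[test], pred)
    perFold[[f]] <- data.frame(fold = f, t(suppressWarnings(computeMetrics(cc))),
                               check.names = FALSE)
    scoreTab[[f]] <- data.frame(id = ids[test], fold = f,
                                truth = labels[test], score = unname(sc),
                                predicted = unname(pred),
                                stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, perFold)
  scoresDf <- do.call(rbind, scoreTab)
  pooledCounts <- confusionCounts(scoresDf$truth, scoresDf$predicted)
  out <- list(folds = folds,
              pooled = suppressWarnings(computeMetrics(pooledCounts)),
              pooledCounts = pooledCounts,
              meanACC = mean(folds$ACC), sdACC = sd(folds$ACC),
              scores = scoresDf, assignment = fold,
              k = k, gamma = gamma, cost = cost, scheme = scheme)
  class(out) <- "hblCV"
  out
}

#' @export
print.hblCV <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation [%s, gamma=%g, C=%g]\n",
              x$k, x$scheme, x$gamma, x$cost))
  cat(sprintf("  pooled: ACC=%.2f SN=%.2f SP=%.2f FPR=%.2f MCC=%.3f\n",
              x$pooled["ACC"], x$pooled["SN"], x$pooled["SP"],
              x$pooled["FPR"], x$pooled["MCC"]))
  cat(sprintf("  fold accuracy: %.2f +/- %.2f\n", x$meanACC, x$sdACC))
  invisible(x)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps all distinct decision-score thresholds in descending order,
#' emitting one (FPR, TPR) point per threshold (plus the (0,0) and (1,1)
#' endpoints), and integrates by the trapezoidal rule. With ties handled by
#' the sweep, the AUC equals the tie-corrected normalized Mann-Whitney U
#' statistic.
#'
#' @param scoresPos Decision scores, higher meaning more positive.
#' @param truth Vector of +1/-1 true labels aligned with `scoresPos`.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc` in \[0, 1\].
#' @examples
#' rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc
#' @export
rocAuc <- function(scoresPos, truth) {
  truth <- as.numeric(truth)
  stopifnot(length(scoresPos) == length(truth), all(truth %in% c(-1, 1)))
  nPos <- sum(truth == 1); nNeg <- sum(truth == -1)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC requires scores from both classes")
  thr <- sort(unique(scoresPos), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scoresPos >= t & truth == 1), 0) / nPos
  fpr <- vapply(thr, function(t) sum(scoresPos >= t & truth == -1), 0) / nNeg
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Multiclass confusion matrix
#'
#' Tabulates actual versus predicted class over a shared id set; per-class
#' sensitivities are the diagonal over the row sums.
#'
#' @param truth,predicted Named character vectors mapping id to class; the
#'   id sets must be identical.
#' @return Square integer matrix, rows = actual class, columns = predicted
#'   class, over the union of observed classes.
#' @export
multiclassConfusion <- function(truth, predicted) {
  if (!length(truth)) stop("empty input: no classifications to tabulate")
  if (is.null(names(truth)) || is.null(names(predicted)))
    stop("truth and predicted must be named by example id")
  if (!setequal(names(truth), names(predicted)))
    stop("truth and predicted must cover the same ids")
  predicted <- predicted[names(truth)]
  lev <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.integer(tab), nrow = length(lev),
              dimnames = list(actual = lev, predicted = lev))
  m
}

#' Write a metrics report as TSV
#'
#' One row per entry of a named list of metric vectors (as produced by
#' [computeMetrics()] or taken from an `hblCV` object), with the standard
#' report columns ACC, SN, SP, FPR, MCC plus any hyperparameters supplied.
#'
#' @param metrics Named list (or single named vector) of metric vectors.
#' @param path Output path.
#' @param extra Optional data.frame of extra columns (e.g. gamma, C).
#' @return `path`, invisibly.
#' @export
writeMetricsTSV <- function(metrics, path, extra = NULL) {
  if (!is.list(metrics)) metrics <- list(metrics = metrics)
  df <- data.frame(name = names(metrics),
                   do.call(rbind, lapply(metrics, function(m)
                     as.data.frame(t(m)))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
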