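#' Classification and regression metrics
#'
#' Binary classification: F1 of the positive class, ROC AUC from continuous
#' scores (rank statistic with tie correction), balanced accuracy (mean of
#' the two recalls) and accuracy. Multiclass: per-class one-vs-rest F1,
#' macro F1, accuracy, balanced accuracy (mean per-class recall), and — with
#' a flag, since it is an extension — macro one-vs-rest AUC when a score
#' matrix is given. Regression: RMSE. Zero-denominator precision/recall/F1
#' are defined as 0.
#'
#' @param y_true observed labels or values.
#' @param y_pred predicted labels or values.
#' @param y_score scores for AUC: vector (binary, higher = more positive)
#'   or matrix with one column per class (multiclass).
#' @param kind "binary", "multiclass" or "regression".
#' @param positive positive-class label for binary tasks (default: second
#'   factor level).
#' @return named list of metrics.
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL,
                            kind = c("binary", "multiclass", "regression"),
                            positive = NULL) {
  kind <- match.arg(kind)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  if (kind == "regression") {
    return(list(rmse = sqrt(mean((as.numeric(y_true) - as.numeric(y_pred))^2))))
  }
  y_true <- as.factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  if (kind == "binary") {
    if (nlevels(y_true) != 2L) stop("binary metrics need exactly two classes in y_true")
    if (is.null(positive)) positive <- levels(y_true)[2L]
    pos <- y_true == positive
    pred_pos <- y_pred == positive
    tp <- sum(pos & pred_pos)
    fp <- sum(!pos & pred_pos)
    fn <- sum(pos & !pred_pos)
    tn <- sum(!pos & !pred_pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    out <- list(
      f1 = f1,
      auc = if (is.null(y_score)) NA_real_ else roc_auc(pos, y_score),
      balanced_accuracy = (rec + spec) / 2,
      accuracy = (tp + tn) / length(y_true),
      precision = prec, recall = rec,
      confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)
    )
    return(out)
  }
  # multiclass
  lev <- levels(y_true)
  per_class_f1 <- vapply(lev, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  recalls <- vapply(lev, function(cl) {
    nc <- sum(y_true == cl)
    if (nc > 0) sum(y_true == cl & y_pred == cl) / nc else NA_real_
  }, numeric(1))
  auc <- NA_real_
  if (!is.null(y_score) && is.matrix(y_score) && !is.null(colnames(y_score))) {
    aucs <- vapply(lev, function(cl) {
      if (!cl %in% colnames(y_score)) return(NA_real_)
      roc_auc(y_true == cl, y_score[, cl])
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
  }
  list(
    f1 = mean(per_class_f1), # macro
    per_class_f1 = per_class_f1,
    auc = auc, auc_flag = "macro one-vs-rest (extension)",
    balanced_accuracy = mean(recalls, na.rm = TRUE),
    accuracy = mean(y_true == y_pred),
    confusion = table(observed = y_true, predicted = y_pred)
  )
}

#' ROC AUC from scores (rank statistic)
#'
#' Mann-Whitney formulation with midranks, so ties in the scores are
#' handled exactly.
#'
#' @param is_pos logical vector of positive-class membership.
#' @param score numeric scores, higher meaning more positive.
#' @return AUC in (0, 1), or NA if a class is absent.
#' @export
roc_auc <- function(is_pos, score) {
  is_pos <- as.logical(is_pos)
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
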