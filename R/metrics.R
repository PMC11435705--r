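#' Classification metrics: accuracy, precision, recall
#'
#' Computes accuracy, precision and recall as percentages from predicted
#' and true labels. For more than two classes, precision and recall are
#' computed one-vs-rest per class from the binary confusion counts
#' (TP, FP, FN, TN) and then averaged: macro-averaging by default, with
#' micro-averaged values also reported. Classes absent from both
#' prediction and truth are excluded from the macro average; a class with
#' no predicted positives contributes precision 0.
#'
#' @param pred integer vector of predicted class ids.
#' @param truth integer vector of true class ids, same length.
#' @param average `"macro"` (default) or `"micro"`: which average the
#'   `precision`/`recall` fields report; both are always present as
#'   `precision_macro` etc.
#' @return a named list: `accuracy`, `precision`, `recall`,
#'   `precision_macro`, `recall_macro`, `precision_micro`,
#'   `recall_micro`, all in percent.
#' @examples
#' classification_metrics(c(0, 1, 1, 0), c(0, 1, 0, 0))
#' @export
classification_metrics <- function(pred, truth, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (length(pred) == 0L || length(truth) == 0L)
    stop_("empty label vectors")
  if (length(pred) != length(truth))
    stop_("`pred` and `truth` have different lengths")
  classes <- sort(unique(c(pred, truth)))
  n <- length(pred)
  acc <- mean(pred == truth) * 100
  tp <- fp <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    c <- classes[i]
    tp[i] <- sum(pred == c & truth == c)
    fp[i] <- sum(pred == c & truth != c)
    fn[i] <- sum(pred != c & truth == c)
  }
  prec_c <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  out <- list(
    accuracy = acc,
    precision_macro = mean(prec_c) * 100,
    recall_macro = mean(rec_c) * 100,
    precision_micro = sum(tp) / max(sum(tp + fp), 1) * 100,
    recall_micro = sum(tp) / max(sum(tp + fn), 1) * 100)
  out$precision <- if (average == "macro") out$precision_macro else out$precision_micro
  out$recall <- if (average == "macro") out$recall_macro else out$recall_micro
  out[c("accuracy", "precision", "recall", "precision_macro", "recall_macro",
        "precision_micro", "recall_micro")]
}

#' Learning-rate schedule
#'
#' Exponential step decay: the learning rate starts at `lr0` and is
#' multiplied by `decay` every two epochs,
#' `lr(e) = lr0 * decay^floor(e / 2)` with `e` the 0-based epoch index.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param lr0 initial learning rate.
#' @param decay multiplicative decay per two epochs (default 0.95).
#' @return learning rate(s).
#' @export
lr_schedule <- function(epoch, lr0, decay = 0.95) {
  lr0 * decay^(epoch %/% 2)
}
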