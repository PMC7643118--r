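# Classifier performance metrics: ROC / precision-recall areas and the
# F1-versus-cutoff curve.

.roc_points <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # collapse ties so each distinct score contributes one operating point
  keep <- c(diff(scores[o]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)))
}

.trapezoid_auc <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

.auroc <- function(scores, positive) {
  pts <- .roc_points(scores, positive)
  .trapezoid_auc(pts$fpr, pts$tpr)
}

.avg_precision <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  prec <- cumsum(pos) / seq_along(pos)
  # ties: every member of a tied block gets the block-end precision
  r <- rev(scores[o])
  block_end <- length(pos) + 1 - match(scores[o], r)  # last index of tie block
  sum((cumsum(pos) / seq_along(pos))[block_end][pos]) / sum(positive)
}

.f1_curve <- function(scores, positive, cutoffs = seq(0, 1, by = 0.01)) {
  f1 <- vapply(cutoffs, function(ct) {
    call <- scores >= ct
    tp <- sum(call & positive)
    if (tp == 0) return(0)
    prec <- tp / sum(call)
    rec <- tp / sum(positive)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  data.frame(cutoff = cutoffs, f1 = f1)
}

.binary_metrics <- function(scores, positive) {
  list(auroc = .auroc(scores, positive),
       auprc = .avg_precision(scores, positive),
       f1 = .f1_curve(scores, positive),
       n_pos = sum(positive), n_neg = sum(!positive))
}

#' Evaluate HRD predictions against genetic truth labels
#'
#' Computes AUROC (trapezoidal integration of the ROC curve), AUPRC
#' (average precision) and the F1-score-versus-cutoff curve for each
#' prediction class: HRD as a whole (positive = BRCA1- or BRCA2-deficient,
#' scored by `p_hrd`), BRCA1-type (scored by `p_brca1`) and BRCA2-type
#' (scored by `p_brca2`).
#'
#' @param predictions `data.frame` from [predict.hrdforest()] (columns
#'   `p_brca1`, `p_brca2`, `p_hrd`).
#' @param truth Factor/character of genetic labels (`"BRCA1"`, `"BRCA2"`,
#'   `"none"`), one per prediction row.
#' @return List of class `hrd_evaluation` with one metric set per prediction
#'   class (a subtype class with no positive samples is reported as `NULL`).
#' @export
evaluate_predictions <- function(predictions, truth) {
  truth <- as.character(truth)
  if (nrow(predictions) != length(truth)) {
    stop("predictions and truth have different lengths")
  }
  hrd_pos <- truth %in% c("BRCA1", "BRCA2")
  if (all(hrd_pos) || !any(hrd_pos)) {
    stop("truth contains a single class; metrics are undefined")
  }
  out <- list(
    HRD = .binary_metrics(predictions$p_hrd, hrd_pos),
    `BRCA1-type` = if (any(truth == "BRCA1")) {
      .binary_metrics(predictions$p_brca1, truth == "BRCA1")
    },
    `BRCA2-type` = if (any(truth == "BRCA2")) {
      .binary_metrics(predictions$p_brca2, truth == "BRCA2")
    }
  )
  class(out) <- "hrd_evaluation"
  out
}

#' @export
print.hrd_evaluation <- function(x, ...) {
  cat("Prediction performance\n")
  for (nm in names(x)) {
    m <- x[[nm]]
    if (is.null(m)) next
    best <- m$f1[which.max(m$f1$f1), ]
    cat(sprintf("  %-11s AUROC %.3f  AUPRC %.3f  max F1 %.3f @ cutoff %.2f (%d+/%d-)\n",
                nm, m$auroc, m$auprc, best$f1, best$cutoff, m$n_pos, m$n_neg))
  }
  invisible(x)
}
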