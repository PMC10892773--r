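#' Multiclass evaluation metrics
#'
#' Accuracy = correct / total; per-class precision, recall and F1 from
#' one-vs-rest tallies (precision = TP / (TP + FP), recall = TP /
#' (TP + FN), F1 = 2 PR / (P + R)); the summary averages are weighted by
#' class support in the true labels.  With weighted averaging, recall is
#' identically equal to accuracy in the multiclass case — the package
#' asserts this identity in its tests.  A class that is never predicted
#' gets precision 0 with a warning; a class absent from the true labels
#' contributes weight 0.
#'
#' @param true,pred equal-length integer label vectors (classes 0-3).
#' @param classes class set; default `0:3`.
#' @return list with `accuracy`, `weighted` (precision/recall/f1),
#'   `per_class` data.frame and the confusion matrix.
#' @export
compute_metrics <- function(true, pred, classes = 0:3) {
  if (length(true) != length(pred) || length(true) == 0)
    pd_stop("true and pred must be equal-length and non-empty",
            "pdmil_error_length_mismatch")
  true <- as.integer(true); pred <- as.integer(pred)
  conf <- table(factor(true, levels = classes),
                factor(pred, levels = classes))
  tp <- diag(conf)
  support <- rowSums(conf)
  predicted <- colSums(conf)
  prec <- rep(0, length(classes))
  nonzero <- predicted > 0
  prec[nonzero] <- tp[nonzero] / predicted[nonzero]
  if (any(!nonzero & support > 0))
    pd_warn("class never predicted: precision set to 0",
            "pdmil_warning_zero_division")
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  list(accuracy = sum(tp) / length(true),
       weighted = c(precision = sum(w * prec), recall = sum(w * rec),
                    f1 = sum(w * f1)),
       per_class = data.frame(class = classes, support = as.integer(support),
                              precision = as.numeric(prec),
                              recall = as.numeric(rec),
                              f1 = as.numeric(f1)),
       confusion = conf)
}
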