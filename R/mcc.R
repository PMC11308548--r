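#' Matthews correlation coefficient from a confusion matrix
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).  When any
#' factor of the denominator is zero the coefficient is defined as 0, the
#' usual convention for degenerate confusion tables.  Equivalent to the
#' Pearson correlation of the binary truth and prediction vectors; robust
#' under class imbalance, which is why it drives model selection here.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A number in \[-1, 1\].
#' @export
compute_mcc <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopf(all(counts >= 0), "negative confusion count")
  stopf(sum(counts) > 0, "empty confusion matrix")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

# Confusion counts of two binary vectors.
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  c(
    tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0),
    tn = sum(truth == 0 & pred == 0)
  )
}

# MCC of binary truth/prediction vectors.
mcc_vec <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  compute_mcc(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]])
}
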