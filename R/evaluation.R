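# AUCPR-based model evaluation.

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: scores are swept over descending unique
#' thresholds (ties grouped at one threshold) and
#' `sum_i (R_i - R_{i-1}) * P_i` accumulated, the convention of standard
#' machine-learning toolkits (no trapezoidal interpolation).
#'
#' @param labels binary vector (at least one positive and one negative).
#' @param scores numeric vector of the same length.
#' @return AUCPR in \[0, 1\].
#' @export
aucpr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (all(labels == 1L) || all(labels == 0L))
    stop("single-class labels: AUCPR undefined")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # group tied scores at one threshold
  grp <- cumsum(!duplicated(sc))
  tp_g <- tapply(lab, grp, sum)
  n_g <- tapply(lab, grp, length)
  tp <- cumsum(tp_g)
  np <- cumsum(n_g)
  P <- sum(labels)
  recall <- tp / P
  precision <- tp / np
  sum((recall - c(0, head(recall, -1))) * precision)
}

#' Per-TF AUCPR from a multi-task model's output node
#'
#' Scores a test batch with the multi-task model and computes the AUCPR of
#' the output node corresponding to one TF against that task's labels.
#'
#' @param multi_model a multi-task `tftl_model`.
#' @param test data.frame with `sequence` and a label matrix in
#'   `attr(, "labels")` (e.g., the `test` element of a `tftl_split`).
#' @param tf_index output-node index (column of the label matrix).
#' @return AUCPR, or `NA` when the task's test labels are single-class.
#' @export
multimodel_tf_aucpr <- function(multi_model, test, tf_index) {
  lab <- split_labels(test)
  stopifnot(tf_index >= 1, tf_index <= ncol(lab))
  p <- predict(multi_model, test$sequence)
  y <- lab[, tf_index]
  if (all(y == 1) || all(y == 0)) return(NA_real_)
  aucpr(y, p[, tf_index])
}

#' Evaluate a single-task model on a test partition
#'
#' @param model a single-output `tftl_model`.
#' @param test data.frame with `sequence` and labels as in
#'   [multimodel_tf_aucpr()].
#' @return AUCPR.
#' @export
evaluate_model <- function(model, test) {
  y <- split_labels(test)[, 1]
  p <- predict(model, test$sequence)[, 1]
  aucpr(y, p)
}

#' Assemble a performance table
#'
#' @param records list of named lists/rows with fields `tf`, `condition`
#'   (`scratch`, `tl`, `multi_model` or `pwm_baseline`), `aucpr`, and
#'   optionally `seed`.
#' @return data.frame with a `delta_aucpr` column added per (tf, seed)
#'   where both `tl` and `scratch` are present.
#' @export
performance_table <- function(records) {
  df <- do.call(rbind, lapply(records, as.data.frame))
  if (!"seed" %in% names(df)) df$seed <- NA_integer_
  df$delta_aucpr <- NA_real_
  for (i in which(df$condition == "tl")) {
    j <- which(df$tf == df$tf[i] & df$condition == "scratch" &
                 (is.na(df$seed[i]) | df$seed == df$seed[i]))
    if (length(j)) df$delta_aucpr[i] <- df$aucpr[i] - df$aucpr[j[1]]
  }
  df
}
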