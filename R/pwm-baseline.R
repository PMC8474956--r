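# PWM occupancy-score baseline classifier.

#' Sum-occupancy score of a PWM on a sequence
#'
#' Slides the probability-form PWM along the forward and reverse-complement
#' strands and sums, over all windows, the product of the per-position
#' probabilities of the observed bases. Returns 0 when the sequence is
#' shorter than the motif.
#'
#' @param pwm 4 x W probability matrix (rows A, C, G, T).
#' @param sequence string over A/C/G/T.
#' @return non-negative occupancy score.
#' @export
sum_occupancy <- function(pwm, sequence) {
  W <- ncol(pwm)
  L <- nchar(sequence)
  if (L < W) return(0)
  scan <- function(seq) {
    codes <- as.integer(cpp_seq_to_codes(seq)) + 1L
    n <- L - W + 1L
    s <- rep(1, n)
    for (i in seq_len(W)) s <- s * pwm[cbind(codes[i:(i + n - 1L)], i)]
    sum(s)
  }
  scan(sequence) + scan(reverse_complement(sequence))
}

#' Reverse complement of a PWM
#'
#' @param pwm 4 x W matrix (rows A, C, G, T).
#' @return the column-reversed, base-complemented matrix.
#' @export
reverse_complement_pwm <- function(pwm) {
  pwm[c(4, 3, 2, 1), rev(seq_len(ncol(pwm))), drop = FALSE]
}

#' Evaluate a PWM as an occupancy-score classifier
#'
#' @param pwm 4 x W probability matrix.
#' @param test data.frame with `sequence` and labels (as in
#'   [evaluate_model()]).
#' @param tf optional TF identifier recorded in the result.
#' @return one-row data.frame (`tf`, `condition = "pwm_baseline"`,
#'   `aucpr`).
#' @export
evaluate_pwm <- function(pwm, test, tf = NA_character_) {
  y <- split_labels(test)[, 1]
  s <- vapply(test$sequence, function(q) sum_occupancy(pwm, q), numeric(1))
  data.frame(tf = tf, condition = "pwm_baseline", aucpr = aucpr(y, s))
}
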