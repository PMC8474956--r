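# Model interpretation: converting first-layer filters to motifs,
# quantifying filter influence by silencing, and per-nucleotide
# attribution with reference sequences.

first_relu_name <- function(model) {
  nm <- names(model$layers)
  nm[which(vapply(model$layers, `[[`, "", "type") == "relu")[1]]
}

# activation map of the first convolutional block (post-ReLU), eval mode;
# returns list(act = (F*L) x B, F, L, K)
filter_activations <- function(model, batch) {
  x <- encode_input(model, batch)
  stopnm <- first_relu_name(model)
  for (l in model$layers) {
    x <- layer_forward(l, x, training = FALSE)$out
    if (identical(l$name, stopnm)) break
  }
  conv <- model$layers$conv1
  list(act = x, F = conv$F, L = conv$L, K = conv$K)
}

#' Sequences of a test set the model predicts correctly
#'
#' A region counts as correctly predicted when the predicted probability is
#' >= 0.5 for a bound region or < 0.5 for an unbound one.
#'
#' @param model a single-task `tftl_model`.
#' @param test data.frame with `sequence` and labels.
#' @param task_index output node used for multi-task models (default 1).
#' @return character vector of correctly predicted sequences.
#' @export
correctly_predicted <- function(model, test, task_index = 1L) {
  y <- split_labels(test)[, task_index]
  p <- predict(model, test$sequence)[, task_index]
  test$sequence[(p >= 0.5 & y == 1) | (p < 0.5 & y == 0)]
}

#' Convert a first-layer filter to a position frequency matrix
#'
#' The filter's activation map (first convolutional block, post-ReLU) is
#' scanned over all positions of all supplied sequences; every full-width
#' window whose activation reaches at least `frac` of the filter's maximum
#' activation over the whole set contributes its one-hot counts.
#'
#' @param model a `tftl_model`.
#' @param sequences character vector, typically the correctly predicted
#'   regions (see [correctly_predicted()]).
#' @param filter_index first-layer filter index.
#' @param frac activation threshold as a fraction of the maximum (0.5).
#' @return list of class `tftl_pfm` with `counts` (4 x K, rows A, C, G, T)
#'   and `n_sites`; a dead filter (maximum activation <= 0) yields
#'   `n_sites = 0`.
#' @export
filter_to_pfm <- function(model, sequences, filter_index, frac = 0.5) {
  if (length(sequences) == 0L) stop("empty sequence set")
  fa <- filter_activations(model, sequences)
  if (filter_index < 1 || filter_index > fa$F) stop("invalid filter index")
  A <- matrix(fa$act[seq(filter_index, nrow(fa$act), by = fa$F), ],
              nrow = fa$L)                     # L x B activation of one filter
  K <- fa$K
  pad_l <- (K - 1) %/% 2
  valid <- seq(pad_l + 1L, fa$L - (K - 1L - pad_l))
  M <- max(A[valid, ])
  counts <- matrix(0, 4, K, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (M <= 0)
    return(structure(list(counts = counts, n_sites = 0L), class = "tftl_pfm"))
  hits <- which(A[valid, , drop = FALSE] >= frac * M, arr.ind = TRUE)
  for (i in seq_len(nrow(hits))) {
    t <- valid[hits[i, 1]]
    b <- hits[i, 2]
    kmer <- substr(sequences[b], t - pad_l, t - pad_l + K - 1L)
    counts <- counts + one_hot(kmer)
  }
  structure(list(counts = counts, n_sites = nrow(hits)), class = "tftl_pfm")
}

#' Convert every first-layer filter to a PFM in one pass
#'
#' Equivalent to calling [filter_to_pfm()] for each filter, but computes
#' the activation map once for the whole sequence set.
#'
#' @inheritParams filter_to_pfm
#' @return list of `tftl_pfm`, one per filter.
#' @export
filter_motifs <- function(model, sequences, frac = 0.5) {
  if (length(sequences) == 0L) stop("empty sequence set")
  fa <- filter_activations(model, sequences)
  K <- fa$K
  pad_l <- (K - 1) %/% 2
  valid <- seq(pad_l + 1L, fa$L - (K - 1L - pad_l))
  codes <- cpp_seq_to_codes(sequences)
  lapply(seq_len(fa$F), function(f) {
    A <- matrix(fa$act[seq(f, nrow(fa$act), by = fa$F), ], nrow = fa$L)
    M <- max(A[valid, ])
    counts <- matrix(0, 4, K, dimnames = list(c("A", "C", "G", "T"), NULL))
    if (M <= 0)
      return(structure(list(counts = counts, n_sites = 0L),
                       class = "tftl_pfm"))
    hits <- which(A[valid, , drop = FALSE] >= frac * M, arr.ind = TRUE)
    for (i in seq_len(nrow(hits))) {
      t <- valid[hits[i, 1]]
      b <- hits[i, 2]
      ks <- codes[(t - pad_l):(t - pad_l + K - 1L), b] + 1L
      counts[cbind(ks, seq_len(K))] <- counts[cbind(ks, seq_len(K))] + 1
    }
    structure(list(counts = counts, n_sites = nrow(hits)),
              class = "tftl_pfm")
  })
}

#' @export
print.tftl_pfm <- function(x, ...) {
  cat("<tftl_pfm> width", ncol(x$counts), "| n_sites", x$n_sites, "\n")
  invisible(x)
}

#' Convert a position frequency matrix to a position weight matrix
#'
#' @param pfm a `tftl_pfm` (or a plain 4 x W count matrix).
#' @param pseudocount total pseudocount distributed uniformly (default 1).
#' @param representation `"probability"` (columns sum to 1) or
#'   `"log_odds"` (log2 of probability over the uniform 0.25 background).
#' @return 4 x W matrix.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 1,
                       representation = c("probability", "log_odds")) {
  representation <- match.arg(representation)
  counts <- if (inherits(pfm, "tftl_pfm")) pfm$counts else pfm
  n <- if (inherits(pfm, "tftl_pfm")) pfm$n_sites else max(colSums(counts))
  p <- sweep(counts + pseudocount / 4, 2, n + pseudocount, "/")
  # renormalize in case column sums differ from n_sites
  p <- sweep(p, 2, colSums(p), "/")
  if (representation == "log_odds") log2(p / 0.25) else p
}

#' Information content of a probability PWM
#'
#' `sum_cols (2 + sum_b p log2 p)` bits under the uniform background, with
#' `0 log 0 = 0`.
#'
#' @param pwm 4 x W probability matrix.
#' @return bits in \[0, 2W\].
#' @export
information_content <- function(pwm) {
  pl <- pwm * log2(pwm)
  pl[pwm == 0] <- 0
  sum(2 + colSums(pl))
}

#' Influence of a first-layer filter by silencing
#'
#' Zeroes the filter's activation map (post-ReLU of the first convolutional
#' block) across the batch, re-runs the remaining layers, and returns the
#' mean over samples and output nodes of the squared difference between the
#' actual and silenced predictions.
#'
#' @param model a `tftl_model` (evaluation mode).
#' @param batch character vector of sequences or an encoded batch.
#' @param filter_index first-layer filter index.
#' @return non-negative influence value.
#' @export
filter_influence <- function(model, batch, filter_index) {
  conv <- model$layers$conv1
  if (filter_index < 1 || filter_index > conv$F) stop("invalid filter index")
  x <- encode_input(model, batch)
  p_actual <- nn_forward(model, x, keep_caches = FALSE)$out
  p_sil <- nn_forward(model, x, keep_caches = FALSE,
                      silence = list(name = first_relu_name(model),
                                     channel = filter_index))$out
  mean((p_actual - p_sil)^2)
}

#' Best alignment similarity between two PWMs
#'
#' Maximum Pearson correlation of aligned probability columns over all
#' offsets with at least four overlapping columns, in the forward and
#' reverse-complement orientations.
#'
#' @param pwm_a,pwm_b 4 x W probability matrices.
#' @param min_overlap minimum overlapping columns (default 4, reduced to
#'   the shorter motif width if necessary).
#' @return list with `score`, `offset` (columns pwm_b is shifted right
#'   relative to pwm_a) and `orientation` (`"forward"` / `"reverse"`).
#' @export
pwm_similarity <- function(pwm_a, pwm_b, min_overlap = 4L) {
  min_overlap <- min(min_overlap, ncol(pwm_a), ncol(pwm_b))
  best <- list(score = -Inf, offset = 0L, orientation = "forward")
  for (orient in c("forward", "reverse")) {
    b <- if (orient == "forward") pwm_b else reverse_complement_pwm(pwm_b)
    Wa <- ncol(pwm_a); Wb <- ncol(b)
    for (o in seq(-(Wb - 1L), Wa - 1L)) {
      ai <- max(1L, o + 1L):min(Wa, o + Wb)
      if (length(ai) < min_overlap) next
      bi <- ai - o
      va <- as.numeric(pwm_a[, ai])
      vb <- as.numeric(b[, bi])
      if (sd(va) == 0 || sd(vb) == 0) next
      r <- cor(va, vb)
      if (r > best$score) best <- list(score = r, offset = o,
                                       orientation = orient)
    }
  }
  if (!is.finite(best$score)) best$score <- 0
  best
}

# ---- attribution -------------------------------------------------------

# forward pass recording the input of every layer (evaluation mode)
forward_with_inputs <- function(model, x) {
  inputs <- vector("list", length(model$layers))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    inputs[[i]] <- x
    r <- layer_forward(model$layers[[i]], x, training = FALSE)
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, inputs = inputs, caches = caches)
}

# Rescale-rule multipliers through one layer. m_out is the multiplier at
# the layer output; xi/ri are the layer inputs under input and reference.
# For every layer the identity sum(m_in * (xi - ri)) == sum(m_out * dy)
# holds exactly, which gives completeness by induction.
layer_multiplier <- function(layer, m_out, xi, ri, yi, yr, cache_x) {
  dxy <- xi - ri
  switch(layer$type,
    dense = crossprod(layer$params$W, m_out),
    conv = cpp_conv_backward(xi, layer$params$W, m_out,
                             layer$C, layer$L, layer$K)$dx,
    bnorm = {
      s <- layer$params$gamma / sqrt(layer$state$running_var + layer$eps)
      matrix(matrix(m_out, nrow = layer$C) * s, nrow = nrow(m_out))
    },
    relu = , sigmoid = {
      dy <- yi - yr
      m <- ifelse(dxy != 0, dy / ifelse(dxy != 0, dxy, 1),
                  if (layer$type == "relu") (xi > 0) * 1
                  else yi * (1 - yi))
      m_out * m
    },
    dropout = m_out,
    maxpool = {
      C <- layer$C; k <- layer$k; Lout <- layer$L %/% k
      m_in <- xi * 0
      dy <- yi - yr
      for (t in seq_len(Lout)) {
        rows_in <- ((t - 1) * k * C + 1):(t * k * C)
        for (c in seq_len(C)) {
          mo <- m_out[(t - 1) * C + c, 1]
          d <- dy[(t - 1) * C + c, 1]
          if (mo == 0 || d == 0) next
          widx <- rows_in[seq(c, length(rows_in), by = C)]
          dx <- dxy[widx, 1]
          j <- cache_x$argmax[(t - 1) * C + c, 1] + 1L  # actual argmax row
          if (dxy[j, 1] == 0) j <- widx[which.max(abs(dx))]
          m_in[j, 1] <- m_in[j, 1] + mo * d / dxy[j, 1]
        }
      }
      m_in
    },
    stop("attribution is not implemented for layer type: ", layer$type)
  )
}

#' Per-nucleotide attribution scores with reference sequences
#'
#' Backpropagation-based contribution scores following the rescale rule:
#' linear layers pass multipliers through their weights, elementwise
#' nonlinearities use the ratio of output to input differences, and max
#' pooling routes each window's output difference to a single input
#' position. Per-reference attributions satisfy the completeness identity
#' `sum(track) = f(x) - f(reference)` exactly (up to single-precision
#' convolution arithmetic) and are averaged over the references.
#'
#' @param model a convolutional `tftl_model` in evaluation mode.
#' @param sequence input sequence (string).
#' @param references character vector of reference sequences of the same
#'   length (e.g., 10 shuffled or unbound sequences).
#' @param task_index output node to attribute (default 1).
#' @return 4 x L matrix of class `tftl_track` (rows A, C, G, T); only the
#'   observed base of each position has a non-zero score.
#' @export
attribution <- function(model, sequence, references, task_index = 1L) {
  if (any(nchar(references) != nchar(sequence)))
    stop("references must have the same length as the sequence")
  if (any(vapply(model$layers, `[[`, "", "type") == "lstm_bi"))
    stop("attribution supports the convolutional architecture only")
  x <- encode_batch(sequence)
  fx <- forward_with_inputs(model, x)
  n_layers <- length(model$layers)
  total <- x * 0
  f_refs <- numeric(length(references))
  for (k in seq_along(references)) {
    r <- encode_batch(references[k])
    fr <- forward_with_inputs(model, r)
    f_refs[k] <- fr$out[task_index, 1]
    m <- matrix(0, model$spec$n_outputs, 1)
    m[task_index, 1] <- 1
    for (i in seq(n_layers, 1)) {
      yi <- if (i == n_layers) fx$out else fx$inputs[[i + 1]]
      yr <- if (i == n_layers) fr$out else fr$inputs[[i + 1]]
      m <- layer_multiplier(model$layers[[i]], m,
                            fx$inputs[[i]], fr$inputs[[i]],
                            yi, yr, fx$caches[[i]])
    }
    total <- total + m * (x - r)
  }
  track <- matrix(total / length(references), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(track, class = c("tftl_track", class(track)),
            f_x = fx$out[task_index, 1], f_ref_mean = mean(f_refs))
}

#' Export an attribution track as a TSV score table
#'
#' @param track a `tftl_track` from [attribution()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_track <- function(track, path) {
  df <- data.frame(position = seq_len(ncol(track)), t(unclass(track)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-filter interpretation report
#'
#' @param model a `tftl_model`.
#' @param test data.frame with `sequence` and labels (test partition).
#' @param motifs optional named list of probability PWMs to match filters
#'   against (best internal match by [pwm_similarity()]).
#' @param frac activation threshold for [filter_to_pfm()].
#' @return data.frame: filter index, information content, influence,
#'   n_sites and (optionally) best match name/score.
#' @export
filter_report <- function(model, test, motifs = NULL, frac = 0.5) {
  seqs <- correctly_predicted(model, test)
  if (length(seqs) == 0L) stop("no correctly predicted regions")
  n_f <- model$layers$conv1$F
  pfms <- filter_motifs(model, seqs, frac = frac)
  rows <- lapply(seq_len(n_f), function(f) {
    pfm <- pfms[[f]]
    infl <- filter_influence(model, test$sequence, f)
    if (pfm$n_sites == 0)
      return(data.frame(filter = f, ic = NA_real_, influence = infl,
                        n_sites = 0L, best_match = NA_character_,
                        match_score = NA_real_))
    pwm <- pfm_to_pwm(pfm)
    bm_name <- NA_character_; bm_score <- NA_real_
    if (!is.null(motifs)) {
      sims <- vapply(motifs, function(m) pwm_similarity(pwm, m)$score, 0)
      bm_name <- names(motifs)[which.max(sims)]
      bm_score <- max(sims)
    }
    data.frame(filter = f, ic = information_content(pwm), influence = infl,
               n_sites = pfm$n_sites, best_match = bm_name,
               match_score = bm_score)
  })
  do.call(rbind, rows)
}
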