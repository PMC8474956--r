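# Pre-training, weight transfer and fine-tuning.

#' Training configuration
#'
#' @param learning_rate Adam learning rate. Multi-task pre-training and
#'   from-scratch baselines use 0.003; fine-tuning uses a 10-fold lower
#'   rate (0.0003) by default in [finetune()].
#' @param batch_size minibatch size (default 100).
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement before early
#'   stopping (the best checkpoint is restored).
#' @param seed integer seed; all shuffling, dropout and initialization
#'   randomness of a run is funnelled through it.
#' @return list of class `tftl_train_config`.
#' @export
train_config <- function(learning_rate = 0.003, batch_size = 100L,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "tftl_train_config")
}

split_labels <- function(d) {
  lab <- attr(d, "labels")
  if (is.null(lab)) matrix(d$label, ncol = 1) else lab
}

# Train a model on a tftl_split with Adam + early stopping on validation
# loss (mean binary cross-entropy over tasks). Returns the best checkpoint
# with the per-epoch log in attr(, "history").
#' Train a sequence model
#'
#' Core minibatch training loop shared by [pretrain_multi()], [finetune()]
#' and from-scratch baselines: Adam optimization of the mean binary
#' cross-entropy across tasks, with early stopping on the validation loss
#' and restoration of the best checkpoint.
#'
#' @param model a `tftl_model`.
#' @param split a `tftl_split` with train and val partitions.
#' @param config a [train_config()].
#' @param freeze character vector of layer names whose parameters are not
#'   updated.
#' @return the trained `tftl_model`; `attr(, "history")` holds per-epoch
#'   train/val losses and `attr(, "best_epoch")` the selected epoch.
#' @export
train_model <- function(model, split, config, freeze = character()) {
  stopifnot(inherits(model, "tftl_model"), inherits(split, "tftl_split"))
  codes_tr <- cpp_seq_to_codes(split$train$sequence)
  codes_va <- cpp_seq_to_codes(split$val$sequence)
  y_tr <- split_labels(split$train)
  y_va <- split_labels(split$val)
  n_tr <- ncol(codes_tr)
  out_idx <- which(names(model$layers) == "output")
  opt <- adam_init(model)
  best <- list(loss = Inf, epoch = 0L, layers = NULL)
  history <- NULL
  wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      tr_loss <- 0
      nb <- 0L
      for (s in seq(1, n_tr, by = config$batch_size)) {
        sel <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        x <- cpp_codes_to_onehot(codes_tr, sel)
        y <- t(y_tr[sel, , drop = FALSE])
        r <- nn_forward(model, x, training = TRUE)
        p <- r$out
        tr_loss <- tr_loss + bce_loss(p, y)
        nb <- nb + 1L
        model <- nn_update_running(model, r$caches)
        # dL/d(logits): start backprop at the output dense layer
        dZ <- (p - y) / length(y)
        g <- nn_backward(model, r$caches, dZ, from = out_idx)
        grads <- g$grads
        for (nm in freeze) grads[[nm]] <- NULL
        st <- adam_step(model, grads, opt, lr = config$learning_rate)
        model <- st$model
        opt <- st$opt
      }
      val_loss <- evaluate_loss(model, codes_va, y_va,
                                batch_size = max(500L, config$batch_size))
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                  val_loss = val_loss))
      if (!is.finite(val_loss) || !is.finite(tr_loss))
        stop("non-finite loss at epoch ", epoch,
             " (train=", tr_loss, ", val=", val_loss, ")")
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch, layers = model$layers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  if (!is.null(best$layers)) model$layers <- best$layers
  attr(model, "history") <- history
  attr(model, "best_epoch") <- best$epoch
  attr(model, "config") <- config
  model
}

evaluate_loss <- function(model, codes, y, batch_size = 500L) {
  n <- ncol(codes)
  tot <- 0
  for (s in seq(1, n, by = batch_size)) {
    sel <- s:min(s + batch_size - 1L, n)
    x <- cpp_codes_to_onehot(codes, sel)
    p <- nn_forward(model, x, training = FALSE, keep_caches = FALSE)$out
    yb <- t(y[sel, , drop = FALSE])
    tot <- tot + bce_loss(p, yb) * length(sel)
  }
  tot / n
}

#' Pre-train a multi-task model
#'
#' @param spec a [model_spec()] whose `n_outputs` matches the number of
#'   label columns of the split.
#' @param split a `tftl_split` built from [extract_multi_task()] output.
#' @param config a [train_config()] (learning rate 0.003 by default).
#' @return the trained multi-task `tftl_model` (best validation
#'   checkpoint), with the pre-training region ids recorded in
#'   `attr(, "train_regions")` for downstream disjointness checks.
#' @export
pretrain_multi <- function(spec, split, config = train_config()) {
  stopifnot(ncol(split_labels(split$train)) == spec$n_outputs)
  model <- build_model(spec)
  model <- train_model(model, split, config)
  attr(model, "train_regions") <-
    unique(c(split$train$region_id, split$val$region_id,
             split$test$region_id))
  model
}

conv_block_names <- function(model) {
  nm <- names(model$layers)
  convs <- grep("^conv", nm, value = TRUE)
  unlist(lapply(convs, function(cv) {
    bn <- sub("conv", "bn", cv)
    c(cv, intersect(bn, nm))
  }))
}

#' Transfer weights from a source model into a freshly initialized model
#'
#' @param source trained `tftl_model` (e.g., a multi-task model).
#' @param target_spec [model_spec()] of the recipient; must share the
#'   architecture and input length of the source (the number of outputs may
#'   differ, typically 1).
#' @param mode `"all_but_output"` (every layer except the output layer is
#'   copied), `"conv1_only"`, `"conv_all"` (only the stated convolutional
#'   blocks are copied; fully connected layers stay freshly initialized) or
#'   `"none"`.
#' @return a `tftl_model` initialized per `mode`; copied weights are
#'   bit-identical to the source's.
#' @export
transfer_weights <- function(source, target_spec,
                             mode = c("all_but_output", "conv1_only",
                                      "conv_all", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "tftl_model"),
            inherits(target_spec, "tftl_model_spec"))
  if (source$spec$architecture != target_spec$architecture ||
      source$spec$input_length != target_spec$input_length)
    stop("source and target architectures differ")
  target <- build_model(target_spec)
  copy <- switch(mode,
    all_but_output = setdiff(names(source$layers), "output"),
    conv1_only = intersect(c("conv1", "bn1"), names(source$layers)),
    conv_all = conv_block_names(source),
    none = character(0))
  for (nm in copy) {
    if (!is.null(source$layers[[nm]]$params))
      target$layers[[nm]]$params <- source$layers[[nm]]$params
    if (!is.null(source$layers[[nm]]$state))
      target$layers[[nm]]$state <- source$layers[[nm]]$state
  }
  attr(target, "transfer_mode") <- mode
  target
}

#' Fine-tune a (transferred) model on a single-task dataset
#'
#' Continues training at a reduced learning rate (default 0.0003, i.e.,
#' 10-fold lower than the 0.003 pre-training rate). With
#' `freeze = "conv_layers"` the convolutional blocks are excluded from the
#' update and their weights remain bit-identical. If `pretrain_regions` is
#' supplied, any overlap between them and the fine-tuning regions is an
#' error (pre-training and fine-tuning regions must be disjoint).
#'
#' @param model a `tftl_model` (typically from [transfer_weights()]).
#' @param split a `tftl_split` of the single-task dataset.
#' @param config a [train_config()]; defaults to the fine-tuning rate.
#' @param freeze `"none"` or `"conv_layers"`.
#' @param pretrain_regions optional character vector of region ids used in
#'   pre-training.
#' @return the fine-tuned `tftl_model`.
#' @export
finetune <- function(model, split,
                     config = train_config(learning_rate = 0.0003),
                     freeze = c("none", "conv_layers"),
                     pretrain_regions = NULL) {
  freeze <- match.arg(freeze)
  if (!is.null(pretrain_regions)) {
    ids <- unique(c(split$train$region_id, split$val$region_id,
                    split$test$region_id))
    bad <- intersect(ids, pretrain_regions)
    if (length(bad))
      stop("fine-tuning regions overlap pre-training regions (",
           length(bad), " region(s))")
  }
  frozen <- if (freeze == "conv_layers") conv_block_names(model)
            else character(0)
  train_model(model, split, config, freeze = frozen)
}

#' Initialize first-layer convolutional filters from PWMs
#'
#' Each probability matrix is resized to the filter width (centred; padded
#' with uniform 0.25 columns or truncated to the central columns), 0.25 is
#' subtracted from every entry, and the result is written into one filter.
#' Remaining filters keep their default initialization.
#'
#' @param model a `tftl_model`.
#' @param pwms list of 4 x W probability matrices (columns sum to 1).
#' @return the model with initialized filters.
#' @export
init_filters_from_pwms <- function(model, pwms) {
  conv <- model$layers$conv1
  if (is.null(conv)) stop("model has no first convolutional layer")
  if (length(pwms) > conv$F)
    stop("more PWMs (", length(pwms), ") than filters (", conv$F, ")")
  K <- conv$K
  for (f in seq_along(pwms)) {
    p <- pwms[[f]]
    stopifnot(nrow(p) == 4)
    if (any(abs(colSums(p) - 1) > 1e-6))
      stop("PWM ", f, ": columns must sum to 1")
    W <- ncol(p)
    if (W < K) {
      left <- (K - W) %/% 2
      p <- cbind(matrix(0.25, 4, left), p, matrix(0.25, 4, K - W - left))
    } else if (W > K) {
      start <- (W - K) %/% 2 + 1
      p <- p[, start:(start + K - 1), drop = FALSE]
    }
    w <- p - 0.25
    # filter rows are laid out patch-position-major, channel fastest
    model$layers$conv1$params$W[f, ] <- as.numeric(w)
  }
  model
}

#' Run replicate experiments over seeds
#'
#' @param experiment function taking a single integer seed and returning a
#'   named numeric vector of performance values (e.g., AUCPRs for transfer
#'   learning and from-scratch conditions).
#' @param seeds integer vector of seeds (default `1:5`).
#' @return data.frame with one row per run; `attr(, "summary")` holds the
#'   per-column median and spread (standard deviation).
#' @export
run_replicates <- function(experiment, seeds = 1:5) {
  rows <- lapply(seeds, function(s) {
    v <- experiment(s)
    data.frame(seed = s, t(v))
  })
  out <- do.call(rbind, rows)
  vals <- out[, setdiff(names(out), "seed"), drop = FALSE]
  attr(out, "summary") <- data.frame(
    metric = names(vals),
    median = vapply(vals, median, numeric(1)),
    spread = vapply(vals, sd, numeric(1)),
    row.names = NULL)
  out
}
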