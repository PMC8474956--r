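#' Specify a sequence-model architecture
#'
#' Two architectures are available: `"basset_like"`, a three-block
#' convolutional network (100 filters of width 19, then 200 of width 7 and
#' 200 of width 4, each with batch normalization, ReLU and 3x max pooling,
#' followed by two 1000-unit fully connected layers with 30% dropout), and
#' `"danq_like"`, a hybrid network (320 filters of width 26 with ReLU, 20%
#' dropout and 13x max pooling, two bidirectional LSTM layers with hidden
#' state 320 and 50% dropout, then a 925-unit fully connected layer). Both
#' end in a fully connected output layer with one logistic output per task.
#'
#' @param architecture `"basset_like"` or `"danq_like"`.
#' @param input_length sequence length in bp; 200 (default), 500 or 1000.
#' @param n_outputs number of output tasks (1 for single-task models).
#' @param seed integer seed for weight initialization.
#' @return an object of class `tftl_model_spec`.
#' @export
model_spec <- function(architecture = c("basset_like", "danq_like"),
                       input_length = 200L, n_outputs = 1L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (!input_length %in% c(200L, 500L, 1000L))
    stop("unsupported input_length: ", input_length,
         " (supported: 200, 500, 1000)")
  if (n_outputs < 1L) stop("n_outputs must be >= 1")
  structure(list(architecture = architecture,
                 input_length = as.integer(input_length),
                 n_outputs = as.integer(n_outputs),
                 seed = as.integer(seed)),
            class = "tftl_model_spec")
}

#' Build a sequence model
#'
#' Instantiates the architecture described by a [model_spec()] with
#' deterministic, seed-controlled weight initialization (He-scaled normal
#' draws for convolutional and dense layers, uniform draws scaled by the
#' hidden-state size for LSTM layers). Layer names are stable across models
#' of the same architecture, which is what makes weight transfer between a
#' multi-task and a single-task model well defined.
#'
#' @param spec a [model_spec()].
#' @return an object of class `tftl_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "tftl_model_spec"))
  with_seed(spec$seed, {
    layers <- if (spec$architecture == "basset_like")
      basset_layers(spec$input_length, spec$n_outputs)
    else danq_layers(spec$input_length, spec$n_outputs)
  })
  names(layers) <- vapply(layers, `[[`, "", "name")
  structure(list(spec = spec, layers = layers), class = "tftl_model")
}

basset_layers <- function(L, n_out) {
  L1 <- L; L2 <- L1 %/% 3L; L3 <- L2 %/% 3L; L4 <- L3 %/% 3L
  flat <- 200L * L4
  list(
    layer_conv("conv1", C = 4L, L = L1, K = 19L, F = 100L),
    layer_bnorm("bn1", C = 100L, L = L1),
    layer_relu("relu1"),
    layer_maxpool("pool1", C = 100L, L = L1, k = 3L),
    layer_conv("conv2", C = 100L, L = L2, K = 7L, F = 200L),
    layer_bnorm("bn2", C = 200L, L = L2),
    layer_relu("relu2"),
    layer_maxpool("pool2", C = 200L, L = L2, k = 3L),
    layer_conv("conv3", C = 200L, L = L3, K = 4L, F = 200L),
    layer_bnorm("bn3", C = 200L, L = L3),
    layer_relu("relu3"),
    layer_maxpool("pool3", C = 200L, L = L3, k = 3L),
    layer_dense("fc1", n_in = flat, n_out = 1000L),
    layer_bnorm("bn4", C = 1000L, L = 1L),
    layer_relu("relu4"),
    layer_dropout("drop1", p = 0.3),
    layer_dense("fc2", n_in = 1000L, n_out = 1000L),
    layer_bnorm("bn5", C = 1000L, L = 1L),
    layer_relu("relu5"),
    layer_dropout("drop2", p = 0.3),
    layer_dense("output", n_in = 1000L, n_out = n_out),
    layer_sigmoid("sigmoid")
  )
}

danq_layers <- function(L, n_out) {
  T <- L %/% 13L
  list(
    layer_conv("conv1", C = 4L, L = L, K = 26L, F = 320L),
    layer_relu("relu1"),
    layer_dropout("drop1", p = 0.2),
    layer_maxpool("pool1", C = 320L, L = L, k = 13L),
    layer_lstm_bi("lstm1", D = 320L, H = 320L, T = T),
    layer_dropout("drop2", p = 0.5),
    layer_lstm_bi("lstm2", D = 640L, H = 320L, T = T),
    layer_dropout("drop3", p = 0.5),
    layer_dense("fc1", n_in = 640L * T, n_out = 925L),
    layer_relu("relu2"),
    layer_dense("output", n_in = 925L, n_out = n_out),
    layer_sigmoid("sigmoid")
  )
}

#' Forward pass of a sequence model
#'
#' @param model a `tftl_model`.
#' @param batch a one-hot batch: either the `(4*L) x B` matrix layout used
#'   internally or a character vector of sequences (encoded on the fly).
#' @param training logical; `TRUE` enables dropout and batch-statistics
#'   normalization. In evaluation mode (default) the forward pass is
#'   deterministic.
#' @return a `B x n_outputs` matrix of probabilities in (0, 1).
#' @export
forward <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "tftl_model"))
  x <- encode_input(model, batch)
  r <- nn_forward(model, x, training = training, keep_caches = FALSE)
  t(r$out)
}

encode_input <- function(model, batch) {
  if (is.character(batch)) batch <- encode_batch(batch)
  L_in <- model$layers[[1]]$L * model$layers[[1]]$C
  if (nrow(batch) != L_in)
    stop("input shape mismatch: expected ", L_in, " rows, got ", nrow(batch))
  batch
}

#' @export
predict.tftl_model <- function(object, newdata, batch_size = 500L, ...) {
  if (is.character(newdata)) newdata <- encode_batch(newdata)
  B <- ncol(newdata)
  out <- matrix(NA_real_, B, object$spec$n_outputs)
  for (s in seq(1, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    out[s:e, ] <- forward(object, newdata[, s:e, drop = FALSE])
  }
  out
}

#' @export
print.tftl_model <- function(x, ...) {
  cat("<tftl_model> ", x$spec$architecture,
      " | input ", x$spec$input_length, " bp | ",
      x$spec$n_outputs, " output(s) | ",
      format(count_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' @export
summary.tftl_model <- function(object, ...) {
  for (l in object$layers) {
    np <- if (is.null(l$params)) 0L else sum(vapply(l$params, length, 1L))
    cat(sprintf("%-8s %-8s %10d params\n", l$name, l$type, np))
  }
  invisible(object)
}

#' Total number of trainable parameters
#' @param model a `tftl_model`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l)
    if (is.null(l$params)) 0L else sum(vapply(l$params, length, 1L)), 1L))
}

#' Save / load a model checkpoint
#'
#' Writes the named weight arrays to `<path>.rds` and a JSON manifest
#' (architecture, spec, seed, provenance) to `<path>.json`.
#'
#' @param model a `tftl_model`.
#' @param path file path prefix (without extension).
#' @param provenance optional named list recorded in the manifest.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, provenance = list()) {
  saveRDS(model, paste0(path, ".rds"))
  manifest <- list(architecture = model$spec$architecture,
                   input_length = model$spec$input_length,
                   n_outputs = model$spec$n_outputs,
                   seed = model$spec$seed,
                   n_params = count_params(model),
                   layers = names(model$layers),
                   provenance = provenance)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(m, "tftl_model"))
  m
}

#' One-hot encode a batch of sequences into the engine layout
#'
#' @param sequences character vector of equal-length A/C/G/T sequences.
#' @return a `(4*L) x B` numeric matrix (channel order A, C, G, T fastest).
#' @export
encode_batch <- function(sequences) {
  codes <- cpp_seq_to_codes(sequences)
  cpp_codes_to_onehot(codes, seq_along(sequences))
}
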