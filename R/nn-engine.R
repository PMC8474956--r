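# Minimal feed-forward training engine.
#
# Feature maps are (C*L) x B matrices, channel index fastest:
# x[(t-1)*C + c, b]. Dense activations are (units) x B. All layers are plain
# lists; forward/backward are pure functions returning caches/gradients so
# training, transfer and interpretation can share one code path.

# Kaiming-uniform initialization with the deep-learning-framework default
# negative-slope correction: W ~ U(+/- sqrt(1/fan_in)), bias ~ U(+/-
# 1/sqrt(fan_in)). The scale matters: over-dispersed initial weights push
# heavily overparameterized networks into memorization instead of feature
# learning.
init_weight <- function(n_out, n_in) {
  b <- sqrt(1 / n_in)
  matrix(runif(n_out * n_in, -b, b), nrow = n_out)
}

init_bias <- function(n_out, n_in) {
  b <- 1 / sqrt(n_in)
  runif(n_out, -b, b)
}

layer_conv <- function(name, C, L, K, F) {
  list(type = "conv", name = name, C = C, L = L, K = K, F = F,
       params = list(W = init_weight(F, C * K), b = init_bias(F, C * K)))
}

layer_bnorm <- function(name, C, L, momentum = 0.1, eps = 1e-5) {
  list(type = "bnorm", name = name, C = C, L = L,
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)),
       state = list(running_mean = numeric(C), running_var = rep(1, C)))
}

layer_relu <- function(name) list(type = "relu", name = name)

layer_dropout <- function(name, p) list(type = "dropout", name = name, p = p)

layer_maxpool <- function(name, C, L, k) {
  list(type = "maxpool", name = name, C = C, L = L, k = k,
       L_out = L %/% k)
}

layer_dense <- function(name, n_in, n_out) {
  list(type = "dense", name = name, n_in = n_in, n_out = n_out,
       params = list(W = init_weight(n_out, n_in),
                     b = init_bias(n_out, n_in)))
}

layer_sigmoid <- function(name) list(type = "sigmoid", name = name)

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- forward -----------------------------------------------------------

# Forward pass through one layer. Returns list(out, cache).
# `silence`: optional list(name=, channel=) zeroing one channel of the named
# layer's output (used for filter-influence analysis).
layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      r <- cpp_conv_forward(x, layer$params$W, layer$params$b,
                            layer$C, layer$L, layer$K, training)
      list(out = r$out, cache = list(x = x, ctx = r$ctx))
    },
    bnorm = {
      if (training) {
        r <- cpp_bn_forward_train(x, layer$C, layer$params$gamma,
                                  layer$params$beta, layer$eps)
        list(out = r$out,
             cache = list(x = x, mu = r$mu, var = r$var, invstd = r$invstd))
      } else {
        out <- cpp_bn_forward_eval(x, layer$C, layer$params$gamma,
                                   layer$params$beta,
                                   layer$state$running_mean,
                                   layer$state$running_var, layer$eps)
        list(out = out, cache = NULL)
      }
    },
    relu = {
      list(out = cpp_relu_forward(x), cache = list(x = x))
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- 1 - layer$p
        mask <- matrix((runif(length(x)) < keep) / keep, nrow = nrow(x))
        list(out = x * mask, cache = list(mask = mask))
      } else list(out = x, cache = NULL)
    },
    maxpool = {
      r <- cpp_maxpool_forward(x, layer$C, layer$L, layer$k)
      list(out = r$out, cache = list(argmax = r$argmax))
    },
    dense = {
      out <- layer$params$W %*% x + layer$params$b
      list(out = out, cache = list(x = x))
    },
    sigmoid = {
      out <- sigmoid(x)
      list(out = out, cache = list(out = out, z = x))
    },
    lstm_bi = lstm_bi_forward(layer, x, training),
    stop("unknown layer type: ", layer$type)
  )
}

#' @keywords internal
nn_forward <- function(model, x, training = FALSE, silence = NULL,
                       keep_caches = TRUE) {
  caches <- vector("list", length(model$layers))
  names(caches) <- names(model$layers)
  acts <- if (keep_caches) caches else NULL
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    r <- layer_forward(layer, x, training = training)
    x <- r$out
    if (!is.null(silence) && identical(silence$name, layer$name)) {
      C <- n_channels_of(model, i)
      idx <- seq(silence$channel, nrow(x), by = C)
      x[idx, ] <- 0
    }
    if (keep_caches) {
      caches[[i]] <- r$cache
      acts[[i]] <- x
    }
  }
  list(out = x, caches = caches, activations = acts)
}

# channel count of the feature map emitted by layer i (for silencing)
n_channels_of <- function(model, i) {
  for (j in seq(i, 1)) {
    l <- model$layers[[j]]
    if (!is.null(l$F)) return(l$F)
    if (!is.null(l$C)) return(l$C)
    if (l$type == "dense") return(l$n_out)
    if (l$type == "lstm_bi") return(2L * l$H)
  }
  stop("cannot infer channel count")
}

# ---- backward ----------------------------------------------------------

layer_backward <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      r <- cpp_conv_backward(cache$x, layer$params$W, dout,
                             layer$C, layer$L, layer$K, need_dx, cache$ctx)
      list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
    },
    bnorm = {
      r <- cpp_bn_backward(cache$x, dout, layer$C, layer$params$gamma,
                           cache$mu, cache$invstd)
      list(dx = r$dx,
           grads = list(gamma = as.numeric(r$dgamma),
                        beta = as.numeric(r$dbeta)))
    },
    relu = list(dx = cpp_relu_backward(cache$x, dout), grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    maxpool = {
      list(dx = cpp_maxpool_backward(cache$argmax, dout, layer$C, layer$L),
           grads = NULL)
    },
    dense = {
      list(dx = crossprod(layer$params$W, dout),
           grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
    },
    sigmoid = {
      list(dx = dout * cache$out * (1 - cache$out), grads = NULL)
    },
    lstm_bi = lstm_bi_backward(layer, cache, dout),
    stop("unknown layer type: ", layer$type)
  )
}

# Backpropagate starting from the gradient at the output of layer `from`
# (defaults to the last layer). Returns list(grads, dx).
nn_backward <- function(model, caches, dout, from = length(model$layers)) {
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  for (i in seq(from, 1)) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dout,
                        need_dx = i > 1L)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(grads = grads, dx = dout)
}

# update batch-norm running statistics from the caches of a training pass
nn_update_running <- function(model, caches) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "bnorm" && !is.null(caches[[i]])) {
      m <- l$momentum
      l$state$running_mean <- (1 - m) * l$state$running_mean + m * caches[[i]]$mu
      l$state$running_var <- (1 - m) * l$state$running_var + m * caches[[i]]$var
      model$layers[[i]] <- l
    }
  }
  model
}

# ---- parameters and Adam ----------------------------------------------

model_params <- function(model) {
  lapply(model$layers, function(l) l$params)
}

model_set_params <- function(model, params) {
  for (nm in names(params)) {
    if (!is.null(params[[nm]])) model$layers[[nm]]$params <- params[[nm]]
  }
  model
}

adam_init <- function(model) {
  zeros_like <- function(p) lapply(p, function(a) a * 0)
  ps <- model_params(model)
  list(t = 0,
       m = lapply(ps, function(p) if (is.null(p)) NULL else zeros_like(p)),
       v = lapply(ps, function(p) if (is.null(p)) NULL else zeros_like(p)))
}

adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    for (pn in names(g)) {
      u <- cpp_adam_update(model$layers[[nm]]$params[[pn]], g[[pn]],
                           opt$m[[nm]][[pn]], opt$v[[nm]][[pn]],
                           lr, beta1, beta2, bc1, bc2, eps)
      model$layers[[nm]]$params[[pn]] <- u$p
      opt$m[[nm]][[pn]] <- u$m
      opt$v[[nm]][[pn]] <- u$v
    }
  }
  list(model = model, opt = opt)
}

# mean binary cross-entropy over all tasks and samples
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
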