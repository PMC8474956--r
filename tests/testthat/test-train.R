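# Training, transfer and fine-tuning behaviour on small synthetic tasks.

make_task <- function(n = 60, seed = 80, motif_seed = 6) {
  withr::with_seed(seed, {
    motif <- make_motif(motif_seed, 8, 12)
    pos <- vapply(seq_len(n / 2), function(i) {
      s <- random_seq(1, 200)
      at <- sample(1:193, 1)
      substr(s, at, at + 7) <- tftl:::sample_motif_instance(motif)
      s
    }, "")
    data.frame(region_id = paste0("r", 1:n),
               sequence = c(pos, random_seq(n / 2, 200)),
               label = rep(c(1L, 0L), each = n / 2))
  })
}

test_that("training reduces the validation loss and selects the best checkpoint", {
  d <- make_task()
  sp <- split_dataset(d, seed = 1)
  cfg <- train_config(max_epochs = 4, patience = 4, batch_size = 24,
                      seed = 2)
  m <- train_model(build_model(model_spec("basset_like", n_outputs = 1,
                                          seed = 2)), sp, cfg)
  h <- attr(m, "history")
  expect_equal(nrow(h), 4L)
  expect_lt(min(h$val_loss), h$val_loss[1])
  expect_equal(attr(m, "best_epoch"), which.min(h$val_loss))
})

test_that("training is bit-reproducible given the seed", {
  d <- make_task(n = 40)
  sp <- split_dataset(d, seed = 3)
  cfg <- train_config(max_epochs = 2, patience = 2, batch_size = 16, seed = 9)
  run <- function() train_model(
    build_model(model_spec("basset_like", n_outputs = 1, seed = 9)), sp, cfg)
  m1 <- run()
  m2 <- run()
  expect_identical(m1$layers$conv1$params$W, m2$layers$conv1$params$W)
  expect_identical(m1$layers$output$params$W, m2$layers$output$params$W)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
})

test_that("transfer_weights copies exactly the layers its mode prescribes", {
  src <- build_model(model_spec("basset_like", n_outputs = 5, seed = 4))
  tspec <- model_spec("basset_like", n_outputs = 1, seed = 5)
  fresh <- build_model(tspec)

  tl <- transfer_weights(src, tspec, mode = "all_but_output")
  expect_identical(tl$layers$conv1$params$W, src$layers$conv1$params$W)
  expect_identical(tl$layers$fc2$params$W, src$layers$fc2$params$W)
  expect_identical(tl$layers$bn1$params$gamma, src$layers$bn1$params$gamma)
  expect_equal(dim(tl$layers$output$params$W), c(1L, 1000L))
  expect_identical(tl$layers$output$params$W, fresh$layers$output$params$W)

  c1 <- transfer_weights(src, tspec, mode = "conv1_only")
  expect_identical(c1$layers$conv1$params$W, src$layers$conv1$params$W)
  expect_identical(c1$layers$conv2$params$W, fresh$layers$conv2$params$W)
  expect_identical(c1$layers$fc1$params$W, fresh$layers$fc1$params$W)

  ca <- transfer_weights(src, tspec, mode = "conv_all")
  expect_identical(ca$layers$conv3$params$W, src$layers$conv3$params$W)
  expect_identical(ca$layers$fc1$params$W, fresh$layers$fc1$params$W)
  # fully connected batch-norm layers are not part of the conv blocks
  expect_identical(ca$layers$bn4$params$gamma, fresh$layers$bn4$params$gamma)

  none <- transfer_weights(src, tspec, mode = "none")
  expect_identical(none$layers$conv1$params$W, fresh$layers$conv1$params$W)

  expect_error(transfer_weights(src, model_spec("danq_like", n_outputs = 1),
                                mode = "all_but_output"),
               "architectures differ")
})

test_that("transferred non-output layers reproduce source activations exactly", {
  src <- build_model(model_spec("basset_like", n_outputs = 5, seed = 6))
  tl <- transfer_weights(src, model_spec("basset_like", n_outputs = 1,
                                         seed = 7), "all_but_output")
  withr::with_seed(81, x <- encode_batch(random_seq(3, 200)))
  a_src <- tftl:::nn_forward(src, x)$activations
  a_tl <- tftl:::nn_forward(tl, x)$activations
  for (nm in setdiff(names(a_src), c("output", "sigmoid")))
    expect_identical(a_src[[nm]], a_tl[[nm]])
})

test_that("fine-tuning defaults to the 10-fold lower learning rate", {
  default_cfg <- formals(finetune)$config
  expect_equal(eval(default_cfg)$learning_rate, 0.003 / 10)
})

test_that("freezing keeps convolutional weights bit-identical through fine-tuning", {
  d <- make_task(n = 40, seed = 82)
  sp <- split_dataset(d, seed = 8)
  src <- build_model(model_spec("basset_like", n_outputs = 2, seed = 10))
  tl0 <- transfer_weights(src, model_spec("basset_like", n_outputs = 1,
                                          seed = 11), "all_but_output")
  cfg <- train_config(learning_rate = 3e-4, max_epochs = 2, patience = 2,
                      batch_size = 16, seed = 12)
  tl <- finetune(tl0, sp, cfg, freeze = "conv_layers")
  for (nm in c("conv1", "conv2", "conv3", "bn1", "bn2", "bn3"))
    expect_identical(tl$layers[[nm]]$params, tl0$layers[[nm]]$params)
  expect_false(identical(tl$layers$fc1$params$W, tl0$layers$fc1$params$W))

  tl_full <- finetune(tl0, sp, cfg, freeze = "none")
  expect_false(identical(tl_full$layers$conv1$params$W,
                         tl0$layers$conv1$params$W))
})

test_that("fine-tuning rejects datasets overlapping the pre-training regions", {
  d <- make_task(n = 40, seed = 83)
  sp <- split_dataset(d, seed = 13)
  m <- build_model(model_spec("basset_like", n_outputs = 1, seed = 14))
  expect_error(finetune(m, sp, pretrain_regions = c("r1", "zz")),
               "overlap pre-training")
  # disjoint pre-training regions pass the check
  cfg <- train_config(learning_rate = 3e-4, max_epochs = 1, patience = 1,
                      batch_size = 16, seed = 15)
  expect_s3_class(finetune(m, sp, cfg, pretrain_regions = c("q1", "q2")),
                  "tftl_model")
})

test_that("PWM filter initialization applies the probability-minus-background formula", {
  m <- build_model(model_spec("basset_like", n_outputs = 1, seed = 16))
  det <- matrix(c(1, 0, 0, 0), 4, 3)          # width 3 -> padded to 19
  wide <- random_pwm(21)                      # width 21 -> truncated
  exact <- random_pwm(19)
  m2 <- init_filters_from_pwms(m, list(det, wide, exact))

  w1 <- matrix(m2$layers$conv1$params$W[1, ], nrow = 4)
  left <- (19 - 3) %/% 2
  expect_equal(w1[, left + 1], c(0.75, -0.25, -0.25, -0.25))
  expect_true(all(w1[, c(seq_len(left), (left + 4):19)] == 0))

  w2 <- matrix(m2$layers$conv1$params$W[2, ], nrow = 4)
  start <- (21 - 19) %/% 2 + 1
  expect_equal(w2, unname(wide[, start:(start + 18)] - 0.25),
               tolerance = 1e-12)

  w3 <- matrix(m2$layers$conv1$params$W[3, ], nrow = 4)
  expect_equal(w3, unname(exact - 0.25), tolerance = 1e-12)

  # untouched filters keep their default initialization
  expect_identical(m2$layers$conv1$params$W[4, ],
                   m$layers$conv1$params$W[4, ])

  bad <- matrix(0.3, 4, 5)
  expect_error(init_filters_from_pwms(m, list(bad)), "sum to 1")
  expect_error(init_filters_from_pwms(m, rep(list(exact), 101)),
               "more PWMs")
})

test_that("run_replicates reports one row per seed with a summary", {
  fake <- function(seed) c(tl = 0.8 + seed / 100, scratch = 0.6 + seed / 100)
  out <- run_replicates(fake, seeds = 1:5)
  expect_equal(nrow(out), 5L)
  s <- attr(out, "summary")
  expect_equal(s$median[s$metric == "tl"], 0.83)
  expect_equal(s$median[s$metric == "scratch"], 0.63)
  out2 <- run_replicates(fake, seeds = 1:5)
  expect_identical(out, out2)
})
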