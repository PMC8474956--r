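# Small hand-checkable convolutional model used across interpretation
# tests: one conv block with batch-norm disabled by construction would not
# match the production stack, so a reduced but structurally faithful model
# is assembled from engine layers.
interp_model <- function(n_filters = 4, K = 5, L = 40, seed = 70,
                         with_bn = TRUE) {
  withr::with_seed(seed, {
    L2 <- L %/% 2
    layers <- list(
      tftl:::layer_conv("conv1", C = 4, L = L, K = K, F = n_filters),
      if (with_bn) tftl:::layer_bnorm("bn1", C = n_filters, L = L),
      tftl:::layer_relu("relu1"),
      tftl:::layer_maxpool("pool1", C = n_filters, L = L, k = 2),
      tftl:::layer_dense("fc1", n_in = n_filters * L2, n_out = 8),
      tftl:::layer_relu("relu2"),
      tftl:::layer_dense("output", n_in = 8, n_out = 1),
      tftl:::layer_sigmoid("sigmoid"))
    layers <- layers[!vapply(layers, is.null, TRUE)]
    names(layers) <- vapply(layers, `[[`, "", "name")
    structure(list(spec = list(architecture = "basset_like",
                               input_length = L, n_outputs = 1, seed = seed),
                   layers = layers), class = "tftl_model")
  })
}

test_that("filter_to_pfm matches a brute-force activation scan", {
  m <- interp_model()
  withr::with_seed(71, seqs <- random_seq(20, 40))
  for (f in 1:4) {
    pfm <- filter_to_pfm(m, seqs, f)
    # brute force: explicit activation computation at every full window
    fa <- tftl:::filter_activations(m, seqs)
    A <- matrix(fa$act[seq(f, nrow(fa$act), by = fa$F), ], nrow = fa$L)
    pad <- (fa$K - 1) %/% 2
    valid <- (pad + 1):(fa$L - (fa$K - 1 - pad))
    M <- max(A[valid, ])
    counts <- matrix(0, 4, fa$K,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    n_sites <- 0
    for (b in seq_along(seqs)) {
      for (t in valid) {
        if (A[t, b] >= 0.5 * M && M > 0) {
          counts <- counts + one_hot(substr(seqs[b], t - pad,
                                            t - pad + fa$K - 1))
          n_sites <- n_sites + 1
        }
      }
    }
    expect_equal(pfm$counts, counts)
    expect_equal(pfm$n_sites, n_sites)
    if (pfm$n_sites > 0)
      expect_true(all(colSums(pfm$counts) == pfm$n_sites))
  }
  # batched variant agrees with the per-filter function
  pfms <- filter_motifs(m, seqs)
  expect_equal(pfms[[2]]$counts, filter_to_pfm(m, seqs, 2)$counts)
  expect_error(filter_to_pfm(m, character(0), 1), "empty sequence")
  expect_error(filter_to_pfm(m, seqs, 99), "invalid filter")
})

test_that("a dead filter yields the empty-motif signal", {
  m <- interp_model(with_bn = FALSE)
  # drive filter 1 permanently negative: ReLU output identically zero
  m$layers$conv1$params$W[1, ] <- 0
  m$layers$conv1$params$b[1] <- -5
  withr::with_seed(72, seqs <- random_seq(5, 40))
  pfm <- filter_to_pfm(m, seqs, 1)
  expect_equal(pfm$n_sites, 0L)
  # and its silencing influence is exactly zero
  expect_identical(filter_influence(m, seqs, 1), 0)
})

test_that("pfm_to_pwm applies the pseudocount and information content is correct", {
  pfm <- structure(list(counts = matrix(c(2, 0, 0, 0,
                                          1, 1, 0, 0), 4, 2,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL)),
                        n_sites = 2L), class = "tftl_pfm")
  p <- pfm_to_pwm(pfm, pseudocount = 1)
  expect_equal(colSums(p), c(1, 1))
  expect_equal(unname(p[1, 1]), (2 + 0.25) / 3)
  lo <- pfm_to_pwm(pfm, pseudocount = 1, representation = "log_odds")
  expect_equal(lo, log2(p / 0.25))

  # uniform counts give zero log-odds everywhere
  uni <- structure(list(counts = matrix(1, 4, 3), n_sites = 4L),
                   class = "tftl_pfm")
  expect_true(all(abs(pfm_to_pwm(uni, representation = "log_odds")) < 1e-12))

  expect_equal(information_content(matrix(0.25, 4, 5)), 0)
  det <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(information_content(det), 2)
  expect_equal(information_content(det[, rep(1, 19)]), 38)
})

test_that("filter influence equals a hand-computed value on a one-filter net", {
  # conv(1 filter, K=1) -> relu -> dense(1) -> sigmoid, no pooling/bn
  layers <- list(
    tftl:::layer_conv("conv1", C = 4, L = 2, K = 1, F = 1),
    tftl:::layer_relu("relu1"),
    tftl:::layer_dense("output", n_in = 2, n_out = 1),
    tftl:::layer_sigmoid("sigmoid"))
  names(layers) <- vapply(layers, `[[`, "", "name")
  m <- structure(list(spec = list(architecture = "basset_like",
                                  input_length = 2, n_outputs = 1, seed = 1),
                      layers = layers), class = "tftl_model")
  m$layers$conv1$params$W[1, ] <- c(1, 2, 3, 4)   # weight per base
  m$layers$conv1$params$b <- 0
  m$layers$output$params$W[1, ] <- c(0.5, -0.25)
  m$layers$output$params$b <- 0.1
  x <- encode_batch("AG")  # conv activations: A -> 1, G -> 3
  p_actual <- 1 / (1 + exp(-(0.5 * 1 - 0.25 * 3 + 0.1)))
  p_sil <- 1 / (1 + exp(-0.1))
  expect_equal(filter_influence(m, "AG", 1), (p_actual - p_sil)^2,
               tolerance = 1e-6)
  # invariant to batch order
  withr::with_seed(73, seqs <- random_seq(6, 2))
  expect_equal(filter_influence(m, seqs, 1),
               filter_influence(m, rev(seqs), 1), tolerance = 1e-12)
})

test_that("pwm_similarity finds self and reverse-complement alignments", {
  withr::with_seed(74, {
    p <- random_pwm(8)
    s <- pwm_similarity(p, p)
    expect_equal(s$score, 1, tolerance = 1e-12)
    expect_equal(s$offset, 0L)
    expect_equal(s$orientation, "forward")
    rc <- reverse_complement_pwm(p)
    s2 <- pwm_similarity(p, rc)
    expect_equal(s2$score, 1, tolerance = 1e-12)
    expect_equal(s2$orientation, "reverse")
  })
})

test_that("pwm_similarity equals brute-force maximization over offsets", {
  withr::with_seed(75, {
    for (i in 1:10) {
      a <- random_pwm(sample(5:9, 1))
      b <- random_pwm(sample(5:9, 1))
      got <- pwm_similarity(a, b)
      best <- -Inf
      for (orient in 1:2) {
        bb <- if (orient == 1) b else reverse_complement_pwm(b)
        for (o in -(ncol(bb) - 1):(ncol(a) - 1)) {
          ai <- max(1, o + 1):min(ncol(a), o + ncol(bb))
          if (length(ai) < 4) next
          r <- suppressWarnings(cor(as.numeric(a[, ai]),
                                    as.numeric(bb[, ai - o])))
          if (!is.na(r)) best <- max(best, r)
        }
      }
      expect_equal(got$score, best, tolerance = 1e-12)
    }
  })
})

test_that("attribution satisfies completeness and its degenerate cases", {
  m <- interp_model(seed = 76)
  withr::with_seed(77, {
    s <- random_seq(1, 40)
    refs <- random_seq(10, 40)
    tr <- attribution(m, s, refs)
    expect_equal(dim(unclass(tr)), c(4L, 40L))
    f_x <- forward(m, s)[1, 1]
    f_r <- mean(forward(m, refs)[, 1])
    expect_lt(abs(sum(tr) - (f_x - f_r)), 1e-3)
    # reference equal to the sequence -> all-zero track
    tr0 <- attribution(m, s, s)
    expect_true(all(tr0 == 0))
    # constant model (zero weights into the output) -> all-zero track
    m0 <- m
    m0$layers$output$params$W[] <- 0
    tr1 <- attribution(m0, s, refs)
    expect_true(all(abs(tr1) < 1e-12))
    expect_error(attribution(m, s, substr(refs, 1, 20)), "same length")
  })
})

test_that("attribution tracks export as per-position score tables", {
  m <- interp_model(seed = 78)
  withr::with_seed(79, {
    tr <- attribution(m, random_seq(1, 40), random_seq(3, 40))
  })
  f <- file.path(tempdir(), "track.tsv")
  export_track(tr, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 40L)
  expect_equal(names(back), c("position", "A", "C", "G", "T"))
})
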