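test_that("resize_regions centres on the floored midpoint and drops boundary violations", {
  r <- data.frame(chrom = "c1", start = 100L, end = 317L)
  out <- resize_regions(r)
  expect_equal(out$start, 108L)
  expect_equal(out$end, 308L)

  r2 <- data.frame(chrom = "c1", start = 0L, end = 200L)
  expect_equal(resize_regions(r2)$start, 0L)
  expect_equal(resize_regions(r2)$end, 200L)

  r3 <- data.frame(chrom = "c1", start = 5L, end = 10L)
  expect_message(out3 <- resize_regions(r3), "dropped")
  expect_equal(nrow(out3), 0L)
  expect_equal(attr(out3, "dropped"), 1L)

  # chromosome-length violation on the right end
  r4 <- data.frame(chrom = "c1", start = 950L, end = 990L)
  expect_message(out4 <- resize_regions(r4, chrom_len = c(c1 = 1000L)))
  expect_equal(nrow(out4), 0L)
})

region1 <- data.frame(chrom = "chr1", start = 0L, end = 200L)

ev_base <- function() {
  list(
    peaks = data.frame(chrom = "chr1", start = 0L, end = 200L, summit = 100L,
                       tf = "TFX", cell_type = "A"),
    tfbs = data.frame(chrom = "chr1", start = 50L, end = 60L, tf = "TFX",
                      cell_type = "A"),
    accessibility = data.frame(chrom = "chr1", start = 0L, end = 200L,
                               cell_type = "A"))
}

test_that("label_pair implements the three-state rules in both dialects", {
  ev <- ev_base()
  catalog <- list(TFX = "A")
  # both evidence kinds in the same accessible cell -> bound
  expect_equal(label_pair("TFX", region1, ev, catalog, "sparse"), 1L)
  expect_equal(label_pair("TFX", region1, ev, catalog, "less_sparse"), 1L)

  # summit only: NULL in sparse, 0 in less-sparse
  ev1 <- ev
  ev1$tfbs <- ev1$tfbs[0, ]
  expect_true(is.na(label_pair("TFX", region1, ev1, catalog, "sparse")))
  expect_equal(label_pair("TFX", region1, ev1, catalog, "less_sparse"), 0L)

  # region accessible only where the TF was not profiled -> NULL in both
  ev2 <- ev_base()
  ev2$accessibility$cell_type <- "B"
  expect_true(is.na(label_pair("TFX", region1, ev2, catalog, "sparse")))
  expect_true(is.na(label_pair("TFX", region1, ev2, catalog, "less_sparse")))

  # accessible and profiled but no evidence at all -> 0 in both
  ev3 <- ev_base()
  ev3$peaks <- ev3$peaks[0, ]
  ev3$tfbs <- ev3$tfbs[0, ]
  expect_equal(label_pair("TFX", region1, ev3, catalog, "sparse"), 0L)
  expect_equal(label_pair("TFX", region1, ev3, catalog, "less_sparse"), 0L)

  # evidence kinds split across two cells never produce a bound call
  ev4 <- ev_base()
  ev4$tfbs$cell_type <- "B"
  ev4$accessibility <- rbind(ev4$accessibility,
                             data.frame(chrom = "chr1", start = 0L,
                                        end = 200L, cell_type = "B"))
  cat2 <- list(TFX = c("A", "B"))
  expect_true(is.na(label_pair("TFX", region1, ev4, cat2, "sparse")))
  expect_equal(label_pair("TFX", region1, ev4, cat2, "less_sparse"), 0L)

  expect_error(label_pair("NOPE", region1, ev, catalog, "sparse"),
               "not in profile catalog")
})

test_that("build_binding_matrices matches the brute-force labeller on random evidence", {
  for (seed in 1:25) {
    e <- random_evidence(seed)
    mats <- suppressWarnings(
      build_binding_matrices(e$peaks, e$tfbs, e$acc, catalog = e$catalog))
    reg <- mats$sparse$regions
    for (d in c("sparse", "less_sparse")) {
      got <- mats[[d]]$values
      for (tf in e$tfs) {
        for (j in seq_len(nrow(reg))) {
          want <- oracle_label(tf, reg[j, ], e$peaks, e$tfbs, e$acc,
                               e$catalog, d)
          expect_identical(got[tf, j], want,
                           info = sprintf("seed=%d %s %s region %d",
                                          seed, d, tf, j))
        }
      }
    }
  }
})

test_that("matrix dialects share ones; less-sparse NULLs are a subset of sparse NULLs", {
  for (seed in 26:35) {
    e <- random_evidence(seed)
    mats <- suppressWarnings(
      build_binding_matrices(e$peaks, e$tfbs, e$acc, catalog = e$catalog))
    s <- mats$sparse$values
    l <- mats$less_sparse$values
    expect_identical(which(s == 1L), which(l == 1L))
    expect_true(all(which(is.na(l)) %in% which(is.na(s))))
    expect_true(all(s %in% c(0L, 1L, NA_integer_)))
  }
})

test_that("matrix construction is invariant to record order and duplication", {
  e <- random_evidence(99)
  m1 <- suppressWarnings(
    build_binding_matrices(e$peaks, e$tfbs, e$acc, catalog = e$catalog))
  perm <- function(d) d[rev(seq_len(nrow(d))), , drop = FALSE]
  m2 <- suppressWarnings(
    build_binding_matrices(perm(e$peaks), perm(e$tfbs), perm(e$acc),
                           catalog = e$catalog))
  expect_identical(m1$sparse$values, m2$sparse$values)
  m3 <- suppressWarnings(
    build_binding_matrices(rbind(e$peaks, e$peaks), rbind(e$tfbs, e$tfbs),
                           rbind(e$acc, e$acc), catalog = e$catalog))
  expect_identical(m1$sparse$values, m3$sparse$values)
  expect_identical(m1$less_sparse$values, m3$less_sparse$values)
})

test_that("no binding evidence yields zero ones; cell-map and empty universe errors", {
  e <- random_evidence(7)
  mats <- suppressWarnings(build_binding_matrices(
    e$peaks[0, ], e$tfbs[0, ], e$acc, catalog = e$catalog))
  expect_equal(sum(mats$sparse$values == 1L, na.rm = TRUE), 0L)
  expect_true(all(is.na(mats$sparse$values) | mats$sparse$values == 0L))

  expect_error(suppressWarnings(build_binding_matrices(
    e$peaks, e$tfbs, e$acc[0, ], catalog = e$catalog)),
    "empty region universe")

  cm <- data.frame(raw_label = c("c1", "c2"), canonical_label = c("X", "X"))
  expect_error(build_binding_matrices(e$peaks, e$tfbs, e$acc, cell_map = cm),
               "missing from the correspondence")
})

test_that("a TF with zero profiled cell types warns and gets an all-NULL row", {
  e <- random_evidence(3)
  cat0 <- e$catalog
  cat0[["T1"]] <- character(0)
  expect_warning(mats <- build_binding_matrices(
    e$peaks, e$tfbs, e$acc, catalog = cat0), "zero profiled")
  expect_true(all(is.na(mats$sparse$values["T1", ])))
})

toy_bm <- function(values) {
  tftl:::new_binding_matrix(
    values,
    data.frame(chrom = "chr1", start = (seq_len(ncol(values)) - 1) * 200L,
               end = seq_len(ncol(values)) * 200L),
    "sparse")
}

test_that("cosine similarity prunes NULLs and flags undefined vectors", {
  v <- rbind(a = c(1L, 1L, 0L, NA), b = c(1L, 0L, 1L, 1L))
  colnames(v) <- paste0("r", 1:4)
  bm <- toy_bm(v)
  # prune index 4 -> dot 1, norms sqrt(2)*sqrt(2)
  expect_equal(cosine_similarity(bm, "a", "b"), 0.5)
  expect_equal(cosine_similarity(bm, "b", "a"), 0.5)
  expect_equal(cosine_similarity(bm, "a", "a"), 1)

  v2 <- rbind(a = c(1L, 1L, 0L, 0L), b = c(0L, 0L, 1L, 1L))
  colnames(v2) <- paste0("r", 1:4)
  expect_equal(cosine_similarity(toy_bm(v2), "a", "b"), 0)

  # zero-norm after pruning -> undefined marker
  v3 <- rbind(a = c(0L, 0L, NA, 1L), b = c(1L, 1L, 1L, NA))
  colnames(v3) <- paste0("r", 1:4)
  expect_true(is.na(cosine_similarity(toy_bm(v3), "a", "b")))
  expect_error(cosine_similarity(toy_bm(v3), "a", "zz"), "not in matrix")
})

test_that("cofactor ranking equals a brute-force sort with alphabetical ties", {
  withr::with_seed(42, {
    v <- matrix(sample(c(0L, 1L, NA), 5 * 30, replace = TRUE,
                       prob = c(.5, .3, .2)), 5, 30,
                dimnames = list(c("E", "A", "C", "B", "D"), NULL))
    v["A", 1:10] <- 1L  # ensure the target has bound regions
    colnames(v) <- paste0("r", 1:30)
    bm <- toy_bm(v)
    rk <- cofactor_ranking(bm, "A")
    sims <- sapply(c("B", "C", "D", "E"), function(tf)
      cosine_similarity(bm, "A", tf))
    sims <- sims[!is.na(sims)]
    want <- names(sims)[order(-sims, names(sims))]
    expect_equal(rk$tf, want)
  })
  # all-orthogonal rows tie at zero and sort alphabetically
  v0 <- diag(4L)
  rownames(v0) <- c("D", "B", "A", "C")
  colnames(v0) <- paste0("r", 1:4)
  rk0 <- cofactor_ranking(toy_bm(v0), "A")
  expect_equal(rk0$tf, c("B", "C", "D"))
  expect_equal(rk0$similarity, c(0, 0, 0))
})

test_that("matrix archives round-trip through the text format", {
  e <- random_evidence(12)
  mats <- suppressWarnings(
    build_binding_matrices(e$peaks, e$tfbs, e$acc, catalog = e$catalog))
  pre <- file.path(tempdir(), "bm_test")
  write_binding_matrix(mats$sparse, pre)
  back <- read_binding_matrix(pre)
  expect_identical(back$values, mats$sparse$values)
  expect_equal(back$dialect, "sparse")
  s <- summary(mats$sparse)
  expect_equal(s$ones + s$zeros + s$nulls,
               rep(ncol(mats$sparse$values), nrow(s)))
})
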