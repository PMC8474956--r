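test_that("one-hot encoding maps bases to unit vectors and round-trips", {
  expect_equal(one_hot("A")[, 1], c(A = 1, C = 0, G = 0, T = 0))
  m <- one_hot("ACGT")
  expect_equal(unname(m), diag(4))
  withr::with_seed(1, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
      enc <- one_hot(s)
      expect_true(all(colSums(enc) == 1))
      expect_equal(one_hot_decode(enc), s)
    }
  })
  expect_error(one_hot("ACGN"), "invalid character")
})

mk_sparse <- function(values) {
  tftl:::new_binding_matrix(
    values,
    data.frame(chrom = "chr1", start = (seq_len(ncol(values)) - 1) * 200L,
               end = seq_len(ncol(values)) * 200L),
    "sparse")
}

test_that("single-task extraction respects labels, exclusions and N filtering", {
  v <- matrix(c(1L, 0L, NA, 1L), 1, 4,
              dimnames = list("TFX", NULL))
  bm <- mk_sparse(v)
  rid <- tftl:::region_ids(bm$regions)
  colnames(bm$values) <- rid
  seqs <- setNames(random_seq(4), rid)

  d <- extract_single_task(bm, "TFX", seqs)
  expect_setequal(d$bound$region_id, rid[c(1, 4)])
  expect_equal(d$unbound$region_id, rid[2])

  d2 <- extract_single_task(bm, "TFX", seqs, exclude_regions = rid[1])
  expect_equal(d2$bound$region_id, rid[4])

  seqs_n <- seqs
  substr(seqs_n[4], 5, 5) <- "N"
  d3 <- extract_single_task(bm, "TFX", seqs_n)
  expect_equal(d3$bound$region_id, rid[1])

  v0 <- v
  v0[1, ] <- 0L
  bm0 <- mk_sparse(v0)
  colnames(bm0$values) <- rid
  expect_error(extract_single_task(bm0, "TFX", seqs), "zero usable bound")
})

test_that("multi-task extraction keeps only fully resolved columns", {
  v <- rbind(T1 = c(1L, 0L, NA, 1L), T2 = c(0L, 1L, 1L, 0L))
  bm <- mk_sparse(v)
  bm$dialect <- "less_sparse"
  rid <- tftl:::region_ids(bm$regions)
  colnames(bm$values) <- rid
  seqs <- setNames(random_seq(4), rid)
  d <- extract_multi_task(bm, c("T1", "T2"), seqs)
  expect_setequal(d$region_id, rid[c(1, 2, 4)])
  expect_equal(dim(attr(d, "labels")), c(3L, 2L))

  # brute-force column scan on a random matrix
  withr::with_seed(5, {
    v2 <- matrix(sample(c(0L, 1L, NA), 3 * 40, TRUE), 3, 40,
                 dimnames = list(c("T1", "T2", "T3"), NULL))
    bm2 <- mk_sparse(v2)
    rid2 <- tftl:::region_ids(bm2$regions)
    colnames(bm2$values) <- rid2
    seqs2 <- setNames(random_seq(40), rid2)
    keep <- rid2[apply(!is.na(v2), 2, all)]
    d2 <- extract_multi_task(bm2, c("T1", "T2", "T3"), seqs2)
    expect_setequal(d2$region_id, keep)
  })
})

test_that("GC-matched downsampling hits a 50:50 ratio with matched bins", {
  withr::with_seed(3, {
    gc_seq <- function(n, gc, len = 100) {
      vapply(seq_len(n), function(i) {
        paste(sample(c("G", "C", "A", "T"), len, TRUE,
                     prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
              collapse = "")
      }, "")
    }
    bound <- data.frame(region_id = paste0("b", 1:50),
                        sequence = gc_seq(50, 0.52))
    unbound <- data.frame(region_id = paste0("u", 1:400),
                          sequence = gc_seq(400, 0.45))
    sub <- gc_matched_downsample(bound, unbound, seed = 9)
    expect_equal(nrow(sub), 50L)
    # GC histogram distance to the bound set does not increase
    bins <- seq(0, 1, by = 0.05)
    h <- function(x) tabulate(findInterval(gc_content(x$sequence), bins,
                                           rightmost.closed = TRUE),
                              nbins = 20)
    d_before <- sum(abs(h(bound) / 50 - h(unbound) / 400))
    d_after <- sum(abs(h(bound) / 50 - h(sub) / 50))
    expect_lte(d_after, d_before)
    # determinism
    sub2 <- gc_matched_downsample(bound, unbound, seed = 9)
    expect_identical(sub, sub2)
    expect_false(identical(
      sub, gc_matched_downsample(bound, unbound, seed = 10)))
    expect_error(gc_matched_downsample(unbound, bound, seed = 1),
                 "fewer unbound")
  })
})

test_that("downsampling draws entirely from the matching GC bin when possible", {
  lowgc <- strrep("AT", 50)
  midgc <- paste0(strrep("GC", 26), strrep("AT", 24))  # 52% GC
  bound <- data.frame(region_id = paste0("b", 1:10),
                      sequence = rep(midgc, 10))
  unbound <- data.frame(region_id = paste0("u", 1:40),
                        sequence = c(rep(midgc, 20), rep(lowgc, 20)))
  sub <- gc_matched_downsample(bound, unbound, seed = 4)
  expect_equal(nrow(sub), 10L)
  expect_true(all(sub$sequence == midgc))
})

test_that("dataset splitting follows 80/10/10 with RC augmentation of train and val", {
  withr::with_seed(11, {
    d <- data.frame(region_id = paste0("r", 1:100),
                    sequence = random_seq(100, 50),
                    label = rep(c(1L, 0L), 50))
  })
  sp <- split_dataset(d, seed = 2)
  expect_equal(nrow(sp$train), 160L)
  expect_equal(nrow(sp$val), 20L)
  expect_equal(nrow(sp$test), 10L)
  expect_true(all(sp$test$origin == "forward"))
  expect_setequal(unique(sp$train$origin), c("forward", "reverse_complement"))
  # regions never straddle partitions
  parts <- list(unique(sp$train$region_id), unique(sp$val$region_id),
                unique(sp$test$region_id))
  expect_equal(length(Reduce(intersect, parts)), 0L)
  expect_equal(sum(lengths(parts)), 100L)
  # RC rows carry the same label as their forward mates
  lab <- attr(sp$train, "labels")
  expect_equal(lab[1:80, 1], lab[81:160, 1])
  # different seeds give different partitions of identical sizes
  sp2 <- split_dataset(d, seed = 3)
  expect_equal(nrow(sp2$train), 160L)
  expect_false(setequal(sp$test$region_id, sp2$test$region_id))
  expect_error(split_dataset(d[1:5, ], seed = 1), "fewer than 10")
})

test_that("a palindromic sequence still yields two oriented training rows", {
  d <- data.frame(region_id = paste0("r", 1:10),
                  sequence = rep("ACGT", 10), label = 1:10 %% 2)
  sp <- split_dataset(d, seed = 1)
  tr <- sp$train
  one <- tr[tr$region_id == tr$region_id[1], ]
  expect_equal(nrow(one), 2L)
  expect_setequal(one$origin, c("forward", "reverse_complement"))
  expect_equal(one$sequence[1], one$sequence[2])
})

test_that("fix_dataset_size balances classes and is seed-deterministic", {
  withr::with_seed(8, {
    d <- data.frame(region_id = paste0("r", 1:5000),
                    sequence = random_seq(5000, 20),
                    label = rep(c(1L, 0L), 2500))
  })
  s1 <- fix_dataset_size(d, 2000L, seed = 5)
  expect_equal(nrow(s1), 2000L)
  expect_equal(sum(s1$label), 1000L)
  expect_identical(s1, fix_dataset_size(d, 2000L, seed = 5))
  subs <- lapply(1:5, function(s) fix_dataset_size(d, 2000L, seed = s))
  ids <- sapply(subs, function(x) paste(x$region_id, collapse = ","))
  expect_equal(length(unique(ids)), 5L)
  expect_identical(fix_dataset_size(d, 5000L, seed = 1), d)
  expect_error(fix_dataset_size(d, 6000L, seed = 1), "only")
})

test_that("dataset export writes all partitions with labels", {
  withr::with_seed(2, {
    d <- data.frame(region_id = paste0("r", 1:20),
                    sequence = random_seq(20, 30), label = rep(0:1, 10))
  })
  sp <- split_dataset(d, seed = 1)
  path <- file.path(tempdir(), "ds.tsv.gz")
  export_dataset(sp, path)
  back <- read.delim(gzfile(path))
  expect_setequal(unique(back$partition), c("train", "val", "test"))
  expect_equal(nrow(back), nrow(sp$train) + nrow(sp$val) + nrow(sp$test))
})
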