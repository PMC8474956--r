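# Independent brute-force oracles, deliberately written with naive loops so
# they share no code with the package implementations they check.

# Per-pair three-state labeller: loops over cell types and records directly.
oracle_label <- function(tf, region, peaks, tfbs, acc, catalog, dialect) {
  profiled <- catalog[[tf]]
  if (is.null(profiled)) profiled <- character(0)
  acc_cells <- character(0)
  for (r in seq_len(nrow(acc))) {
    if (acc$chrom[r] == region$chrom && acc$start[r] < region$end &&
        acc$end[r] > region$start)
      acc_cells <- c(acc_cells, acc$cell_type[r])
  }
  matched <- intersect(unique(acc_cells), profiled)
  if (length(matched) == 0) return(NA_integer_)
  single <- FALSE
  for (cell in matched) {
    pk <- FALSE
    for (r in seq_len(nrow(peaks))) {
      if (peaks$tf[r] == tf && peaks$cell_type[r] == cell &&
          peaks$chrom[r] == region$chrom &&
          peaks$summit[r] >= region$start && peaks$summit[r] < region$end) {
        pk <- TRUE
        break
      }
    }
    tb <- FALSE
    for (r in seq_len(nrow(tfbs))) {
      if (tfbs$tf[r] == tf && tfbs$cell_type[r] == cell &&
          tfbs$chrom[r] == region$chrom &&
          tfbs$start[r] < region$end && tfbs$end[r] > region$start) {
        tb <- TRUE
        break
      }
    }
    if (pk && tb) return(1L)
    if (pk || tb) single <- TRUE
  }
  if (single && dialect == "sparse") return(NA_integer_)
  0L
}

# Average precision by exhaustive threshold enumeration.
oracle_aucpr <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  ap <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    prec <- tp / sum(called)
    rec <- tp / P
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Occupancy score by explicit window enumeration on both strands.
oracle_occupancy <- function(pwm, sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_strand <- function(s) {
    W <- ncol(pwm)
    L <- nchar(s)
    if (L < W) return(0)
    total <- 0
    for (j in 1:(L - W + 1)) {
      p <- 1
      for (i in 1:W) {
        base <- substr(s, j + i - 1, j + i - 1)
        p <- p * pwm[base, i]
      }
      total <- total + p
    }
    total
  }
  rc <- paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
  score_strand(sequence) + score_strand(rc)
}

# Plain-R "same"-padded 1D convolution over the (C*L) x B layout.
oracle_conv <- function(x, W, b, C, L, K) {
  B <- ncol(x)
  F <- nrow(W)
  pad_l <- (K - 1) %/% 2
  out <- matrix(0, F * L, B)
  for (bb in 1:B) {
    for (t in 1:L) {
      patch <- numeric(C * K)
      for (k in 1:K) {
        p <- t - pad_l + k - 1
        if (p >= 1 && p <= L)
          patch[((k - 1) * C + 1):(k * C)] <- x[((p - 1) * C + 1):(p * C), bb]
      }
      out[((t - 1) * F + 1):(t * F), bb] <- as.numeric(W %*% patch) + b
    }
  }
  out
}

# Random evidence triple generator for matrix property tests.
random_evidence <- function(seed, n_tfs = 3, n_regions = 5, n_cells = 3,
                            n_peaks = 12, n_tfbs = 12, n_acc = 10) {
  withr::with_seed(seed, {
    tfs <- paste0("T", seq_len(n_tfs))
    cells <- paste0("c", seq_len(n_cells))
    regions <- data.frame(chrom = "chr1",
                          start = (seq_len(n_regions) - 1L) * 200L,
                          end = seq_len(n_regions) * 200L)
    rand_reg <- function(n) sample(n_regions, n, replace = TRUE)
    pi <- rand_reg(n_peaks)
    peaks <- data.frame(chrom = "chr1",
                        start = regions$start[pi], end = regions$end[pi],
                        summit = regions$start[pi] +
                          sample(0:199, n_peaks, replace = TRUE),
                        tf = sample(tfs, n_peaks, replace = TRUE),
                        cell_type = sample(cells, n_peaks, replace = TRUE))
    ti <- rand_reg(n_tfbs)
    off <- sample(0:190, n_tfbs, replace = TRUE)
    tfbs <- data.frame(chrom = "chr1",
                       start = regions$start[ti] + off,
                       end = regions$start[ti] + off + 8L,
                       tf = sample(tfs, n_tfbs, replace = TRUE),
                       cell_type = sample(cells, n_tfbs, replace = TRUE))
    ai <- rand_reg(n_acc)
    acc <- unique(data.frame(chrom = "chr1",
                             start = regions$start[ai],
                             end = regions$end[ai],
                             cell_type = sample(cells, n_acc,
                                                replace = TRUE)))
    catalog <- lapply(setNames(tfs, tfs), function(tf)
      sample(cells, sample(0:n_cells, 1)))
    list(tfs = tfs, cells = cells, regions = regions, peaks = peaks,
         tfbs = tfbs, acc = acc, catalog = catalog)
  })
}

random_seq <- function(n, len = 200) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

random_pwm <- function(width) {
  m <- matrix(rgamma(4 * width, 1) + 1e-9, 4, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}
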