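# Turning binding-matrix slices into balanced, split, one-hot encoded
# machine-learning datasets.

#' One-hot encode a single DNA sequence
#'
#' @param sequence string over A/C/G/T.
#' @return 4 x L matrix with rows A, C, G, T; each column a unit basis
#'   vector.
#' @export
one_hot <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  m <- matrix(cpp_codes_to_onehot(cpp_seq_to_codes(sequence), 1L),
              nrow = 4L)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' @rdname one_hot
#' @param encoded a 4 x L one-hot matrix.
#' @export
one_hot_decode <- function(encoded) {
  paste(c("A", "C", "G", "T")[apply(encoded, 2, which.max)], collapse = "")
}

# fetch sequences for region ids from a named character vector or a
# Biostrings genome (DNAStringSet named by chromosome)
region_sequences <- function(regions, source) {
  rid <- region_ids(regions)
  if (is.character(source)) {
    miss <- setdiff(rid, names(source))
    if (length(miss)) stop("missing sequences for ", length(miss), " region(s)")
    return(setNames(unname(source[rid]), rid))
  }
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(source[[regions$chrom[i]]],
                                    regions$start[i] + 1L, regions$end[i]))
  }, "")
  setNames(toupper(seqs), rid)
}

has_n <- function(x) grepl("[^ACGT]", x)

#' Extract a single-task (one TF) dataset from the sparse matrix
#'
#' Bound examples are the regions labelled 1 for the TF, unbound the
#' regions labelled 0; unresolved entries are skipped. Regions listed in
#' `exclude_regions` (e.g., the regions used for pre-training) and
#' sequences containing non-ACGT characters are discarded.
#'
#' @param bm the sparse-dialect `tftl_bm`.
#' @param tf TF identifier.
#' @param sequences named character vector (region id -> sequence) or a
#'   `Biostrings::DNAStringSet` genome named by chromosome.
#' @param exclude_regions character vector of region ids to drop.
#' @return list with data.frames `bound` and `unbound`
#'   (`region_id`, `sequence`).
#' @export
extract_single_task <- function(bm, tf, sequences,
                                exclude_regions = character()) {
  if (!tf %in% rownames(bm$values)) stop("TF not in matrix: ", tf)
  seqs <- region_sequences(bm$regions, sequences)
  row <- bm$values[tf, ]
  pick <- function(val) {
    rid <- names(row)[!is.na(row) & row == val]
    rid <- setdiff(rid, exclude_regions)
    s <- seqs[rid]
    rid <- rid[!has_n(s)]
    data.frame(region_id = rid, sequence = unname(seqs[rid]),
               stringsAsFactors = FALSE)
  }
  bound <- pick(1L)
  if (nrow(bound) == 0L) stop("TF has zero usable bound regions: ", tf)
  list(bound = bound, unbound = pick(0L))
}

#' Extract a multi-task dataset from the less-sparse matrix
#'
#' Keeps only the regions whose label column is fully resolved (no NA)
#' across all requested TFs.
#'
#' @param bm the less-sparse `tftl_bm`.
#' @param tf_list character vector of TFs (tasks), in output column order.
#' @param sequences as in [extract_single_task()].
#' @param exclude_regions character vector of region ids to drop.
#' @return data.frame (`region_id`, `sequence`) with the binary label
#'   matrix in `attr(, "labels")` (rows = regions, columns = TFs).
#' @export
extract_multi_task <- function(bm, tf_list, sequences,
                               exclude_regions = character()) {
  miss <- setdiff(tf_list, rownames(bm$values))
  if (length(miss)) stop("TF(s) not in matrix: ", paste(miss, collapse = ", "))
  sub <- bm$values[tf_list, , drop = FALSE]
  keep <- colSums(is.na(sub)) == 0L
  rid <- colnames(sub)[keep]
  rid <- setdiff(rid, exclude_regions)
  seqs <- region_sequences(bm$regions, sequences)[rid]
  rid <- rid[!has_n(seqs)]
  if (length(rid) == 0L) stop("no fully resolved regions for this TF set")
  out <- data.frame(region_id = rid, sequence = unname(seqs[rid]),
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- t(sub[, rid, drop = FALSE])
  out
}

#' GC-matched downsampling of unbound regions to a 50:50 ratio
#'
#' Selects `nrow(bound)` unbound regions whose %GC distribution matches the
#' bound set: within each 5-percentage-point GC bin the selected count equals
#' the bound count, borrowing from the nearest non-exhausted bin when a bin
#' runs out. Deterministic given `seed`.
#'
#' @param bound,unbound data.frames with a `sequence` column.
#' @param seed integer seed.
#' @param bin_width GC bin width (default 0.05).
#' @return the selected subset of `unbound` rows.
#' @export
gc_matched_downsample <- function(bound, unbound, seed, bin_width = 0.05) {
  n <- nrow(bound)
  if (nrow(unbound) < n)
    stop("fewer unbound (", nrow(unbound), ") than bound (", n, ") regions")
  nb <- ceiling(1 / bin_width)
  bin_of <- function(gc) pmin(floor(gc / bin_width), nb - 1L) + 1L
  need <- tabulate(bin_of(gc_content(bound$sequence)), nbins = nb)
  pool <- split(seq_len(nrow(unbound)),
                factor(bin_of(gc_content(unbound$sequence)), levels = 1:nb))
  with_seed(seed, {
    take <- integer(0)
    deficit <- integer(nb)
    for (b in seq_len(nb)) {
      avail <- pool[[b]]
      k <- min(need[b], length(avail))
      if (k > 0) {
        sel <- if (length(avail) == 1L) avail else sample(avail, k)
        sel <- sel[seq_len(k)]
        take <- c(take, sel)
        pool[[b]] <- setdiff(avail, sel)
      }
      deficit[b] <- need[b] - k
    }
    for (b in which(deficit > 0)) {
      while (deficit[b] > 0) {
        sizes <- lengths(pool)
        cand <- which(sizes > 0)
        if (length(cand) == 0L) stop("unbound pool exhausted")
        nearest <- cand[order(abs(cand - b), cand)][1]
        avail <- pool[[nearest]]
        k <- min(deficit[b], length(avail))
        sel <- if (length(avail) == 1L) avail else sample(avail, k)
        sel <- sel[seq_len(k)]
        take <- c(take, sel)
        pool[[nearest]] <- setdiff(avail, sel)
        deficit[b] <- deficit[b] - k
      }
    }
    unbound[sort(take), , drop = FALSE]
  })
}

#' Split a dataset into train/validation/test with reverse-complement
#' augmentation
#'
#' Regions are partitioned 80/10/10 before augmentation, so a region and
#' its reverse complement never straddle partitions. The training and
#' validation partitions contain each region in both orientations; the test
#' partition is forward-only.
#'
#' @param dataset data.frame with `region_id`, `sequence` and either a
#'   `label` column or a label matrix in `attr(, "labels")`.
#' @param seed integer seed controlling the random partition.
#' @param fractions train/val/test fractions (default `c(0.8, 0.1, 0.1)`).
#' @return list of class `tftl_split` with data.frames `train`, `val`,
#'   `test`, each with an `origin` column (`forward` /
#'   `reverse_complement`) and labels carried per row.
#' @export
split_dataset <- function(dataset, seed, fractions = c(0.8, 0.1, 0.1)) {
  n <- nrow(dataset)
  if (n < 10L) stop("fewer than 10 regions cannot be split 80/10/10")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  labels <- attr(dataset, "labels")
  if (is.null(labels)) {
    stopifnot("label" %in% names(dataset))
    labels <- matrix(dataset$label, ncol = 1,
                     dimnames = list(NULL, "label"))
  }
  ord <- with_seed(seed, sample.int(n))
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  idx <- list(train = ord[seq_len(n_train)],
              val = ord[n_train + seq_len(n_val)],
              test = ord[n_train + n_val + seq_len(n_test)])
  part <- function(i, augment) {
    d <- data.frame(region_id = dataset$region_id[i],
                    sequence = dataset$sequence[i],
                    origin = "forward", stringsAsFactors = FALSE)
    lab <- labels[i, , drop = FALSE]
    if (augment) {
      rc <- d
      rc$sequence <- reverse_complement(rc$sequence)
      rc$origin <- "reverse_complement"
      d <- rbind(d, rc)
      lab <- rbind(lab, lab)
    }
    attr(d, "labels") <- lab
    d
  }
  structure(list(train = part(idx$train, TRUE),
                 val = part(idx$val, TRUE),
                 test = part(idx$test, FALSE)),
            seed = seed, fractions = fractions, class = "tftl_split")
}

#' @export
print.tftl_split <- function(x, ...) {
  cat("<tftl_split> train=", nrow(x$train), " val=", nrow(x$val),
      " test=", nrow(x$test), " sequences (RC-augmented train/val)\n",
      sep = "")
  invisible(x)
}

#' Downsample a labelled dataset to a fixed number of regions
#'
#' For a single-task dataset the subsample is class-balanced (half bound,
#' half unbound); for a multi-task dataset it is uniform. Deterministic
#' given `seed`.
#'
#' @param dataset data.frame as in [split_dataset()].
#' @param n_target number of regions to keep.
#' @param seed integer seed.
#' @return the downsampled dataset (labels attribute preserved).
#' @export
fix_dataset_size <- function(dataset, n_target, seed) {
  n <- nrow(dataset)
  if (n < n_target) stop("dataset has only ", n, " regions; need ", n_target)
  if (n == n_target) return(dataset)
  labels <- attr(dataset, "labels")
  single <- !is.null(dataset$label) || (!is.null(labels) && ncol(labels) == 1)
  lab <- if (!is.null(dataset$label)) dataset$label else
    if (!is.null(labels)) labels[, 1] else NULL
  keep <- with_seed(seed, {
    if (single && !is.null(lab)) {
      pos <- which(lab == 1)
      neg <- which(lab == 0)
      k_pos <- min(length(pos), ceiling(n_target / 2))
      k_neg <- n_target - k_pos
      if (k_neg > length(neg)) {
        k_neg <- length(neg)
        k_pos <- n_target - k_neg
      }
      sort(c(sample(pos, k_pos), sample(neg, k_neg)))
    } else sort(sample.int(n, n_target))
  })
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(labels)) attr(out, "labels") <- labels[keep, , drop = FALSE]
  out
}

#' Export a dataset split as a gzipped TSV
#'
#' Columns: region id, sequence, label(s), origin, partition.
#'
#' @param split a `tftl_split`.
#' @param path output path (`.tsv.gz`).
#' @return `path`, invisibly.
#' @export
export_dataset <- function(split, path) {
  rows <- lapply(c("train", "val", "test"), function(p) {
    d <- split[[p]]
    lab <- attr(d, "labels")
    cbind(d, as.data.frame(lab), partition = p)
  })
  out <- do.call(rbind, rows)
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
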