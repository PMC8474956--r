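# Self-contained synthetic worlds with known ground truth: motifs, motif
# families (binding modes), cofactor co-occurrence, sequences, evidence
# records and the resulting three-state binding matrices.

#' Generate a random motif with a target information content
#'
#' Draws a random base composition per column and anneals a global
#' sharpness parameter until the total information content is within 0.5
#' bits of `ic_target`.
#'
#' @param seed integer seed.
#' @param width motif width in bp.
#' @param ic_target total information content in bits (0 to 2 * width).
#' @return 4 x width probability matrix (rows A, C, G, T).
#' @export
make_motif <- function(seed, width, ic_target) {
  stopifnot(ic_target >= 0, ic_target <= 2 * width)
  with_seed(seed, {
    raw <- matrix(rgamma(4 * width, shape = 0.5) + 1e-9, 4, width)
    raw <- sweep(raw, 2, colSums(raw), "/")
    sharpen <- function(beta) {
      p <- raw^beta
      sweep(p, 2, colSums(p), "/")
    }
    lo <- 0; hi <- 400
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (information_content(sharpen(mid)) < ic_target) lo <- mid
      else hi <- mid
    }
    m <- sharpen((lo + hi) / 2)
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
}

#' Generate a family of perturbed motif variants
#'
#' Models a shared binding mode: each variant keeps most base columns but
#' replaces a `divergence` fraction of them (at least one when
#' `divergence > 0`) with fresh random columns annealed to the same
#' per-column information content, so variants stay equally "sharp" while
#' their similarity to the base decreases with `divergence` in
#' expectation.
#'
#' @param base 4 x W probability matrix.
#' @param n number of variants.
#' @param divergence expected fraction of replaced columns in \[0, 1\]
#'   (0 returns copies).
#' @param seed integer seed.
#' @return list of `n` probability matrices.
#' @export
make_family <- function(base, n, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1)
  W <- ncol(base)
  col_ic <- function(p) {
    pl <- p * log2(p)
    pl[p == 0] <- 0
    2 + sum(pl)
  }
  fresh_column <- function(ic_target) {
    raw <- rgamma(4, shape = 0.5) + 1e-9
    raw <- raw / sum(raw)
    lo <- 0; hi <- 400
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      p <- raw^mid
      if (col_ic(p / sum(p)) < ic_target) lo <- mid else hi <- mid
    }
    p <- raw^((lo + hi) / 2)
    p / sum(p)
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- base
      if (divergence > 0) {
        k <- max(1L, rbinom(1, W, divergence))
        for (j in sample.int(W, k))
          m[, j] <- fresh_column(col_ic(base[, j]))
      }
      rownames(m) <- rownames(base)
      m
    })
  })
}

sample_motif_instance <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm, 2, function(p)
    sample.int(4, 1, prob = p))], collapse = "")
}

#' Configuration of a synthetic TF binding world
#'
#' @param n_tfs number of TFs.
#' @param n_regions number of 200-bp regions in the accessibility universe.
#' @param region_length region length in bp (default 200).
#' @param gc background G+C fraction (default 0.41, genome-like).
#' @param motif_width range (min, max) of motif widths.
#' @param ic range (min, max) of total motif information content in bits.
#' @param binding_modes integer vector, one mode per TF (TFs sharing a
#'   value form a motif family); default: all distinct.
#' @param family_divergence column-mixing divergence of family variants.
#' @param cofactors optional data.frame (`tf_a`, `tf_b`, `prob`): regions
#'   bound by `tf_a` are additionally bound by `tf_b` with probability
#'   `prob`.
#' @param bound_rate per-TF probability that a resolvable region is bound
#'   (scalar or vector of length `n_tfs`).
#' @param n_cell_types number of simulated cell types.
#' @param profile_prob probability a TF is ChIP-profiled in a cell type.
#' @param access_prob probability a region is accessible in a cell type.
#'   Together with `profile_prob` this induces the unresolved (NULL) rate.
#' @param single_evidence_rate probability that an accessible, unbound
#'   (TF, region) pair receives exactly one evidence kind (these become
#'   NULL in the sparse dialect and 0 in the less-sparse dialect).
#' @param seed mandatory integer seed.
#' @return list of class `tftl_world_config`.
#' @export
world_config <- function(n_tfs = 8L, n_regions = 2000L, region_length = 200L,
                         gc = 0.41, motif_width = c(10L, 12L),
                         ic = c(9, 11), binding_modes = NULL,
                         family_divergence = 0.2, cofactors = NULL,
                         bound_rate = 0.15, n_cell_types = 3L,
                         profile_prob = 1, access_prob = 1,
                         single_evidence_rate = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(binding_modes)) binding_modes <- seq_len(n_tfs)
  stopifnot(length(binding_modes) == n_tfs,
            gc > 0, gc < 1, all(bound_rate >= 0), all(bound_rate <= 1),
            profile_prob >= 0, profile_prob <= 1,
            access_prob >= 0, access_prob <= 1,
            single_evidence_rate >= 0, single_evidence_rate <= 1)
  if (motif_width[2] > region_length)
    stop("motif wider than the region length")
  structure(list(n_tfs = as.integer(n_tfs),
                 n_regions = as.integer(n_regions),
                 region_length = as.integer(region_length), gc = gc,
                 motif_width = motif_width, ic = ic,
                 binding_modes = as.integer(binding_modes),
                 family_divergence = family_divergence,
                 cofactors = cofactors,
                 bound_rate = rep_len(bound_rate, n_tfs),
                 n_cell_types = as.integer(n_cell_types),
                 profile_prob = profile_prob, access_prob = access_prob,
                 single_evidence_rate = single_evidence_rate,
                 seed = as.integer(seed)),
            class = "tftl_world_config")
}

#' Generate a synthetic world
#'
#' Draws motifs per binding mode (family variants for TFs sharing a mode),
#' simulates cell-type coverage (which induces unresolved matrix entries),
#' samples ground-truth bound (TF, region) pairs with configurable
#' cofactor co-occurrence, emits peak-summit/TFBS/accessibility evidence
#' records, implants one stochastically sampled motif instance per bound
#' pair into GC-controlled background sequences, and builds both matrix
#' dialects through [build_binding_matrices()] so the real labelling code
#' path is exercised.
#'
#' @param config a [world_config()].
#' @return list of class `tftl_world`: `tf_ids`, `binding_modes` (named
#'   list, selection-ready), `motifs`, `regions`, `sequences` (named by
#'   region id), `matrices` (`$sparse`, `$less_sparse`), `evidence`, and
#'   `truth` (`$bound` logical TF x region matrix, `$implants`
#'   data.frame).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "tftl_world_config"))
  cfg <- config
  with_seed(cfg$seed, {
    tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    # one base motif per binding mode; family members are variants
    modes <- cfg$binding_modes
    motifs <- vector("list", cfg$n_tfs)
    for (m in unique(modes)) {
      idx <- which(modes == m)
      w <- sample(cfg$motif_width[1]:cfg$motif_width[2], 1)
      ict <- runif(1, cfg$ic[1], cfg$ic[2])
      base <- make_motif(sample.int(1e6, 1), w, ict)
      if (length(idx) == 1L) motifs[[idx]] <- base
      else {
        fam <- make_family(base, length(idx), cfg$family_divergence,
                           seed = sample.int(1e6, 1))
        for (j in seq_along(idx)) motifs[[idx[j]]] <- fam[[j]]
      }
    }
    names(motifs) <- tf_ids

    L <- cfg$region_length
    regions <- data.frame(chrom = "chrS",
                          start = (seq_len(cfg$n_regions) - 1L) * L,
                          end = seq_len(cfg$n_regions) * L)
    rid <- region_ids(regions)
    cells <- sprintf("cell%02d", seq_len(cfg$n_cell_types))

    profiled <- matrix(runif(cfg$n_tfs * cfg$n_cell_types) < cfg$profile_prob,
                       cfg$n_tfs, cfg$n_cell_types,
                       dimnames = list(tf_ids, cells))
    accessible <- matrix(runif(cfg$n_regions * cfg$n_cell_types) <
                           cfg$access_prob,
                         cfg$n_regions, cfg$n_cell_types,
                         dimnames = list(rid, cells))

    matched <- accessible %*% t(profiled) > 0        # region x tf: any cell
    bound <- matrix(FALSE, cfg$n_tfs, cfg$n_regions,
                    dimnames = list(tf_ids, rid))
    for (i in seq_len(cfg$n_tfs)) {
      cand <- which(matched[, i])
      bound[i, cand] <- runif(length(cand)) < cfg$bound_rate[i]
    }
    if (!is.null(cfg$cofactors)) {
      for (r in seq_len(nrow(cfg$cofactors))) {
        a <- cfg$cofactors$tf_a[r]; b <- cfg$cofactors$tf_b[r]
        p <- cfg$cofactors$prob[r]
        cand <- which(bound[a, ] & matched[, match(b, tf_ids)])
        hit <- cand[runif(length(cand)) < p]
        bound[b, hit] <- TRUE
      }
    }

    # evidence records: one peak summit + one TFBS in a common matched cell
    # per bound pair, plus single-evidence (ambiguous) records at the
    # configured rate on unbound matched pairs
    pick_cell <- function(i, j) {
      ok <- which(accessible[j, ] & profiled[i, ])
      cells[if (length(ok) == 1L) ok else sample(ok, 1)]
    }
    pk <- list(s = integer(0), tf = character(0), cell = character(0))
    tb <- list(o = integer(0), tf = character(0), cell = character(0))
    for (i in seq_len(cfg$n_tfs)) {
      reg_idx <- which(bound[i, ])
      if (length(reg_idx)) {
        cell <- vapply(reg_idx, function(j) pick_cell(i, j), "")
        s <- regions$start[reg_idx] + sample.int(L, length(reg_idx),
                                                 replace = TRUE) - 1L
        o <- regions$start[reg_idx] + sample.int(L - 10L, length(reg_idx),
                                                 replace = TRUE) - 1L
        pk$s <- c(pk$s, s)
        pk$tf <- c(pk$tf, rep(tf_ids[i], length(reg_idx)))
        pk$cell <- c(pk$cell, cell)
        tb$o <- c(tb$o, o)
        tb$tf <- c(tb$tf, rep(tf_ids[i], length(reg_idx)))
        tb$cell <- c(tb$cell, cell)
      }
      if (cfg$single_evidence_rate > 0) {
        cand <- which(matched[, i] & !bound[i, ])
        amb <- cand[runif(length(cand)) < cfg$single_evidence_rate]
        if (length(amb) == 0L) next
        cell <- vapply(amb, function(j) pick_cell(i, j), "")
        as_peak <- runif(length(amb)) < 0.5
        s <- regions$start[amb] + sample.int(L, length(amb),
                                             replace = TRUE) - 1L
        o <- regions$start[amb] + sample.int(L - 10L, length(amb),
                                             replace = TRUE) - 1L
        pk$s <- c(pk$s, s[as_peak])
        pk$tf <- c(pk$tf, rep(tf_ids[i], sum(as_peak)))
        pk$cell <- c(pk$cell, cell[as_peak])
        tb$o <- c(tb$o, o[!as_peak])
        tb$tf <- c(tb$tf, rep(tf_ids[i], sum(!as_peak)))
        tb$cell <- c(tb$cell, cell[!as_peak])
      }
    }
    peaks <- data.frame(chrom = rep("chrS", length(pk$s)),
                        start = pmax(0L, pk$s - 50L), end = pk$s + 50L,
                        summit = pk$s, tf = pk$tf, cell_type = pk$cell)
    tfbs <- data.frame(chrom = rep("chrS", length(tb$o)),
                       start = tb$o, end = tb$o + 10L, tf = tb$tf,
                       cell_type = tb$cell)
    acc_idx <- which(accessible, arr.ind = TRUE)
    acc <- data.frame(chrom = "chrS",
                      start = regions$start[acc_idx[, 1]],
                      end = regions$end[acc_idx[, 1]],
                      cell_type = cells[acc_idx[, 2]])

    # background sequences at the configured GC (integer codes 1..4),
    # then motif implants; implants avoid overlapping each other when a
    # non-clashing position can be found in 20 draws
    base_p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    codes <- matrix(sample.int(4L, cfg$n_regions * L, replace = TRUE,
                               prob = base_p), nrow = L)
    imp <- list(region = character(0), tf = character(0),
                start = integer(0), end = integer(0), strand = character(0))
    used <- vector("list", cfg$n_regions)
    for (i in seq_len(cfg$n_tfs)) {
      pw <- motifs[[i]]
      w <- ncol(pw)
      reg_idx <- which(bound[i, ])
      if (length(reg_idx) == 0L) next
      # column-wise instance sampling, vectorized over implants
      cum <- apply(pw, 2, cumsum)
      u <- matrix(runif(length(reg_idx) * w), ncol = w)
      inst <- matrix(1L, length(reg_idx), w)
      for (jc in seq_len(w))
        inst[, jc] <- 1L + (u[, jc] > cum[1, jc]) + (u[, jc] > cum[2, jc]) +
          (u[, jc] > cum[3, jc])
      strand <- ifelse(runif(length(reg_idx)) < 0.5, "+", "-")
      pos_i <- integer(length(reg_idx))
      for (k in seq_along(reg_idx)) {
        j <- reg_idx[k]
        ik <- inst[k, ]
        if (strand[k] == "-") ik <- rev(5L - ik)
        pos <- NA_integer_
        for (try in 1:20) {
          cand <- sample.int(L - w + 1L, 1)
          clash <- any(vapply(used[[j]], function(iv)
            cand <= iv[2] && (cand + w - 1L) >= iv[1], TRUE))
          if (!clash) { pos <- cand; break }
        }
        if (is.na(pos)) pos <- sample.int(L - w + 1L, 1)
        codes[pos:(pos + w - 1L), j] <- ik
        used[[j]] <- c(used[[j]], list(c(pos, pos + w - 1L)))
        pos_i[k] <- pos
      }
      imp$region <- c(imp$region, rid[reg_idx])
      imp$tf <- c(imp$tf, rep(tf_ids[i], length(reg_idx)))
      imp$start <- c(imp$start, pos_i)
      imp$end <- c(imp$end, pos_i + w - 1L)
      imp$strand <- c(imp$strand, strand)
    }
    seqs <- setNames(cpp_codes_to_seq(codes), rid)
    implants <- data.frame(region_id = imp$region, tf = imp$tf,
                           start = imp$start, end = imp$end,
                           strand = imp$strand)

    catalog <- lapply(seq_len(cfg$n_tfs), function(i) cells[profiled[i, ]])
    names(catalog) <- tf_ids
    mats <- build_binding_matrices(peaks, tfbs, acc,
                                   region_length = L,
                                   chrom_len = c(chrS = cfg$n_regions * L),
                                   catalog = catalog)
    structure(list(config = cfg, tf_ids = tf_ids,
                   binding_modes = setNames(as.list(modes), tf_ids),
                   motifs = motifs, regions = regions, sequences = seqs,
                   matrices = mats,
                   evidence = list(peaks = peaks, tfbs = tfbs,
                                   accessibility = acc, catalog = catalog),
                   truth = list(bound = bound, implants = implants,
                                profiled = profiled,
                                accessible = accessible)),
              class = "tftl_world")
  })
}

#' @export
print.tftl_world <- function(x, ...) {
  cat("<tftl_world> ", x$config$n_tfs, " TFs x ", x$config$n_regions,
      " regions | ", sum(x$truth$bound), " bound pairs | seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits FASTA sequences, BED-style evidence TSVs, both matrix archives
#' and a ground-truth JSON manifest.
#'
#' @param world a `tftl_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(world$sequences),
    file.path(dir, "regions.fa"))
  utils::write.table(world$evidence$peaks, file.path(dir, "peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$evidence$tfbs, file.path(dir, "tfbs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$evidence$accessibility, file.path(dir, "dhs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_binding_matrix(world$matrices$sparse, file.path(dir, "sparse"))
  write_binding_matrix(world$matrices$less_sparse,
                       file.path(dir, "less_sparse"))
  write_meme(world$motifs, file.path(dir, "true_motifs.meme"))
  jsonlite::write_json(
    list(seed = world$config$seed,
         n_tfs = world$config$n_tfs,
         n_regions = world$config$n_regions,
         binding_modes = world$binding_modes,
         implants = world$truth$implants),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
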