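# Selection of biologically relevant pre-training TF sets.
#
# Five strategies: TFs sharing a binding mode with the target; cofactors
# (top of the binding-vector cosine ranking, different binding mode);
# non-cofactors with the same binding mode (bottom of the ranking);
# functional partners by confidence score (different binding mode); and
# randomly selected TFs with different binding modes. Ties are always
# broken by score then lexicographic TF identifier.

#' Read a TF -> binding-mode table
#'
#' TSV with columns `tf` and `binding_modes` (comma-separated integers).
#'
#' @param path file path.
#' @return named list: TF -> integer vector of binding modes.
#' @export
read_binding_modes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "binding_modes") %in% names(df)))
  setNames(lapply(strsplit(as.character(df$binding_modes), ","),
                  function(x) as.integer(trimws(x))), df$tf)
}

#' Read a TF partner-confidence table
#'
#' TSV with columns `tf`, `partner`, `confidence`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_partners <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "partner", "confidence") %in% names(df)))
  df
}

#' Do two TFs share a binding mode?
#'
#' @param tf_a,tf_b TF identifiers.
#' @param bm_table named list TF -> binding-mode vector (see
#'   [read_binding_modes()]).
#' @return logical.
#' @export
share_binding_mode <- function(tf_a, tf_b, bm_table) {
  for (tf in c(tf_a, tf_b))
    if (is.null(bm_table[[tf]])) stop("TF with unknown binding mode: ", tf)
  length(intersect(bm_table[[tf_a]], bm_table[[tf_b]])) > 0
}

# TFs with a known binding mode, minus the target; warns about unknowns
known_mode_pool <- function(tfs, target, bm_table) {
  pool <- setdiff(tfs, target)
  unknown <- pool[!pool %in% names(bm_table)]
  if (length(unknown))
    warning("excluding TF(s) with unknown binding mode: ",
            paste(unknown, collapse = ", "))
  setdiff(pool, unknown)
}

new_pretrain_set <- function(target, strategy, members, include_target) {
  structure(list(target_tf = target, strategy = strategy,
                 members = members, include_target = include_target),
            class = "tftl_pretrain_set")
}

#' @export
print.tftl_pretrain_set <- function(x, ...) {
  cat("<tftl_pretrain_set> target=", x$target_tf, " strategy=", x$strategy,
      if (x$include_target) " (target included)", "\n  members: ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

take_k <- function(target, k, include_target, ranked, strategy) {
  need <- if (include_target) k - 1L else k
  if (length(ranked) < need)
    stop("only ", length(ranked), " eligible TF(s); need ", need)
  members <- head(ranked, need)
  if (include_target) members <- c(target, members)
  new_pretrain_set(target, strategy, members, include_target)
}

#' Select cofactors of a target TF for pre-training
#'
#' Ranks all other TFs by binding-vector cosine similarity to the target
#' (sparse matrix), removes those sharing a binding mode with the target
#' (unless `ignore_modes`), and keeps the top `k` (top `k - 1` plus the
#' target itself when `include_target`).
#'
#' @param target target TF.
#' @param bm sparse-dialect `tftl_bm`.
#' @param bm_table binding-mode table.
#' @param k pre-training set size (default 5).
#' @param include_target include the target among the `k`.
#' @param ignore_modes skip the binding-mode filter ("best cofactors
#'   regardless of binding mode").
#' @return a `tftl_pretrain_set`.
#' @export
select_cofactors <- function(target, bm, bm_table, k = 5L,
                             include_target = FALSE, ignore_modes = FALSE) {
  rk <- cofactor_ranking(bm, target)
  pool <- known_mode_pool(rk$tf, target, bm_table)
  rk <- rk[rk$tf %in% pool, , drop = FALSE]
  if (!ignore_modes) {
    shared <- vapply(rk$tf, share_binding_mode, TRUE,
                     tf_b = target, bm_table = bm_table)
    rk <- rk[!shared, , drop = FALSE]
  }
  take_k(target, k, include_target, rk$tf, "cofactor")
}

#' Select non-cofactors sharing the target's binding mode
#'
#' Keeps only TFs sharing a binding mode with the target and takes the
#' bottom `k` of the cosine-similarity ranking (least correlated binding).
#'
#' @inheritParams select_cofactors
#' @return a `tftl_pretrain_set`.
#' @export
select_noncofactors_same_bm <- function(target, bm, bm_table, k = 5L,
                                        include_target = FALSE) {
  rk <- cofactor_ranking(bm, target)
  pool <- known_mode_pool(rk$tf, target, bm_table)
  rk <- rk[rk$tf %in% pool, , drop = FALSE]
  shared <- vapply(rk$tf, share_binding_mode, TRUE,
                   tf_b = target, bm_table = bm_table)
  rk <- rk[shared, , drop = FALSE]
  # ascending similarity, ties by TF id
  ranked <- rk$tf[order(rk$similarity, rk$tf)]
  take_k(target, k, include_target, ranked, "noncofactor_same_bm")
}

#' Select functional partners by confidence score
#'
#' Sorts the target's partners by decreasing confidence (ties by TF
#' identifier), removes those sharing a binding mode with the target
#' (unless `ignore_modes`), and keeps the top `k`.
#'
#' @inheritParams select_cofactors
#' @param partners partner table (see [read_partners()]).
#' @return a `tftl_pretrain_set`.
#' @export
select_string_partners <- function(target, partners, bm_table, k = 5L,
                                   include_target = FALSE,
                                   ignore_modes = FALSE) {
  p <- partners[partners$tf == target, , drop = FALSE]
  p <- p[order(-p$confidence, p$partner), , drop = FALSE]
  pool <- known_mode_pool(p$partner, target, bm_table)
  p <- p[p$partner %in% pool, , drop = FALSE]
  if (!ignore_modes) {
    shared <- vapply(p$partner, share_binding_mode, TRUE,
                     tf_b = target, bm_table = bm_table)
    p <- p[!shared, , drop = FALSE]
  }
  take_k(target, k, include_target, p$partner, "string_partner")
}

#' Select TFs sharing the target's binding mode (random draw)
#'
#' @inheritParams select_cofactors
#' @param candidates character vector of candidate TFs (e.g., the matrix
#'   rows).
#' @param seed integer seed for the uniform draw.
#' @return a `tftl_pretrain_set`.
#' @export
select_same_bm <- function(target, candidates, bm_table, k = 5L,
                           include_target = FALSE, seed = 1L) {
  pool <- known_mode_pool(candidates, target, bm_table)
  pool <- sort(pool[vapply(pool, share_binding_mode, TRUE,
                           tf_b = target, bm_table = bm_table)])
  ranked <- with_seed(seed, sample(pool))
  out <- take_k(target, k, include_target, ranked, "same_bm")
  out
}

#' Select random TFs with different binding modes
#'
#' @inheritParams select_same_bm
#' @return a `tftl_pretrain_set`.
#' @export
select_random_diff_bm <- function(target, candidates, bm_table, k = 5L,
                                  include_target = FALSE, seed = 1L) {
  pool <- known_mode_pool(candidates, target, bm_table)
  pool <- sort(pool[!vapply(pool, share_binding_mode, TRUE,
                            tf_b = target, bm_table = bm_table)])
  ranked <- with_seed(seed, sample(pool))
  take_k(target, k, include_target, ranked, "random_diff_bm")
}

#' Bury a pre-training core among additional TFs
#'
#' Extends a pre-training set to `n_total` members by adding TFs drawn
#' uniformly from `pool`, each with no shared binding mode with the
#' target.
#'
#' @param core a `tftl_pretrain_set`.
#' @param pool character vector of candidate TFs to draw from.
#' @param bm_table binding-mode table.
#' @param n_total total set size (default 50).
#' @param seed integer seed.
#' @return a `tftl_pretrain_set` with the core preserved.
#' @export
bury <- function(core, pool, bm_table, n_total = 50L, seed = 1L) {
  stopifnot(inherits(core, "tftl_pretrain_set"))
  need <- n_total - length(core$members)
  pool <- known_mode_pool(setdiff(pool, c(core$members, core$target_tf)),
                          core$target_tf, bm_table)
  pool <- sort(pool[!vapply(pool, share_binding_mode, TRUE,
                            tf_b = core$target_tf, bm_table = bm_table)])
  if (length(pool) < need)
    stop("pool has only ", length(pool), " eligible TF(s); need ", need)
  extra <- with_seed(seed, sample(pool, need))
  new_pretrain_set(core$target_tf, paste0(core$strategy, "_buried"),
                   c(core$members, extra), core$include_target)
}
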