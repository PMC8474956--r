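# Three-state TF x region binding matrices.
#
# Entries are 1 (bound: accessible region with both a ChIP-seq peak summit
# and a TFBS of the TF in one and the same matched cell type), 0 (unbound:
# accessible in a cell type where the TF was profiled, without such
# support) or NA (unresolved). Two dialects differ in how single-evidence
# cases (summit or TFBS, not both) are treated: NA in the "sparse" dialect,
# 0 in the "less_sparse" dialect. Coordinates are BED-style 0-based
# half-open; summits are single 0-based positions.

#' Resize genomic regions to a fixed length around their midpoint
#'
#' Each region is re-centred on `floor((start + end) / 2)` and extended to
#' `target_len` bp. Regions whose resized span would cross a chromosome
#' boundary (start < 0, or end beyond `chrom_len` when known) are dropped
#' with a message.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param target_len even positive target length in bp (default 200).
#' @param chrom_len optional named vector of chromosome lengths.
#' @return the resized data.frame; dropped rows are removed and flagged in
#'   `attr(, "dropped")` (row indices of the input).
#' @export
resize_regions <- function(regions, target_len = 200L, chrom_len = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            target_len > 0, target_len %% 2 == 0,
            all(regions$start < regions$end))
  center <- (regions$start + regions$end) %/% 2L
  start <- center - target_len %/% 2L
  end <- start + target_len
  bad <- start < 0L
  if (!is.null(chrom_len)) {
    cl <- chrom_len[as.character(regions$chrom)]
    bad <- bad | (!is.na(cl) & end > cl)
  }
  if (any(bad))
    message("resize_regions: dropped ", sum(bad),
            " region(s) crossing a chromosome boundary")
  out <- data.frame(chrom = regions$chrom, start = start, end = end,
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- which(bad)
  out
}

region_ids <- function(regions) {
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}

# map raw cell-type labels through a correspondence table (raw -> canonical)
apply_cell_map <- function(x, cell_map) {
  if (is.null(cell_map)) return(x)
  stopifnot(all(c("raw_label", "canonical_label") %in% names(cell_map)))
  i <- match(x, cell_map$raw_label)
  if (anyNA(i))
    stop("cell-type label(s) missing from the correspondence table: ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  cell_map$canonical_label[i]
}

#' Label one TF-region pair under the three-state rules
#'
#' Reference per-pair labeller: returns 1 if some matched cell type has the
#' region accessible with both a peak summit inside the region and an
#' overlapping TFBS of the TF; NA (unresolved) if the region is accessible
#' in no cell type where the TF was profiled; otherwise 0, except that
#' cases supported by exactly one evidence kind in every doubly-unsupported
#' cell are NA under the `sparse` dialect and 0 under `less_sparse`.
#'
#' @param tf TF identifier.
#' @param region one-row data.frame (`chrom`, `start`, `end`), already
#'   resized to matrix-column length.
#' @param evidence list with data.frames `peaks` (`chrom`, `summit`, `tf`,
#'   `cell_type`), `tfbs` (`chrom`, `start`, `end`, `tf`, `cell_type`) and
#'   `accessibility` (`chrom`, `start`, `end`, `cell_type`).
#' @param catalog named list: TF identifier -> character vector of cell
#'   types in which the TF was ChIP-profiled.
#' @param dialect `"sparse"` or `"less_sparse"`.
#' @return integer 1, 0 or NA.
#' @export
label_pair <- function(tf, region, evidence, catalog,
                       dialect = c("sparse", "less_sparse")) {
  dialect <- match.arg(dialect)
  if (!tf %in% names(catalog)) stop("TF not in profile catalog: ", tf)
  acc <- evidence$accessibility
  acc_cells <- unique(acc$cell_type[acc$chrom == region$chrom &
                                      acc$start < region$end &
                                      acc$end > region$start])
  matched <- intersect(acc_cells, catalog[[tf]])
  if (length(matched) == 0L) return(NA_integer_)
  pk <- evidence$peaks
  tb <- evidence$tfbs
  any_single <- FALSE
  for (cell in matched) {
    has_peak <- any(pk$tf == tf & pk$cell_type == cell &
                      pk$chrom == region$chrom &
                      pk$summit >= region$start & pk$summit < region$end)
    has_tfbs <- any(tb$tf == tf & tb$cell_type == cell &
                      tb$chrom == region$chrom &
                      tb$start < region$end & tb$end > region$start)
    if (has_peak && has_tfbs) return(1L)
    if (has_peak || has_tfbs) any_single <- TRUE
  }
  if (any_single) {
    if (dialect == "sparse") NA_integer_ else 0L
  } else 0L
}

#' Build the sparse and less-sparse TF binding matrices
#'
#' Constructs both dialects of the three-state binding matrix over a region
#' universe defined by the accessibility intervals (resized to
#' `region_length` bp). A ChIP-seq record counts for a region when its
#' summit lies inside the region; a TFBS counts on >= 1 bp overlap; all
#' evidence is matched by (canonical) cell type, and the same cell type
#' must carry both evidence kinds for a bound call.
#'
#' @param peaks data.frame of ChIP-seq peaks: `chrom`, `start`, `end`,
#'   `summit` (0-based position inside the peak), `tf`, `cell_type`.
#' @param tfbs data.frame of TFBS predictions: `chrom`, `start`, `end`,
#'   `tf`, `cell_type`.
#' @param accessibility data.frame of accessible regions: `chrom`, `start`,
#'   `end`, `cell_type`.
#' @param cell_map optional correspondence data.frame (`raw_label`,
#'   `canonical_label`) applied to every cell-type column.
#' @param region_length matrix column length in bp (default 200).
#' @param chrom_len optional named chromosome lengths for boundary checks.
#' @param catalog optional named list TF -> profiled cell types; by default
#'   derived from the peak records (any cell type with >= 1 peak of the TF).
#' @return list with elements `sparse` and `less_sparse`, both of class
#'   `tftl_bm` over identical TF and region orderings.
#' @export
build_binding_matrices <- function(peaks, tfbs, accessibility,
                                   cell_map = NULL, region_length = 200L,
                                   chrom_len = NULL, catalog = NULL) {
  peaks <- unique(peaks)
  tfbs <- unique(tfbs)
  accessibility <- unique(accessibility)
  peaks$cell_type <- apply_cell_map(peaks$cell_type, cell_map)
  tfbs$cell_type <- apply_cell_map(tfbs$cell_type, cell_map)
  accessibility$cell_type <- apply_cell_map(accessibility$cell_type, cell_map)

  reg <- resize_regions(unique(accessibility[c("chrom", "start", "end")]),
                        target_len = region_length, chrom_len = chrom_len)
  reg <- unique(reg)
  reg <- reg[order(reg$chrom, reg$start, reg$end), , drop = FALSE]
  rownames(reg) <- NULL
  if (nrow(reg) == 0L) stop("empty region universe")
  rid <- region_ids(reg)
  reg_gr <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start + 1L, reg$end))

  if (is.null(catalog)) {
    catalog <- split(peaks$cell_type, peaks$tf)
    catalog <- lapply(catalog, unique)
  }
  tf_ids <- sort(unique(c(names(catalog), peaks$tf, tfbs$tf)))
  no_prof <- setdiff(tf_ids, names(catalog)[lengths(catalog) > 0])
  if (length(no_prof))
    warning("TF(s) with zero profiled cell types (all-NULL rows): ",
            paste(no_prof, collapse = ", "))

  # map each evidence record to the region(s) it supports
  acc_orig <- resize_regions(accessibility[c("chrom", "start", "end")],
                             target_len = region_length,
                             chrom_len = chrom_len)
  keep <- setdiff(seq_len(nrow(accessibility)), attr(acc_orig, "dropped"))
  acc_idx <- match(region_ids(acc_orig), rid)
  acc_hits <- data.frame(region = acc_idx,
                         cell = accessibility$cell_type[keep])

  pk_gr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(peaks$summit + 1L,
                                                   peaks$summit + 1L))
  pk_ov <- GenomicRanges::findOverlaps(pk_gr, reg_gr)
  pk_hits <- data.frame(region = S4Vectors::subjectHits(pk_ov),
                        tf = peaks$tf[S4Vectors::queryHits(pk_ov)],
                        cell = peaks$cell_type[S4Vectors::queryHits(pk_ov)])

  tb_gr <- GenomicRanges::GRanges(tfbs$chrom,
                                  IRanges::IRanges(tfbs$start + 1L, tfbs$end))
  tb_ov <- GenomicRanges::findOverlaps(tb_gr, reg_gr)
  tb_hits <- data.frame(region = S4Vectors::subjectHits(tb_ov),
                        tf = tfbs$tf[S4Vectors::queryHits(tb_ov)],
                        cell = tfbs$cell_type[S4Vectors::queryHits(tb_ov)])

  acc_by_cell <- split(acc_hits$region, acc_hits$cell)
  acc_by_cell <- lapply(acc_by_cell, unique)
  pk_by_tf <- split(pk_hits[c("region", "cell")], pk_hits$tf)
  tb_by_tf <- split(tb_hits[c("region", "cell")], tb_hits$tf)

  R <- nrow(reg)
  sparse <- matrix(NA_integer_, length(tf_ids), R,
                   dimnames = list(tf_ids, rid))
  less <- sparse
  for (tf in tf_ids) {
    cells <- intersect(catalog[[tf]] %||% character(), names(acc_by_cell))
    if (length(cells) == 0L) next
    row_s <- rep(NA_integer_, R)
    pk_tf <- pk_by_tf[[tf]]
    tb_tf <- tb_by_tf[[tf]]
    both_any <- integer(0)
    single_any <- integer(0)
    for (cell in cells) {
      ac <- acc_by_cell[[cell]]
      pc <- if (is.null(pk_tf)) integer(0) else
        intersect(pk_tf$region[pk_tf$cell == cell], ac)
      uc <- if (is.null(tb_tf)) integer(0) else
        intersect(tb_tf$region[tb_tf$cell == cell], ac)
      both_any <- union(both_any, intersect(pc, uc))
      single_any <- union(single_any, union(setdiff(pc, uc), setdiff(uc, pc)))
    }
    matched_any <- unique(unlist(acc_by_cell[cells], use.names = FALSE))
    single_any <- setdiff(single_any, both_any)
    row_s[matched_any] <- 0L
    row_l <- row_s
    row_s[single_any] <- NA_integer_
    row_l[single_any] <- 0L
    row_s[both_any] <- 1L
    row_l[both_any] <- 1L
    sparse[tf, ] <- row_s
    less[tf, ] <- row_l
  }
  list(sparse = new_binding_matrix(sparse, reg, "sparse"),
       less_sparse = new_binding_matrix(less, reg, "less_sparse"))
}

new_binding_matrix <- function(values, regions, dialect) {
  structure(list(values = values, regions = regions, dialect = dialect),
            class = "tftl_bm")
}

#' @export
print.tftl_bm <- function(x, ...) {
  cat("<tftl_bm> ", x$dialect, " dialect | ", nrow(x$values), " TFs x ",
      ncol(x$values), " regions | ones=", sum(x$values == 1L, na.rm = TRUE),
      " zeros=", sum(x$values == 0L, na.rm = TRUE),
      " null=", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Per-TF counts of bound / unbound / unresolved entries
#' @param object a `tftl_bm`.
#' @param ... unused.
#' @return data.frame with columns `tf`, `ones`, `zeros`, `nulls`.
#' @export
summary.tftl_bm <- function(object, ...) {
  v <- object$values
  data.frame(tf = rownames(v),
             ones = rowSums(v == 1L, na.rm = TRUE),
             zeros = rowSums(v == 0L, na.rm = TRUE),
             nulls = rowSums(is.na(v)),
             row.names = NULL)
}

#' Cosine similarity between the binding vectors of two TFs
#'
#' Positions unresolved (NA) in either row are removed from both vectors
#' before computing `dot(a, b) / (||a|| ||b||)`. When either pruned vector
#' has zero norm the similarity is undefined and `NA` is returned (this is
#' how TFs without bound regions are excluded from similarity analyses).
#'
#' @param bm a `tftl_bm` (use the sparse dialect for cofactor analyses).
#' @param tf_a,tf_b TF identifiers present in the matrix.
#' @return numeric in \[0, 1\], or `NA` when undefined.
#' @export
cosine_similarity <- function(bm, tf_a, tf_b) {
  v <- bm$values
  for (tf in c(tf_a, tf_b))
    if (!tf %in% rownames(v)) stop("TF not in matrix: ", tf)
  a <- v[tf_a, ]
  b <- v[tf_b, ]
  keep <- !is.na(a) & !is.na(b)
  a <- as.numeric(a[keep])
  b <- as.numeric(b[keep])
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Rank candidate cofactors of a TF by binding-vector cosine similarity
#'
#' @param bm a sparse-dialect `tftl_bm`.
#' @param target_tf TF identifier.
#' @return data.frame (`tf`, `similarity`) over all other TFs with a
#'   defined similarity, sorted by decreasing similarity with ties broken
#'   by TF identifier.
#' @export
cofactor_ranking <- function(bm, target_tf) {
  tfs <- setdiff(rownames(bm$values), target_tf)
  if (!target_tf %in% rownames(bm$values))
    stop("TF not in matrix: ", target_tf)
  sim <- vapply(tfs, function(tf) cosine_similarity(bm, target_tf, tf),
                numeric(1))
  out <- data.frame(tf = tfs, similarity = unname(sim))
  out <- out[!is.na(out$similarity), , drop = FALSE]
  out <- out[order(-out$similarity, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a binding-matrix archive
#'
#' The archive is plain text: `<prefix>_values.tsv` holds the dense matrix
#' with `-1` as the unresolved sentinel, `<prefix>_tfs.tsv` and
#' `<prefix>_regions.tsv` the row and column indexes, and
#' `<prefix>_summary.tsv` the per-TF 1/0/NULL counts.
#'
#' @param bm a `tftl_bm`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_binding_matrix <- function(bm, prefix) {
  v <- bm$values
  v[is.na(v)] <- -1L
  utils::write.table(v, paste0(prefix, "_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(bm$values), paste0(prefix, "_tfs.tsv"))
  utils::write.table(cbind(bm$regions, region_id = region_ids(bm$regions),
                           dialect = bm$dialect),
                     paste0(prefix, "_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary(bm), paste0(prefix, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_binding_matrix
#' @export
read_binding_matrix <- function(prefix) {
  tfs <- readLines(paste0(prefix, "_tfs.tsv"))
  reg <- utils::read.delim(paste0(prefix, "_regions.tsv"),
                           stringsAsFactors = FALSE)
  v <- as.matrix(utils::read.delim(paste0(prefix, "_values.tsv"),
                                   header = FALSE))
  v <- matrix(as.integer(v), nrow = length(tfs),
              dimnames = list(tfs, reg$region_id))
  v[v == -1L] <- NA_integer_
  new_binding_matrix(v, reg[c("chrom", "start", "end")],
                     dialect = reg$dialect[1])
}
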