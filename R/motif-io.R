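# Minimal JASPAR and MEME motif readers/writers.

#' Read motifs in JASPAR format
#'
#' Parses the four-row `A [ ... ]` count/probability blocks. Matrices are
#' returned as 4 x W with rows A, C, G, T.
#'
#' @param path file path.
#' @return named list of matrices (names from the `>` header lines).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR records in ", path)
  out <- list()
  for (h in heads) {
    id <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]][1]
    block <- lines[(h + 1):(h + 4)]
    rows <- lapply(block, function(ln) {
      body <- sub("^\\s*[ACGTacgt]", "", ln)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- toupper(substr(trimws(block), 1, 1))
    out[[id]] <- m[c("A", "C", "G", "T"), , drop = FALSE]
  }
  out
}

#' Write motifs in JASPAR format
#'
#' @param motifs named list of 4 x W matrices (rows A, C, G, T).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(motifs)) {
    m <- motifs[[id]]
    writeLines(paste0(">", id), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read motifs in MEME format
#'
#' Parses `letter-probability matrix` blocks; returns 4 x W probability
#' matrices with rows A, C, G, T.
#'
#' @param path file path.
#' @return named list of probability matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0L) stop("no MEME motifs in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    hdr <- grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1] + s
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr]))
    rows <- lapply(lines[(hdr + 1):(hdr + w)], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- m
  }
  out
}

#' Write motifs in MEME format
#'
#' @param motifs named list of 4 x W probability matrices.
#' @param path output file path.
#' @param nsites nominal site counts (recycled; default 20).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, nsites = 20L) {
  nsites <- rep_len(nsites, length(motifs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s", names(motifs)[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m), nsites[i]), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
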