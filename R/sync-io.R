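## Reader/writer for the PoPoolation2 synchronized allele-count format:
## tab-separated contig, position, reference base, then one "A:T:C:G:N:del"
## sextuple of non-negative integer counts per pooled sample.

## Parse a character vector of sync lines into a SyncCounts object.
## `offset` is the number of lines preceding these in the file, so error
## messages can name absolute line numbers when reading in chunks.
.parseSyncLines <- function(lines, sampleIds = NULL, offset = 0L) {
  lineno <- function(i) offset + i
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && (any(nf < 4L) || length(unique(nf)) > 1L)) {
    bad <- which(nf < 4L | nf != nf[1])[1]
    stop("sync parse error at line ", lineno(bad),
         ": expected >= 4 tab-separated fields, consistent across lines")
  }
  k <- if (length(nf)) nf[1] else 4L
  nsamp <- k - 3L
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nsamp))
  if (length(sampleIds) != nsamp)
    stop("expected ", length(sampleIds), " samples but file has ", nsamp,
         " count columns")
  n <- length(lines)
  if (n == 0L) {
    return(SyncCounts(
      data.frame(contig = character(0), pos = integer(0), ref = character(0)),
      array(integer(0), dim = c(0L, nsamp, 6L)), sampleIds))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = k, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos <= 0L)) {
    bad <- which(is.na(pos) | pos <= 0L)[1]
    stop("sync parse error at line ", lineno(bad),
         ": position must be a positive integer, got '", m[bad, 2], "'")
  }
  ref <- toupper(m[, 3])
  if (!all(ref %in% c("A", "C", "G", "T", "N"))) {
    bad <- which(!(ref %in% c("A", "C", "G", "T", "N")))[1]
    stop("sync parse error at line ", lineno(bad),
         ": reference base must be one of A,C,G,T,N, got '", m[bad, 3], "'")
  }
  counts <- array(NA_integer_, dim = c(n, nsamp, 6L))
  for (j in seq_len(nsamp)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      bad <- which(lengths(parts) != 6L)[1]
      stop("sync parse error at line ", lineno(bad), ": sample field ", j,
           " must be a colon-separated sextuple, got '", m[bad, 3L + j], "'")
    }
    v <- suppressWarnings(as.integer(unlist(parts, use.names = FALSE)))
    if (anyNA(v) || any(v < 0L)) {
      bad <- (which(is.na(v) | v < 0L)[1] - 1L) %/% 6L + 1L
      stop("sync parse error at line ", lineno(bad), ": sample field ", j,
           " must contain non-negative integers, got '", m[bad, 3L + j], "'")
    }
    counts[, j, ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  SyncCounts(data.frame(contig = m[, 1], pos = pos, ref = ref),
             counts, sampleIds)
}

#' Read a PoPoolation2 synchronized file
#'
#' Order-preserving; CRLF line endings are tolerated on input but never
#' written. Malformed lines raise an error naming the offending line number.
#'
#' @param path path to the `.sync` file (plain text or gzip).
#' @param sampleIds optional sample names, one per count column; defaults to
#'   `sample1..sampleK`.
#' @return a [SyncCounts].
#' @seealso [writeSync()], [syncApply()] for chunked processing of large files.
#' @export
readSync <- function(path, sampleIds = NULL) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[lines != ""]
  .parseSyncLines(lines, sampleIds)
}

#' Write a SyncCounts object in synchronized format
#'
#' Inverse of [readSync()]: tab and colon separators, no trailing whitespace,
#' every line newline-terminated. Round-trips byte-exactly on canonical files.
#'
#' @param sync a [SyncCounts].
#' @param path output path.
#' @export
writeSync <- function(sync, path) {
  con <- file(path, open = "wb")  # binary: never emit CRLF
  on.exit(close(con))
  n <- nrow(sync@info)
  if (n == 0L) return(invisible(NULL))
  nsamp <- length(sync@sampleIds)
  cols <- vapply(seq_len(nsamp), function(j) {
    do.call(paste, c(lapply(1:6, function(a) sync@counts[, j, a]),
                     list(sep = ":")))
  }, character(n))
  cols <- matrix(cols, nrow = n)
  lines <- do.call(paste, c(list(sync@info$contig, sync@info$pos,
                                 sync@info$ref),
                            lapply(seq_len(nsamp), function(j) cols[, j]),
                            list(sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

#' Process a synchronized file in chunks
#'
#' Reads the file `chunkSize` lines at a time so memory use is bounded by the
#' chunk, not the file; `fun` is applied to the [SyncCounts] parsed from each
#' chunk.
#'
#' @param path path to the `.sync` file.
#' @param fun function of one argument (a `SyncCounts` chunk).
#' @param chunkSize lines per chunk.
#' @param sampleIds optional sample names.
#' @return list of `fun` results, one per chunk, invisibly.
#' @export
syncApply <- function(path, fun, chunkSize = 10000L, sampleIds = NULL) {
  con <- file(path, open = "r")
  on.exit(close(con))
  out <- list()
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (length(lines) == 0L) break
    keep <- sub("\r$", "", lines)
    keep <- keep[keep != ""]
    chunk <- .parseSyncLines(keep, sampleIds, offset = offset)
    out[[length(out) + 1L]] <- fun(chunk)
    offset <- offset + length(lines)
  }
  invisible(out)
}

#' Major allele of one or more allele-count records
#'
#' The argmax over the five callable alleles A, C, G, T and deletion (N is
#' excluded from allele calling). Ties break in the fixed order
#' A < C < G < T < del; records with zero callable coverage return
#' `("none", 0)`.
#'
#' @param counts either a length-6 vector in sync order `A,T,C,G,N,del` or a
#'   `records x 6` matrix of such rows.
#' @return `data.frame` with columns `allele` and `count`.
#' @export
majorAllele <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 6L)
  ord <- match(c("A", "C", "G", "T", "del"), SYNC_ALLELES)
  m <- counts[, ord, drop = FALSE]
  j <- max.col(m, ties.method = "first")
  best <- m[cbind(seq_len(nrow(m)), j)]
  allele <- c("A", "C", "G", "T", "del")[j]
  allele[best == 0] <- "none"
  best[allele == "none"] <- 0
  data.frame(allele = allele, count = as.integer(best))
}

#' Read and validate a two-column sample design table
#'
#' Tab-separated with columns `sample_id` and `group`; groups must be `wild`
#' or `albino`, at least one sample each, and row order must match the sync
#' file's column order.
#'
#' @param path design TSV path.
#' @return `data.frame` with `sample_id`, `group`.
#' @export
readDesign <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  checkDesign(d)
}

#' @rdname readDesign
#' @param design a design `data.frame` to validate (and normalize).
#' @export
checkDesign <- function(design) {
  if (!all(c("sample_id", "group") %in% names(design)))
    stop("design must have columns sample_id and group")
  design$group <- as.character(design$group)
  if (!all(design$group %in% c("wild", "albino")))
    stop("design groups must be 'wild' or 'albino'")
  if (!all(c("wild", "albino") %in% design$group))
    stop("design needs at least one wild and one albino sample")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  design
}

#' @rdname readDesign
#' @param design a design `data.frame`.
#' @export
writeDesign <- function(design, path) {
  write.table(design[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
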