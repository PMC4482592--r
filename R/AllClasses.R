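#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats p.adjust binom.test rpois rnbinom rlnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

#' Transcriptome: contigs plus predicted open reading frames
#'
#' A de novo transcriptome assembly as the coordinate frame for all site
#' annotation: a set of contig sequences together with zero or more predicted
#' ORFs per contig. All coordinates are 1-based and inclusive on the contig's
#' forward strand; minus-strand ORFs are supported and their 5'/3' UTR sides
#' are defined relative to the coding strand.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of contig sequences, uniquely named.
#' @slot orfs a `data.frame` with columns `orf_id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `note`; `end - start + 1` must be a multiple
#'   of 3 and every ORF must lie within its contig.
#'
#' @seealso [Transcriptome()], [locateSite()], [translateOrf()]
#' @exportClass Transcriptome
setClass("Transcriptome",
  representation(seqs = "DNAStringSet", orfs = "data.frame"))

setValidity("Transcriptome", function(object) {
  msgs <- character(0)
  nm <- names(object@seqs)
  if (length(object@seqs)) {
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      msgs <- c(msgs, "all contigs must be named")
    if (anyDuplicated(nm))
      msgs <- c(msgs, "contig names must be unique")
    if (any(Biostrings::width(object@seqs) < 1L))
      msgs <- c(msgs, "contig sequences must have length >= 1")
  }
  orfs <- object@orfs
  need <- c("orf_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(orfs))) {
    msgs <- c(msgs, paste("orfs must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(orfs)) {
    if (anyDuplicated(orfs$orf_id))
      msgs <- c(msgs, "orf_id values must be unique")
    if (!all(orfs$contig %in% nm))
      msgs <- c(msgs, "every ORF must sit on a known contig")
    if (!all(orfs$strand %in% c("+", "-")))
      msgs <- c(msgs, "ORF strand must be '+' or '-'")
    if (any(orfs$start < 1L) || any(orfs$end < orfs$start))
      msgs <- c(msgs, "ORF coordinates must satisfy 1 <= start <= end")
    if (all(orfs$contig %in% nm)) {
      len <- setNames(Biostrings::width(object@seqs), nm)
      if (any(orfs$end > len[orfs$contig]))
        msgs <- c(msgs, "every ORF must lie within [1, contig length]")
    }
    if (any((orfs$end - orfs$start + 1L) %% 3L != 0L))
      msgs <- c(msgs, "ORF length must be a multiple of 3")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Transcriptome
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of contig
#'   sequences over the alphabet A, C, G, T, N.
#' @param orfs `data.frame` of predicted ORFs (`orf_id`, `contig`, `start`,
#'   `end`, `strand`, optional `note`), 1-based inclusive forward-strand
#'   coordinates. Defaults to no ORFs.
#' @return a validated `Transcriptome` object.
#' @examples
#' tx <- Transcriptome(c(c1 = "ATGGCATAA"),
#'                     data.frame(orf_id = "o1", contig = "c1",
#'                                start = 1, end = 9, strand = "+"))
#' translateOrf(tx, "o1")
#' @export
Transcriptome <- function(seqs, orfs = NULL) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(orfs))
    orfs <- data.frame(orf_id = character(0), contig = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), note = character(0))
  orfs <- as.data.frame(orfs, stringsAsFactors = FALSE)
  if (is.null(orfs$note)) orfs$note <- rep("", nrow(orfs))
  orfs$start <- as.integer(orfs$start)
  orfs$end <- as.integer(orfs$end)
  rownames(orfs) <- NULL
  methods::new("Transcriptome", seqs = seqs, orfs = orfs)
}

#' @describeIn Transcriptome contig sequences as a `DNAStringSet`.
#' @param x,object a `Transcriptome`.
#' @export
contigSeqs <- function(x) x@seqs

#' @describeIn Transcriptome the ORF annotation table.
#' @export
orfs <- function(x) x@orfs

setMethod("show", "Transcriptome", function(object) {
  cat("Transcriptome with", length(object@seqs), "contigs and",
      nrow(object@orfs), "ORFs\n")
  if (length(object@seqs)) {
    w <- Biostrings::width(object@seqs)
    cat("  contig length: ", min(w), "-", max(w), " nt\n", sep = "")
  }
  if (nrow(object@orfs))
    cat("  strands: +", sum(object@orfs$strand == "+"),
        " / -", sum(object@orfs$strand == "-"), "\n", sep = "")
})

#' SyncCounts: per-sample allele counts at transcriptome positions
#'
#' In-memory model of a PoPoolation2 synchronized file: for every covered
#' position of every contig, the counts of A, T, C, G, N and deletion observed
#' in each pooled sample. Column order follows the file; allele order follows
#' the sync format (`A:T:C:G:N:del`).
#'
#' @slot info `data.frame` with columns `contig`, `pos` (1-based), `ref`.
#' @slot counts integer array `records x samples x 6`, allele slices named
#'   `A,T,C,G,N,del`.
#' @slot sampleIds character vector naming the sample columns.
#'
#' @seealso [readSync()], [writeSync()], [callAlbefactionSites()]
#' @exportClass SyncCounts
setClass("SyncCounts",
  representation(info = "data.frame", counts = "array", sampleIds = "character"))

setValidity("SyncCounts", function(object) {
  msgs <- character(0)
  if (!all(c("contig", "pos", "ref") %in% names(object@info)))
    msgs <- c(msgs, "info must have columns contig, pos, ref")
  d <- dim(object@counts)
  if (length(d) != 3L || d[3] != 6L)
    msgs <- c(msgs, "counts must be a records x samples x 6 array")
  else {
    if (d[1] != nrow(object@info))
      msgs <- c(msgs, "counts and info must agree on record count")
    if (d[2] != length(object@sampleIds))
      msgs <- c(msgs, "counts and sampleIds must agree on sample count")
  }
  if (nrow(object@info) && any(object@info$pos < 1L))
    msgs <- c(msgs, "positions must be >= 1")
  if (length(object@counts) && any(object@counts < 0L))
    msgs <- c(msgs, "allele counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SyncCounts object
#'
#' @param info `data.frame` with `contig`, `pos`, `ref`.
#' @param counts integer array `records x samples x 6` in sync allele order
#'   `A,T,C,G,N,del`.
#' @param sampleIds sample names, one per count column.
#' @return a validated `SyncCounts`.
#' @export
SyncCounts <- function(info, counts, sampleIds) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  info$pos <- as.integer(info$pos)
  rownames(info) <- NULL
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, sampleIds, SYNC_ALLELES)
  methods::new("SyncCounts", info = info, counts = counts,
               sampleIds = as.character(sampleIds))
}

#' @describeIn SyncCounts record-level contig/pos/ref table.
#' @param x,object a `SyncCounts`.
#' @export
syncInfo <- function(x) x@info

#' @describeIn SyncCounts the `records x samples x 6` count array.
#' @export
alleleCounts <- function(x) x@counts

#' @describeIn SyncCounts sample identifiers in file column order.
#' @export
sampleIds <- function(x) x@sampleIds

setMethod("show", "SyncCounts", function(object) {
  cat("SyncCounts:", nrow(object@info), "positions x",
      length(object@sampleIds), "samples\n")
  if (length(object@sampleIds))
    cat("  samples:", paste(object@sampleIds, collapse = ", "), "\n")
  if (nrow(object@info))
    cat("  contigs:", length(unique(object@info$contig)), "\n")
})

setMethod("length", "SyncCounts", function(x) nrow(x@info))
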