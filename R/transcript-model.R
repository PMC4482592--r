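## Coordinate frame and sequence logic for de novo transcripts: translation,
## UTR/CDS placement, substitution and indel consequence calls.

.getOrf <- function(tx, orfId) {
  i <- match(orfId, tx@orfs$orf_id)
  if (is.na(i)) stop("unknown ORF id: ", orfId)
  tx@orfs[i, ]
}

.contigSeq <- function(tx, contig) {
  i <- match(contig, names(tx@seqs))
  if (is.na(i)) stop("unknown contig: ", contig)
  tx@seqs[[i]]
}

## Standard genetic code as a codon -> amino acid lookup (stops are "*").
GENETIC_CODE_TABLE <- Biostrings::getGeneticCode()

## Translate a coding-strand nucleotide string codon by codon; any codon
## containing an ambiguous base renders "X", stops render "*".
.translateNt <- function(nt) {
  nt <- as.character(nt)
  n <- nchar(nt)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate one predicted ORF to its peptide
#'
#' The ORF's nucleotide range is extracted from the contig, reverse
#' complemented first when the ORF is on the minus strand, and translated with
#' the standard genetic code. Stop codons render as `"*"`; any codon
#' containing an ambiguous base (e.g. `N`) renders as `"X"`.
#'
#' @param tx a [Transcriptome].
#' @param orfId the `orf_id` of the ORF to translate.
#' @return the peptide as a single character string.
#' @examples
#' tx <- Transcriptome(c(c1 = "ATGGCATAA"),
#'                     data.frame(orf_id = "o1", contig = "c1",
#'                                start = 1, end = 9, strand = "+"))
#' translateOrf(tx, "o1")  # "MA*"
#' @export
translateOrf <- function(tx, orfId) {
  o <- .getOrf(tx, orfId)
  s <- .contigSeq(tx, o$contig)
  if (o$start < 1L || o$end > length(s))
    stop("ORF ", orfId, " out of contig bounds")
  if ((o$end - o$start + 1L) %% 3L != 0L)
    stop("ORF ", orfId, " length is not a multiple of 3")
  nt <- Biostrings::subseq(s, o$start, o$end)
  if (o$strand == "-") nt <- Biostrings::reverseComplement(nt)
  .translateNt(nt)
}

#' Peptides for every ORF of a transcriptome
#'
#' @param tx a [Transcriptome].
#' @return named character vector of peptides, one per ORF.
#' @export
orfPeptides <- function(tx) {
  ids <- tx@orfs$orf_id
  setNames(vapply(ids, function(i) translateOrf(tx, i), character(1)), ids)
}

#' Collapse identical protein sequences into clusters
#'
#' Exact string identity defines the clusters; the representative of each
#' cluster is the lexicographically smallest member id (C-locale ordering), so
#' the result is deterministic. Every input id appears in exactly one cluster.
#'
#' @param peptides named character vector: names are ORF/protein ids, values
#'   are non-empty peptide strings.
#' @return `data.frame` with one row per cluster: `peptide`, `representative`,
#'   `members` (comma-joined ids), `size`; rows ordered by representative.
#' @export
collapseIdenticalProteins <- function(peptides) {
  if (length(peptides) == 0L)
    return(data.frame(peptide = character(0), representative = character(0),
                      members = character(0), size = integer(0)))
  if (is.null(names(peptides)) || anyDuplicated(names(peptides)))
    stop("peptides must be uniquely named")
  if (any(is.na(peptides)) || any(peptides == ""))
    stop("empty peptide sequences are not allowed")
  groups <- split(names(peptides), peptides)
  groups <- lapply(groups, function(ids) ids[order(ids, method = "radix")])
  rep_id <- vapply(groups, `[[`, character(1), 1L)
  out <- data.frame(peptide = names(groups),
                    representative = unname(rep_id),
                    members = vapply(groups, paste, character(1), collapse = ","),
                    size = lengths(groups),
                    row.names = NULL)
  out[order(out$representative, method = "radix"), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Place a contig position relative to each predicted ORF
#'
#' For every ORF on the contig the position is classified as 5' UTR, CDS or
#' 3' UTR *relative to the coding strand*: on a minus-strand ORF the 5' UTR is
#' the high-coordinate side of the contig. CDS positions additionally carry
#' the codon index (1-based along the peptide) and the position within the
#' codon (1-3, read along the coding strand). Contigs without any ORF yield a
#' single `outside` call.
#'
#' @param tx a [Transcriptome].
#' @param contig contig id.
#' @param pos 1-based position on the contig's forward strand.
#' @return `data.frame` with columns `orf_id`, `region` (one of
#'   `five_prime_utr`, `cds`, `three_prime_utr`, `outside`), `codon_index`,
#'   `codon_position` (both `NA` unless `region == "cds"`).
#' @export
locateSite <- function(tx, contig, pos) {
  s <- .contigSeq(tx, contig)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > length(s))
    stop("position ", pos, " outside contig ", contig,
         " [1, ", length(s), "]")
  o <- tx@orfs[tx@orfs$contig == contig, , drop = FALSE]
  if (nrow(o) == 0L)
    return(data.frame(orf_id = NA_character_, region = "outside",
                      codon_index = NA_integer_, codon_position = NA_integer_))
  calls <- lapply(seq_len(nrow(o)), function(i) {
    st <- o$start[i]; en <- o$end[i]; plus <- o$strand[i] == "+"
    if (pos < st) {
      region <- if (plus) "five_prime_utr" else "three_prime_utr"
      ci <- cp <- NA_integer_
    } else if (pos > en) {
      region <- if (plus) "three_prime_utr" else "five_prime_utr"
      ci <- cp <- NA_integer_
    } else {
      region <- "cds"
      off <- if (plus) pos - st else en - pos  # 0-based offset along coding strand
      ci <- off %/% 3L + 1L
      cp <- off %% 3L + 1L
    }
    data.frame(orf_id = o$orf_id[i], region = region,
               codon_index = ci, codon_position = cp)
  })
  do.call(rbind, calls)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify a single-base substitution within a coding region
#'
#' The affected codon is retranslated with the alternative allele substituted
#' in (alleles are given on the contig's forward strand and complemented
#' automatically for minus-strand ORFs). Equal amino acids give `synonymous`,
#' a gained stop `stop_gained`, a lost stop `stop_lost`, otherwise
#' `nonsynonymous`. Codons containing ambiguous bases translate to `"X"` and
#' are reported as `nonsynonymous` with a warning rather than dropped.
#'
#' @param tx a [Transcriptome].
#' @param orfId ORF whose reading frame is used.
#' @param pos 1-based contig position; must fall in the CDS of `orfId`.
#' @param refBase the contig (assembly) base at `pos`, forward strand.
#' @param altBase the alternative allele, forward strand.
#' @return one-row `data.frame`: `kind`, `ref_aa`, `alt_aa`, `codon_index`,
#'   `codon_position`.
#' @export
classifySubstitution <- function(tx, orfId, pos, refBase, altBase) {
  o <- .getOrf(tx, orfId)
  s <- .contigSeq(tx, o$contig)
  loc <- locateSite(tx, o$contig, pos)
  loc <- loc[!is.na(loc$orf_id) & loc$orf_id == orfId, , drop = FALSE]
  if (nrow(loc) != 1L || loc$region != "cds")
    stop("position ", pos, " is not in the CDS of ORF ", orfId)
  at <- as.character(Biostrings::subseq(s, pos, pos))
  if (!identical(at, toupper(refBase)))
    stop("reference allele mismatch at ", o$contig, ":", pos,
         " (contig has ", at, ", got ", refBase, ")")
  plus <- o$strand == "+"
  ci <- loc$codon_index; cp <- loc$codon_position
  if (plus) {
    c_start <- o$start + 3L * (ci - 1L)
    codon <- as.character(Biostrings::subseq(s, c_start, c_start + 2L))
    alt <- toupper(altBase)
  } else {
    c_end <- o$end - 3L * (ci - 1L)
    codon <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(s, c_end - 2L, c_end)))
    alt <- unname(.COMPLEMENT[toupper(altBase)])
  }
  if (is.na(alt)) stop("invalid alternative allele: ", altBase)
  alt_codon <- codon
  substr(alt_codon, cp, cp) <- alt
  ref_aa <- .translateNt(codon)
  alt_aa <- .translateNt(alt_codon)
  kind <- if (grepl("X", ref_aa, fixed = TRUE) ||
              grepl("X", alt_aa, fixed = TRUE)) {
    warning("ambiguous codon at ", o$contig, ":", pos,
            "; reported as nonsynonymous with amino acid 'X'")
    "nonsynonymous"
  } else if (identical(ref_aa, alt_aa)) {
    "synonymous"
  } else if (alt_aa == "*") {
    "stop_gained"
  } else if (ref_aa == "*") {
    "stop_lost"
  } else {
    "nonsynonymous"
  }
  data.frame(kind = kind, ref_aa = ref_aa, alt_aa = alt_aa,
             codon_index = ci, codon_position = cp)
}

#' Classify the consequence of a deletion relative to one ORF
#'
#' A deletion of `deletedLength` contiguous bases starting at `pos` (forward
#' strand). Deletions that do not touch the CDS are `noncoding`; a CDS overlap
#' whose length is not a multiple of 3 is a `frameshift`; an in-frame CDS
#' deletion is `inframe_del` unless retranslating the truncated ORF reveals a
#' premature internal stop, in which case `stop_gained`.
#'
#' @param tx a [Transcriptome].
#' @param orfId ORF against which the consequence is assessed.
#' @param pos 1-based first deleted position.
#' @param deletedLength number of deleted bases (>= 1).
#' @return one-row `data.frame`: `kind`, `ref_aa`, `alt_aa` (always `NA` for
#'   indels), `peptide` (retranslation for in-frame CDS deletions, else `NA`).
#' @export
classifyIndel <- function(tx, orfId, pos, deletedLength = 1L) {
  o <- .getOrf(tx, orfId)
  s <- .contigSeq(tx, o$contig)
  pos <- as.integer(pos); deletedLength <- as.integer(deletedLength)
  if (deletedLength < 1L) stop("deletedLength must be >= 1")
  del_end <- pos + deletedLength - 1L
  if (pos < 1L || del_end > length(s))
    stop("deletion [", pos, ", ", del_end, "] extends past contig ",
         o$contig, " [1, ", length(s), "]")
  ov <- max(0L, min(del_end, o$end) - max(pos, o$start) + 1L)
  if (ov == 0L)
    return(data.frame(kind = "noncoding", ref_aa = NA_character_,
                      alt_aa = NA_character_, peptide = NA_character_))
  if (ov %% 3L != 0L)
    return(data.frame(kind = "frameshift", ref_aa = NA_character_,
                      alt_aa = NA_character_, peptide = NA_character_))
  orf_pos <- o$start:o$end
  keep <- orf_pos[orf_pos < pos | orf_pos > del_end]
  nt <- paste(strsplit(as.character(s), "")[[1]][keep], collapse = "")
  nt <- Biostrings::DNAString(nt)
  if (o$strand == "-") nt <- Biostrings::reverseComplement(nt)
  pep <- .translateNt(nt)
  n_aa <- nchar(pep)
  internal_stop <- n_aa > 1L &&
    grepl("*", substr(pep, 1L, n_aa - 1L), fixed = TRUE)
  kind <- if (internal_stop) "stop_gained" else "inframe_del"
  data.frame(kind = kind, ref_aa = NA_character_, alt_aa = NA_character_,
             peptide = pep)
}

#' Read a transcriptome from FASTA contigs and a BED ORF table
#'
#' The ORF table is 6-column BED (contig, 0-based half-open start, end,
#' orf_id, score, strand); coordinates are converted to the package's 1-based
#' inclusive convention at this boundary.
#'
#' @param fastaPath path to the contig FASTA.
#' @param bedPath optional path to the ORF BED file.
#' @return a [Transcriptome].
#' @export
readTranscriptome <- function(fastaPath, bedPath = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  orfs <- if (!is.null(bedPath)) readOrfBed(bedPath) else NULL
  Transcriptome(seqs, orfs)
}

#' @rdname readTranscriptome
#' @param tx a [Transcriptome] to write.
#' @param fastaPath,bedPath output paths (FASTA wrapped at 60 columns; BED
#'   0-based half-open).
#' @export
writeTranscriptome <- function(tx, fastaPath, bedPath = NULL) {
  Biostrings::writeXStringSet(tx@seqs, fastaPath, width = 60L)
  if (!is.null(bedPath)) writeOrfBed(tx@orfs, bedPath)
  invisible(NULL)
}

#' Read/write the 6-column BED ORF table
#'
#' @param path file path.
#' @return `readOrfBed`: a `data.frame` in 1-based inclusive coordinates with
#'   columns `orf_id`, `contig`, `start`, `end`, `strand`, `note`.
#' @export
readOrfBed <- function(path) {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("contig", "start0", "end", "orf_id",
                                "score", "strand"))
  if (nrow(b) && !all(b$strand %in% c("+", "-")))
    stop("BED strand column must be '+' or '-'")
  data.frame(orf_id = as.character(b$orf_id), contig = as.character(b$contig),
             start = as.integer(b$start0) + 1L, end = as.integer(b$end),
             strand = b$strand, note = rep("", nrow(b)))
}

#' @rdname readOrfBed
#' @param orfTable ORF table in the package's 1-based convention.
#' @export
writeOrfBed <- function(orfTable, path) {
  b <- data.frame(contig = orfTable$contig, start0 = orfTable$start - 1L,
                  end = orfTable$end, orf_id = orfTable$orf_id, score = ".",
                  strand = orfTable$strand)
  write.table(b, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
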