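## Reciprocal-best-hit orthology from BLAST tabular output under strict
## alignment-length / identity / E-value gates, plus pigmentation gene-panel
## extraction and the cross-referenced colour-gene report.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular (outfmt 6) results
#'
#' Expects the 12 standard columns. Malformed numeric fields raise an error
#' naming the offending line.
#'
#' @param path path to the tabular file.
#' @return `data.frame` with the standard outfmt-6 column names.
#' @export
readBlastTab <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12L)
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ", ncol(d))
  names(d) <- BLAST6_COLS
  for (col in c("pident", "length", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("BLAST parse error at line ", bad, ": non-numeric ", col,
           " value '", d[[col]][bad], "'")
    }
    d[[col]] <- v
  }
  if (any(d$length < 1) || any(d$pident < 0) || any(d$pident > 100))
    stop("invalid BLAST rows: need length >= 1 and 0 <= pident <= 100")
  d
}

#' Best gated hit per query
#'
#' Hits are first filtered by the three gates — all strict, so hits sitting
#' exactly on a boundary are excluded — then the highest-bitscore hit is
#' chosen per query; bitscore ties break by lower E-value, then by
#' lexicographically smallest subject id. Queries with no passing hit are
#' absent from the result.
#'
#' @param hits `data.frame` from [readBlastTab()].
#' @param maxEvalue E-value gate; hits pass when `evalue < maxEvalue`
#'   (default 1e-9).
#' @param minAlnLen alignment-length gate, amino acids; hits pass when
#'   `length > minAlnLen` (default 100).
#' @param minIdentity percent-identity gate; hits pass when
#'   `pident > minIdentity` (default 60).
#' @param dropTies if `TRUE`, a query whose top two passing hits tie on both
#'   bitscore and E-value is dropped instead of resolved lexicographically.
#' @return named character vector mapping query id to best subject id.
#' @export
bestHits <- function(hits, maxEvalue = 1e-9, minAlnLen = 100,
                     minIdentity = 60, dropTies = FALSE) {
  keep <- hits$evalue < maxEvalue & hits$length > minAlnLen &
    hits$pident > minIdentity
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) return(setNames(character(0), character(0)))
  ord <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid, method = "radix")
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  best <- h[first, , drop = FALSE]
  if (dropTies) {
    tied <- vapply(seq_len(nrow(best)), function(i) {
      rest <- h[!first & h$qseqid == best$qseqid[i], , drop = FALSE]
      nrow(rest) > 0 && rest$bitscore[1] == best$bitscore[i] &&
        rest$evalue[1] == best$evalue[i]
    }, logical(1))
    best <- best[!tied, , drop = FALSE]
  }
  setNames(best$sseqid, best$qseqid)
}

#' Reciprocal best hit pairs
#'
#' A pair `(x, y)` is emitted iff `x`'s best subject is `y` and `y`'s best
#' subject is `x`; each gene therefore appears in at most one pair.
#'
#' @param bestA2B named vector from [bestHits()] on the species-A-vs-B search.
#' @param bestB2A named vector from [bestHits()] on the reverse search.
#' @return `data.frame` with `species_a_gene`, `species_b_gene`, sorted by
#'   `species_a_gene`.
#' @export
reciprocalPairs <- function(bestA2B, bestB2A) {
  qa <- names(bestA2B)
  mutual <- !is.na(bestB2A[bestA2B]) & bestB2A[bestA2B] == qa
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(species_a_gene = qa[mutual],
                    species_b_gene = unname(bestA2B[mutual]))
  out <- out[order(out$species_a_gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a colour-gene panel (one gene name per line)
#'
#' Blank lines and `#` comments are skipped; matching is case-insensitive.
#'
#' @param path panel file; defaults to the pigmentation panel bundled with
#'   the package (canonical melanogenesis / pigment-cell gene names).
#' @return character vector of gene names.
#' @export
readGenePanel <- function(path = system.file("extdata",
                                             "colour_gene_panel.txt",
                                             package = "PoolSift")) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[x != ""]
  if (length(x) == 0L) stop("gene panel is empty")
  x
}

#' Cross-referenced colour-gene report
#'
#' One row per panel gene: its ortholog contig(s) from the RBB pairs
#' (case-insensitive exact match of the panel name against the species-B gene
#' id), the DE consensus verdict of those contigs, and the number of mutation
#' sites falling on them. Panel genes without an ortholog are reported as
#' not found.
#'
#' @param pairs [reciprocalPairs()] output with species B carrying the gene
#'   names the panel uses.
#' @param panel character vector of panel gene names.
#' @param consensusCalls optional [deConsensus()] output keyed by contig id.
#' @param mutationSites optional annotated site table keyed by `contig`.
#' @return `data.frame`: `panel_gene`, `found`, `contigs`, `de_tier`,
#'   `de_direction`, `n_mutation_sites`, `mutation_effects`.
#' @export
colourReport <- function(pairs, panel, consensusCalls = NULL,
                         mutationSites = NULL) {
  panel <- unique(panel)
  rows <- lapply(panel, function(g) {
    hit <- pairs[tolower(pairs$species_b_gene) == tolower(g), , drop = FALSE]
    contigs <- sort(unique(hit$species_a_gene), method = "radix")
    de_tier <- de_dir <- NA_character_
    n_sites <- 0L
    effects <- NA_character_
    if (length(contigs) && !is.null(consensusCalls) && nrow(consensusCalls)) {
      cc <- consensusCalls[consensusCalls$gene_id %in% contigs, , drop = FALSE]
      if (nrow(cc)) {
        de_tier <- paste(sort(unique(cc$tier)), collapse = ",")
        de_dir <- paste(sort(unique(cc$direction)), collapse = ",")
      }
    }
    if (length(contigs) && !is.null(mutationSites) && nrow(mutationSites)) {
      ms <- mutationSites[mutationSites$contig %in% contigs, , drop = FALSE]
      n_sites <- nrow(ms)
      if (n_sites && "effect" %in% names(ms)) {
        ef <- ms$effect[!is.na(ms$effect)]
        if (length(ef)) effects <- paste(sort(unique(ef)), collapse = ",")
      }
    }
    data.frame(panel_gene = g, found = length(contigs) > 0,
               contigs = if (length(contigs))
                 paste(contigs, collapse = ",") else NA_character_,
               de_tier = de_tier, de_direction = de_dir,
               n_mutation_sites = n_sites, mutation_effects = effects)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(panel_gene = character(0), found = logical(0),
                      contigs = character(0), de_tier = character(0),
                      de_direction = character(0),
                      n_mutation_sites = integer(0),
                      mutation_effects = character(0))
  rownames(out) <- NULL
  out
}
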