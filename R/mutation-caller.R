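## Strain-differential ("albefaction-related") mutation calling from pooled
## allele counts: an allele well supported in every wild-type pool but absent
## from every albino pool, plus albino-homozygous deletion calls, per-pool
## homozygosity assessment and region/effect annotation.

#' Thresholds for the albefaction-site caller
#'
#' @param minWildCount minimum count of the candidate allele required in
#'   *every* wild sample (default 6, i.e. strictly more than five reads).
#' @param maxAlbinoCount maximum count tolerated in *any* albino sample
#'   (default 0, i.e. the allele must be absent).
#' @param homozygosityFraction allele fraction of non-N coverage at or above
#'   which a sample is considered homozygous (default 1.0, strict).
#' @return a validated list of class `CallerThresholds`.
#' @export
callerThresholds <- function(minWildCount = 6L, maxAlbinoCount = 0L,
                             homozygosityFraction = 1.0) {
  minWildCount <- as.integer(minWildCount)
  maxAlbinoCount <- as.integer(maxAlbinoCount)
  if (minWildCount < 1L) stop("minWildCount must be >= 1")
  if (maxAlbinoCount < 0L) stop("maxAlbinoCount must be >= 0")
  if (homozygosityFraction <= 0 || homozygosityFraction > 1)
    stop("homozygosityFraction must be in (0, 1]")
  structure(list(minWildCount = minWildCount,
                 maxAlbinoCount = maxAlbinoCount,
                 homozygosityFraction = homozygosityFraction),
            class = "CallerThresholds")
}

.groupIdx <- function(sync, design) {
  design <- checkDesign(design)
  if (nrow(design) != length(sync@sampleIds))
    stop("design has ", nrow(design), " samples but sync has ",
         length(sync@sampleIds), " count columns")
  list(wild = which(design$group == "wild"),
       albino = which(design$group == "albino"))
}

.countString <- function(counts, i, j) {
  paste(counts[i, j, ], collapse = ":")
}

## non-N coverage per record x sample
.coverage <- function(counts) {
  idx <- match(c("A", "T", "C", "G", "del"), SYNC_ALLELES)
  apply(counts[, , idx, drop = FALSE], c(1, 2), sum)
}

#' Call albefaction-related mutation sites
#'
#' A site is emitted for base `b` in A, C, G, T when `b`'s count is at least
#' `minWildCount` in every wild sample and at most `maxAlbinoCount` in every
#' albino sample. If more than one base qualifies at a position, one row per
#' qualifying base is emitted and flagged `multi_allelic`. Output is sorted by
#' (contig, pos); wild-sample homozygosity for the called allele is assessed
#' per [assessWildHomozygosity()].
#'
#' @param sync a [SyncCounts].
#' @param design sample design (`sample_id`, `group`), rows in sync column
#'   order.
#' @param th a [callerThresholds()] list.
#' @return `data.frame` with columns `contig`, `pos`, `ref`, `wild_allele`,
#'   `multi_allelic`, `homozygous_in_all_wild`, and one `count_<sample_id>`
#'   column per sample holding the `A:T:C:G:N:del` snapshot.
#' @export
callAlbefactionSites <- function(sync, design, th = callerThresholds()) {
  g <- .groupIdx(sync, design)
  n <- nrow(sync@info)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), wild_allele = character(0),
                      multi_allelic = logical(0),
                      homozygous_in_all_wild = logical(0))
  if (n == 0L) return(empty)
  bases <- c("A", "C", "G", "T")
  qual <- matrix(FALSE, n, 4L, dimnames = list(NULL, bases))
  for (b in bases) {
    a <- match(b, SYNC_ALLELES)
    wild_ok <- rowSums(sync@counts[, g$wild, a, drop = FALSE] >=
                         th$minWildCount) == length(g$wild)
    alb_ok <- rowSums(sync@counts[, g$albino, a, drop = FALSE] <=
                        th$maxAlbinoCount) == length(g$albino)
    qual[, b] <- wild_ok & alb_ok
  }
  hit <- which(rowSums(qual) > 0)
  if (length(hit) == 0L) return(empty)
  rows <- do.call(rbind, lapply(hit, function(i) {
    bs <- bases[qual[i, ]]
    data.frame(idx = i, wild_allele = bs,
               multi_allelic = length(bs) > 1L)
  }))
  out <- data.frame(contig = sync@info$contig[rows$idx],
                    pos = sync@info$pos[rows$idx],
                    ref = sync@info$ref[rows$idx],
                    wild_allele = rows$wild_allele,
                    multi_allelic = rows$multi_allelic)
  out$homozygous_in_all_wild <- assessWildHomozygosity(
    out, sync, design, rows$idx, th$homozygosityFraction)
  snap <- lapply(seq_along(sync@sampleIds), function(j) {
    vapply(rows$idx, function(i) .countString(sync@counts, i, j), character(1))
  })
  names(snap) <- paste0("count_", sync@sampleIds)
  out <- cbind(out, as.data.frame(snap, optional = TRUE))
  ord <- order(out$contig, out$pos, out$wild_allele, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess wild-sample homozygosity for called sites
#'
#' A site's called allele is homozygous in the wild strain when in *every*
#' wild sample its count divided by the sample's non-N coverage is at least
#' `fraction`; a wild sample with zero coverage makes the site
#' non-homozygous.
#'
#' @param sites `data.frame` with `contig`, `pos`, `wild_allele` (as produced
#'   by [callAlbefactionSites()]).
#' @param sync the [SyncCounts] the sites were called from.
#' @param design the sample design.
#' @param recordIdx optional pre-matched row indices of `sites` into `sync`;
#'   matched on (contig, pos) when omitted.
#' @param fraction homozygosity fraction threshold (default 1.0).
#' @return logical vector, one element per site row.
#' @export
assessWildHomozygosity <- function(sites, sync, design, recordIdx = NULL,
                                   fraction = 1.0) {
  if (nrow(sites) == 0L) return(logical(0))
  g <- .groupIdx(sync, design)
  if (is.null(recordIdx)) {
    key <- paste(sync@info$contig, sync@info$pos)
    recordIdx <- match(paste(sites$contig, sites$pos), key)
    if (anyNA(recordIdx))
      stop("some sites are absent from the sync records")
  }
  cov <- .coverage(sync@counts)
  vapply(seq_len(nrow(sites)), function(r) {
    i <- recordIdx[r]
    a <- match(sites$wild_allele[r], SYNC_ALLELES)
    cnt <- sync@counts[i, g$wild, a]
    cv <- cov[i, g$wild]
    all(cv > 0) && all(cnt / cv >= fraction)
  }, logical(1))
}

#' Call albino-homozygous deletions
#'
#' A deletion is emitted when in *every* albino sample the deletion is the
#' major allele with count >= 1 and fraction of non-N coverage at least
#' `homozygosityFraction`, while in at least one wild sample the deletion
#' fraction falls below that threshold.
#'
#' @inheritParams callAlbefactionSites
#' @return `data.frame`: `contig`, `pos`, `ref`,
#'   `homozygous_in_all_albino` (always `TRUE` for emitted calls), plus
#'   per-sample `count_<sample_id>` snapshots; sorted by (contig, pos).
#' @export
callAlbinoDeletions <- function(sync, design, th = callerThresholds()) {
  g <- .groupIdx(sync, design)
  n <- nrow(sync@info)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), homozygous_in_all_albino = logical(0))
  if (n == 0L) return(empty)
  d <- match("del", SYNC_ALLELES)
  cov <- .coverage(sync@counts)
  del <- sync@counts[, , d, drop = TRUE]
  if (is.null(dim(del))) del <- matrix(del, nrow = n)
  frac <- ifelse(cov > 0, del / cov, 0)
  major <- matrix(FALSE, n, dim(sync@counts)[2])
  for (j in seq_len(ncol(major)))
    major[, j] <- majorAllele(sync@counts[, j, , drop = TRUE])$allele == "del"
  hf <- th$homozygosityFraction
  alb_ok <- rowSums(major[, g$albino, drop = FALSE] &
                      del[, g$albino, drop = FALSE] >= 1L &
                      frac[, g$albino, drop = FALSE] >= hf) == length(g$albino)
  wild_not <- rowSums(frac[, g$wild, drop = FALSE] < hf) >= 1L
  hit <- which(alb_ok & wild_not)
  if (length(hit) == 0L) return(empty)
  out <- data.frame(contig = sync@info$contig[hit], pos = sync@info$pos[hit],
                    ref = sync@info$ref[hit],
                    homozygous_in_all_albino = TRUE)
  snap <- lapply(seq_along(sync@sampleIds), function(j) {
    vapply(hit, function(i) .countString(sync@counts, i, j), character(1))
  })
  names(snap) <- paste0("count_", sync@sampleIds)
  out <- cbind(out, as.data.frame(snap, optional = TRUE))
  ord <- order(out$contig, out$pos, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate called sites with transcript region and coding effect
#'
#' Each site is placed relative to every ORF of its contig via [locateSite()].
#' The per-site summary region follows the priority CDS > 5' UTR > 3' UTR >
#' outside; when the summary call is CDS the substitution effect is computed
#' with [classifySubstitution()] using the contig (assembly) base as reference
#' and the wild-only allele as alternative. Deletion calls (rows without a
#' `wild_allele` column) are classified with [classifyIndel()]. The full
#' per-(site, ORF) region table is attached as `attr(result, "regionCalls")`.
#'
#' @param sites output of [callAlbefactionSites()] or [callAlbinoDeletions()].
#' @param tx a [Transcriptome]; every site contig must exist in it.
#' @param deletionLength deleted length assumed for deletion calls (default 1).
#' @return `sites` with added columns `region`, `orf_id`, `effect`, `ref_aa`,
#'   `alt_aa`, `codon_index`, `codon_position`.
#' @export
annotateSites <- function(sites, tx, deletionLength = 1L) {
  is_del <- !("wild_allele" %in% names(sites))
  add <- data.frame(region = character(0), orf_id = character(0),
                    effect = character(0), ref_aa = character(0),
                    alt_aa = character(0), codon_index = integer(0),
                    codon_position = integer(0))
  if (nrow(sites) == 0L) {
    out <- cbind(sites, add[rep(0L, 0), ])
    attr(out, "regionCalls") <- data.frame(site = integer(0),
                                           orf_id = character(0),
                                           region = character(0))
    return(out)
  }
  unknown <- setdiff(unique(sites$contig), names(tx@seqs))
  if (length(unknown))
    stop("sites reference unknown contig(s): ", paste(unknown, collapse = ", "))
  prio <- c(cds = 1L, five_prime_utr = 2L, three_prime_utr = 3L, outside = 4L)
  region_calls <- vector("list", nrow(sites))
  rows <- lapply(seq_len(nrow(sites)), function(r) {
    rc <- locateSite(tx, sites$contig[r], sites$pos[r])
    region_calls[[r]] <<- cbind(site = r, rc)
    rc <- rc[order(prio[rc$region], rc$orf_id, method = "radix"), , drop = FALSE]
    top <- rc[1L, ]
    eff <- data.frame(effect = NA_character_, ref_aa = NA_character_,
                      alt_aa = NA_character_, codon_index = NA_integer_,
                      codon_position = NA_integer_)
    if (is_del) {
      if (!is.na(top$orf_id)) {
        ic <- classifyIndel(tx, top$orf_id, sites$pos[r], deletionLength)
        eff$effect <- ic$kind
      } else {
        eff$effect <- "noncoding"
      }
    } else if (top$region == "cds") {
      base <- as.character(Biostrings::subseq(
        .contigSeq(tx, sites$contig[r]), sites$pos[r], sites$pos[r]))
      cs <- classifySubstitution(tx, top$orf_id, sites$pos[r],
                                 base, sites$wild_allele[r])
      eff <- data.frame(effect = cs$kind, ref_aa = cs$ref_aa,
                        alt_aa = cs$alt_aa, codon_index = cs$codon_index,
                        codon_position = cs$codon_position)
    }
    cbind(data.frame(region = top$region, orf_id = top$orf_id), eff)
  })
  out <- cbind(sites, do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "regionCalls") <- do.call(rbind, region_calls)
  out
}

#' Summarize annotated sites by region, effect and genes hit
#'
#' @param sites output of [annotateSites()].
#' @return list with `region_counts` (per-(site, ORF) region tallies),
#'   `summary_region_counts` (per-site summary region tallies),
#'   `effect_counts`, `n_sites`, `n_genes` (distinct contigs) and
#'   `genes_per_region`.
#' @export
summarizeSites <- function(sites) {
  regions <- c("five_prime_utr", "cds", "three_prime_utr", "outside")
  effects <- c("synonymous", "nonsynonymous", "stop_gained", "stop_lost",
               "frameshift", "inframe_del", "noncoding")
  zero <- function(nm) setNames(integer(length(nm)), nm)
  rc <- attr(sites, "regionCalls")
  region_counts <- zero(regions)
  if (!is.null(rc) && nrow(rc)) {
    t1 <- table(factor(rc$region, levels = regions))
    region_counts[] <- as.integer(t1)
  }
  summary_counts <- zero(regions)
  effect_counts <- zero(effects)
  genes_per_region <- zero(regions)
  if (nrow(sites)) {
    summary_counts[] <- as.integer(table(factor(sites$region, levels = regions)))
    eff <- sites$effect[!is.na(sites$effect)]
    effect_counts[] <- as.integer(table(factor(eff, levels = effects)))
    for (rg in regions)
      genes_per_region[rg] <-
        length(unique(sites$contig[sites$region == rg]))
  }
  list(region_counts = region_counts,
       summary_region_counts = summary_counts,
       effect_counts = effect_counts,
       n_sites = nrow(sites),
       n_genes = length(unique(sites$contig)),
       genes_per_region = genes_per_region)
}

#' Write annotated sites as TSV and as minimal VCF
#'
#' The TSV has a fixed column order and a header line beginning `#`. The VCF
#' is minimal 4.2: ALT is the wild-only allele and INFO carries `REGION` and
#' `EFFECT` keys.
#'
#' @param sites annotated site table.
#' @param path output path.
#' @export
writeSitesTsv <- function(sites, path) {
  writeTsv(sites, path)
}

#' @rdname writeSitesTsv
#' @param tx optional [Transcriptome] used to emit `##contig` header lines.
#' @export
writeSitesVcf <- function(sites, path, tx = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=PoolSift",
           '##INFO=<ID=REGION,Number=1,Type=String,Description="Transcript region of the site">',
           '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Predicted coding effect">')
  if (!is.null(tx) && length(tx@seqs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(tx@seqs),
                          Biostrings::width(tx@seqs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(hdr, con, sep = "\n")
  if (nrow(sites)) {
    info <- sprintf("REGION=%s;EFFECT=%s", sites$region,
                    ifelse(is.na(sites$effect), ".", sites$effect))
    alt <- if ("wild_allele" %in% names(sites)) sites$wild_allele else "<DEL>"
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       sites$contig, sites$pos, sites$ref, alt, info),
               con, sep = "\n")
  }
  invisible(NULL)
}

#' Write a data frame as a diff-friendly TSV
#'
#' Fixed column order, a header line beginning `#`, no quoting, newline line
#' endings; the package's standard output surface, read back by [readTsv()].
#'
#' @param d `data.frame`.
#' @param path output path.
#' @export
writeTsv <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(d), collapse = "\t")), con, sep = "\n")
  if (nrow(d)) {
    body <- do.call(paste, c(lapply(d, as.character), list(sep = "\t")))
    writeLines(body, con, sep = "\n")
  }
  invisible(NULL)
}

#' Read a TSV written by the package's writers
#'
#' @param path file path (header line begins `#`).
#' @return `data.frame`.
#' @export
readTsv <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) < 2L) {
    d <- as.data.frame(rep(list(character(0)), length(cols)))
    names(d) <- cols
    return(d)
  }
  read.delim(path, header = FALSE, skip = 1L,
             col.names = cols, stringsAsFactors = FALSE)
}
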