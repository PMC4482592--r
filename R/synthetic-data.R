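## Seeded generators for every input the pipeline consumes, with planted
## ground truth: transcriptome contigs carrying strand-aware ORFs,
## synchronized allele counts with planted wild-only alleles, engineered
## decoys and albino-homozygous deletions, and negative-binomial count
## matrices with planted fold changes.
##
## One global seed fans out to fixed per-generator substreams (seed + 101,
## + 202, + 303) so adding records to one generator does not shift the
## random streams of the others.

## Per-generator substream: fixed offsets from the master seed, kept inside
## the 32-bit integer range.
.substream <- function(seed, offset) {
  set.seed((as.integer(seed) %% 2147480000L) + offset)
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic study generators
#'
#' Defaults define the simulated study's conditions: 30 contigs of 300-1500
#' nt mostly carrying one ORF (both strands), 2 pooled samples per strain at
#' ~30x coverage, 20 planted albefaction sites with wild-allele counts of
#' 6-20 reads, 480 decoy positions each violating exactly one clause of the
#' calling rule, 3 planted albino-homozygous deletions, and a 2000-gene
#' negative-binomial count matrix in which 10% of genes carry a 4-fold
#' planted expression change. The NB dispersion default of 1e-4 (BCV 0.01)
#' models technical-replicate-like pooled libraries.
#'
#' @param seed integer master seed.
#' @param nContigs number of contigs.
#' @param contigLength length-2 range of contig lengths (nt).
#' @param orfProb probability a contig carries an ORF.
#' @param orfLengthCodons length-2 range of ORF lengths in codons
#'   (including start and stop).
#' @param minusStrandProb probability an ORF sits on the minus strand.
#' @param nSamplesPerGroup pooled samples per strain.
#' @param coverageMean Poisson mean of per-sample background coverage.
#' @param nPlantedSites planted albefaction sites.
#' @param plantedWildCount length-2 range of the planted wild-allele count.
#' @param nDecoys decoy polymorphisms violating exactly one rule clause.
#' @param nPlantedDeletions planted albino-homozygous deletions.
#' @param nGenes genes in the count matrix.
#' @param meanLog length-2 (meanlog, sdlog) of the log-normal NB mean
#'   distribution.
#' @param dispersion NB dispersion (1/size).
#' @param plantedDEFraction fraction of genes with a planted fold change.
#' @param foldChange planted wild/albino mean ratio.
#' @param libFactorRange length-2 range of per-sample library size factors.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nContigs = 30L,
                             contigLength = c(300L, 1500L), orfProb = 0.8,
                             orfLengthCodons = c(30L, 120L),
                             minusStrandProb = 0.5, nSamplesPerGroup = 2L,
                             coverageMean = 30, nPlantedSites = 20L,
                             plantedWildCount = c(6L, 20L), nDecoys = 480L,
                             nPlantedDeletions = 3L, nGenes = 2000L,
                             meanLog = c(3, 1.2), dispersion = 1e-4,
                             plantedDEFraction = 0.1, foldChange = 4,
                             libFactorRange = c(0.8, 1.2)) {
  cfg <- list(seed = as.integer(seed), nContigs = as.integer(nContigs),
              contigLength = as.integer(contigLength), orfProb = orfProb,
              orfLengthCodons = as.integer(orfLengthCodons),
              minusStrandProb = minusStrandProb,
              nSamplesPerGroup = as.integer(nSamplesPerGroup),
              coverageMean = coverageMean,
              nPlantedSites = as.integer(nPlantedSites),
              plantedWildCount = as.integer(plantedWildCount),
              nDecoys = as.integer(nDecoys),
              nPlantedDeletions = as.integer(nPlantedDeletions),
              nGenes = as.integer(nGenes), meanLog = meanLog,
              dispersion = dispersion,
              plantedDEFraction = plantedDEFraction, foldChange = foldChange,
              libFactorRange = libFactorRange)
  stopifnot(cfg$nContigs >= 0L, cfg$nSamplesPerGroup >= 1L,
            cfg$nPlantedSites >= 0L, cfg$nDecoys >= 0L,
            cfg$plantedWildCount[1] >= callerThresholds()$minWildCount)
  class(cfg) <- "SimulationConfig"
  cfg
}

.randomContig <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.randomOrfNt <- function(nCodons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, nCodons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate a synthetic transcriptome with planted ORFs
#'
#' Contigs are uniform random nucleotide strings; planted ORFs start with
#' ATG, end with a stop codon, contain no internal stop on the coding strand
#' and leave UTRs on both sides. Both strands are represented. Reproducible:
#' the same config yields byte-identical output.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `tx` (a [Transcriptome]) and `truth` (skeleton list).
#' @export
generateTranscriptome <- function(cfg = simulationConfig()) {
  .substream(cfg$seed, 101L)
  n <- cfg$nContigs
  if (n == 0L)
    return(list(tx = Transcriptome(character(0)), truth = list()))
  lens <- sample(seq(cfg$contigLength[1], cfg$contigLength[2]), n,
                 replace = TRUE)
  ids <- sprintf("contig%03d", seq_len(n))
  seqs <- vapply(lens, .randomContig, character(1))
  names(seqs) <- ids
  orf_rows <- list()
  for (i in seq_len(n)) {
    if (runif(1) > cfg$orfProb) next
    max_codons <- (lens[i] - 20L) %/% 3L  # leave room for UTRs
    if (max_codons < cfg$orfLengthCodons[1]) next
    nc <- sample(seq(cfg$orfLengthCodons[1],
                     min(cfg$orfLengthCodons[2], max_codons)), 1L)
    orf_len <- 3L * nc
    start <- sample(seq(5L, lens[i] - orf_len - 4L), 1L)
    end <- start + orf_len - 1L
    strand <- if (runif(1) < cfg$minusStrandProb) "-" else "+"
    nt <- .randomOrfNt(nc)
    if (strand == "-") nt <- .revcomp(nt)
    substr(seqs[i], start, end) <- nt
    orf_rows[[length(orf_rows) + 1L]] <-
      data.frame(orf_id = sprintf("%s.orf1", ids[i]), contig = ids[i],
                 start = start, end = end, strand = strand, note = "")
    # occasionally a second, non-overlapping ORF downstream
    tail_room <- lens[i] - end - 10L
    if (runif(1) < 0.2 && tail_room >= 3L * cfg$orfLengthCodons[1] + 8L) {
      nc2 <- cfg$orfLengthCodons[1]
      s2 <- end + 5L
      e2 <- s2 + 3L * nc2 - 1L
      nt2 <- .randomOrfNt(nc2)
      substr(seqs[i], s2, e2) <- nt2
      orf_rows[[length(orf_rows) + 1L]] <-
        data.frame(orf_id = sprintf("%s.orf2", ids[i]), contig = ids[i],
                   start = s2, end = e2, strand = "+", note = "")
    }
  }
  orfs <- if (length(orf_rows)) do.call(rbind, orf_rows) else NULL
  list(tx = Transcriptome(seqs, orfs), truth = list())
}

## Pick `n` distinct (contig, pos) coordinates not already in `used`.
.samplePositions <- function(tx, n, used = character(0)) {
  lens <- Biostrings::width(tx@seqs)
  ids <- names(tx@seqs)
  out <- data.frame(contig = character(0), pos = integer(0))
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not place ", n, " distinct positions")
    need <- n - nrow(out)
    ci <- sample(seq_along(ids), need, replace = TRUE)
    pos <- vapply(ci, function(i) sample.int(lens[i], 1L), integer(1))
    cand <- data.frame(contig = ids[ci], pos = pos)
    key <- paste(cand$contig, cand$pos)
    ok <- !(key %in% used) & !duplicated(key)
    out <- rbind(out, cand[ok, , drop = FALSE])
    used <- c(used, key[ok])
  }
  out[seq_len(n), , drop = FALSE]
}

.baseAt <- function(tx, contig, pos)
  as.character(Biostrings::subseq(.contigSeq(tx, contig), pos, pos))

## Summary region under the CDS > 5'UTR > 3'UTR > outside priority rule.
.summaryRegion <- function(tx, contig, pos) {
  rc <- locateSite(tx, contig, pos)
  prio <- c(cds = 1L, five_prime_utr = 2L, three_prime_utr = 3L,
            outside = 4L)
  rc$region[order(prio[rc$region])][1]
}

.otherBase <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

## One sync count sextuple (A:T:C:G:N:del order) with `ref` supported by
## `refCount` reads and optionally `alt` by `altCount`.
.mkCounts <- function(ref, refCount, alt = NULL, altCount = 0L,
                      delCount = 0L) {
  v <- setNames(integer(6), SYNC_ALLELES)
  v[ref] <- as.integer(refCount)
  if (!is.null(alt)) v[alt] <- v[alt] + as.integer(altCount)
  v["del"] <- as.integer(delCount)
  v
}

#' Generate a synchronized file with planted ground truth
#'
#' Plants `nPlantedSites` albefaction sites (wild-only allele with count in
#' `plantedWildCount` in every wild sample, absent from every albino
#' sample), `nDecoys` decoys that each violate exactly one clause of the
#' calling rule (one wild sample at count 5; allele present once in one
#' albino sample; allele absent from one wild sample; or an ordinary shared
#' polymorphism), and `nPlantedDeletions` deletions homozygous in every
#' albino sample. Deletion plants keep one wild sample's reference support
#' below the wild-allele gate so each plant triggers exactly one caller.
#'
#' @param cfg a [simulationConfig()].
#' @param txg output of [generateTranscriptome()] (or a list with `tx`).
#' @return list: `sync` (a [SyncCounts]), `design`, and `truth` with
#'   `plantedSites`, `plantedDeletions`, `decoys`.
#' @export
generateSync <- function(cfg = simulationConfig(),
                         txg = generateTranscriptome(cfg)) {
  .substream(cfg$seed, 202L)
  tx <- txg$tx
  ns <- cfg$nSamplesPerGroup
  design <- data.frame(
    sample_id = c(sprintf("wild%d", seq_len(ns)),
                  sprintf("albino%d", seq_len(ns))),
    group = rep(c("wild", "albino"), each = ns))
  wild <- seq_len(ns); albino <- ns + seq_len(ns)
  nsamp <- 2L * ns
  th <- callerThresholds()
  nTotal <- cfg$nPlantedSites + cfg$nDecoys + cfg$nPlantedDeletions
  if (nTotal == 0L || length(tx@seqs) == 0L) {
    sync <- SyncCounts(data.frame(contig = character(0), pos = integer(0),
                                  ref = character(0)),
                       array(integer(0), dim = c(0L, nsamp, 6L)),
                       design$sample_id)
    return(list(sync = sync, design = design,
                truth = list(plantedSites = NULL, plantedDeletions = NULL,
                             decoys = NULL)))
  }
  coords <- .samplePositions(tx, nTotal)
  idx_sites <- seq_len(cfg$nPlantedSites)
  idx_decoy <- cfg$nPlantedSites + seq_len(cfg$nDecoys)
  idx_del <- cfg$nPlantedSites + cfg$nDecoys + seq_len(cfg$nPlantedDeletions)
  counts <- array(0L, dim = c(nTotal, nsamp, 6L))
  refs <- vapply(seq_len(nTotal),
                 function(i) .baseAt(tx, coords$contig[i], coords$pos[i]),
                 character(1))
  refs[refs == "N"] <- "A"
  rcov <- function() max(1L, rpois(1L, cfg$coverageMean))
  planted <- list(); decoys <- list(); dels <- list()
  for (i in idx_sites) {
    alt <- .otherBase(refs[i])
    wc <- sample(seq(cfg$plantedWildCount[1], cfg$plantedWildCount[2]), ns,
                 replace = TRUE)
    for (j in wild)
      counts[i, j, ] <- .mkCounts(refs[i], rcov(), alt, wc[j])
    for (j in albino)
      counts[i, j, ] <- .mkCounts(refs[i], rcov())
    planted[[length(planted) + 1L]] <-
      data.frame(contig = coords$contig[i], pos = coords$pos[i],
                 ref = refs[i], allele = alt,
                 region = .summaryRegion(tx, coords$contig[i],
                                         coords$pos[i]))
  }
  decoy_kinds <- c("wild_at_five", "present_in_albino", "absent_in_one_wild",
                   "shared_polymorphism")
  for (k in seq_along(idx_decoy)) {
    i <- idx_decoy[k]
    kind <- decoy_kinds[(k - 1L) %% 4L + 1L]
    alt <- .otherBase(refs[i])
    hi <- function() sample(seq(th$minWildCount,
                                cfg$plantedWildCount[2]), 1L)
    altc <- switch(kind,
      wild_at_five = c(th$minWildCount - 1L,
                       vapply(seq_len(ns - 1L), function(x) hi(), integer(1))),
      present_in_albino = vapply(wild, function(x) hi(), integer(1)),
      absent_in_one_wild = c(0L, vapply(seq_len(ns - 1L),
                                        function(x) hi(), integer(1))),
      shared_polymorphism = vapply(wild, function(x) hi(), integer(1)))
    for (j in wild)
      counts[i, j, ] <- .mkCounts(refs[i], rcov(), alt, altc[j])
    alb_alt <- switch(kind,
      present_in_albino = c(1L, integer(ns - 1L)),
      shared_polymorphism = vapply(albino, function(x) hi(), integer(1)),
      integer(ns))
    for (j in seq_len(ns))
      counts[i, albino[j], ] <- .mkCounts(refs[i], rcov(), alt, alb_alt[j])
    decoys[[length(decoys) + 1L]] <-
      data.frame(contig = coords$contig[i], pos = coords$pos[i],
                 ref = refs[i], allele = alt, kind = kind)
  }
  for (i in idx_del) {
    # wild: reference reads, one sample held below the wild-allele gate
    refc <- c(th$minWildCount - 1L,
              vapply(seq_len(ns - 1L),
                     function(x) max(th$minWildCount, rcov()), integer(1)))
    for (j in wild)
      counts[i, j, ] <- .mkCounts(refs[i], refc[j])
    for (j in albino)
      counts[i, j, ] <- .mkCounts(refs[i], 0L, delCount = rcov())
    dels[[length(dels) + 1L]] <-
      data.frame(contig = coords$contig[i], pos = coords$pos[i],
                 ref = refs[i],
                 region = .summaryRegion(tx, coords$contig[i],
                                         coords$pos[i]))
  }
  info <- data.frame(contig = coords$contig, pos = coords$pos, ref = refs)
  ord <- order(info$contig, info$pos, method = "radix")
  sync <- SyncCounts(info[ord, , drop = FALSE],
                     counts[ord, , , drop = FALSE], design$sample_id)
  bindOr <- function(x) if (length(x)) {
    d <- do.call(rbind, x)
    d <- d[order(d$contig, d$pos, method = "radix"), , drop = FALSE]
    rownames(d) <- NULL
    d
  } else NULL
  list(sync = sync, design = design,
       truth = list(plantedSites = bindOr(planted),
                    plantedDeletions = bindOr(dels),
                    decoys = bindOr(decoys)))
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' Gene means are log-normal; counts are NB with per-sample library-size
#' scaling. A `plantedDEFraction` of genes receive the configured wild/albino
#' mean ratio (`foldChange`), split symmetrically (sqrt(fc) up, 1/sqrt(fc)
#' down) with random direction.
#'
#' @param cfg a [simulationConfig()].
#' @param nullSim if `TRUE`, plant no fold changes regardless of
#'   `plantedDEFraction` (null calibration runs).
#' @return list: `counts` (genes x samples), `design`, `truth` (data.frame
#'   `gene_id`, `direction` of planted DE genes; empty when none).
#' @export
generateCounts <- function(cfg = simulationConfig(), nullSim = FALSE) {
  .substream(cfg$seed, 303L)
  ns <- cfg$nSamplesPerGroup
  design <- data.frame(
    sample_id = c(sprintf("wild%d", seq_len(ns)),
                  sprintf("albino%d", seq_len(ns))),
    group = rep(c("wild", "albino"), each = ns))
  g <- cfg$nGenes
  if (g == 0L) {
    return(list(counts = matrix(integer(0), 0, 2L * ns,
                                dimnames = list(NULL, design$sample_id)),
                design = design,
                truth = data.frame(gene_id = character(0),
                                   direction = character(0))))
  }
  ids <- sprintf("gene%05d", seq_len(g))
  mu <- rlnorm(g, meanlog = cfg$meanLog[1], sdlog = cfg$meanLog[2])
  lib <- runif(2L * ns, cfg$libFactorRange[1], cfg$libFactorRange[2])
  nDE <- if (nullSim) 0L else round(cfg$plantedDEFraction * g)
  de_idx <- if (nDE > 0L) sort(sample.int(g, nDE)) else integer(0)
  dir_up <- if (nDE > 0L) runif(nDE) < 0.5 else logical(0)
  fc_w <- rep(1, g); fc_a <- rep(1, g)
  s <- sqrt(cfg$foldChange)
  fc_w[de_idx] <- ifelse(dir_up, s, 1 / s)
  fc_a[de_idx] <- ifelse(dir_up, 1 / s, s)
  size <- 1 / cfg$dispersion
  counts <- matrix(0L, g, 2L * ns, dimnames = list(ids, design$sample_id))
  for (j in seq_len(2L * ns)) {
    f <- if (j <= ns) fc_w else fc_a
    counts[, j] <- rnbinom(g, mu = mu * f * lib[j], size = size)
  }
  truth <- data.frame(gene_id = ids[de_idx],
                      direction = ifelse(dir_up, "up_in_wild", "up_in_albino"))
  list(counts = counts, design = design, truth = truth)
}

#' Write a full synthetic study to a directory
#'
#' Emits exactly the file formats the pipeline consumes: contig FASTA, ORF
#' BED, synchronized file, design TSV, count matrix TSV, and the ground
#' truth tables as TSVs.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
generateStudy <- function(cfg = simulationConfig(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txg <- generateTranscriptome(cfg)
  sg <- generateSync(cfg, txg)
  cg <- generateCounts(cfg)
  writeTranscriptome(txg$tx, file.path(dir, "contigs.fasta"),
                     file.path(dir, "orfs.bed"))
  writeSync(sg$sync, file.path(dir, "counts.sync"))
  writeDesign(sg$design, file.path(dir, "design.tsv"))
  writeCountMatrix(cg$counts, file.path(dir, "gene_counts.tsv"))
  for (nm in names(sg$truth))
    if (!is.null(sg$truth[[nm]]))
      writeTsv(sg$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  if (nrow(cg$truth))
    writeTsv(cg$truth, file.path(dir, "truth_plantedDE.tsv"))
  invisible(list(tx = txg$tx, sync = sg$sync, design = sg$design,
                 counts = cg$counts,
                 truth = c(sg$truth, list(plantedDE = cg$truth))))
}
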