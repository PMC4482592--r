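## End-to-end orchestration of the wild-versus-albino comparison: mutation
## calling + annotation, DE consensus, orthology / colour-gene report, and
## the join between expression and mutation results. All outputs are
## "#"-headed TSVs with fixed column orders so identical inputs give
## byte-identical results.

#' Run the full wild-versus-albino pipeline
#'
#' Reads the inputs, calls and annotates albefaction sites and
#' albino-homozygous deletions, runs the DE stage (two supplied method
#' tables, or the bundled binomial test on a count matrix when none are
#' given), computes the consensus, optionally derives RBB orthologs and the
#' colour-gene report, joins DE calls with mutation sites, and writes every
#' result as a TSV under `outDir`.
#'
#' @param fasta,orfBed,sync,designPath paths to the contig FASTA, ORF BED,
#'   synchronized file and sample design TSV.
#' @param countMatrix optional genes-x-samples count TSV for the bundled
#'   test.
#' @param deTable1,deTable2 optional pre-computed DE result TSVs (method 1
#'   interpreted under the logFC rule, method 2 under the PostFC rule when
#'   it has a `PostFC` column, else logFC).
#' @param blastA2B,blastB2A optional BLAST outfmt-6 paths for RBB orthology.
#' @param panel optional gene-panel path (defaults to the bundled
#'   pigmentation panel when orthology inputs are given).
#' @param outDir output directory, created if needed.
#' @param callerTh,consensusTh threshold lists.
#' @return invisibly, a list of the in-memory result tables.
#' @export
runPipeline <- function(fasta, orfBed, sync, designPath,
                        countMatrix = NULL, deTable1 = NULL, deTable2 = NULL,
                        blastA2B = NULL, blastB2A = NULL, panel = NULL,
                        outDir, callerTh = callerThresholds(),
                        consensusTh = consensusThresholds()) {
  paths <- c(fasta = fasta, orfBed = orfBed, sync = sync,
             design = designPath, countMatrix = countMatrix,
             deTable1 = deTable1, deTable2 = deTable2,
             blastA2B = blastA2B, blastB2A = blastB2A, panel = panel)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[PoolSift] ", ...)

  tx <- readTranscriptome(fasta, orfBed)
  design <- readDesign(designPath)
  sy <- readSync(sync, sampleIds = design$sample_id)
  log("inputs: ", length(contigSeqs(tx)), " contigs, ", length(sy),
      " sync records, ", nrow(design), " samples")

  sites <- callAlbefactionSites(sy, design, callerTh)
  sites <- annotateSites(sites, tx)
  dels <- callAlbinoDeletions(sy, design, callerTh)
  dels <- annotateSites(dels, tx)
  log("mutation caller: ", nrow(sites), " sites, ", nrow(dels),
      " deletions (minWildCount=", callerTh$minWildCount,
      ", maxAlbinoCount=", callerTh$maxAlbinoCount, ")")
  writeSitesTsv(sites, file.path(outDir, "albefaction_sites.tsv"))
  writeSitesVcf(sites, file.path(outDir, "albefaction_sites.vcf"), tx)
  writeSitesTsv(dels, file.path(outDir, "albino_deletions.tsv"))

  if (!is.null(deTable1)) {
    t1 <- readDETable(deTable1, "method1")
    candA <- methodCandidates(t1, consensusTh, "logfc")
  } else if (!is.null(countMatrix)) {
    cm <- readCountMatrix(countMatrix)
    t1 <- simpleCountTest(cm, design, consensusTh)
    candA <- methodCandidates(t1, consensusTh, "logfc")
  } else {
    candA <- NULL
  }
  candB <- if (!is.null(deTable2)) {
    t2 <- readDETable(deTable2, "method2")
    rule <- if ("PostFC" %in% names(t2)) "postfc" else "logfc"
    methodCandidates(t2, consensusTh, rule)
  } else NULL
  consensus <- if (!is.null(candA) || !is.null(candB)) {
    if (is.null(candA)) { candA <- candB; candB <- NULL }
    cc <- deConsensus(candA, candB, consensusTh)
    log("DE consensus: ", nrow(cc), " genes (",
        sum(cc$tier == "definite"), " definite)")
    writeTsv(cc, file.path(outDir, "de_consensus.tsv"))
    cc
  } else NULL

  pairs <- NULL
  if (!is.null(blastA2B) && !is.null(blastB2A)) {
    a2b <- bestHits(readBlastTab(blastA2B))
    b2a <- bestHits(readBlastTab(blastB2A))
    pairs <- reciprocalPairs(a2b, b2a)
    log("orthology: ", nrow(pairs), " reciprocal best hit pairs")
    writeTsv(pairs, file.path(outDir, "ortholog_pairs.tsv"))
    panelGenes <- if (!is.null(panel)) readGenePanel(panel)
                  else readGenePanel()
    creport <- colourReport(pairs, panelGenes, consensus, sites)
    writeTsv(creport, file.path(outDir, "colour_report.tsv"))
  }

  joined <- if (!is.null(consensus)) {
    j <- crossReference(consensus, sites)
    writeTsv(j, file.path(outDir, "de_mutation_join.tsv"))
    j
  } else NULL

  invisible(list(sites = sites, deletions = dels, consensus = consensus,
                 pairs = pairs, joined = joined))
}

#' Join DE consensus calls with annotated mutation sites
#'
#' Genes appearing in both result sets (contig id = gene id), with DE tier
#' and direction next to the number and kinds of mutation sites on the
#' contig. Deterministically ordered by gene id.
#'
#' @param consensusCalls [deConsensus()] output.
#' @param annotatedSites [annotateSites()] output.
#' @return `data.frame`: `gene_id`, `tier`, `direction`, `n_sites`,
#'   `effects` (comma-joined distinct non-NA effects).
#' @export
crossReference <- function(consensusCalls, annotatedSites) {
  shared <- intersect(consensusCalls$gene_id, annotatedSites$contig)
  shared <- sort(shared, method = "radix")
  rows <- lapply(shared, function(g) {
    cc <- consensusCalls[consensusCalls$gene_id == g, , drop = FALSE]
    ms <- annotatedSites[annotatedSites$contig == g, , drop = FALSE]
    ef <- unique(ms$effect[!is.na(ms$effect)])
    data.frame(gene_id = g, tier = cc$tier[1], direction = cc$direction[1],
               n_sites = nrow(ms),
               effects = if (length(ef))
                 paste(sort(ef, method = "radix"), collapse = ",")
               else NA_character_)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene_id = character(0), tier = character(0),
                         direction = character(0), n_sites = integer(0),
                         effects = character(0))
  rownames(out) <- NULL
  out
}
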