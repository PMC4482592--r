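# The calling rule: some base must be supported by strictly more than five
# reads in every wild sample and be absent (count 0) from every albino
# sample under the default thresholds.

test_that("caller boundaries: >5 in all wild, absent in all albino", {
  sy <- syncFromStrings(
    contig = rep("c1", 4), pos = 1:4, ref = rep("G", 4),
    sampleStrings = list(
      w1 = c("6:0:0:4:0:0", "5:0:0:9:0:0", "10:0:0:5:0:0", "0:6:0:5:0:0"),
      w2 = c("6:0:0:3:0:0", "12:0:0:2:0:0", "10:0:0:4:0:0", "0:8:0:4:0:0"),
      a1 = c("0:0:0:7:0:0", "0:0:0:8:0:0", "1:0:0:9:0:0", "0:0:0:9:0:0"),
      a2 = c("0:0:0:5:0:0", "0:0:0:6:0:0", "0:0:0:7:0:0", "0:0:0:3:0:0")),
    sampleIds = c("w1", "w2", "a1", "a2"))
  sites <- callAlbefactionSites(sy, wdesign())
  # pos 1: A=6 in both wild, absent in albino -> called
  # pos 2: one wild sample at exactly 5 -> NOT called
  # pos 3: albino1 carries one A read -> NOT called
  # pos 4: T qualifies -> called
  expect_identical(sites$pos, c(1L, 4L))
  expect_identical(sites$wild_allele, c("A", "T"))
  expect_false(any(sites$multi_allelic))
})

test_that("multi-allelic qualifying sites emit one flagged row per base", {
  sy <- syncFromStrings(
    "c1", 10L, "G",
    sampleStrings = list(w1 = "7:6:0:0:0:0", w2 = "8:9:0:0:0:0",
                         a1 = "0:0:0:5:0:0", a2 = "0:0:0:5:0:0"),
    sampleIds = c("w1", "w2", "a1", "a2"))
  sites <- callAlbefactionSites(sy, wdesign())
  expect_identical(nrow(sites), 2L)
  expect_true(all(sites$multi_allelic))
  expect_identical(sort(sites$wild_allele), c("A", "T"))
})

test_that("empty input and arity mismatches behave as specified", {
  sy <- syncFromStrings(character(0), integer(0), character(0),
                        sampleStrings = list(w1 = character(0),
                                             w2 = character(0),
                                             a1 = character(0),
                                             a2 = character(0)),
                        sampleIds = c("w1", "w2", "a1", "a2"))
  expect_identical(nrow(callAlbefactionSites(sy, wdesign())), 0L)
  expect_error(callAlbefactionSites(sy, wdesign(3, 2)), "design has")
})

test_that("wild homozygosity requires full allele fraction in every pool", {
  mk <- function(w1, w2) syncFromStrings(
    "c1", 1L, "G",
    sampleStrings = list(w1 = w1, w2 = w2,
                         a1 = "0:0:0:4:0:0", a2 = "0:0:0:4:0:0"),
    sampleIds = c("w1", "w2", "a1", "a2"))
  d <- wdesign()
  s1 <- callAlbefactionSites(mk("6:0:0:0:0:0", "7:0:0:0:0:0"), d)
  expect_true(s1$homozygous_in_all_wild)
  s2 <- callAlbefactionSites(mk("6:0:1:0:0:0", "7:0:0:0:0:0"), d)
  expect_false(s2$homozygous_in_all_wild)
  # N reads are excluded from coverage: A=6 + N=2 is still homozygous
  s3 <- callAlbefactionSites(mk("6:0:0:0:2:0", "7:0:0:0:0:0"), d)
  expect_true(s3$homozygous_in_all_wild)
  # randomized check against direct fraction computation
  set.seed(31)
  for (i in 1:25) {
    w1 <- sprintf("%d:0:%d:0:%d:0", sample(6:12, 1), sample(0:2, 1),
                  sample(0:2, 1))
    w2 <- sprintf("%d:0:%d:0:%d:0", sample(6:12, 1), sample(0:2, 1),
                  sample(0:2, 1))
    sy <- mk(w1, w2)
    s <- callAlbefactionSites(sy, d)
    frac <- function(x) {
      v <- as.integer(strsplit(x, ":")[[1]])
      v[1] / (sum(v) - v[5])
    }
    expect_identical(s$homozygous_in_all_wild,
                     frac(w1) >= 1 && frac(w2) >= 1)
  }
})

test_that("albino-homozygous deletions need full deletion fraction", {
  d <- wdesign()
  mk <- function(a1, a2, w1 = "8:0:0:0:0:0", w2 = "9:0:0:0:0:0")
    syncFromStrings("c1", 1L, "A",
                    sampleStrings = list(w1 = w1, w2 = w2, a1 = a1, a2 = a2),
                    sampleIds = c("w1", "w2", "a1", "a2"))
  called <- callAlbinoDeletions(mk("0:0:0:0:0:8", "0:0:0:0:0:8"), d)
  expect_identical(nrow(called), 1L)
  expect_true(called$homozygous_in_all_albino)
  # half-deleted albino pool: not homozygous at fraction 1.0
  expect_identical(nrow(callAlbinoDeletions(mk("4:0:0:0:0:4",
                                               "0:0:0:0:0:8"), d)), 0L)
  # deletion fixed in every sample of both strains: not strain-specific
  expect_identical(nrow(callAlbinoDeletions(
    mk("0:0:0:0:0:8", "0:0:0:0:0:8",
       w1 = "0:0:0:0:0:7", w2 = "0:0:0:0:0:7"), d)), 0L)
})

test_that("thresholds act monotonically and order does not matter", {
  cfg <- simulationConfig(seed = 13, nPlantedSites = 15, nDecoys = 60,
                          nPlantedDeletions = 2)
  sg <- generateSync(cfg)
  d <- sg$design
  key <- function(s) paste(s$contig, s$pos, s$wild_allele)
  base <- callAlbefactionSites(sg$sync, d, callerThresholds(6, 0))
  stricter <- callAlbefactionSites(sg$sync, d, callerThresholds(9, 0))
  looser <- callAlbefactionSites(sg$sync, d, callerThresholds(6, 1))
  expect_true(all(key(stricter) %in% key(base)))
  expect_true(all(key(base) %in% key(looser)))
  # record order must not affect the (sorted) result
  set.seed(1)
  perm <- sample(length(sg$sync))
  shuffled <- SyncCounts(syncInfo(sg$sync)[perm, ],
                         alleleCounts(sg$sync)[perm, , , drop = FALSE],
                         sampleIds(sg$sync))
  again <- callAlbefactionSites(shuffled, d)
  expect_identical(key(again), key(base))
})

test_that("caller equals a per-record brute force on simulated streams", {
  cfg <- simulationConfig(seed = 23, nPlantedSites = 20, nDecoys = 120,
                          nPlantedDeletions = 3)
  sg <- generateSync(cfg)
  th <- callerThresholds()
  counts <- alleleCounts(sg$sync)
  wild <- which(sg$design$group == "wild")
  albino <- which(sg$design$group == "albino")
  expected <- list()
  for (i in seq_len(length(sg$sync))) {
    for (b in c("A", "C", "G", "T")) {
      a <- match(b, c("A", "T", "C", "G", "N", "del"))
      if (all(counts[i, wild, a] >= th$minWildCount) &&
          all(counts[i, albino, a] <= th$maxAlbinoCount))
        expected[[length(expected) + 1L]] <-
          paste(syncInfo(sg$sync)$contig[i], syncInfo(sg$sync)$pos[i], b)
    }
  }
  got <- callAlbefactionSites(sg$sync, sg$design, th)
  expect_setequal(paste(got$contig, got$pos, got$wild_allele),
                  unlist(expected))
})

test_that("annotation fills region and effect; unknown contigs error", {
  tx <- Transcriptome(
    c(c1 = paste0("AAAA", "ATGCTTTAC", "TAAGGGGGGG"), c2 = "ACGTACGT"),
    data.frame(orf_id = "o1", contig = "c1", start = 5L, end = 16L,
               strand = "+"))
  sites <- data.frame(contig = c("c1", "c1", "c1", "c2"),
                      pos = c(2L, 10L, 20L, 3L),
                      ref = c("A", "T", "G", "G"),
                      wild_allele = c("C", "C", "A", "A"))
  ann <- annotateSites(sites, tx)
  expect_identical(ann$region,
                   c("five_prime_utr", "cds", "three_prime_utr", "outside"))
  expect_identical(ann$effect[1], NA_character_)
  expect_identical(ann$effect[2], "synonymous")  # CTT -> CTC
  expect_true(is.na(ann$effect[3]))
  expect_error(annotateSites(data.frame(contig = "cX", pos = 1L, ref = "A",
                                        wild_allele = "C"), tx),
               "unknown contig")
})

test_that("multi-ORF sites take the CDS call under the priority rule", {
  tx <- Transcriptome(
    c(c1 = paste0("ATGAAATAA", "CC", "ATGCCCTAA", "CCCC")),
    data.frame(orf_id = c("oA", "oB"), contig = c("c1", "c1"),
               start = c(1L, 12L), end = c(9L, 20L), strand = "+"))
  # position 13 is 3' UTR for oA but CDS for oB -> summary region cds
  ann <- annotateSites(data.frame(contig = "c1", pos = 13L, ref = "T",
                                  wild_allele = "G"), tx)
  expect_identical(ann$region, "cds")
  expect_identical(ann$orf_id, "oB")
  rc <- attr(ann, "regionCalls")
  expect_identical(nrow(rc), 2L)
  expect_setequal(rc$region, c("three_prime_utr", "cds"))
})

test_that("summaries tally regions, effects and genes hit", {
  tx <- toyTx()
  cfg <- simulationConfig(seed = 3, nPlantedSites = 12, nDecoys = 30,
                          nPlantedDeletions = 1)
  sg <- generateSync(cfg, list(tx = generateTranscriptome(cfg)$tx))
  txs <- generateTranscriptome(cfg)$tx
  sites <- callAlbefactionSites(sg$sync, sg$design)
  ann <- annotateSites(sites, txs)
  sm <- summarizeSites(ann)
  expect_identical(sm$n_sites, nrow(ann))
  expect_identical(sm$n_genes, length(unique(ann$contig)))
  expect_identical(sum(sm$summary_region_counts), nrow(ann))
  rc <- attr(ann, "regionCalls")
  expect_identical(sum(sm$region_counts), nrow(rc))
  expect_identical(unname(sum(sm$effect_counts)),
                   sum(!is.na(ann$effect)))
  # empty input gives an all-zero table
  sm0 <- summarizeSites(annotateSites(sites[0, ], txs))
  expect_identical(sm0$n_sites, 0L)
  expect_true(all(sm0$region_counts == 0L))
})

test_that("site TSV and VCF outputs carry the calls", {
  tx <- Transcriptome(
    c(c1 = paste0("AAAA", "ATGCTTTAC", "TAAGGGGGGG")),
    data.frame(orf_id = "o1", contig = "c1", start = 5L, end = 16L,
               strand = "+"))
  sites <- annotateSites(
    data.frame(contig = "c1", pos = 10L, ref = "T", wild_allele = "C"), tx)
  tsv <- tempfile(); vcf <- tempfile()
  writeSitesTsv(sites, tsv)
  writeSitesVcf(sites, vcf, tx)
  back <- readTsv(tsv)
  expect_identical(back$pos, 10L)
  expect_identical(back$effect, "synonymous")
  v <- readLines(vcf)
  expect_identical(v[1], "##fileformat=VCFv4.2")
  body <- v[!startsWith(v, "#")]
  expect_match(body, "c1\t10\t.\tT\tC\t.\tPASS\tREGION=cds;EFFECT=synonymous",
               fixed = TRUE)
})
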