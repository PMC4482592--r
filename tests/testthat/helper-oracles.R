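# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately avoid the package's code paths:
# regions come from a per-position counting scan, substitution effects from
# full-ORF retranslation of a mutated contig, BH from the literal step-up
# definition, and best hits from an exhaustive per-query scan.

revcompStr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

translateStr <- function(nt) {
  d <- Biostrings::DNAString(nt)
  if (grepl("[^ACGT]", nt))
    as.character(Biostrings::translate(d, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  else
    as.character(Biostrings::translate(d, no.init.codon = TRUE))
}

# Per-position region scan for one ORF: walk the contig along the coding
# strand, counting coding bases, and label each position from the counter.
oracleRegionScan <- function(contigLen, start, end, strand) {
  region <- character(contigLen)
  codon_index <- rep(NA_integer_, contigLen)
  codon_position <- rep(NA_integer_, contigLen)
  walk <- if (strand == "+") seq_len(contigLen) else rev(seq_len(contigLen))
  seen_coding <- 0L
  in_cds_done <- FALSE
  for (p in walk) {
    if (p >= start && p <= end) {
      region[p] <- "cds"
      codon_index[p] <- seen_coding %/% 3L + 1L
      codon_position[p] <- seen_coding %% 3L + 1L
      seen_coding <- seen_coding + 1L
      in_cds_done <- TRUE
    } else if (!in_cds_done) {
      region[p] <- "five_prime_utr"
    } else {
      region[p] <- "three_prime_utr"
    }
  }
  list(region = region, codon_index = codon_index,
       codon_position = codon_position)
}

# Substitution effect by retranslating the entire ORF for both alleles.
oracleSubstitution <- function(contigSeq, start, end, strand, pos, altBase) {
  mut <- contigSeq
  substr(mut, pos, pos) <- altBase
  extract <- function(s) {
    orf <- substr(s, start, end)
    if (strand == "-") orf <- revcompStr(orf)
    translateStr(orf)
  }
  ref_pep <- extract(contigSeq)
  alt_pep <- extract(mut)
  if (grepl("X", ref_pep) || grepl("X", alt_pep)) return("nonsynonymous")
  if (identical(ref_pep, alt_pep)) return("synonymous")
  d <- which(strsplit(ref_pep, "")[[1]] != strsplit(alt_pep, "")[[1]])[1]
  ra <- substr(ref_pep, d, d); aa <- substr(alt_pep, d, d)
  if (aa == "*") "stop_gained" else if (ra == "*") "stop_lost"
  else "nonsynonymous"
}

# Literal step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive per-query best-hit scan under the strict gates.
oracleBestHits <- function(hits, maxEvalue = 1e-9, minAlnLen = 100,
                           minIdentity = 60) {
  res <- character(0)
  for (q in unique(hits$qseqid)) {
    rows <- hits[hits$qseqid == q & hits$evalue < maxEvalue &
                   hits$length > minAlnLen & hits$pident > minIdentity, ,
                 drop = FALSE]
    if (nrow(rows) == 0) next
    best <- NULL
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (is.null(best) ||
          r$bitscore > best$bitscore ||
          (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
          (r$bitscore == best$bitscore && r$evalue == best$evalue &&
             r$sseqid < best$sseqid)) {
        best <- r
      }
    }
    res[q] <- best$sseqid
  }
  res
}

randomBlastTable <- function(nq = 8, ns = 8, nhits = 30) {
  data.frame(
    qseqid = sprintf("q%02d", sample.int(nq, nhits, replace = TRUE)),
    sseqid = sprintf("s%02d", sample.int(ns, nhits, replace = TRUE)),
    pident = round(runif(nhits, 40, 100), 1),
    length = sample(50:300, nhits, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L,
    evalue = 10^-sample(5:40, nhits, replace = TRUE),
    bitscore = sample(seq(80, 400, by = 10), nhits, replace = TRUE))
}

# A small transcriptome with hand-placed ORFs on both strands.
toyTx <- function() {
  set.seed(424242)
  cfg <- simulationConfig(seed = 424242, nContigs = 10,
                          contigLength = c(120L, 260L),
                          orfLengthCodons = c(12L, 40L), orfProb = 1)
  generateTranscriptome(cfg)$tx
}

# Build a SyncCounts in code from a matrix of "A:T:C:G:N:del" strings.
syncFromStrings <- function(contig, pos, ref, sampleStrings, sampleIds) {
  n <- length(pos)
  counts <- array(0L, dim = c(n, length(sampleIds), 6L))
  for (j in seq_along(sampleIds)) {
    parts <- strsplit(sampleStrings[[j]], ":", fixed = TRUE)
    counts[, j, ] <- matrix(as.integer(unlist(parts)), ncol = 6L,
                            byrow = TRUE)
  }
  SyncCounts(data.frame(contig = contig, pos = pos, ref = ref),
             counts, sampleIds)
}

# Bind 3D count arrays along the record dimension.
abind_1 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(a) dim(a)[1], integer(1)))
  out <- array(0L, dim = c(n, dim(parts[[1]])[2], dim(parts[[1]])[3]),
               dimnames = c(list(NULL), dimnames(parts[[1]])[2:3]))
  at <- 0L
  for (a in parts) {
    k <- dim(a)[1]
    if (k) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

wdesign <- function(nw = 2, na = 2) {
  data.frame(sample_id = c(sprintf("w%d", seq_len(nw)),
                           sprintf("a%d", seq_len(na))),
             group = rep(c("wild", "albino"), c(nw, na)))
}
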