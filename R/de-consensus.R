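## Two-method differential-expression consensus: Benjamini-Hochberg
## adjustment, per-method candidate rules (|logFC| > 1 / PostFC outside
## [0.5, 2], adjusted value < 0.05, all strict), their merge, the "definite"
## tier at adjusted < 0.001 by both methods, and a bundled exact binomial
## two-group count test so the pipeline runs end to end without external DE
## fits.

#' Thresholds for DE candidate selection and consensus
#'
#' All comparisons against these thresholds are strict inequalities, so genes
#' sitting exactly on a boundary are excluded.
#'
#' @param minAbsLogFC minimum |log2 fold change| for the logFC rule
#'   (default 1).
#' @param postFCHigh,postFCLow posterior fold-change gates for the PostFC
#'   rule (defaults 2 and 0.5; must be reciprocal).
#' @param alpha adjusted-value cutoff for candidates (default 0.05).
#' @param definiteAlpha adjusted-value cutoff, per method, for the definite
#'   tier (default 0.001).
#' @param minTotalCounts prefilter: a gene must reach this many counts summed
#'   across all samples to be tested (default 10, i.e. at least ten).
#' @return a validated list of class `ConsensusThresholds`.
#' @export
consensusThresholds <- function(minAbsLogFC = 1, postFCHigh = 2,
                                postFCLow = 1 / postFCHigh, alpha = 0.05,
                                definiteAlpha = 0.001, minTotalCounts = 10L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (definiteAlpha >= alpha) stop("definiteAlpha must be below alpha")
  if (abs(postFCLow * postFCHigh - 1) > 1e-8)
    stop("postFCLow must equal 1/postFCHigh")
  structure(list(minAbsLogFC = minAbsLogFC, postFCHigh = postFCHigh,
                 postFCLow = postFCLow, alpha = alpha,
                 definiteAlpha = definiteAlpha,
                 minTotalCounts = as.integer(minTotalCounts)),
            class = "ConsensusThresholds")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate control: with the p-values sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped
#' back to the input order. Stable under ties and idempotent for m = 1.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return adjusted values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Read a method-agnostic DE test-result table
#'
#' Tab-separated with a header; must contain `gene_id`, a fold-change measure
#' column (`logFC` or `PostFC`), a probability column (`pvalue` or `ppde`),
#' and optionally `adjusted`.
#'
#' @param path TSV path.
#' @param methodLabel label recorded for the method.
#' @return `data.frame` with normalized columns `gene_id`, `logFC` and/or
#'   `PostFC`, `pvalue`/`ppde`, `adjusted` (NA when absent).
#' @export
readDETable <- function(path, methodLabel = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(d)) stop("DE table needs a gene_id column")
  if (!any(c("logFC", "PostFC") %in% names(d)))
    stop("DE table needs a logFC or PostFC column")
  if (anyDuplicated(d$gene_id)) stop("one row per gene required")
  if (!"adjusted" %in% names(d)) d$adjusted <- NA_real_
  d$method_label <- methodLabel
  d
}

#' Select per-method DE candidates under the strict threshold rules
#'
#' `rule = "logfc"` keeps genes with `|logFC| > minAbsLogFC` and adjusted
#' value `< alpha`; `rule = "postfc"` keeps genes with
#' `PostFC < postFCLow` or `PostFC > postFCHigh` and adjusted value
#' `< alpha`. All inequalities strict. When the table carries no `adjusted`
#' column, the logfc rule derives it from `pvalue` by [bhAdjust()]; the
#' postfc rule takes `1 - ppde` directly as an FDR-like quantity (set
#' `adjustPpde = TRUE` to BH-adjust it instead).
#'
#' Direction is fixed as wild-versus-albino: positive logFC and
#' `PostFC > postFCHigh` mean up-regulated in the wild type.
#'
#' @param tbl a [readDETable()]-style `data.frame`.
#' @param th a [consensusThresholds()] list.
#' @param rule `"logfc"` or `"postfc"`.
#' @param adjustPpde for the postfc rule, BH-adjust `1 - ppde` rather than
#'   using it directly (default `FALSE`).
#' @return `data.frame` with `gene_id`, `measure` (the fold-change value),
#'   `adjusted`, `direction` (`up_in_wild`/`up_in_albino`).
#' @export
methodCandidates <- function(tbl, th = consensusThresholds(),
                             rule = c("logfc", "postfc"),
                             adjustPpde = FALSE) {
  rule <- match.arg(rule)
  adj <- tbl$adjusted
  if (rule == "logfc") {
    if (!"logFC" %in% names(tbl)) stop("logfc rule needs a logFC column")
    if (is.null(adj) || all(is.na(adj))) {
      if (!"pvalue" %in% names(tbl))
        stop("need adjusted or pvalue column for the logfc rule")
      adj <- bhAdjust(tbl$pvalue)
    }
    keep <- abs(tbl$logFC) > th$minAbsLogFC & adj < th$alpha
    measure <- tbl$logFC
    direction <- ifelse(tbl$logFC > 0, "up_in_wild", "up_in_albino")
  } else {
    if (!"PostFC" %in% names(tbl)) stop("postfc rule needs a PostFC column")
    if (is.null(adj) || all(is.na(adj))) {
      if (!"ppde" %in% names(tbl))
        stop("need adjusted or ppde column for the postfc rule")
      adj <- 1 - tbl$ppde
      if (adjustPpde) adj <- bhAdjust(adj)
    }
    keep <- (tbl$PostFC < th$postFCLow | tbl$PostFC > th$postFCHigh) &
      adj < th$alpha
    measure <- tbl$PostFC
    direction <- ifelse(tbl$PostFC > 1, "up_in_wild", "up_in_albino")
  }
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_id = tbl$gene_id[keep], measure = measure[keep],
                    adjusted = adj[keep], direction = direction[keep])
  out[order(out$gene_id, method = "radix"), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Merge two methods' candidate sets into a consensus call table
#'
#' The union of both candidate sets, annotated with which method(s) called
#' each gene. A gene is tier `definite` only when both methods called it with
#' concordant direction and both adjusted values fall strictly below
#' `definiteAlpha`; genes with discordant directions are flagged and excluded
#' from the definite tier.
#'
#' @param callsA,callsB outputs of [methodCandidates()]; `callsB` may be
#'   `NULL` for a single-method run (all calls then stay `candidate`).
#' @param th a [consensusThresholds()] list.
#' @return `data.frame` sorted by `gene_id`: `gene_id`, `called_by`
#'   (`method1`, `method2` or `both`), `direction`, `discordant`, `tier`,
#'   `adjusted_m1`, `adjusted_m2`.
#' @export
deConsensus <- function(callsA, callsB = NULL, th = consensusThresholds()) {
  if (is.null(callsB))
    callsB <- data.frame(gene_id = character(0), measure = numeric(0),
                         adjusted = numeric(0), direction = character(0))
  genes <- sort(unique(c(callsA$gene_id, callsB$gene_id)), method = "radix")
  ia <- match(genes, callsA$gene_id)
  ib <- match(genes, callsB$gene_id)
  in_a <- !is.na(ia); in_b <- !is.na(ib)
  called_by <- ifelse(in_a & in_b, "both", ifelse(in_a, "method1", "method2"))
  dirA <- callsA$direction[ia]; dirB <- callsB$direction[ib]
  discordant <- in_a & in_b & dirA != dirB
  direction <- ifelse(in_a, dirA, dirB)
  direction[discordant] <- "discordant"
  adjA <- callsA$adjusted[ia]; adjB <- callsB$adjusted[ib]
  definite <- in_a & in_b & !discordant &
    adjA < th$definiteAlpha & adjB < th$definiteAlpha
  data.frame(gene_id = genes, called_by = called_by, direction = direction,
             discordant = discordant,
             tier = ifelse(definite, "definite", "candidate"),
             adjusted_m1 = adjA, adjusted_m2 = adjB)
}

#' Bundled two-group exact binomial count test
#'
#' A deliberately simple stand-in DE test so the pipeline runs without
#' external model fits: genes with fewer than `minTotalCounts` summed counts
#' are dropped; for each remaining gene the wild-group count sum is tested
#' against the albino-group sum with a two-sided exact binomial test whose
#' expected proportion comes from the groups' total library sizes. logFC is
#' the log2 ratio of library-size-normalized group means computed with a
#' +0.5 pseudocount; raw p-values are BH-adjusted.
#'
#' @param counts non-negative integer matrix, genes x samples, with row and
#'   column names.
#' @param design sample design (`sample_id`, `group`), matching the count
#'   columns by name.
#' @param th a [consensusThresholds()] list (supplies `minTotalCounts`).
#' @return `data.frame`: `gene_id`, `logFC`, `pvalue`, `adjusted`,
#'   `method_label = "binomial"`.
#' @export
simpleCountTest <- function(counts, design, th = consensusThresholds()) {
  design <- checkDesign(design)
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), design$sample_id))
    stop("count matrix columns must match design sample ids")
  counts <- counts[, design$sample_id, drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  wild <- design$group == "wild"
  if (sum(lib[wild]) == 0 || sum(lib[!wild]) == 0)
    stop("a group has zero total library size")
  keep <- rowSums(counts) >= th$minTotalCounts
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L)
    return(data.frame(gene_id = character(0), logFC = numeric(0),
                      pvalue = numeric(0), adjusted = numeric(0),
                      method_label = character(0)))
  w <- rowSums(counts[, wild, drop = FALSE])
  a <- rowSums(counts[, !wild, drop = FALSE])
  p0 <- sum(lib[wild]) / sum(lib)
  pval <- vapply(seq_along(w), function(i) {
    binom.test(w[i], w[i] + a[i], p = p0)$p.value
  }, numeric(1))
  rates <- sweep(counts + 0.5, 2, lib, "/")
  logFC <- log2(rowMeans(rates[, wild, drop = FALSE]) /
                  rowMeans(rates[, !wild, drop = FALSE]))
  data.frame(gene_id = rownames(counts), logFC = unname(logFC),
             pvalue = pval, adjusted = bhAdjust(pval),
             method_label = "binomial")
}

#' Read a genes-by-samples count matrix TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCountMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountMatrix
#' @param counts matrix to write.
#' @export
writeCountMatrix <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
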