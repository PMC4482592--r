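---
title: "Calling strain-differential mutations and expression changes from pooled transcriptomes"
author: "PoolSift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling strain-differential mutations and expression changes from pooled transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoolSift)
```

## The problem

A spontaneous albino strain appearing in an aquaculture population — the
motivating case is a golden, melanin-free variant of an otherwise darkly
pigmented catfish — poses a concrete molecular question: is
the loss of melanin caused by coding mutations that disable a pigmentation
gene, or by changes in how pigmentation genes are expressed?

With no reference genome, the practical study design is to sequence pooled
RNA of both strains, assemble a de novo transcriptome, and compare the two
strains along two independent axes:

1. **Allele presence/absence.** Map every strain's pooled reads back to the
   assembly and tabulate, position by position, the counts of A, C, G, T, N
   and deletion alleles per pool. A site where some allele is well supported
   in *every* wild-type pool but entirely absent from *every* albino pool is
   a candidate strain-differential ("albefaction-related") mutation: under a
   recessive model the albino strain may be fixed for a different allele.
2. **Expression.** Count reads per transcript per pool and ask which genes
   change expression between strains, requiring agreement between two
   different testing methods before trusting a call.

Finally, because pigmentation biology is well mapped in model fish, assigned
orthologs (reciprocal best protein hits against a reference proteome) let
the analyst ask specifically what happened to the canonical colour genes
(*tyr*, *tyrp1*, *slc7a11*, ...).

PoolSift implements this comparative machinery as reusable, tested
components, taking the standard file formats as its boundaries: contig FASTA
plus an ORF BED table (assembly and ORF prediction are upstream tools' jobs),
a PoPoolation2 synchronized allele-count file (read mapping, duplicate
marking and quality filtering are likewise upstream), two
differential-expression result tables in a method-agnostic layout, BLAST
tabular files for orthology, and a plain-text gene-name panel.

## The mutation-calling rule

At one position of one contig, let $c_{s}(b)$ be the count of allele
$b \in \{A, C, G, T\}$ in pooled sample $s$. With wild-type pools $W$ and
albino pools $A$, allele $b$ is called **albefaction-related** iff

$$ \min_{s \in W} c_s(b) \ge k \quad\text{and}\quad \max_{s \in A} c_s(b) \le m, $$

with defaults $k = 6$ (strictly more than five supporting reads in every
wild pool) and $m = 0$ (absent from every albino pool). The rule is
deliberately deterministic — presence/absence of an allele across pools,
not an allele-frequency test — because pooled samples of unequal sizes make
per-individual genotype models inapplicable. Both thresholds are exposed
(`callerThresholds()`) so count-based variants can be explored; "frequency"
is read as a raw count, which is what the synchronized format stores and
the only reading under which "absent" is well defined.

Two secondary assessments refine the calls:

* **Wild homozygosity** (`assessWildHomozygosity()`): the called allele's
  count divided by the pool's non-N coverage must reach a configurable
  fraction (default 1.0, i.e. no other allele observed) in every wild pool.
  A pool with zero coverage can never attest homozygosity. In practice
  called sites are rarely homozygous in all wild pools — the wild strain is
  outbred and segregating — and this flag makes that explicit.
* **Albino-homozygous deletions** (`callAlbinoDeletions()`): the deletion
  allele (sixth slot of the sync format) must be the major allele, with
  count ≥ 1 and fraction ≥ the homozygosity threshold, in every albino
  pool, while at least one wild pool falls below that fraction. Deletions
  are treated as a callable sixth allele precisely so this class of
  strain-fixed events is reachable from the same input.

N counts are excluded from coverage and from allele calling throughout
(the PoPoolation2 convention). Multi-allelic qualifying sites — two bases
passing the rule at one position — are emitted one row per allele and
flagged, never silently merged.

## Coordinates, regions and consequences

All coordinates are 1-based and inclusive on the contig's forward strand;
BED input is converted at the parser boundary. ORFs may sit on either
strand, and one contig may carry several ORFs.

`locateSite()` classifies a position relative to each ORF of its contig:
5' UTR, CDS or 3' UTR *along the coding strand*, so on a minus-strand ORF
the 5' UTR is the high-coordinate side. CDS positions carry a codon index
and an intra-codon position read along the coding strand. The per-site
summary applied by `annotateSites()` uses a fixed priority — CDS, then
5' UTR, then 3' UTR, then outside — chosen so that a potentially
protein-changing interpretation is never shadowed by a UTR call from a
second ORF; the full per-(site, ORF) table is retained alongside.

Substitution consequences (`classifySubstitution()`) retranslate the single
affected codon: synonymous, nonsynonymous, stop_gained, stop_lost. The
reference allele is the assembly (contig) base and the alternative is the
wild-only allele; the assembly is the only available anchor, and the
per-method direction of change is recorded so users can re-polarize.
Codons containing ambiguous bases translate to "X" and are reported as
nonsynonymous with a warning rather than dropped — conservative, visible,
and countable. Deletion consequences (`classifyIndel()`) are `noncoding`
outside the CDS; a CDS overlap that is not a multiple of 3 is a
`frameshift`; an in-frame deletion is retranslated end-to-end and reported
as `stop_gained` if a premature internal stop appears, otherwise
`inframe_del`.

Translation uses the standard genetic code (table sourced from Biostrings)
via a direct codon lookup. The test suite checks every region call against
an independent per-position counting scan and every substitution call
against full-ORF retranslation with Biostrings' own translator, for all
three alternative bases at every CDS position of a ten-contig toy
transcriptome with minus-strand ORFs.

## Differential-expression consensus

The package does not re-implement count-model DE tests: edgeR- and
EBSeq-style result tables are its ingestion surface, normalized to
`gene_id`, a fold-change measure (`logFC` or `PostFC`), a probability
column, and optionally a pre-adjusted value. The selection rules are those
a two-method consensus analysis would print:

* logFC rule: $|\log_2 FC| > 1$ **and** BH-adjusted p < 0.05;
* PostFC rule: posterior fold change < 0.5 or > 2 **and** adjusted
  posterior-probability complement < 0.05;
* **definite tier**: called by both methods, concordant in direction, and
  both adjusted values < 0.001.

Every comparison is a strict inequality, so a gene sitting exactly on a
boundary is excluded; the tests pin this with exactly-at-threshold and
one-epsilon-past fixtures. When an EBSeq-style table carries no adjusted
column, `1 - PPDE` is taken directly as an FDR-like quantity (it is a
posterior error probability); set `adjustPpde = TRUE` to BH-adjust it
instead. Direction is fixed as wild-versus-albino: positive logFC and
PostFC > 2 mean up-regulated in the wild type. Benjamini–Hochberg
adjustment is delegated to `stats::p.adjust`; the suite still verifies it
elementwise against a literal step-up oracle on a thousand random vectors.

`simpleCountTest()` is bundled plumbing, not a contribution: a two-sided
exact binomial test of the wild-group count sum against the albino-group
sum, with the expected proportion taken from total library sizes, after
dropping genes with fewer than ten counts across all samples. It exists so
the pipeline runs end to end without external fits, and it is honest under
its stated conditions (see the generator section); for real biological
replicates an overdispersion-aware model is the right tool.

## Orthology and colour genes

`bestHits()` filters BLAST tabular rows by three gates — alignment length
> 100 amino acids, identity > 60 percent of the aligned region, E-value
< 1e-9 — then keeps the highest-bitscore hit per query, breaking ties by
lower E-value and then lexicographic subject id (a deterministic choice;
`dropTies = TRUE` discards tied queries instead). The identity gate applies
to the aligned region as BLAST reports it, not the full protein length, and
no multi-HSP stitching is attempted: each row stands alone. All three gates
are strict, so boundary hits are excluded. `reciprocalPairs()` keeps
mutually-best pairs, which is symmetric in the two species by construction.

`colourReport()` joins a pigmentation gene panel (case-insensitive exact
name match; a ~20-name canonical melanogenesis panel ships with the
package) against the ortholog pairs, the DE consensus and the mutation
calls, yielding one row per panel gene with its contigs, DE verdict and
any mutation sites — the table an analyst scans to answer "what happened
to *tyr*?".

## The synthetic study generator

`generateStudy()` emits every input the pipeline consumes, with planted
ground truth, so all stages are testable without sequencing data. Its
defaults define the simulated study conditions:

* 30 contigs of 300–1500 nt, 80% carrying an ORF of 30–120 codons (ATG …
  stop, no internal stop), strands equiprobable, occasionally a second
  non-overlapping ORF;
* 2 pooled samples per strain, background coverage Poisson with mean 30;
* 20 planted albefaction sites (wild-only allele at 6–20 reads in every
  wild pool, absent from albino pools), 480 decoys, 3 planted
  albino-homozygous deletions;
* a 2000-gene count matrix, log-normal means (meanlog 3, sdlog 1.2),
  negative-binomial dispersion 1e-4, library-size factors in [0.8, 1.2],
  10% of genes carrying a 4-fold planted change split symmetrically
  between directions.

Decoys are engineered to violate **exactly one** clause of the calling rule
— one wild pool at exactly five supporting reads, one albino pool carrying
a single read of the allele, the allele missing from one wild pool, or an
ordinary polymorphism shared by both strains — so the tests probe each
failure mode of the filter explicitly rather than relying on a sequencing
error model. Planted deletions keep one wild pool's reference support below
the wild-allele gate so each plant triggers exactly one caller and recovery
can be asserted exactly.

The dispersion default of 1e-4 (a biological coefficient of variation of
0.01) models the fact that each library is a pool of individuals sequenced
once — technical-replicate-like variation, the canonical BCV figure for
technical replicates in the edgeR literature. This is also the regime in
which the bundled binomial test's pooled-count conditioning is valid, which
the calibration test verifies (null p-values uniform to within 3 binomial
standard errors at 2000 genes). What the generator does **not** emulate:
biological replicate dispersion (BCV 0.1–0.4), sequencing error, mapping
artefacts, coverage that tracks expression, or linkage between sites.
Passing tests therefore demonstrate the *logic* of the callers under their
stated assumptions, not robustness to noisy real libraries.

A single master seed fans out to fixed per-generator substreams (offsets
101, 202, 303), so regenerating one input never shifts the random streams
of the others, and every output is byte-identical across runs for a fixed
configuration.

## Numerical and design choices

* Thresholds: caller defaults (6, 0, homozygosity 1.0) and consensus
  defaults (1, 2/0.5, 0.05, 0.001, 10) are the printed conventions of this
  analysis style; every one is a function argument.
* Ties: the major-allele order A < C < G < T < del; best-hit ties by
  E-value then subject id; cluster representatives are the
  lexicographically smallest member id. All outputs are sorted with
  C-locale (radix) ordering, so runs are byte-reproducible across locales.
* Degenerate inputs: empty sync streams, zero-contig configurations, empty
  panels and empty candidate sets all yield empty, well-typed results
  rather than errors; a zero-coverage pool fails homozygosity; zero total
  library size in a group is an error.
* Problem sizes in the test suite (503-record sync streams, 1000-record
  round trips, 2000-gene matrices, a ten-contig exhaustive annotation
  oracle, 100 random orthology fixtures) were chosen as the smallest sizes
  at which the property being tested is meaningfully exercised.

## Limitations

* The caller is presence/absence logic; it attaches no statistical
  significance to allele-frequency differences and will not find sites
  where the albino allele is merely rare rather than absent.
* Effect prediction assumes the predicted ORF is correct and complete;
  splice-aware genome coordinates and alternative genetic codes are out of
  scope.
* The "reference" for amino-acid change is the assembly consensus; if the
  assembly collapsed the albino allele at a site, ref/alt roles invert
  (the direction is recorded, so this is recoverable).
* RBB orthology with strict gates undercounts orthologs between distant
  species; that conservatism is inherited by the colour-gene report.
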