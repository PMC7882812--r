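---
title: "Scanning spliced 3'UTRs for QRE / miRNA-site proximity"
author: "qrescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning spliced 3'UTRs for QRE / miRNA-site proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrescan)
```

## The question the pipeline answers

Quaking (QKI) is an RNA-binding protein that stabilises mRNAs by binding
quaking response elements (QREs) in their 3'UTRs. The QRE is bipartite: a
core pentamer `ACUAA`, often followed within a short distance by a
half-site `UAAY` (Y = C or U). miRNAs destabilise the same transcripts by
pairing with target sites in the same UTRs. When a QRE and a miRNA target
site lie within a few nucleotides of each other, a bound RBP can sterically
mask the miRNA site, so the two factors act as antagonists on one
transcript. `qrescan` implements the in-silico side of that argument as a
five-stage screen:

1. build each transcript's 3'UTR as a *spliced region* (ordered exonic
   blocks) and extract its exon-joined RNA sequence;
2. scan the spliced sequence for every `ACUAA` occurrence and map each hit
   back to genomic blocks — a hit crossing an exon junction maps to two
   blocks and exists only in spliced space;
3. filter candidate miRNA target sites by the expression of their miRNA
   (top 50% of the expression table) and by targeting strength
   (mirSVR-style score strictly below −1);
4. cross-validate QRE hits against eCLIP narrowPeak replicates by genomic
   overlap (≥ 1 bp against any block, any replicate by default);
5. report QRE–site pairs at a genomic distance strictly below 20 nt and
   summarise them per gene.

The expression side is independent of the motif side: a panel gene is
*detectable* when it has a non-zero count in at least one sample; each
dataset contributes a direction call (`Up` when log2 fold change ≥ 0.4,
`Down` when ≤ −0.4); a gene is *consensus-regulated* when the same
direction appears in at least two of three datasets. A packaged call
matrix of 17 regulated guidance-cue genes across three
monocyte-to-macrophage differentiation datasets reproduces the worked
example: 9 consensus `Up`, 8 consensus `Down` (shown under Worked example
below).

## Coordinate conventions

All internal coordinates are 0-based, half-open `[start, end)`, on both
the genome and the transcript. GTF's 1-based closed spans and BED's
0-based half-open spans are converted exactly once, at the I/O boundary.
Transcript coordinate 0 is the 5'-most base in transcript orientation: the
leftmost block start on `+`, the rightmost `end − 1` on `-`. The package
maintains the transcript↔genome mapping as an explicit bijection
(`map_to_genome()` / `map_from_genome()`), and `map_interval_to_genome()`
splits an interval at exon junctions so the emitted block widths always
sum to the interval length.

Two readings of "distance" are possible once features live on a spliced
transcript. `interval_gap()` counts the bases strictly *between* two
intervals: overlapping or book-ended features are at distance 0, so a
shared base never counts as separation. The proximity scan measures this
gap on **genomic** coordinates by default, because both feature kinds are
stored as genomic ranges; within a single UTR exon the genomic and spliced
measures coincide. A `spliced` mode is provided for the case where a QRE
and a site sit in different exons of the same UTR — adjacent on the mRNA,
far apart on the genome. Sites that are not fully inside the UTR's exonic
blocks are skipped in spliced mode, with a logged reason.

## Decision rules and their boundaries

Every threshold is inclusive or strict exactly as printed by the source
rules, and each boundary is pinned by a unit test:

| parameter | default | rule |
|---|---|---|
| proximity | 20 nt | strict `<`: a pair at exactly 20 nt is excluded |
| mirSVR score | −1.0 | strict `<`: a site scoring exactly −1.0 is dropped |
| miRNA expression | top 50% | `≥` the table-wide 50% quantile; ties included |
| direction call | ±0.4 log2 | inclusive: log2 fold change exactly 0.4 is `Up` |
| consensus | 2 of 3 | same direction in ≥ 2 datasets; conflicts are `None` |
| eCLIP support | 1 replicate | any-block, ≥ 1 bp, strand-ignorant overlap |

Choices the sources leave open, decided here once and exposed as
configuration:

- **Expression reference population.** "Top 50%" is computed over all
  miRNAs in the expression table, not only those with candidate sites,
  with multiple sample columns averaged first. This is the most
  reproducible reading; miRNAs absent from the table fail the filter
  rather than erroring (they are counted in the log).
- **Half-site.** The validation/proximity pipeline keys on the core
  `ACUAA` alone; `UAAY` is annotated as metadata with a 20 nt search
  window downstream of the core (`half_site_max_gap`, a gap-filling
  default — no published window exists).
- **Replicate threshold.** `min_replicates = 1` by default; support in
  both eCLIP duplicates is reported as a column rather than enforced,
  since the overlay rule itself names no replicate requirement.
- **Isoform policy.** Every transcript's 3'UTR is scanned independently
  and rows carry `transcript_id`; gene-level summaries take the union.
- **CDS-derived UTRs.** When explicit `three_prime_utr` features exist
  they are used verbatim; otherwise the UTR is the exonic territory
  strictly 3' of the annotated CDS end, with no stop-codon adjustment.
- **`± log2 0.4`.** Read as |log2 fold change| ≥ 0.4 — a ±-symmetric
  threshold is only meaningful on the log scale. The pseudocount default
  is 1 for count data; 0 is allowed for intensity data.
- **Overlapping motif occurrences** are all reported; the scan applies no
  exclusion rule, and `N` never matches.

## What the generator emulates — and what it does not

`sim_config()` defines the study conditions for all tests: 20 genes on one
contig, 2–3 exons each, both strands (half minus by default), 3'UTRs of
150–300 nt always spanning the final exon junction; 3 planted proximal
genes whose QRE-site gap is drawn from 3–15 nt (strictly inside the 20 nt
rule); one decoy gene per failure class — site at ≥ 20 nt, miRNA below the
median expression, score of −0.5, and a fully passing site whose QRE has
no peak; extra QRE-only and site-only genes as background. Peaks cover
each peak-bearing QRE in both replicates by default (`peak_coverage = 1`),
plus intergenic noise peaks that cannot touch a UTR. The miRNA expression
table is balanced so that expressed miRNAs sit strictly above, and
low-expression miRNAs strictly below, the table median for every seed —
the decoy classes are therefore separated by construction, not by luck.

Expression tables mirror a heterogeneous trio: one single-sample count
dataset and two three-replicate intensity datasets, with planted log2 fold
changes of ±1 and log-normal noise (`noise_sd = 0.1` on the natural-log
scale). Every third regulated gene is left unchanged in the third dataset
so the two-of-three consensus rule is genuinely exercised. The
patient/sibling pair carries a −1 log2 deficit on the planted proximal
genes in both cell states, and a 12-donor table of paired regulator/target
values with slope 1 supports the correlation check.

One deliberate asymmetry: accidental `ACUAA` occurrences arising in the
random background are left in place *except* inside the UTRs of genes that
carry peaks, where they are rewritten (one base is changed, which cannot
create a new occurrence). Without this, a chance motif under a planted
peak could validate and pair with a decoy site, and the planted truth
would hold only for most seeds. The truth table records every occurrence
that survives, planted or natural, so scanner tests can still distinguish
"planted" from "correct": the scanner's contract is *all* occurrences.
Setting `mask_background = TRUE` extends the rewrite to every UTR.

What the generator does **not** emulate: realistic eCLIP signal shapes or
peak calling, read-level data, alternative polyadenylation, isoform
complexity beyond one transcript per gene, miRNA family structure, and
sequence composition biases of real UTRs. Passing the planted-recovery
test therefore demonstrates that the pipeline's logic is exact under its
own assumptions — not that those filters are biologically sufficient on
real data, where annotation errors, overlapping genes and peak noise all
occur.

## Numerical and degenerate-input choices

- Empty intervals are rejected at construction; blocks must be sorted and
  non-overlapping, so every `spliced_region` is a valid coordinate system.
- A narrowPeak file with zero lines is a valid "no peaks called" input;
  the pipeline then reports zero validated QREs and zero pairs and exits
  cleanly.
- Transcripts with neither explicit UTR features nor a CDS are skipped
  with a warning; a CDS reaching the transcript's 3' end yields no UTR
  (`NULL`), not an error.
- Unknown bases are kept as `N` in the spliced RNA and can never match the
  core.
- Ordering of every report is deterministic (gene symbol, then transcript
  position), so re-running a configuration reproduces reports byte for
  byte; timestamps exist only in the JSON manifest.
- Problem sizes in the test suite were chosen to make the checks
  exhaustive rather than sampled where feasible: 1000 random sequences
  (length 0–2000) against a brute-force window oracle, 1000 random spliced
  regions with every position round-tripped, and full-pipeline recovery on
  the 20-gene fixture.

## Worked example

```{r eval = FALSE}
library(qrescan)

# packaged 17-gene call matrix: >=2-of-3 consensus
cons <- consensus_table(load_ngc_call_matrix(), regulation_config())
table(cons$consensus)
#> Down   Up
#>    8    9

# simulate a study and run the full pipeline
cfg <- sim_config(seed = 101)
study <- simulate_study(cfg, "fixture")
rc <- run_config("fixture/genome.fa", "fixture/annotation.gtf",
                 "fixture/mirna_sites.tsv", "fixture/mirna_expression.tsv",
                 c(rep1 = "fixture/eclip_rep1.narrowPeak",
                   rep2 = "fixture/eclip_rep2.narrowPeak"),
                 out_dir = "reports")
res <- run_pipeline(rc)
res$gene_summary
#>   gene_symbol n_pairs best_distance_nt n_mirnas max_replicate_support
#> 1     GENE001       1                9        1                     2
#> 2     GENE002       1                3        1                     2
#> 3     GENE003       1               10        1                     2
identical(sort(res$gene_summary$gene_symbol),
          study$truth$planted_proximal_genes)
#> TRUE
```

## Known limitations

- The proximity scan enumerates same-gene (hit, site) combinations
  directly; this is exact and fast for panel-scale inputs (tens of genes,
  thousands of features) but would want an interval index for
  genome-scale scans.
- No statistical enrichment test is attached to the proximity counts — no
  permutation null is defined for the screen, so the output is a
  candidate list, not a p-value.
- mirSVR-style scores and miRNA-site coordinates are taken as input; the
  package does not predict target sites.
- Consensus calling accepts precomputed per-dataset calls (as in the
  packaged matrix) or derives them from expression tables with the
  package's own fold-change rule; it does not re-run differential
  expression statistics.
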