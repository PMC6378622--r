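---
title: "Substrain-exclusive variant triage: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrain-exclusive variant triage: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substrainr)
library(dplyr)
```

## The problem and the model

Two inbred lines derived from the same strain ("substrains") accumulate
private fixed mutations after separation. If the lines differ in a phenotype
— the motivating case is reduced antibody class-switch recombination (CSR)
in one line's B cells — candidate causal loci can be sought among variants
that are called in one line and absent from the other. The pipeline treats
this as four successive reductions:

1. per-line variant calls → **line-exclusive, high-confidence variants**;
2. exclusive variants → **(gene, region class) assignments**;
3. assigned genes → **candidates** via gene-set membership and expression;
4. candidate variants → **predicted regulatory effects** (TFBS gain/loss,
   splice-window deltas, UTR location flags).

Each reduction is a pure function of tabular inputs, so every stage takes a
tibble and returns one, and each run is deterministic given its inputs.

## Filtering: thresholds and their semantics

The filter keeps a variant when all of the following hold, with **strict**
inequalities throughout:

* `qual > 100` — the variant caller's site quality score;
* `alt_depth > 10` — reads supporting the alternate allele, taken from
  `FORMAT/AD` of the first sample (second and following fields), falling back
  to `INFO/DP4` (sum of the last two counts) when `AD` is absent. Records
  exposing neither are dropped and counted, never silently kept;
* spacing `> 10` nt to the nearest same-line, same-chromosome variant
  (anchor-position distance on normalized variants);
* the full `(chrom, pos, ref, alt)` key is absent from the other line.

Boundary values are therefore excluded: a variant with quality exactly 100
or alt depth exactly 10 never passes. Two points were genuinely open and are
exposed as switches rather than hidden choices:

* **Stage order.** Exclusivity is evaluated against the other line's
  *unfiltered* set by default (`exclusivity_against = "raw"`): a variant
  weakly called in the other line is evidence against line-specificity even
  if it would not itself survive filtering. The alternative
  (`"filtered"`) runs quality/depth/spacing first.
* **Close pairs.** The spacing rule removes *both* members of any pair
  within 10 nt (`spacing_mode = "drop-all"`): clustered calls near indels
  are mutually suspect, and a keep-one rule would be order-dependent. The
  greedy `"keep-first"` sweep is available for comparison. The default is
  equivalent to the quadratic all-pairs definition, which the tests verify
  directly.

Multi-allelic records are split into one variant per alternate allele
*before* any filtering, so every rule is allele-aware; position-only
exclusivity is available behind `position_only = TRUE` but is less
conservative for "specific to line X" claims. Alleles are reduced to minimal
representation (shared suffix then prefix trimmed, one anchor base kept for
indels); left-alignment against the reference is the upstream caller's
responsibility and is not re-done here.

## Gene assignment

Classes follow a fixed priority: **CDS > nCDS > RR > intergenic**, decided
on the variant's affected reference span `[pos, pos + nchar(ref) - 1]`.
Within a gene, the sub-context is the finest of exonic-CDS, 5′/3′ UTR
(strand-aware, derived as exon-minus-CDS partitioned around the CDS extent),
intron, or non-coding exon. Gene models are per-gene unions of exon and CDS
intervals across isoforms, because triage and reporting operate at gene
level. Strand never affects class or distance, only the UTR labels.

Variants outside genes are attributed to the nearest gene span within
`max_assign_distance` (default 100,000 nt — large enough to capture
neighbouring-gene regulation in a gene-dense region while keeping the
contract defined; there is no canonical value for this cap). Ties break by
smaller gene start, then lexicographic gene id. A regulatory region that
names its target gene overrides proximity for variants inside it; in the
bundled simulator the two always agree.

## Candidate triage

A gene is a candidate iff it has ≥ 1 exclusive-variant annotation, is in
≥ 1 supplied gene set, and shows expression `> expr_threshold` in ≥ 1
designated population. The expression check is a *presence* check, not a
differential test, mirroring how one would confirm a candidate is expressed
at all in the relevant cell type. There is no canonical threshold for
"expressed"; the default (120, on the arbitrary linear scale of the bundled
expression tables) is a required configuration value, not a biological
constant, and `no_expression_filter = TRUE` disables the check. Genes absent
from the expression table fail the check and are counted in the triage
report rather than erroring, since incomplete atlases are the norm. Genes
reachable only through intergenic nearest-gene assignment are triaged
identically, with `intergenic` retained in the class column.

## Motif model and effect prediction

A motif is a position probability matrix with pseudocount `ε = 0.01` added
per cell and columns renormalized; scores are summed log2 odds against a
uniform background (both configurable). Relative score maps raw scores into
[0, 1] between the matrix's attainable extremes, and a hit is a window with
relative score ≥ 0.80 on either strand. The 0.80 default is standard
practice for PWM screens whose upstream tools do not publish exact cutoffs;
it is configurable per scan. `N` bases contribute their background-expected
log odds (exactly 0 under a uniform background), so windows at contig edges
are scored rather than discarded.

For a variant, both alleles of the window
`[pos - (W_max - 1), pos + nchar(ref) - 1 + (W_max - 1)]` are scanned.
A ref-side hit is **lost** when it overlaps the edited span and no alt-side
hit of the same motif and strand overlaps the alt-side edited span;
**gained** is the converse. Correspondence by overlap (rather than exact
coordinates) is what makes the operation well-defined for indels, whose
coordinate systems differ between alleles, and makes ref/alt swap exactly
exchange gained and lost — a property the tests check on random variants.
A consequence worth knowing: several overlapping placements of one motif
destroyed together are reported as several lost sites, which matches how
multi-site losses at a single deletion are usually described.

The splice assessment is deliberately a simple surrogate, not a
reimplementation of dedicated splice-prediction tools: a variant is only
assessed if its span intersects a donor window (last 3 exonic + first 6
intronic nt) or acceptor window (last 14 intronic + 1 exonic nt), and the
verdict is `possible_effect` only when the window's consensus-PWM score
changes by more than `splice_delta_threshold` (2 bits by default — roughly
the penalty for degrading one well-conserved consensus position). Deep
intronic variants therefore always return `no_predicted_effect`, which is
the expected verdict class for them. The bundled donor/acceptor matrices are
synthetic canonical-consensus frequencies.

## What the synthetic study emulates — and what it does not

`simulate_study()` builds the entire input bundle from one seed. The default
configuration is the package's reference study: one 200-kb chromosome, 30
three-exon genes, 12 regulatory regions each targeting a flanking gene, 40
shared variants, 30 private variants per line with the allocation
5 low-quality + 5 low-depth + 3 clustered pairs (gap drawn from 1..10 nt)
+ 14 passing per line, 3 planted motif disruptions and 1 motif creation in
line A, seed 7. Quality and depth draws straddle the thresholds
(`[20, 100]` / `[101, 500]` and `[1, 10]` / `[11, 60]`) so both filter
branches are always exercised, and one planted variant per line pins each
boundary value exactly. Indels are 1–4 nt with a correct VCF anchor base.
Non-clustered variants are kept > 30 nt apart so only the intended pairs
trip the spacing filter, and the stage truths stay independent.

The background sequence is i.i.d. uniform ACGT. The built-in demonstration
motifs (Ets-like, Sox-like, RREB-like) have four high-information core
positions (97:1:1:1) and weak flanks, which gives them two properties the
generator relies on: a window is a hit iff its four core bases match
exactly, and a single core SNP moves the best relative score from 1.0 to
about 0.77, across the 0.80 threshold. Core 4-mers are chosen so that no
motif's core (or its reverse complement) occurs inside another motif's
consensus or near-miss word; residual chance hits in the background are
removed by re-rolling the affected region, bounded, with a named
configuration error on failure. Planted truths are verified independently in
the tests by brute-force rescanning of the emitted FASTA.

The gene sets and expression table are constructed around the planted line-A
variants, including the negative controls that make recovery a real test: a
variant-bearing gene in no set, a set member with expression below
threshold, set members with no variants, and an intergenic-only gene.

What the simulation does **not** emulate: realistic chromosome structure and
GC content, linkage between variants, genotype uncertainty, mapping
artifacts, overlapping genes, alternative isoform usage, and real motif
databases. Exact recovery on simulated data therefore demonstrates that the
pipeline's logic implements its contracts — not that the thresholds are
optimal for any particular real dataset.

## Numerical and degenerate-input choices

* All internal coordinates are 1-based inclusive; BED's 0-based half-open
  convention is converted exactly once at the format boundary.
* Normalization is idempotent; variant tables are kept sorted by
  `(chrom, pos, ref, alt)` and duplicate keys are integrity errors (or
  counted drops at VCF load).
* Ties in nearest-gene assignment and host-gene choice break by gene start,
  then gene id; classification is invariant to input file order.
* Empty inputs flow through: empty variant sets filter to empty sets, an
  annotation-free genome classifies everything intergenic, genes without
  introns return `no_predicted_effect`, and sequences shorter than a motif
  scan to an empty hit list.
* Report JSON is written with fixed 6-significant-digit formatting for
  diffability; two runs with identical inputs produce byte-identical data
  outputs (the run report additionally records wall time).

## Problem sizes used by the test suite

The suite validates the filters against quadratic brute-force oracles on
randomized sets up to 500 variants, motif scanning against per-offset
rescoring on ~100 random sequence/matrix pairs, classification and
nearest-gene assignment against per-base membership scans on ~100 random
layouts, allele-swap symmetry on 50+ random variants, and full end-to-end
exact recovery on the reference study and a smaller 135-kb variant of it.
These sizes were chosen to exercise every code path many times while keeping
a full run around a minute on one CPU.

## Known limitations

* The TFBS delta is a local, motif-by-motif screen; it does not model
  cooperative binding, chromatin context, or motif families sharing cores.
* The splice surrogate only inspects canonical donor/acceptor windows;
  branch points, exonic enhancers/silencers and deep intronic elements are
  out of scope.
* Transcript-consequence prediction (synonymous/missense, frameshift) is
  deliberately not performed; CDS variants are flagged as coding and left to
  dedicated tools.
* Exclusivity is evidence of line specificity, not of causality; the
  candidate table is a prioritization, and reproducing any specific
  published gene list requires the corresponding real genomes and database
  snapshots.
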