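# substrainr

Inbred mouse substrains separated for only a few decades can differ in
phenotype because each line fixes its own private mutations. When two
substrains sharing one reference genome diverge in a trait — for example, in
the efficiency of antibody class-switch recombination (CSR) in B cells — a
practical way to find candidate causal loci is to whole-genome sequence both
lines, call variants against the common reference, and ask which
high-confidence variants are **exclusive to one line**, which genes they
touch, and what they might do to gene regulation.

`substrainr` implements that comparison as a tested, reusable, tidyverse-style
pipeline:

1. **Exclusivity filtering.** Starting from two per-line VCFs, keep variants
   with call quality `QUAL > 100`, alt-allele depth `> 10` reads, more than
   10 nt from any same-line neighbour (both members of a close pair are
   suspect and removed), and absent — by full `(chrom, pos, ref, alt)` allele
   key — from the other line's call set. The result is a per-line list of
   line-specific SNPs and INDELs with a stage-by-stage count report.
2. **Gene assignment.** Each exclusive variant gets exactly one region class
   with priority **CDS > nCDS > RR > intergenic** (coding sequence;
   non-coding genic, i.e. UTR/intron/non-coding exon; regulatory region;
   intergenic), and a gene: the host gene for genic variants, the nearest
   gene within 100 kb otherwise.
3. **Candidate triage.** Genes with at least one exclusive variant are
   intersected with user-supplied gene sets (GMT; pathway and ontology lists)
   and an expression table, keeping genes expressed above a threshold in
   designated cell populations (e.g. follicular and germinal-centre B cells).
4. **Effect prediction.** For regulatory-region and intergenic candidate
   variants, both alleles of the local sequence are scanned with
   position-weight matrices (JASPAR or TRANSFAC text) and binding sites
   **gained or lost** by the alternate allele are reported. A site's score is
   the summed log2 odds `sum_i log2(p(b_i, i) / q(b_i))`, thresholded on the
   relative score `(raw - min) / (max - min) >= 0.8`, both strands. Intronic
   variants get a splice-window assessment (donor −3..+6, acceptor −14..+1,
   consensus-PWM score delta); UTR variants are flagged by location.

Because real substrain genomes, pathway databases and expression atlases are
large external resources, the package also ships a **synthetic-study
generator**: a deterministic simulator that emits a toy genome, annotation,
regulatory regions, gene sets, expression table and paired VCFs in which
every variant's filter fate, region class, gene, motif effect and candidate
status is planted and recorded in a ground-truth ledger — so the whole
pipeline can be validated for exact recovery.

## Worked example

```r
library(substrainr)
library(dplyr)

sim   <- simulate_study(sim_config(seed = 7))   # reference study conditions
dir   <- file.path(tempdir(), "demo")
paths <- write_sim(sim, dir)

cfg <- pipeline_config(
  vcf_a = paths[["vcf_a"]], vcf_b = paths[["vcf_b"]],
  genome = paths[["genome"]], gff3 = paths[["gff3"]], bed = paths[["bed"]],
  gmt = paths[["gmt"]], expression = paths[["expression"]],
  motifs = paths[["motifs"]], out_dir = file.path(dir, "out"))
run <- run_pipeline(cfg, quiet = TRUE)

run$filter$report
#> <csr_filter_report>
#>   thresholds: qual > 100, alt_depth > 10, gap > 10 nt (drop-all, exclusivity vs raw)
#> # A tibble: 6 x 4
#>   line  stage          n_in n_out
#> 1 A     exclusivity      70    30
#> 2 B     exclusivity      70    30
#> 3 A     quality_depth    30    20
#> 4 B     quality_depth    30    20
#> 5 A     spacing          20    14
#> 6 B     spacing          20    14
#>   exclusive set composition:
#>   line    snp indel total
#> 1 A         9     5    14
#> 2 B        11     3    14
```

Each line starts with 70 calls (40 shared + 30 private); exclusivity keeps
the 30 private ones, the quality/depth filter drops 10 (low score or low alt
depth), and the spacing filter drops the 6 clustered calls, leaving 14
line-exclusive variants per line, split into SNPs and INDELs as in the
two-line summary a substrain comparison reports.

```r
run$candidates
#> <csr_candidates> 10 candidate gene(s)
#> # A tibble: 10 x 7
#>   gene_id  n_variants gene_sets    max_expression passes_expression region_classes
#> 1 SGENE002          1 csr_pathway             838 TRUE              RR
#> 2 SGENE003          1 csr_ontology            768 TRUE              nCDS
#> 3 SGENE004          2 csr_pathway             527 TRUE              RR
#> ...

run$effects$tfbs |> count(tf_name, status)
#> # A tibble: 4 x 3
#>   tf_name   status     n
#> 1 Ets-like  gained     1
#> 2 Ets-like  lost       1
#> 3 RREB-like lost       1
#> 4 Sox-like  lost       1
```

Ten genes carry exclusive variants, belong to a CSR-linked gene set and are
expressed in the designated B-cell populations. Of their regulatory-region
variants, three destroy a planted binding site (reported as `lost`) and one
completes a near-miss site (`gained`) — the same call structure used to
reason about, say, a deletion removing Sox-4 sites from a phosphatase
regulatory region or an insertion creating one near a kinase gene.

Scoring the run against the generator's ledger confirms exact recovery:

```r
glance(truth_report(sim$truth, run))
#> # A tibble: 1 x 4
#>   n_stages min_sensitivity min_specificity exact_recovery
#> 1        8               1               1 TRUE
```

`autoplot()` methods exist for the filter report, the candidate table, the
effect report and the truth report; `tidy()`/`glance()` give tibble views.
A thin command-line wrapper (`inst/scripts/substrain-delta`) exposes
`simulate` and `run-all` for shell use.

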