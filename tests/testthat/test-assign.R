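toy_genes <- function() {
  tibble::tibble(
    gene_id = c("GA", "GB"), name = c("GA", "GB"), chrom = "chr1",
    strand = c("+", "-"),
    span_start = c(1000L, 5000L), span_end = c(2000L, 6000L),
    biotype = "protein_coding",
    exons = list(tibble::tibble(start = c(1000L, 1600L),
                                end = c(1200L, 2000L)),
                 tibble::tibble(start = c(5000L, 5600L),
                                end = c(5200L, 6000L))),
    cds = list(tibble::tibble(start = c(1100L, 1600L),
                              end = c(1200L, 1900L)),
               tibble::tibble(start = c(5100L, 5600L),
                              end = c(5200L, 5900L)))
  )
}

mk_v <- function(pos, ref = "A", alt = "G") {
  tibble::tibble(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
                 qual = 200, alt_depth = 20,
                 vclass = variant_class(ref, alt), line = "A")
}

test_that("classification follows the CDS > nCDS > RR > intergenic priority", {
  genes <- toy_genes()
  regions <- tibble::tibble(chrom = "chr1", start = 1150L, end = 3000L,
                            target_gene_id = NA_character_,
                            source_label = "t")
  # inside CDS and inside a listed regulatory region: CDS wins
  got <- classify_variants(mk_v(1150), genes, regions)
  expect_equal(got$region_class, "CDS")
  expect_equal(got$sub_context, "exonic_CDS")
  expect_equal(got$gene_id, "GA")
  # intron between exon1 and exon2
  intr <- classify_variants(mk_v(1400), genes, regions)
  expect_equal(intr$region_class, "nCDS")
  expect_equal(intr$sub_context, "intronic")
  # outside every gene span but inside the region: RR
  rr <- classify_variants(mk_v(2500), genes, regions)
  expect_equal(rr$region_class, "RR")
  ig <- classify_variants(mk_v(4000), genes, regions)
  expect_equal(ig$region_class, "intergenic")
})

test_that("UTR sub-contexts are strand-aware", {
  genes <- toy_genes()
  # GA is '+': exon bases left of the CDS are 5' UTR, right would be 3'
  utr5 <- classify_variants(mk_v(1050), genes)
  expect_equal(utr5$sub_context, "UTR5")
  utr3 <- classify_variants(mk_v(1950), genes)
  expect_equal(utr3$sub_context, "UTR3")
  # GB is '-': the same genomic sides flip
  utr3m <- classify_variants(mk_v(5050), genes)
  expect_equal(utr3m$sub_context, "UTR3")
  utr5m <- classify_variants(mk_v(5950), genes)
  expect_equal(utr5m$sub_context, "UTR5")
  # a gene without CDS yields noncoding_exon
  nc <- genes[1, ]
  nc$cds <- list(tibble::tibble(start = integer(0), end = integer(0)))
  expect_equal(classify_variants(mk_v(1050), nc)$sub_context,
               "noncoding_exon")
})

test_that("nearest-gene assignment minimizes distance with stated tie-breaks", {
  genes <- toy_genes()
  near <- assign_nearest_gene(mk_v(2500), genes)   # 500 nt from GA, 2500 from GB
  expect_equal(near$gene_id, "GA")
  expect_equal(near$distance, 500)
  # equidistant: smaller span_start wins
  mid <- assign_nearest_gene(mk_v(3500), genes)    # 1500 from both spans
  expect_equal(mid$gene_id, "GA")
  # beyond the cap: unassigned
  far <- assign_nearest_gene(mk_v(2500), genes, max_distance = 100)
  expect_true(is.na(far$gene_id))
})

test_that("classification and nearest gene match brute-force oracles", {
  set.seed(61)
  for (k in 1:40) {
    lay <- rand_layout(n_genes = sample(2:4, 1), n_regions = sample(0:3, 1))
    for (j in 1:6) {
      ref_len <- sample(1:3, 1)
      v <- mk_v(sample.int(4000 - 5, 1), ref = rand_seq(ref_len),
                alt = rand_seq(1))
      if (v$ref == v$alt) next
      got <- classify_variants(v, lay$genes, lay$regions)
      expect_equal(got$region_class, oracle_classify(v, lay$genes,
                                                     lay$regions))
      near <- assign_nearest_gene(v, lay$genes, max_distance = 800)
      want <- oracle_nearest(v, lay$genes, cap = 800)
      expect_equal(near$gene_id, want$gene)
      expect_equal(near$distance, want$d)
    }
  }
})

test_that("classification is invariant to annotation order and strand flips", {
  set.seed(77)
  lay <- rand_layout(n_genes = 4, n_regions = 3)
  vs <- dplyr::bind_rows(lapply(sample.int(3900, 25), mk_v))
  base <- annotate_variants(vs, lay$genes, lay$regions, max_distance = 1500)
  shuf <- annotate_variants(vs, lay$genes[sample(nrow(lay$genes)), ],
                            lay$regions[sample(nrow(lay$regions)), ],
                            max_distance = 1500)
  expect_equal(as.data.frame(base), as.data.frame(shuf))
  flipped <- lay$genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  flip <- annotate_variants(vs, flipped, lay$regions, max_distance = 1500)
  expect_equal(flip$region_class, base$region_class)
  expect_equal(flip$gene_id, base$gene_id)
  expect_equal(flip$distance, base$distance)
})

test_that("degenerate annotations behave as documented", {
  no_genes <- toy_genes()[0, ]
  ann <- annotate_variants(dplyr::bind_rows(mk_v(10), mk_v(500)), no_genes)
  expect_true(all(ann$region_class == "intergenic"))
  expect_true(all(is.na(ann$gene_id)))

  expect_equal(nrow(annotate_variants(mk_v(10)[0, ], toy_genes())), 0L)

  expect_error(
    classify_variants(mk_v(10), toy_genes(), known_chroms = "chrX"),
    class = "substrainr_integrity_error")
})

test_that("annotation tables survive the TSV round trip", {
  lay <- rand_layout(n_genes = 3, n_regions = 2)
  ann <- annotate_variants(dplyr::bind_rows(mk_v(150), mk_v(2000)),
                           lay$genes, lay$regions)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(ann[names(back)]),
               ignore_attr = TRUE)
})
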