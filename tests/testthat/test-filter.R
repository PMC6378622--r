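test_that("quality/depth filter applies the strict > 100 and > 10 rules", {
  vs <- variant_tbl("chr1", c(100, 200, 300, 400), "A", "G",
                    qual = c(100, 101, 500, 101),
                    alt_depth = c(50, 11, 10, 10), line = "A")
  kept <- filter_quality_depth(vs, filter_thresholds())
  expect_equal(kept$pos, 200L)           # only qual 101 & depth 11 survives
  expect_equal(nrow(filter_quality_depth(vs[0, ], filter_thresholds())), 0L)
})

test_that("spacing filter removes both members of close pairs", {
  two <- variant_tbl("chr1", c(100, 110), c("A", "C"), c("G", "T"),
                     qual = 200, alt_depth = 20, line = "A")
  expect_equal(nrow(filter_spacing(two)), 0L)  # gap 10 <= 10: both removed

  three <- variant_tbl("chr1", c(100, 111, 200), c("A", "C", "G"),
                       c("G", "T", "A"), qual = 200, alt_depth = 20,
                       line = "A")
  expect_equal(nrow(filter_spacing(three)), 3L)  # min gap 11: all kept

  one <- three[2, ]
  expect_identical(filter_spacing(one), one)

  # keep-first greedy mode retains the left member
  expect_equal(filter_spacing(two, mode = "keep-first")$pos, 100L)

  unsorted <- two[2:1, ]
  expect_error(filter_spacing(unsorted), class = "substrainr_integrity_error")
})

test_that("spacing filter equals the all-pairs definition on random sets", {
  set.seed(91)
  for (k in 1:30) {
    vs <- rand_variant_set(sample(2:120, 1), max_pos = 600)
    gap <- sample(c(1, 5, 10, 25), 1)
    got <- filter_spacing(vs, filter_thresholds(min_gap = gap))
    want <- oracle_spacing(vs, gap)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("exclusivity calling is allele-aware set difference", {
  a <- variant_tbl("chr1", c(10, 50, 90), c("A", "C", "G"), c("G", "T", "A"),
                   qual = 200, alt_depth = 20, line = "A")
  b <- variant_tbl("chr1", c(50, 90), c("C", "G"), c("T", "C"),
                   qual = 200, alt_depth = 20, line = "B")
  ex <- call_exclusive(a, b)
  expect_equal(ex$a$pos, c(10L, 90L))   # pos 90 differs by allele (A vs C)
  expect_equal(ex$b$pos, 90L)

  # position-only matching collapses the allele distinction
  ex_pos <- call_exclusive(a, b, by = "position")
  expect_equal(ex_pos$a$pos, 10L)

  same <- call_exclusive(a, dplyr::mutate(a, line = "B"))
  expect_equal(nrow(same$a), 0L)
  expect_equal(nrow(same$b), 0L)

  expect_error(call_exclusive(a, a), class = "substrainr_usage_error")
})

test_that("exclusivity equals brute-force key difference on random sets", {
  set.seed(17)
  for (k in 1:25) {
    a <- rand_variant_set(sample(5:80, 1), line = "A", max_pos = 300)
    b <- rand_variant_set(sample(5:80, 1), line = "B", max_pos = 300)
    got <- call_exclusive(a, b)
    want <- oracle_exclusive(a, b)
    expect_equal(as.data.frame(got$a), as.data.frame(want$a))
    expect_equal(as.data.frame(got$b), as.data.frame(want$b))
    expect_length(intersect(variant_key(got$a), variant_key(got$b)), 0)
  }
})

test_that("filters are idempotent subsets and quality filter is monotone", {
  set.seed(23)
  vs <- rand_variant_set(80)
  th <- filter_thresholds()
  f1 <- filter_quality_depth(vs, th)
  expect_true(all(variant_key(f1) %in% variant_key(vs)))
  expect_identical(filter_quality_depth(f1, th), f1)
  s1 <- filter_spacing(vs, th)
  expect_identical(filter_spacing(s1, th), s1)

  for (pair in list(c(50, 100), c(100, 200), c(0, 400))) {
    lo <- filter_quality_depth(vs, filter_thresholds(min_qual = pair[1]))
    hi <- filter_quality_depth(vs, filter_thresholds(min_qual = pair[2]))
    expect_true(all(variant_key(hi) %in% variant_key(lo)))
  }
})

test_that("summarize_exclusive splits SNP from INDEL counts", {
  a <- variant_tbl("chr1", c(10, 50, 90, 130, 170),
                   c("A", "C", "G", "T", "C"),
                   c("G", "T", "A", "TAG", "CTT"),
                   qual = 200, alt_depth = 20, line = "A")
  b <- a[0, ]
  counts <- summarize_exclusive(a, b)
  expect_equal(counts$snp, c(3L, 0L))
  expect_equal(counts$indel, c(2L, 0L))
  expect_equal(counts$total, c(5L, 0L))
})

test_that("full filter run produces a telescoping stage report", {
  set.seed(3)
  a <- rand_variant_set(60, line = "A", max_pos = 2000)
  b <- rand_variant_set(60, line = "B", max_pos = 2000)
  res <- filter_exclusive(a, b)
  st <- res$report$stages
  for (ln in c("A", "B")) {
    s <- st[st$line == ln, ]
    expect_equal(s$n_in[-1], s$n_out[-nrow(s)])   # output k = input k+1
    expect_equal(s$n_in - s$n_out, lengths(s$dropped_keys))
  }
  expect_equal(sum(res$report$counts$total), nrow(res$a) + nrow(res$b))
  td <- tidy(res$report)
  expect_true(all(td$n_dropped >= 0))
  expect_s3_class(autoplot(res$report), "ggplot")

  # the two stage orders agree when no close pair straddles the line split
  res2 <- filter_exclusive(a, b, exclusivity_against = "filtered")
  expect_true(all(variant_key(res2$a) %in% variant_key(a)))
})
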