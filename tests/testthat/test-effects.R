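# builds a genome with `word` planted at `at` inside random background that
# contains no hit of any motif in `pwms` overlapping the planted window
plant_word <- function(word, at, len = 400, pwms = builtin_tf_motifs(),
                       thr = 0.8) {
  for (try in 1:100) {
    s <- rand_seq(len)
    substr(s, at, at + nchar(word) - 1) <- word
    pre <- substr(s, 1, at - 1)
    post <- substr(s, at + nchar(word), len)
    clean <- all(vapply(pwms, function(p) {
      h <- scan_motif(s, p, thr)
      W <- pwm_width(p)
      keep <- h$start <= at + nchar(word) - 1 & h$start + W - 1 >= at
      nrow(h[keep, ]) == 0 || word == pwm_consensus(p)
    }, logical(1)))
    if (clean) return(c(chr1 = s))
  }
  stop("could not build a clean planted genome")
}

mk_var <- function(pos, ref, alt, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 qual = 200, alt_depth = 20,
                 vclass = variant_class(ref, alt), line = "A")
}

test_that("a core SNP in a planted consensus is called as exactly one lost site", {
  set.seed(101)
  pwms <- builtin_tf_motifs()
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    g <- plant_word(pwm_consensus(p), at = 200, pwms = pwms)
    core <- substrainr:::pwm_core_position(p)
    pos <- 200 + core$col - 1
    v <- mk_var(pos, core$best, core$worst)
    d <- tfbs_delta(g, v, pwms, 0.8)
    expect_equal(nrow(d), 1L)
    expect_equal(d$motif_id, nm)
    expect_equal(d$status, "lost")
    expect_equal(d$site_start, 200L)
  }
})

test_that("a SNP completing a near-miss word is called as exactly one gained site", {
  set.seed(103)
  pwms <- builtin_tf_motifs()
  p <- pwms$SOXL1
  core <- substrainr:::pwm_core_position(p)
  near_miss <- pwm_consensus(p)
  substr(near_miss, core$col, core$col) <- core$worst
  g <- plant_word(near_miss, at = 150, pwms = pwms)
  v <- mk_var(150 + core$col - 1, core$worst, core$best)
  d <- tfbs_delta(g, v, pwms, 0.8)
  expect_equal(nrow(d), 1L)
  expect_equal(d$status, "gained")
  expect_equal(d$motif_id, "SOXL1")
})

test_that("deltas respect the brute-force two-window rescoring definition", {
  set.seed(107)
  pwms <- builtin_tf_motifs()
  for (k in 1:15) {
    g <- c(chr1 = rand_seq(200))
    pos <- sample(60:140, 1)
    ref <- substr(g[["chr1"]], pos, pos)
    v <- mk_var(pos, ref, sample(setdiff(BASES4, ref), 1))
    d <- tfbs_delta(g, v, pwms, 0.8)
    # reference: rescan full ref and alt chromosomes, compare hits that
    # overlap the edited base
    g_alt <- apply_variant(g, v)
    for (nm in names(pwms)) {
      p <- pwms[[nm]]
      W <- pwm_width(p)
      covers <- function(h) h[h$start <= pos & h$start + W - 1 >= pos, ]
      rh <- covers(oracle_scan(g[["chr1"]], p, 0.8))
      ah <- covers(oracle_scan(g_alt[["chr1"]], p, 0.8))
      want_lost <- rh[!(rh$strand %in% ah$strand), ]
      want_gain <- ah[!(ah$strand %in% rh$strand), ]
      got <- d[d$motif_id == nm, ]
      expect_equal(nrow(got[got$status == "lost", ]), nrow(want_lost))
      expect_equal(nrow(got[got$status == "gained", ]), nrow(want_gain))
    }
  }
})

test_that("tfbs_delta errors on reference mismatch and ignores identity edits", {
  g <- c(chr1 = paste(rep("ACGT", 50), collapse = ""))
  pwms <- builtin_tf_motifs()
  expect_error(tfbs_delta(g, mk_var(1, "T", "G"), pwms),
               class = "substrainr_integrity_error")
  ident <- tibble::tibble(chrom = "chr1", pos = 9L, ref = "A", alt = "A")
  expect_equal(nrow(tfbs_delta(g, ident, pwms)), 0L)
})

test_that("swapping ref and alt swaps gained and lost exactly", {
  set.seed(109)
  pwms <- builtin_tf_motifs()
  n_checked <- 0
  while (n_checked < 50) {
    g <- c(chr1 = rand_seq(300))
    pos <- sample(80:200, 1)
    if (runif(1) < 0.5) {
      ref <- substr(g[["chr1"]], pos, pos)
      alt <- sample(setdiff(BASES4, ref), 1)
    } else if (runif(1) < 0.5) {
      ref <- substr(g[["chr1"]], pos, pos)
      alt <- paste0(ref, rand_seq(sample(1:3, 1)))
      if (alt == ref) next
    } else {
      ref <- substr(g[["chr1"]], pos, pos + sample(1:3, 1))
      alt <- substr(ref, 1, 1)
    }
    v <- mk_var(pos, ref, alt)
    d1 <- tfbs_delta(g, v, pwms, 0.8)
    g2 <- apply_variant(g, v)
    d2 <- tfbs_delta(g2, mk_var(pos, alt, ref), pwms, 0.8)
    swap <- function(d) sort(paste(d$motif_id, d$strand,
                                   ifelse(d$status == "lost", "gained",
                                          "lost")))
    expect_equal(sort(paste(d1$motif_id, d1$strand, d1$status)), swap(d2))
    n_checked <- n_checked + 1
  }
})

test_that("splice assessment flags only variants inside donor/acceptor windows", {
  # one '+' gene: exon 101-200, intron 201-800, exon 801-900
  gene <- tibble::tibble(
    gene_id = "G1", name = "G1", chrom = "chr1", strand = "+",
    span_start = 101L, span_end = 900L, biotype = "protein_coding",
    exons = list(tibble::tibble(start = c(101L, 801L),
                                end = c(200L, 900L))),
    cds = list(tibble::tibble(start = 120L, end = 880L)))
  set.seed(113)
  g <- c(chr1 = rand_seq(1000))
  # canonical GT at the donor so that disrupting it scores a large drop
  substr(g[["chr1"]], 201, 202) <- "GT"

  deep <- splice_assess(g, mk_var(500, substr(g[["chr1"]], 500, 500), "A"),
                        gene)
  if (deep$ref == deep$alt) deep <- splice_assess(
    g, mk_var(500, substr(g[["chr1"]], 500, 500), "C"), gene)
  expect_equal(deep$verdict, "no_predicted_effect")
  expect_false(deep$in_donor_window)

  hit <- splice_assess(g, mk_var(201, "G", "C"), gene)
  expect_true(hit$in_donor_window)
  expect_equal(hit$verdict, "possible_effect")
  expect_lt(hit$donor_delta, 0)

  # window membership on the minus strand matches brute-force extraction
  gene_m <- gene
  gene_m$strand <- "-"
  # '-' donor sits at the intron's right end: last 6 intronic + 3 exonic
  win <- substrainr:::splice_windows(gene_m[1, ])
  don <- win[win$site == "donor", ]
  expect_equal(c(don$start, don$end), c(795L, 803L))
  acc <- win[win$site == "acceptor", ]
  expect_equal(c(acc$start, acc$end), c(200L, 214L))

  # a gene without introns cannot have a splice effect
  single <- gene
  single$exons <- list(tibble::tibble(start = 101L, end = 900L))
  none <- splice_assess(g, mk_var(500, substr(g[["chr1"]], 500, 500), "A"),
                        single)
  expect_equal(none$verdict, "no_predicted_effect")
  expect_false(none$in_donor_window || none$in_acceptor_window)
})

test_that("predict_effects routes candidate variants by region class", {
  sim <- simulate_study(small_sim_config())
  d <- withr::local_tempdir()
  run <- run_sim_pipeline(sim, d)
  eff <- run$effects
  tab <- tabulate_candidates(run$candidates)
  expect_equal(nrow(eff$splice), sum(tab$sub_context == "intronic"))
  expect_equal(nrow(eff$flags),
               sum(tab$sub_context %in% c("UTR5", "UTR3", "exonic_CDS",
                                          "noncoding_exon")))
  utr5 <- eff$flags$note[grepl("5' UTR", eff$flags$note)]
  expect_equal(length(utr5),
               sum(tab$sub_context == "UTR5"))
  td <- tidy(eff)
  expect_true(all(c("effect", "gene_id") %in% names(td)))
  expect_s3_class(autoplot(eff), "ggplot")

  # an empty candidate list yields an empty report
  empty <- predict_effects(run$candidates[0, ], sim$genome, sim$genes,
                           sim$motifs)
  expect_equal(nrow(empty$tfbs), 0L)
  expect_equal(nrow(empty$splice), 0L)
})
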