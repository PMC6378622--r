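test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim(simulate_study(cfg), d1)
  write_sim(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the variant draw
  other <- simulate_study(small_sim_config(seed = 6))
  base <- simulate_study(cfg)
  expect_false(identical(base$variants_a$pos, other$variants_a$pos))
})

test_that("asymmetric private counts leave the other line shared-only", {
  cfg <- sim_config(seed = 2, chrom_length = 80000, n_genes = 12,
                    n_regions = 4, n_shared_variants = 3,
                    n_private_variants = c(5, 0), n_fail_qual = 0,
                    n_fail_depth = 0, n_clustered_pairs = 0,
                    n_motif_disruptions = 0, n_motif_creations = 0)
  sim <- simulate_study(cfg)
  tb <- sim$truth[sim$truth$line == "B", ]
  expect_true(all(tb$exclusivity == "shared"))
  ta <- sim$truth[sim$truth$line == "A", ]
  expect_equal(sum(ta$exclusivity == "private"), 5L)
  # no private key ever appears in the other line's VCF
  expect_length(intersect(
    variant_key(sim$variants_a[!variant_key(sim$variants_a) %in%
                                 variant_key(sim$variants_b), ]),
    variant_key(sim$variants_b)), 0)
})

test_that("planted truth is self-consistent with its own quality values", {
  sim <- simulate_study(small_sim_config())
  t <- sim$truth
  expect_true(all(t$qual[t$fate == "fail_qual"] <= 100))
  expect_true(all(t$alt_depth[t$fate == "fail_depth"] <= 10))
  expect_true(all(t$qual[t$fate %in% c("pass", "fail_spacing")] > 100))
  expect_true(all(t$alt_depth[t$fate %in% c("pass", "fail_spacing")] > 10))
  # boundary values are pinned exactly once per line
  expect_true(all(tapply(t$qual[t$fate == "fail_qual"],
                         t$line[t$fate == "fail_qual"],
                         function(q) any(q == 100))))
  # every emitted variant appears exactly once per line
  expect_false(any(duplicated(paste(t$line, variant_key(t)))))
  # clustered members really are <= 10 nt from a same-line neighbor
  sp <- t[t$fate == "fail_spacing", ]
  for (i in seq_len(nrow(sp))) {
    same <- t[t$line == sp$line[i] & t$chrom == sp$chrom[i] &
                t$pos != sp$pos[i], ]
    expect_true(min(abs(same$pos - sp$pos[i])) <= 10)
  }
})

test_that("planted motif effects are verified by brute-force scanning", {
  sim <- simulate_study(small_sim_config())
  effects <- sim$truth[sim$truth$motif_effect != "none", ]
  expect_equal(sum(grepl("^lost", effects$motif_effect)), 3L)
  expect_equal(sum(grepl("^gained", effects$motif_effect)), 1L)
  for (i in seq_len(nrow(effects))) {
    v <- effects[i, ]
    motif <- sub(".*:", "", v$motif_effect)
    p <- sim$motifs[[motif]]
    W <- pwm_width(p)
    win_lo <- v$pos - W + 1
    win_hi <- v$pos + nchar(v$ref) - 1 + W - 1
    ref_seq <- substr(sim$genome[[v$chrom]], win_lo, win_hi)
    alt_seq <- paste0(substr(ref_seq, 1, v$pos - win_lo), v$alt,
                      substr(ref_seq, v$pos - win_lo + 1 + nchar(v$ref),
                             nchar(ref_seq)))
    ref_hits <- nrow(oracle_scan(ref_seq, p, 0.8))
    alt_hits <- nrow(oracle_scan(alt_seq, p, 0.8))
    if (grepl("^lost", v$motif_effect)) {
      expect_gt(ref_hits, alt_hits)
    } else {
      expect_gt(alt_hits, ref_hits)
    }
  }
})

test_that("truth region classes agree with an independent classification", {
  sim <- simulate_study(small_sim_config())
  pass <- sim$truth[sim$truth$exclusivity == "private" &
                      sim$truth$fate == "pass", ]
  for (i in seq_len(nrow(pass))) {
    v <- pass[i, ]
    expect_equal(oracle_classify(v, sim$genes, sim$regions),
                 v$region_class,
                 label = sprintf("variant %s:%d", v$chrom, v$pos))
  }
})

test_that("infeasible configurations fail with named constraints", {
  expect_error(sim_config(n_private_variants = 4),
               class = "substrainr_usage_error")
  expect_error(
    simulate_study(sim_config(seed = 1, chrom_length = 20000, n_genes = 30,
                              n_shared_variants = 0, n_private_variants = 0,
                              n_clustered_pairs = 0,
                              n_motif_disruptions = 0,
                              n_motif_creations = 0)),
    "fit")
  expect_error(sim_config(n_regions = 2, n_motif_disruptions = 3),
               class = "substrainr_usage_error")
})

test_that("truth_report scores imperfect pipelines as imperfect", {
  sim <- simulate_study(small_sim_config())
  d <- withr::local_tempdir()
  run <- run_sim_pipeline(sim, d)
  tr <- truth_report(sim$truth, run)
  expect_true(attr(tr, "exact_recovery"))

  # lowering the quality threshold to 0 admits fail_qual variants: they
  # surface as false positives at the quality/depth stage
  d2 <- withr::local_tempdir()
  run0 <- run_sim_pipeline(sim, d2, min_qual = 0, min_alt_depth = 0)
  tr0 <- truth_report(sim$truth, run0)
  qd <- tr0[tr0$stage == "quality_depth", ]
  expect_gt(qd$fp, 0)
  expect_lt(qd$specificity, 1)

  # an emptied pipeline scores sensitivity 0
  gutted <- run
  gutted$filter$report$stages$kept_keys <-
    rep(list(character(0)), nrow(gutted$filter$report$stages))
  gutted$candidates <- run$candidates[0, ]
  gutted$effects$tfbs <- run$effects$tfbs[0, ]
  tr_empty <- truth_report(sim$truth, gutted)
  expect_equal(tr_empty$sensitivity[tr_empty$stage == "exclusivity"], 0)
  expect_equal(tr_empty$sensitivity[tr_empty$stage == "candidates"], 0)
  g <- glance(tr)
  expect_true(g$exact_recovery)
  expect_s3_class(autoplot(tr), "ggplot")
})
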