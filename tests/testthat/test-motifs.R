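test_that("JASPAR parsing normalizes counts with the pseudocount formula", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TFA",
               "A [ 10  0  3 ]",
               "C [  0 10  3 ]",
               "G [  0  0  2 ]",
               "T [  0  0  2 ]"), f)
  ms <- read_motifs(f, "jaspar", pseudocount = 0.01)
  p <- ms[["MA0001.1"]]
  expect_equal(pwm_width(p), 3L)
  expect_equal(unname(colSums(p$prob)), rep(1, 3), tolerance = 1e-9)
  # a zero count becomes (0 + eps) / (N + 4 eps)
  expect_equal(unname(p$prob["C", 1]), 0.01 / 10.04)
  expect_equal(unname(p$prob["A", 1]), 10.01 / 10.04)
  expect_equal(p$tf_name, "TFA")
})

test_that("TRANSFAC and JASPAR dialects yield identical matrices", {
  counts <- matrix(c(8, 1, 1, 0,
                     0, 9, 1, 0,
                     2, 2, 3, 3,
                     0, 0, 0, 10), nrow = 4, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  ref <- pwm(counts, "M1", "M1")
  fj <- withr::local_tempfile(fileext = ".jaspar")
  ft <- withr::local_tempfile(fileext = ".txt")
  write_motifs_jaspar(list(ref), fj)
  write_motifs_transfac(list(ref), ft)
  from_j <- read_motifs(fj, "jaspar")[["M1"]]
  from_t <- read_motifs(ft, "transfac")[["M1"]]
  expect_equal(from_j$prob, from_t$prob)
  expect_equal(from_j$prob, ref$prob)

  expect_error(read_motifs(fj, "meme"), class = "substrainr_usage_error")
  writeLines(c("AC M2", "P0 A C G T", "01 0 0 0 0", "//"), ft)
  expect_error(read_motifs(ft, "transfac"),
               class = "substrainr_format_error")
})

test_that("consensus attains the maximum score and relative scores stay in [0,1]", {
  set.seed(9)
  for (k in 1:20) {
    p <- rand_pwm()
    rng <- pwm_score_range(p)
    expect_equal(pwm_score(p, pwm_consensus(p)), unname(rng["max"]))
    anti <- paste(c("A", "C", "G", "T")[apply(p$prob, 2, which.min)],
                  collapse = "")
    expect_equal(pwm_score(p, anti), unname(rng["min"]))
    hits <- scan_motif(rand_seq(60), p, threshold_rel = 0)
    expect_true(all(hits$rel_score >= 0 & hits$rel_score <= 1))
  }
})

test_that("a degenerate width-1 motif hits every matching base", {
  m <- matrix(c(100, 0, 0, 0), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(m, "W1")
  hits <- scan_motif("AAA", p, threshold_rel = 0.99)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 1:3)
  # reverse strand scores the complement (T column), far below threshold
  expect_equal(nrow(hits[hits$strand == "-", ]), 0L)
  # too-short sequence: empty, not an error
  expect_equal(nrow(scan_motif("AC", pwm(cbind(m, m, m), "W3"), 0.5)), 0L)
})

test_that("scanning equals brute-force rescoring and is strand-symmetric", {
  set.seed(29)
  for (k in 1:25) {
    p <- rand_pwm()
    s <- rand_seq(sample(25:60, 1))
    thr <- sample(c(0, 0.5, 0.8), 1)
    got <- scan_motif(s, p, thr)
    want <- oracle_scan(s, p, thr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)

    # scanning the reverse complement mirrors coordinates and swaps strands
    rc_hits <- scan_motif(rc_str(s), p, thr)
    W <- pwm_width(p)
    L <- nchar(s)
    mirrored <- tibble::tibble(
      start = L - got$start - W + 2L,
      strand = ifelse(got$strand == "+", "-", "+"),
      score = got$score)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(rc_hits$start, mirrored$start)
    expect_equal(rc_hits$strand, mirrored$strand)
    expect_equal(rc_hits$score, mirrored$score, tolerance = 1e-12)
  }
})

test_that("hit sets shrink monotonically as the scan threshold rises", {
  set.seed(33)
  p <- rand_pwm(6)
  s <- rand_seq(300)
  thresholds <- c(0, 0.3, 0.6, 0.8, 0.95)
  hit_keys <- lapply(thresholds, function(t) {
    h <- scan_motif(s, p, t)
    paste(h$start, h$strand)
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(hit_keys[[i]] %in% hit_keys[[i - 1]]))
  }
  # raising the threshold above every score empties the hit set
  expect_equal(nrow(scan_motif(s, p, 1 + 1e-9)), 0L)
})

test_that("N bases contribute the background-expected log-odds", {
  m <- matrix(c(97, 1, 1, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(cbind(m, m), "NN")
  # under a uniform background the q-weighted mean probability is 0.25,
  # so an N scores exactly 0 at that position
  expect_equal(pwm_score(p, "AN"),
               unname(log2(p$prob["A", 1] / 0.25)), tolerance = 1e-12)
  expect_equal(pwm_score(p, "NN"), 0, tolerance = 1e-12)
})
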