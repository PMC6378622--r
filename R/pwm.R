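#' Position weight matrices
#'
#' A `pwm` is a per-position base-probability model of a transcription-factor
#' binding motif. Counts (or probabilities) are regularized with a pseudocount
#' added to every cell and renormalized so each column sums to 1. Scanning
#' scores a window as the summed log2 odds against the background, and maps
#' raw scores to a relative score in \[0, 1\] between the matrix's attainable
#' minimum and maximum.
#'
#' @param mat 4 x W numeric matrix of counts or probabilities; rows A, C, G, T
#'   (rownames optional but must be ACGT order or named).
#' @param motif_id Motif identifier.
#' @param tf_name Transcription factor name (defaults to `motif_id`).
#' @param background Named base probabilities (default uniform).
#' @param pseudocount Pseudocount added per cell before renormalization.
#' @return An object of class `pwm`.
#' @examples
#' m <- pwm(matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4,
#'          dimnames = list(c("A", "C", "G", "T"), NULL)), "M1")
#' pwm_consensus(m)
#' @export
pwm <- function(mat, motif_id, tf_name = motif_id,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort_format("PWM matrix must have 4 rows (A, C, G, T)")
  if (is.null(rownames(mat))) rownames(mat) <- BASES
  mat <- mat[BASES, , drop = FALSE]
  if (ncol(mat) < 1) abort_format("PWM must have width >= 1")
  if (any(mat < 0) || any(!is.finite(mat))) {
    abort_format("PWM entries must be finite and non-negative")
  }
  cs <- colSums(mat)
  if (any(cs == 0)) abort_format("PWM column with zero total count")
  prob <- sweep(mat + pseudocount, 2, cs + 4 * pseudocount, "/")
  background <- background[BASES] / sum(background)
  structure(
    list(motif_id = motif_id, tf_name = tf_name, prob = prob,
         background = background, pseudocount = pseudocount, counts = mat),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), width %d, consensus %s\n",
              x$motif_id, x$tf_name, pwm_width(x), pwm_consensus(x)))
  invisible(x)
}

#' PWM width
#' @param p A `pwm`.
#' @return Integer motif width.
#' @export
pwm_width <- function(p) ncol(p$prob)

# log2-odds matrix and the expected contribution used for N bases
pwm_logodds <- function(p) {
  lo <- log2(p$prob / p$background)
  n_contrib <- log2(colSums(p$background * p$prob) /
                      sum(p$background * p$background))
  list(lo = lo, n = n_contrib)
}

#' Consensus word and score extremes
#'
#' The consensus (per-position argmax base) attains the maximum raw score; the
#' anti-consensus attains the minimum. Relative scores are
#' `(raw - min) / (max - min)`.
#'
#' @param p A `pwm`.
#' @return `pwm_consensus()`: consensus string. `pwm_score_range()`: named
#'   numeric `c(min, max)` of attainable raw log2-odds scores.
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$prob, 2, which.max)], collapse = "")
}

#' @rdname pwm_consensus
#' @export
pwm_score_range <- function(p) {
  lo <- pwm_logodds(p)$lo
  c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
}

#' Score fixed-width windows against a PWM
#'
#' @param p A `pwm`.
#' @param words Character vector of sequences of exactly the motif width
#'   (ACGT or N; N contributes its background-expected log-odds).
#' @return Numeric raw log2-odds scores.
#' @export
pwm_score <- function(p, words) {
  W <- pwm_width(p)
  if (any(nchar(words) != W)) abort_usage("words must have the motif width")
  sc <- pwm_logodds(p)
  vapply(words, function(w) {
    b <- match(strsplit(w, "", fixed = TRUE)[[1]], BASES)
    sum(ifelse(is.na(b), sc$n, sc$lo[cbind(b, seq_len(W))]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a sequence for motif hits
#'
#' Scores every offset of `seq` on both strands (reverse strand = reverse
#' complement of the window) and reports hits whose relative score is at least
#' `threshold_rel`. Hit `start` is the 1-based leftmost base of the matched
#' window on the forward sequence regardless of strand.
#'
#' @param seq A single sequence string (ACGT/N).
#' @param p A `pwm`.
#' @param threshold_rel Relative score threshold in \[0, 1\].
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Tibble: `motif_id`, `tf_name`, `start`, `strand`, `score`,
#'   `rel_score`, ordered by `start` then strand. Sequences shorter than the
#'   motif yield an empty tibble.
#' @export
scan_motif <- function(seq, p, threshold_rel = 0.8, both_strands = TRUE) {
  W <- pwm_width(p)
  L <- nchar(seq)
  empty <- tibble(motif_id = character(0), tf_name = character(0),
                  start = integer(0), strand = character(0),
                  score = numeric(0), rel_score = numeric(0))
  if (L < W) return(empty)
  rng <- pwm_score_range(p)
  sc <- pwm_logodds(p)

  score_strand <- function(s) {
    codes <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
    n_off <- nchar(s) - W + 1L
    idx <- outer(seq_len(n_off), 0:(W - 1), "+")
    cm <- matrix(codes[idx], nrow = n_off)
    contrib <- matrix(0, nrow = n_off, ncol = W)
    for (j in seq_len(W)) {
      cj <- cm[, j]
      contrib[, j] <- ifelse(is.na(cj), sc$n[j], sc$lo[cbind(cj, j)])
    }
    rowSums(contrib)
  }

  fwd <- score_strand(seq)
  res <- tibble(start = seq_along(fwd), strand = "+", score = fwd)
  if (both_strands) {
    rev_scores <- score_strand(reverse_complement(seq))
    # offset s' on the reverse complement maps to forward start L - s' - W + 2
    res <- bind_rows(res, tibble(
      start = L - seq_along(rev_scores) - W + 2L, strand = "-",
      score = rev_scores
    ))
  }
  res$rel_score <- (res$score - rng["min"]) / (rng["max"] - rng["min"])
  res <- res[res$rel_score >= threshold_rel, , drop = FALSE]
  out <- tibble(motif_id = p$motif_id, tf_name = p$tf_name,
                start = as.integer(res$start), strand = res$strand,
                score = res$score, rel_score = res$rel_score)
  arrange(out, .data$start, .data$strand)
}

#' Scan a sequence with a collection of motifs
#'
#' @param seq Sequence string.
#' @param pwms List of `pwm` objects.
#' @inheritParams scan_motif
#' @return Row-bound [scan_motif()] results.
#' @export
scan_motifs <- function(seq, pwms, threshold_rel = 0.8, both_strands = TRUE) {
  list_rbind(map(pwms, scan_motif, seq = seq, threshold_rel = threshold_rel,
                 both_strands = both_strands))
}

#' Read motif matrices (JASPAR or TRANSFAC dialect)
#'
#' JASPAR: `>ID NAME` header followed by four `A|C|G|T [ counts... ]` rows.
#' TRANSFAC: blocks with `AC` (accession), `ID`/`DE` (name), a `P0` column
#' header and numbered count rows, terminated by `//`.
#'
#' @param path Motif text file.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of `pwm` objects (names = motif ids).
#' @export
read_motifs <- function(path, dialect = c("jaspar", "transfac"),
                        pseudocount = 0.01,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort_usage(
                        paste0("unknown motif dialect: ", dialect[1])))
  lines <- readLines(path)
  if (dialect == "jaspar") {
    parse_jaspar(lines, pseudocount, background)
  } else {
    parse_transfac(lines, pseudocount, background)
  }
}

parse_jaspar <- function(lines, pseudocount, background) {
  lines <- lines[nzchar(str_trim(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0) abort_format("no JASPAR headers ('>') found")
  out <- list()
  for (h in seq_along(hdr)) {
    i <- hdr[h]
    stop_at <- if (h < length(hdr)) hdr[h + 1] - 1 else length(lines)
    block <- lines[(i + 1):stop_at]
    if (length(block) < 4) abort_format("JASPAR block with fewer than 4 rows")
    toks <- strsplit(str_trim(sub("^>", "", lines[i])), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- map(block[1:4], function(l) {
      base <- str_trim(substr(str_trim(l), 1, 1))
      nums <- regmatches(l, gregexpr("[0-9.]+(?:[eE][+-]?[0-9]+)?", l))[[1]]
      list(base = base, counts = as.numeric(nums))
    })
    bases <- map_chr(rows, "base")
    if (!setequal(bases, BASES)) {
      abort_format(paste0("JASPAR block for ", motif_id,
                          " must have A, C, G, T rows"))
    }
    wlen <- unique(lengths(map(rows, "counts")))
    if (length(wlen) != 1) {
      abort_format(paste0("ragged JASPAR matrix for ", motif_id))
    }
    mat <- do.call(rbind, map(rows, "counts"))
    rownames(mat) <- bases
    out[[motif_id]] <- pwm(mat[BASES, , drop = FALSE], motif_id, tf_name,
                           background, pseudocount)
  }
  out
}

parse_transfac <- function(lines, pseudocount, background) {
  out <- list()
  motif_id <- NULL
  tf_name <- NULL
  col_order <- NULL
  counts <- list()
  flush <- function() {
    if (is.null(motif_id)) return()
    if (length(counts) == 0) {
      abort_format(paste0("TRANSFAC block ", motif_id, " has no count rows"))
    }
    mat <- t(do.call(rbind, counts))
    rownames(mat) <- col_order
    out[[motif_id]] <<- pwm(mat[BASES, , drop = FALSE], motif_id,
                            tf_name %||% motif_id, background, pseudocount)
    motif_id <<- NULL; tf_name <<- NULL; col_order <<- NULL; counts <<- list()
  }
  for (l in lines) {
    l <- str_trim(l)
    if (!nzchar(l) || l == "XX") next
    if (l == "//") { flush(); next }
    tag <- substr(l, 1, 2)
    rest <- str_trim(substr(l, 3, nchar(l)))
    if (tag == "AC") {
      motif_id <- strsplit(rest, "\\s+")[[1]][1]
    } else if (tag %in% c("ID", "DE") && is.null(tf_name)) {
      tf_name <- strsplit(rest, "\\s+")[[1]][1]
    } else if (tag == "P0" || tag == "PO") {
      col_order <- toupper(strsplit(rest, "\\s+")[[1]][1:4])
    } else if (grepl("^[0-9]{2}$", tag)) {
      vals <- strsplit(rest, "\\s+")[[1]]
      counts[[length(counts) + 1]] <- as.numeric(vals[1:4])
      if (is.null(col_order)) col_order <- BASES
    }
  }
  flush()
  if (length(out) == 0) abort_format("no TRANSFAC blocks parsed")
  out
}

#' Write motifs in JASPAR text format
#'
#' Writes the stored count matrices (probabilities times 100 when a motif was
#' built directly from probabilities).
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs_jaspar <- function(pwms, path) {
  lines <- unlist(map(pwms, function(p) {
    m <- p$counts
    c(sprintf(">%s %s", p$motif_id, p$tf_name),
      sprintf("%s [ %s ]", BASES,
              vapply(BASES, function(b) paste(sprintf("%g", m[b, ]),
                                              collapse = " "), character(1))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write motifs in TRANSFAC flat text format
#'
#' @inheritParams write_motifs_jaspar
#' @export
write_motifs_transfac <- function(pwms, path) {
  lines <- unlist(map(pwms, function(p) {
    m <- p$counts
    c(sprintf("AC %s", p$motif_id), "XX", sprintf("ID %s", p$tf_name), "XX",
      "P0 A C G T",
      sprintf("%02d %g %g %g %g", seq_len(ncol(m)),
              m["A", ], m["C", ], m["G", ], m["T", ]),
      "XX", "//")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in demonstration TF motifs
#'
#' Three synthetic motifs (an ETS-like, a SOX-like and an RREB-like matrix)
#' designed with four high-information core positions and weak flanking
#' positions, so that a single-base change at a core position moves the best
#' hit across the default 0.80 relative-score threshold. Used as the default
#' motif set of the synthetic-study generator.
#'
#' @param pseudocount Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
builtin_tf_motifs <- function(pseudocount = 0.01) {
  core <- function(b) {
    v <- c(A = 1, C = 1, G = 1, T = 1)
    v[b] <- 97
    v
  }
  weak <- function(b) {
    v <- c(A = 22, C = 22, G = 22, T = 22)
    v[b] <- 34
    v
  }
  build <- function(spec, id, name) {
    mat <- vapply(seq_along(spec$bases), function(i) {
      if (spec$is_core[i]) core(spec$bases[i]) else weak(spec$bases[i])
    }, numeric(4))
    rownames(mat) <- BASES
    pwm(mat, id, name, pseudocount = pseudocount)
  }
  list(
    ETSL1 = build(list(bases = c("A", "C", "G", "G", "A", "A", "G", "T"),
                       is_core = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                                   FALSE, FALSE)), "ETSL1", "Ets-like"),
    SOXL1 = build(list(bases = c("A", "A", "C", "A", "A", "T", "G", "G"),
                       is_core = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                                   FALSE, FALSE)), "SOXL1", "Sox-like"),
    # core 4-mers (and their reverse complements) are chosen so that no
    # motif's core occurs inside another motif's consensus or near-miss
    # word on either strand; a hit requires an exact core match, so planted
    # instances can be created/destroyed by one core SNP without
    # deterministic cross-motif artifacts
    RREBL1 = build(list(bases = c("G", "T", "C", "T", "G", "A", "T", "C", "C"),
                        is_core = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                                    FALSE, FALSE, FALSE)), "RREBL1",
                   "RREB-like")
  )
}
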