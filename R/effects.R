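#' TFBS gain/loss prediction for one variant
#'
#' Substitutes the alternate allele into the local reference sequence and
#' compares motif hits between the two alleles. The scan window spans
#' `[pos - (Wmax - 1), pos + nchar(ref) - 1 + (Wmax - 1)]` (clipped to the
#' chromosome), with `Wmax` the widest motif, so every placement that can
#' touch the edited bases is scored on both alleles.
#'
#' A ref-side hit is **lost** when its interval overlaps the edited span and
#' no alt-side hit of the same motif and strand overlaps the alt edited span;
#' **gained** is the converse. Comparing against the edited span (rather than
#' exact coordinates) makes the correspondence robust to the coordinate
#' shifts indels introduce, and makes the operation exactly symmetric under
#' swapping ref/alt. Hits not touching the edited span are identical on both
#' sides and are ignored.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param v One-row variant tibble (normalized).
#' @param pwms List of `pwm` objects.
#' @param threshold_rel Relative score threshold for a hit (default 0.8).
#' @return Tibble with one row per gained/lost site: `chrom`, `pos`, `ref`,
#'   `alt`, `motif_id`, `tf_name`, `status` (`"gained"`/`"lost"`), `strand`,
#'   `site_start` (genomic, allele-side coordinates), `score`, `rel_score`.
#' @export
tfbs_delta <- function(genome, v, pwms, threshold_rel = 0.8) {
  stopifnot(nrow(v) == 1)
  chrom_seq <- genome[[v$chrom]]
  if (is.null(chrom_seq)) {
    abort_integrity(paste0("chromosome not in genome: ", v$chrom))
  }
  ref_len <- nchar(v$ref)
  ref_at <- subseq_chr(chrom_seq, v$pos, v$pos + ref_len - 1L)
  if (!identical(ref_at, v$ref)) {
    abort_integrity(sprintf(
      "reference mismatch at %s:%d — genome has '%s', variant ref is '%s'",
      v$chrom, v$pos, ref_at, v$ref))
  }
  if (identical(v$ref, v$alt)) {
    return(empty_delta_tbl())
  }
  wmax <- max(map_int(pwms, pwm_width))
  wstart <- max(1L, v$pos - (wmax - 1L))
  wend <- min(nchar(chrom_seq), v$pos + ref_len - 1L + (wmax - 1L))
  ref_win <- subseq_chr(chrom_seq, wstart, wend)
  e1 <- v$pos - wstart + 1L                  # edited span, window coords
  e2_ref <- e1 + ref_len - 1L
  e2_alt <- e1 + nchar(v$alt) - 1L
  alt_win <- paste0(substr(ref_win, 1, e1 - 1L), v$alt,
                    substr(ref_win, e2_ref + 1L, nchar(ref_win)))

  deltas <- map(pwms, function(p) {
    W <- pwm_width(p)
    rh <- scan_motif(ref_win, p, threshold_rel)
    ah <- scan_motif(alt_win, p, threshold_rel)
    rh <- rh[overlaps(rh$start, rh$start + W - 1L, e1, e2_ref), , drop = FALSE]
    ah <- ah[overlaps(ah$start, ah$start + W - 1L, e1, e2_alt), , drop = FALSE]
    lost <- rh[!rh$strand %in% ah$strand, , drop = FALSE]
    gained <- ah[!ah$strand %in% rh$strand, , drop = FALSE]
    bind_rows(
      if (nrow(lost) > 0) mutate(lost, status = "lost"),
      if (nrow(gained) > 0) mutate(gained, status = "gained")
    )
  })
  deltas <- bind_rows(deltas)
  if (nrow(deltas) == 0) return(empty_delta_tbl())
  tibble(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    motif_id = deltas$motif_id, tf_name = deltas$tf_name,
    status = deltas$status, strand = deltas$strand,
    site_start = wstart + deltas$start - 1L,
    score = deltas$score, rel_score = deltas$rel_score
  ) |>
    arrange(.data$motif_id, .data$status, .data$strand, .data$site_start)
}

empty_delta_tbl <- function() {
  tibble(chrom = character(0), pos = integer(0), ref = character(0),
         alt = character(0), motif_id = character(0), tf_name = character(0),
         status = character(0), strand = character(0),
         site_start = integer(0), score = double(0), rel_score = double(0))
}

#' Built-in splice-site scoring matrices
#'
#' Synthetic consensus-frequency matrices for the splice donor (9 nt: last 3
#' exonic + first 6 intronic bases, dominated by the invariant GT) and
#' acceptor (15 nt: last 14 intronic bases — polypyrimidine tract plus the
#' invariant AG — and the first exonic base). These are simple surrogates for
#' dedicated splice-prediction tools, intended only for the window-delta
#' assessment of [splice_assess()].
#'
#' @return Named list with `donor` and `acceptor` `pwm` objects.
#' @export
builtin_splice_motifs <- function() {
  donor <- rbind(
    A = c(33, 61, 10, 1, 1, 50, 71, 6, 15),
    C = c(37, 13, 3, 1, 1, 3, 8, 9, 17),
    G = c(18, 12, 80, 97, 1, 45, 12, 81, 19),
    T = c(12, 14, 7, 1, 97, 2, 9, 4, 49)
  )
  pyr <- c(A = 10, C = 30, G = 10, T = 50)
  acc <- vapply(1:12, function(i) pyr, numeric(4))
  acc <- cbind(acc, c(A = 97, C = 1, G = 1, T = 1),
               c(A = 1, C = 1, G = 97, T = 1),
               c(A = 25, C = 15, G = 50, T = 10))
  rownames(acc) <- BASES
  list(donor = pwm(donor, "DONOR", "splice_donor"),
       acceptor = pwm(acc, "ACCEPTOR", "splice_acceptor"))
}

# strand-aware donor/acceptor windows of one gene, from its merged exons.
# Returns tibble: site ("donor"/"acceptor"), start, end (genomic, 1-based).
splice_windows <- function(gene, donor_exonic = 3L, donor_intronic = 6L,
                           acceptor_intronic = 14L, acceptor_exonic = 1L) {
  ex <- gene$exons[[1]]
  if (nrow(ex) < 2) {
    return(tibble(site = character(0), start = integer(0), end = integer(0)))
  }
  ex <- ex[order(ex$start), ]
  istart <- ex$end[-nrow(ex)] + 1L   # intron genomic bounds
  iend <- ex$start[-1] - 1L
  if (gene$strand == "+") {
    bind_rows(
      tibble(site = "donor", start = istart - donor_exonic,
             end = istart + donor_intronic - 1L),
      tibble(site = "acceptor", start = iend - acceptor_intronic + 1L,
             end = iend + acceptor_exonic)
    )
  } else {
    bind_rows(
      tibble(site = "donor", start = iend - donor_intronic + 1L,
             end = iend + donor_exonic),
      tibble(site = "acceptor", start = istart - acceptor_exonic,
             end = istart + acceptor_intronic - 1L)
    )
  }
}

#' Splice-window assessment of an intronic variant
#'
#' Tests whether the variant's affected span intersects a donor window (last
#' 3 exonic + first 6 intronic nt of an intron, strand-aware) or an acceptor
#' window (last 14 intronic + first exonic nt). If it does, the window is
#' rescored on the alternate allele and the verdict is `"possible_effect"`
#' when `|alt score - ref score| > delta_threshold` (log2-odds units);
#' otherwise — including any variant outside all windows and genes without
#' introns — the verdict is `"no_predicted_effect"`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param v One-row variant tibble, intronic for `gene`.
#' @param gene One-row gene tibble.
#' @param splice_pwms List with `donor` and `acceptor` `pwm` objects
#'   (default [builtin_splice_motifs()]).
#' @param delta_threshold Score-change threshold in log2-odds units
#'   (default 2).
#' @return One-row tibble: variant key columns, `in_donor_window`,
#'   `in_acceptor_window`, `donor_delta`, `acceptor_delta`, `verdict`.
#' @export
splice_assess <- function(genome, v, gene,
                          splice_pwms = builtin_splice_motifs(),
                          delta_threshold = 2) {
  stopifnot(nrow(v) == 1, nrow(gene) == 1)
  wins <- splice_windows(gene)
  ve <- v$pos + nchar(v$ref) - 1L
  res <- tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                gene_id = gene$gene_id,
                in_donor_window = FALSE, in_acceptor_window = FALSE,
                donor_delta = NA_real_, acceptor_delta = NA_real_,
                verdict = "no_predicted_effect")
  if (nrow(wins) == 0) return(res)
  hit <- wins[overlaps(v$pos, ve, wins$start, wins$end), , drop = FALSE]
  if (nrow(hit) == 0) return(res)
  chrom_seq <- genome[[v$chrom]]
  for (k in seq_len(nrow(hit))) {
    p <- splice_pwms[[hit$site[k]]]
    delta <- splice_window_delta(chrom_seq, v, hit$start[k], hit$end[k],
                                 gene$strand, p)
    if (hit$site[k] == "donor") {
      res$in_donor_window <- TRUE
      res$donor_delta <- delta
    } else {
      res$in_acceptor_window <- TRUE
      res$acceptor_delta <- delta
    }
    if (is.finite(delta) && abs(delta) > delta_threshold) {
      res$verdict <- "possible_effect"
    }
  }
  res
}

# alt-minus-ref PWM score of a splice window; the window is anchored at its
# reference coordinates, and bases shifted in by an indel fill the window.
splice_window_delta <- function(chrom_seq, v, wstart, wend, strand, p) {
  W <- pwm_width(p)
  ref_word <- subseq_chr(chrom_seq, wstart, wend)
  # apply the edit to a local copy extending past the window for indels
  pad <- abs(nchar(v$alt) - nchar(v$ref)) + 1L
  lend <- min(nchar(chrom_seq), wend + pad)
  local <- subseq_chr(chrom_seq, wstart, lend)
  off <- v$pos - wstart + 1L
  alt_local <- paste0(substr(local, 1, off - 1L), v$alt,
                      substr(local, off + nchar(v$ref), nchar(local)))
  alt_word <- substr(alt_local, 1, W)
  if (nchar(alt_word) < W || nchar(ref_word) < W) return(NA_real_)
  if (strand == "-") {
    ref_word <- reverse_complement(ref_word)
    alt_word <- reverse_complement(alt_word)
  }
  pwm_score(p, alt_word) - pwm_score(p, ref_word)
}

#' Predict regulatory effects for triaged candidates
#'
#' Routes each candidate variant by region class: regulatory-region and
#' intergenic variants are screened for TFBS gain/loss ([tfbs_delta()]);
#' intronic variants get a splice-window assessment ([splice_assess()]);
#' 5'/3' UTR variants are flagged as possible regulatory effects by location;
#' coding and non-coding-exon variants are noted as outside the scope of
#' regulatory prediction.
#'
#' @param candidates A `csr_candidates` object.
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene tibble (for splice windows).
#' @param pwms List of TF `pwm` objects.
#' @param splice_pwms Donor/acceptor matrices (default
#'   [builtin_splice_motifs()]).
#' @param threshold_rel Motif scan threshold.
#' @param splice_delta_threshold Splice score-change threshold.
#' @return Object of class `csr_effects`: list of tibbles `tfbs`, `splice`,
#'   `flags`.
#' @export
predict_effects <- function(candidates, genome, genes, pwms,
                            splice_pwms = builtin_splice_motifs(),
                            threshold_rel = 0.8,
                            splice_delta_threshold = 2) {
  tab <- tabulate_candidates(candidates)
  tfbs <- list()
  splice <- list()
  flags <- list()
  for (i in seq_len(nrow(tab))) {
    v <- tab[i, ]
    if (v$region_class %in% c("RR", "intergenic")) {
      tfbs[[length(tfbs) + 1]] <-
        mutate(tfbs_delta(genome, v, pwms, threshold_rel),
               gene_id = v$gene_id)
    } else if (v$sub_context == "intronic") {
      g <- genes[genes$gene_id == v$gene_id, ]
      splice[[length(splice) + 1]] <-
        splice_assess(genome, v, g, splice_pwms, splice_delta_threshold)
    } else if (v$sub_context %in% c("UTR5", "UTR3")) {
      side <- if (v$sub_context == "UTR5") "5' UTR" else "3' UTR"
      flags[[length(flags) + 1]] <- tibble(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = v$gene_id,
        note = paste0("located in ", side, " - possible regulatory effect"))
    } else {
      flags[[length(flags) + 1]] <- tibble(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = v$gene_id,
        note = if (v$region_class == "CDS") {
          "coding - out of scope for regulatory prediction"
        } else {
          "non-coding exon - no regulatory prediction"
        })
    }
  }
  structure(list(
    tfbs = if (length(tfbs)) bind_rows(tfbs) else
      mutate(empty_delta_tbl(), gene_id = character(0)),
    splice = bind_rows(splice),
    flags = bind_rows(flags)
  ), class = "csr_effects")
}

#' @export
print.csr_effects <- function(x, ...) {
  cat(sprintf("<csr_effects> %d TFBS delta(s), %d splice assessment(s), %d flag(s)\n",
              nrow(x$tfbs), nrow(x$splice), nrow(x$flags)))
  invisible(x)
}

#' Tidy an effect report
#'
#' One row per predicted effect across the three effect families, with a
#' common `effect` column (`"tfbs_gained"`, `"tfbs_lost"`,
#' `"splice_possible_effect"`, `"splice_no_predicted_effect"`, or the
#' location-flag note).
#'
#' @param x A `csr_effects` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.csr_effects <- function(x, ...) {
  bind_rows(
    if (nrow(x$tfbs) > 0) {
      transmute(x$tfbs, .data$chrom, .data$pos, .data$ref, .data$alt,
                .data$gene_id, family = "tfbs",
                effect = paste0("tfbs_", .data$status),
                detail = paste0(.data$motif_id, "/", .data$strand))
    },
    if (nrow(x$splice) > 0) {
      transmute(x$splice, .data$chrom, .data$pos, .data$ref, .data$alt,
                .data$gene_id, family = "splice",
                effect = paste0("splice_", .data$verdict),
                detail = sprintf("donor=%s acceptor=%s",
                                 .data$in_donor_window,
                                 .data$in_acceptor_window))
    },
    if (nrow(x$flags) > 0) {
      transmute(x$flags, .data$chrom, .data$pos, .data$ref, .data$alt,
                .data$gene_id, family = "flag", effect = .data$note,
                detail = NA_character_)
    }
  )
}

#' Plot TFBS gain/loss predictions
#'
#' @param object A `csr_effects` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csr_effects <- function(object, ...) {
  d <- object$tfbs
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No TFBS gains or losses predicted") +
             ggplot2::theme_minimal())
  }
  d$variant <- paste0(d$gene_id, "\n", d$chrom, ":", d$pos)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant, fill = .data$status)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::facet_wrap(~motif_id) +
    ggplot2::labs(x = NULL, y = "binding sites", fill = NULL,
                  title = "Predicted TFBS gains and losses") +
    ggplot2::theme_minimal()
}
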