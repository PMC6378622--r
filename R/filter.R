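#' Filtering thresholds
#'
#' The three thresholds of the variant filter, all applied as strict
#' inequalities exactly as stated (keep `qual > 100`, `alt_depth > 10`, and
#' only variants more than 10 nt from any same-line neighbor).
#'
#' @param min_qual Keep variants with `qual` strictly greater (default 100).
#' @param min_alt_depth Keep variants with `alt_depth` strictly greater
#'   (default 10).
#' @param min_gap Keep variants whose distance to every same-chromosome
#'   neighbor is strictly greater (default 10 nt).
#' @return A list of class `csr_thresholds`.
#' @export
filter_thresholds <- function(min_qual = 100, min_alt_depth = 10,
                              min_gap = 10) {
  if (min_qual < 0 || min_alt_depth < 0 || min_gap < 0) {
    abort_usage("thresholds must be non-negative")
  }
  structure(list(min_qual = min_qual, min_alt_depth = as.integer(min_alt_depth),
                 min_gap = as.integer(min_gap)), class = "csr_thresholds")
}

#' Quality and alt-allele-depth filter
#'
#' Keeps exactly the variants with `qual > min_qual` and
#' `alt_depth > min_alt_depth`; boundary values (qual exactly at the
#' threshold, depth exactly at the threshold) are excluded. Order preserved.
#'
#' @param vs Variant tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return Filtered variant tibble (possibly empty).
#' @export
filter_quality_depth <- function(vs, thresholds = filter_thresholds()) {
  vs[vs$qual > thresholds$min_qual &
       vs$alt_depth > thresholds$min_alt_depth, , drop = FALSE]
}

#' Inter-variant spacing filter
#'
#' Removes variants that lie too close to another variant of the same line on
#' the same chromosome, where distance is the absolute difference of anchor
#' positions. In `"drop-all"` mode (default) every variant with some neighbor
#' at distance `<= min_gap` is removed — both members of a close pair go,
#' matching the all-pairs definition and avoiding order dependence. In
#' `"keep-first"` mode a greedy left-to-right sweep keeps a variant if it is
#' more than `min_gap` from the last kept one.
#'
#' @param vs Sorted variant tibble (unsorted input is an integrity error).
#' @param thresholds A [filter_thresholds()] object.
#' @param mode `"drop-all"` or `"keep-first"`.
#' @return Filtered variant tibble.
#' @export
filter_spacing <- function(vs, thresholds = filter_thresholds(),
                           mode = c("drop-all", "keep-first")) {
  mode <- match.arg(mode)
  assert_sorted_variants(vs)
  if (nrow(vs) < 2) return(vs)
  keep <- logical(nrow(vs))
  for (ch in unique(vs$chrom)) {
    idx <- which(vs$chrom == ch)
    pos <- vs$pos[idx]
    if (mode == "drop-all") {
      # sorted order: the nearest neighbor of each variant is adjacent
      gap_prev <- c(Inf, diff(pos))
      gap_next <- c(diff(pos), Inf)
      keep[idx] <- pmin(gap_prev, gap_next) > thresholds$min_gap
    } else {
      last_kept <- -Inf
      for (j in seq_along(idx)) {
        if (pos[j] - last_kept > thresholds$min_gap) {
          keep[idx[j]] <- TRUE
          last_kept <- pos[j]
        }
      }
    }
  }
  vs[keep, , drop = FALSE]
}

#' Line-exclusivity calling
#'
#' Splits two lines' variant sets into the variants exclusive to each line:
#' a variant is exclusive when its full `(chrom, pos, ref, alt)` allele key is
#' absent from the other line's set. With `by = "position"` the comparison
#' uses `(chrom, pos)` only.
#'
#' @param vs_a,vs_b Normalized variant tibbles from two different lines.
#' @param by `"key"` (allele-aware, default) or `"position"`.
#' @return List with elements `a` and `b`: the exclusive subsets, input order
#'   preserved.
#' @export
call_exclusive <- function(vs_a, vs_b, by = c("key", "position")) {
  by <- match.arg(by)
  if (nrow(vs_a) > 0 && nrow(vs_b) > 0 &&
      vs_a$line[1] == vs_b$line[1]) {
    abort_usage("both variant sets carry the same line label")
  }
  keyfun <- if (by == "key") variant_key else function(x) {
    paste(x$chrom, x$pos, sep = ":")
  }
  list(
    a = vs_a[!(keyfun(vs_a) %in% keyfun(vs_b)), , drop = FALSE],
    b = vs_b[!(keyfun(vs_b) %in% keyfun(vs_a)), , drop = FALSE]
  )
}

#' Run the full exclusivity filter
#'
#' Chains the stages that reduce two raw per-line call sets to line-exclusive,
#' quality-filtered, well-spaced variant lists:
#' exclusivity (against the other line's raw set by default) →
#' quality/depth → spacing. With `exclusivity_against = "filtered"` the
#' quality/depth and spacing filters run first and exclusivity is evaluated
#' against the other line's filtered set.
#'
#' @param vs_a,vs_b Normalized variant tibbles (two lines).
#' @param thresholds A [filter_thresholds()] object.
#' @param exclusivity_against `"raw"` (default) or `"filtered"`.
#' @param spacing_mode Passed to [filter_spacing()].
#' @param by Passed to [call_exclusive()].
#' @return Object of class `csr_filter_result`: list with `a`, `b` (final
#'   exclusive variant tibbles) and `report` (a `csr_filter_report`).
#' @export
filter_exclusive <- function(vs_a, vs_b, thresholds = filter_thresholds(),
                             exclusivity_against = c("raw", "filtered"),
                             spacing_mode = c("drop-all", "keep-first"),
                             by = c("key", "position")) {
  exclusivity_against <- match.arg(exclusivity_against)
  spacing_mode <- match.arg(spacing_mode)
  by <- match.arg(by)

  stages <- list()
  note_stage <- function(line, stage, before, after) {
    stages[[length(stages) + 1]] <<- tibble(
      line = line, stage = stage, n_in = nrow(before), n_out = nrow(after),
      kept_keys = list(variant_key(after)),
      dropped_keys = list(setdiff(variant_key(before), variant_key(after)))
    )
  }

  if (exclusivity_against == "raw") {
    ex <- call_exclusive(vs_a, vs_b, by = by)
    note_stage("A", "exclusivity", vs_a, ex$a)
    note_stage("B", "exclusivity", vs_b, ex$b)
    qa <- filter_quality_depth(ex$a, thresholds)
    qb <- filter_quality_depth(ex$b, thresholds)
    note_stage("A", "quality_depth", ex$a, qa)
    note_stage("B", "quality_depth", ex$b, qb)
    sa <- filter_spacing(qa, thresholds, mode = spacing_mode)
    sb <- filter_spacing(qb, thresholds, mode = spacing_mode)
    note_stage("A", "spacing", qa, sa)
    note_stage("B", "spacing", qb, sb)
  } else {
    qa <- filter_quality_depth(vs_a, thresholds)
    qb <- filter_quality_depth(vs_b, thresholds)
    note_stage("A", "quality_depth", vs_a, qa)
    note_stage("B", "quality_depth", vs_b, qb)
    fa <- filter_spacing(qa, thresholds, mode = spacing_mode)
    fb <- filter_spacing(qb, thresholds, mode = spacing_mode)
    note_stage("A", "spacing", qa, fa)
    note_stage("B", "spacing", qb, fb)
    ex <- call_exclusive(fa, fb, by = by)
    note_stage("A", "exclusivity", fa, ex$a)
    note_stage("B", "exclusivity", fb, ex$b)
    sa <- ex$a
    sb <- ex$b
  }

  report <- new_filter_report(bind_rows(stages), sa, sb,
                              thresholds, exclusivity_against, spacing_mode)
  structure(list(a = sa, b = sb, report = report),
            class = "csr_filter_result")
}

new_filter_report <- function(stages, excl_a, excl_b, thresholds,
                              exclusivity_against, spacing_mode) {
  structure(list(
    stages = stages,
    counts = summarize_exclusive(excl_a, excl_b),
    thresholds = thresholds,
    exclusivity_against = exclusivity_against,
    spacing_mode = spacing_mode
  ), class = "csr_filter_report")
}

#' Per-line SNP and INDEL counts of exclusive sets
#'
#' SNPs are variants with single-base ref and alt; everything else (insertion,
#' deletion, multi-base substitution) is counted as INDEL, matching the
#' two-way summary of line-specific polymorphism counts.
#'
#' @param excl_a,excl_b Final exclusive variant tibbles.
#' @return Tibble: `line`, `snp`, `indel`, `total`.
#' @export
summarize_exclusive <- function(excl_a, excl_b) {
  one <- function(x, fallback) {
    tibble(
      line = if (nrow(x) > 0) x$line[1] else fallback,
      snp = sum(x$vclass == "SNP"),
      indel = sum(x$vclass != "SNP"),
      total = nrow(x)
    )
  }
  bind_rows(one(excl_a, "A"), one(excl_b, "B"))
}

#' @export
print.csr_filter_report <- function(x, ...) {
  cat("<csr_filter_report>\n")
  cat(sprintf("  thresholds: qual > %g, alt_depth > %d, gap > %d nt (%s, exclusivity vs %s)\n",
              x$thresholds$min_qual, x$thresholds$min_alt_depth,
              x$thresholds$min_gap, x$spacing_mode, x$exclusivity_against))
  print(select(x$stages, "line", "stage", "n_in", "n_out"))
  cat("  exclusive set composition:\n")
  print(x$counts)
  invisible(x)
}

#' @rdname tidy.csr_filter_report
#' @export
glance.csr_filter_report <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "line",
                     values_from = c("snp", "indel", "total"))
}

#' Tidy a filter report
#'
#' `tidy()` returns the stage telescope (one row per line and stage with
#' input/output counts); `glance()` returns the per-line SNP/INDEL totals in
#' one row.
#'
#' @param x A `csr_filter_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.csr_filter_report <- function(x, ...) {
  mutate(select(x$stages, "line", "stage", "n_in", "n_out"),
         n_dropped = .data$n_in - .data$n_out)
}

#' Plot a filter report
#'
#' Bar chart of variants surviving each filter stage, per line.
#'
#' @param object A `csr_filter_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csr_filter_report <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = unique(d$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_out,
                                  fill = .data$line)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "filter stage", y = "variants kept",
                  title = "Line-exclusive variant filtering") +
    ggplot2::theme_minimal()
}
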