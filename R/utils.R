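# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Error classes mirror the pipeline's exit-code conventions:
# usage/config (2), format (3), integrity/reference-mismatch (4).
abort_usage <- function(msg) abort(msg, class = "substrainr_usage_error")
abort_format <- function(msg) abort(msg, class = "substrainr_format_error")
abort_integrity <- function(msg) abort(msg, class = "substrainr_integrity_error")

#' Variant identity key
#'
#' Builds the `(chrom, pos, ref, alt)` identity key used for line-exclusivity
#' comparison and for joining variants to ground truth.
#'
#' @param x A variant tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# uppercase ACGT check
is_dna <- function(x) {
  nzchar(x) & !str_detect(x, "[^ACGT]")
}

# 1-based inclusive interval overlap
overlaps <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

# gap between two 1-based inclusive intervals (0 if they touch/overlap)
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# substring extraction on a plain character chromosome
subseq_chr <- function(seq, start, end) {
  substr(seq, start, end)
}

# fixed formatting for report JSON: 6 significant digits on doubles
signif6 <- function(x) {
  if (is.double(x)) signif(x, 6) else x
}
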