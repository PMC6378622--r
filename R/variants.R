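#' Variant tables
#'
#' Variants are plain tibbles with one row per called difference from the
#' reference, 1-based, minimally represented (no shared leading/trailing bases
#' beyond the single anchor base of an indel). Columns:
#'
#' * `chrom`, `pos` — sequence name and 1-based position of the first ref base
#' * `ref`, `alt` — non-empty uppercase ACGT allele strings, `ref != alt`
#' * `qual` — non-negative variant call quality (the caller's site score)
#' * `alt_depth` — reads supporting the alternate allele
#' * `vclass` — one of `"SNP"`, `"INS"`, `"DEL"`, `"MNP"`, derived from the
#'   allele lengths
#' * `line` — label of the source line
#'
#' `variant_tbl()` validates, normalizes, sorts by `(chrom, pos, ref, alt)` and
#' rejects duplicate keys.
#'
#' @param chrom,pos,ref,alt,qual,alt_depth Vectors of equal length (recycled
#'   length-1 allowed via tibble).
#' @param line Single line label applied to all rows.
#' @return A sorted, normalized variant tibble.
#' @examples
#' variant_tbl("chr1", 101, "A", "G", qual = 150, alt_depth = 12, line = "A")
#' @export
variant_tbl <- function(chrom, pos, ref, alt, qual, alt_depth, line) {
  x <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    qual = as.numeric(qual), alt_depth = as.integer(alt_depth),
    line = as.character(line)
  )
  validate_variants(normalize_variants(x), dedupe = FALSE)
}

#' Variant class from allele lengths
#'
#' @param ref,alt Allele strings.
#' @return `"SNP"` (1/1), `"INS"` (alt longer), `"DEL"` (ref longer) or
#'   `"MNP"` (equal lengths > 1).
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1L & la == 1L ~ "SNP",
    la > lr ~ "INS",
    lr > la ~ "DEL",
    TRUE ~ "MNP"
  )
}

#' Normalize variants to minimal representation
#'
#' Trims bases shared between `ref` and `alt` — first from the right, then
#' from the left (advancing `pos`) — while keeping at least one base in each
#' allele, so indels retain their single VCF anchor base. Idempotent. `vclass`
#' is (re)derived from the trimmed alleles.
#'
#' @param x Variant tibble (`vclass` optional on input).
#' @return The tibble with `pos`, `ref`, `alt`, `vclass` normalized.
#' @export
normalize_variants <- function(x) {
  if (nrow(x) == 0) {
    x$vclass <- character(0)
    return(x)
  }
  trimmed <- pmap(list(x$pos, x$ref, x$alt), function(pos, ref, alt) {
    r <- strsplit(ref, "", fixed = TRUE)[[1]]
    a <- strsplit(alt, "", fixed = TRUE)[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix (keep anchor base)
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    list(pos = as.integer(pos), ref = paste(r, collapse = ""),
         alt = paste(a, collapse = ""))
  })
  x$pos <- map_int(trimmed, "pos")
  x$ref <- map_chr(trimmed, "ref")
  x$alt <- map_chr(trimmed, "alt")
  x$vclass <- variant_class(x$ref, x$alt)
  x
}

# validate + sort + (optionally) drop duplicate keys
validate_variants <- function(x, dedupe = FALSE) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "alt_depth", "vclass", "line")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort_format(paste0("variant table missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(!is_dna(x$ref)) || any(!is_dna(x$alt))) {
      abort_format("ref/alt alleles must be non-empty uppercase ACGT strings")
    }
    if (any(x$ref == x$alt)) abort_format("ref and alt must differ")
    if (any(x$pos < 1L)) abort_format("positions must be >= 1")
    if (any(x$qual < 0) || any(x$alt_depth < 0)) {
      abort_format("qual and alt_depth must be non-negative")
    }
    if (!identical(x$vclass, variant_class(x$ref, x$alt))) {
      abort_format("vclass inconsistent with allele lengths")
    }
  }
  x <- arrange(x, .data$chrom, .data$pos, .data$ref, .data$alt)
  dup <- duplicated(variant_key(x))
  if (any(dup)) {
    if (dedupe) {
      x <- x[!dup, , drop = FALSE]
    } else {
      abort_integrity("duplicate (chrom, pos, ref, alt) keys in variant table")
    }
  }
  x[, need]
}

# sortedness check used by order-sensitive operations
assert_sorted_variants <- function(x) {
  o <- order(x$chrom, x$pos, x$ref, x$alt)
  if (!identical(o, seq_len(nrow(x)))) {
    abort_integrity("variant table is not sorted by (chrom, pos, ref, alt)")
  }
  invisible(x)
}
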