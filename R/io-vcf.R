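#' Read a VCF into a variant tibble
#'
#' Parses a VCF 4.x file with `vcfR`, splits multi-allelic records into one row
#' per alternate allele, recovers the alt-allele depth, normalizes alleles to
#' minimal representation and returns a sorted variant tibble.
#'
#' Alt-allele depth is taken from `FORMAT/AD` of the first sample (field
#' `k + 1` for the k-th alternate allele); if `AD` is absent the record falls
#' back to `INFO/DP4` (alt depth = sum of the last two values, applied to every
#' alt of the record). Records with missing `QUAL`, unrecoverable alt depth, or
#' non-ACGT alleles are dropped and counted in the load report attached as
#' `attr(x, "load_report")`.
#'
#' @param path Path to a VCF file.
#' @param line_label Label recorded in the `line` column.
#' @return A normalized, sorted variant tibble. Attribute `load_report` is a
#'   list of record/drop counts.
#' @export
read_vcf <- function(path, line_label) {
  if (!file.exists(path)) abort_usage(paste0("VCF not found: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort_format(paste0("malformed VCF '", path, "': ", conditionMessage(e)))
    }
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    abort_format(paste0("no parseable records in VCF: ", path))
  }
  gt <- v@gt
  has_sample <- !is.null(gt) && ncol(gt) >= 2

  n_rec <- nrow(fix)
  dropped <- c(missing_qual = 0L, missing_depth = 0L, bad_allele = 0L,
               duplicate_key = 0L)
  rows <- list()
  for (i in seq_len(n_rec)) {
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    alts <- strsplit(fix[i, "ALT"] %||% "", ",", fixed = TRUE)[[1]]
    ref <- toupper(fix[i, "REF"])
    if (is.na(qual)) {
      dropped["missing_qual"] <- dropped["missing_qual"] + length(alts)
      next
    }
    # per-alt depths: AD first, DP4 fallback
    ad <- NULL
    if (has_sample) {
      fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
      j <- match("AD", fmt)
      if (!is.na(j)) {
        fields <- strsplit(gt[i, 2], ":", fixed = TRUE)[[1]]
        if (j <= length(fields)) {
          ad <- suppressWarnings(as.integer(
            strsplit(fields[j], ",", fixed = TRUE)[[1]]
          ))
        }
      }
    }
    dp4_alt <- NA_integer_
    if (is.null(ad)) {
      m <- regmatches(fix[i, "INFO"] %||% "",
                      regexpr("(?:^|;)DP4=([0-9,]+)", fix[i, "INFO"] %||% ""))
      if (length(m) == 1 && nzchar(m)) {
        vals <- as.integer(strsplit(sub(".*DP4=", "", m), ",")[[1]])
        if (length(vals) == 4) dp4_alt <- sum(vals[3:4])
      }
    }
    for (k in seq_along(alts)) {
      alt <- toupper(alts[k])
      if (!is_dna(ref) || !is_dna(alt) || ref == alt) {
        dropped["bad_allele"] <- dropped["bad_allele"] + 1L
        next
      }
      depth <- if (!is.null(ad)) {
        if (length(ad) >= k + 1 && !is.na(ad[k + 1])) ad[k + 1] else NA_integer_
      } else {
        dp4_alt
      }
      if (is.na(depth)) {
        dropped["missing_depth"] <- dropped["missing_depth"] + 1L
        next
      }
      rows[[length(rows) + 1]] <- tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, qual = qual, alt_depth = as.integer(depth),
        line = line_label
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort_format(paste0("no usable records in VCF: ", path))
  }
  out <- normalize_variants(out)
  n_before <- nrow(out)
  out <- validate_variants(out, dedupe = TRUE)
  dropped["duplicate_key"] <- n_before - nrow(out)
  attr(out, "load_report") <- list(
    n_records = n_rec, n_variants = nrow(out), dropped = as.list(dropped)
  )
  out
}

#' Write a variant tibble as VCF 4.2
#'
#' Emits one single-sample record per variant with `QUAL` and `FORMAT/AD`
#' (ref depth is not modelled and is written as 0). Inverse of [read_vcf()]
#' on the internal model.
#'
#' @param x Variant tibble.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contigs = NULL) {
  sample_name <- if (nrow(x) > 0) x$line[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=substrainr",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##INFO=<ID=VCLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (ref,alt)\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  recs <- if (nrow(x) == 0) character(0) else {
    sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tVCLASS=%s\tGT:AD\t1/1:0,%d",
            x$chrom, x$pos, x$ref, x$alt, sprintf("%g", x$qual),
            x$vclass, x$alt_depth)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
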