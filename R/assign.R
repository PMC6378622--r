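#' Classify variants by genomic region
#'
#' Assigns each variant exactly one region class with the fixed priority
#' CDS > nCDS > RR > intergenic: a variant whose affected reference span
#' `[pos, pos + nchar(ref) - 1]` overlaps a coding interval is `CDS`; else if
#' it falls within a gene span it is `nCDS` with the finest sub-context (5'
#' UTR, 3' UTR, intron, or non-coding exon); else if it overlaps a regulatory
#' region it is `RR`; otherwise `intergenic`. Strand affects only the UTR5/
#' UTR3 labels, never the class.
#'
#' @param vs Variant tibble.
#' @param genes Gene tibble as from [read_gff3()].
#' @param regions Region tibble as from [read_bed()] (may be empty).
#' @param known_chroms Optional character vector of valid chromosome names
#'   (e.g. `names(genome)`); a variant on a chromosome outside it is an
#'   annotation-mismatch error. `NULL` disables the check.
#' @return `vs` with columns `region_class`, `sub_context`, `gene_id`
#'   (host gene for CDS/nCDS, `NA` otherwise), `distance` (0 for genic,
#'   `NA` otherwise) appended; input order preserved.
#' @export
classify_variants <- function(vs, genes, regions = NULL,
                              known_chroms = NULL) {
  if (!is.null(known_chroms)) {
    bad <- setdiff(unique(vs$chrom), known_chroms)
    if (length(bad) > 0) {
      abort_integrity(paste0("variant chromosome(s) absent from annotation: ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (is.null(regions)) {
    regions <- tibble(chrom = character(0), start = integer(0),
                      end = integer(0), target_gene_id = character(0),
                      source_label = character(0))
  }
  n <- nrow(vs)
  region_class <- rep("intergenic", n)
  sub_context <- rep("none", n)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    vs1 <- vs$pos[i]
    ve1 <- vs$pos[i] + nchar(vs$ref[i]) - 1L
    gsel <- which(genes$chrom == vs$chrom[i] &
                    genes$span_start <= ve1 & genes$span_end >= vs1)
    if (length(gsel) > 0) {
      # priority among host genes: CDS hit beats nCDS; ties by span_start, id
      cand <- map_dfr(gsel, function(g) {
        cls <- classify_within_gene(genes[g, ], vs1, ve1)
        tibble(g = g, class = cls$class, sub = cls$sub)
      })
      cand$rank <- ifelse(cand$class == "CDS", 1L, 2L)
      cand <- cand[order(cand$rank, genes$span_start[cand$g],
                         genes$gene_id[cand$g]), ]
      pick <- cand[1, ]
      region_class[i] <- pick$class
      sub_context[i] <- pick$sub
      gene_id[i] <- genes$gene_id[pick$g]
      distance[i] <- 0
    } else {
      rsel <- which(regions$chrom == vs$chrom[i] &
                      regions$start <= ve1 & regions$end >= vs1)
      if (length(rsel) > 0) {
        region_class[i] <- "RR"
        sub_context[i] <- "regulatory"
      }
    }
  }
  out <- vs
  out$region_class <- region_class
  out$sub_context <- sub_context
  out$gene_id <- gene_id
  out$distance <- distance
  out
}

# classification of a span already known to be inside a gene span
classify_within_gene <- function(g, vs1, ve1) {
  ex <- g$exons[[1]]
  cd <- g$cds[[1]]
  if (nrow(cd) > 0 && any(overlaps(vs1, ve1, cd$start, cd$end))) {
    return(list(class = "CDS", sub = "exonic_CDS"))
  }
  in_exon <- nrow(ex) > 0 && any(overlaps(vs1, ve1, ex$start, ex$end))
  if (!in_exon) {
    return(list(class = "nCDS", sub = "intronic"))
  }
  if (nrow(cd) == 0) {
    return(list(class = "nCDS", sub = "noncoding_exon"))
  }
  # exonic but non-coding: UTR, sided by position relative to the CDS extent
  cds_lo <- min(cd$start)
  cds_hi <- max(cd$end)
  upstream <- ve1 < cds_lo   # genomically left of the CDS
  if (g$strand == "+") {
    list(class = "nCDS", sub = if (upstream) "UTR5" else "UTR3")
  } else {
    list(class = "nCDS", sub = if (upstream) "UTR3" else "UTR5")
  }
}

#' Nearest-gene assignment
#'
#' For variants outside genes (regulatory or intergenic), finds the gene whose
#' span minimizes the distance to the variant's affected span on the same
#' chromosome (0 when overlapping). Ties are broken by smaller `span_start`,
#' then lexicographic `gene_id`. Genes farther than `max_distance` yield `NA`.
#' Strand is ignored.
#'
#' @param vs Variant tibble.
#' @param genes Gene tibble.
#' @param max_distance Maximum assignment distance in nt (default 100000).
#' @return Tibble with one row per variant: `gene_id` (or `NA`), `distance`.
#' @export
assign_nearest_gene <- function(vs, genes, max_distance = 100000) {
  out_gene <- rep(NA_character_, nrow(vs))
  out_dist <- rep(NA_real_, nrow(vs))
  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(vs))) {
      sel <- which(genes$chrom == vs$chrom[i])
      if (length(sel) == 0) next
      ve <- vs$pos[i] + nchar(vs$ref[i]) - 1L
      d <- interval_gap(vs$pos[i], ve, genes$span_start[sel],
                        genes$span_end[sel])
      o <- order(d, genes$span_start[sel], genes$gene_id[sel])
      best <- o[1]
      if (d[best] <= max_distance) {
        out_gene[i] <- genes$gene_id[sel[best]]
        out_dist[i] <- d[best]
      }
    }
  }
  tibble(gene_id = out_gene, distance = out_dist)
}

#' Annotate a variant set with region class and gene assignment
#'
#' Combines [classify_variants()] and [assign_nearest_gene()]: CDS/nCDS
#' variants carry their host gene at distance 0; RR variants take the
#' region's `target_gene_id` when one is recorded (at its span distance),
#' falling back to the nearest gene; intergenic variants take the nearest
#' gene within `max_distance` (or no gene). Input order is preserved.
#'
#' @inheritParams classify_variants
#' @param max_distance Nearest-gene cap in nt.
#' @return Annotation tibble: variant columns plus `region_class`,
#'   `sub_context`, `gene_id`, `distance`. Attribute `class_counts` holds the
#'   per-class summary.
#' @export
annotate_variants <- function(vs, genes, regions = NULL,
                              max_distance = 100000, known_chroms = NULL) {
  ann <- classify_variants(vs, genes, regions, known_chroms)
  outside <- which(ann$region_class %in% c("RR", "intergenic"))
  if (length(outside) > 0) {
    near <- assign_nearest_gene(ann[outside, ], genes, max_distance)
    ann$gene_id[outside] <- near$gene_id
    ann$distance[outside] <- near$distance
    # explicit region targets override proximity for RR variants
    if (!is.null(regions) && nrow(regions) > 0) {
      for (i in outside[ann$region_class[outside] == "RR"]) {
        ve <- ann$pos[i] + nchar(ann$ref[i]) - 1L
        rsel <- which(regions$chrom == ann$chrom[i] &
                        regions$start <= ve & regions$end >= ann$pos[i] &
                        !is.na(regions$target_gene_id))
        if (length(rsel) > 0) {
          tg <- regions$target_gene_id[rsel[1]]
          gi <- match(tg, genes$gene_id)
          if (!is.na(gi)) {
            ann$gene_id[i] <- tg
            ann$distance[i] <- interval_gap(ann$pos[i], ve,
                                            genes$span_start[gi],
                                            genes$span_end[gi])
          }
        }
      }
    }
  }
  attr(ann, "class_counts") <- count(ann, .data$region_class)
  ann
}

#' Write / read an annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `qual`, `alt_depth`,
#' `vclass`, `line`, `region_class`, `sub_context`, `gene_id`, `distance`.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path` (write) / the tibble (read).
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(ann, path, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    qual = readr::col_double(), alt_depth = readr::col_integer(),
    vclass = readr::col_character(), line = readr::col_character(),
    region_class = readr::col_character(),
    sub_context = readr::col_character(),
    gene_id = readr::col_character(), distance = readr::col_double()
  ), na = "")
}
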