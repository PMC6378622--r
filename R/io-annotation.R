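#' Read a FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences, one per record.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) abort_format(
                   paste0("malformed FASTA '", path, "': ",
                          conditionMessage(e))))
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) abort_format("duplicate sequence names in FASTA")
  setNames(toupper(as.character(ss)), nm)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 with a gene/mRNA/exon/CDS hierarchy (via `rtracklayer`) and
#' collapses it to one gene-level model per gene: exon and CDS intervals are
#' the per-gene union across isoforms (merged with `IRanges::reduce`).
#' Children whose parent cannot be resolved to a gene are skipped with a
#' warning.
#'
#' @param path GFF3 file.
#' @return Tibble with one row per gene: `gene_id`, `name`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `biotype`, and list-columns `exons`, `cds` of
#'   two-column tibbles (`start`, `end`, 1-based inclusive, merged, sorted).
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) abort_format(
                   paste0("malformed GFF3 '", path, "': ",
                          conditionMessage(e))))
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    warn(paste0("empty GFF3: ", path))
    return(empty_gene_tbl())
  }
  if (any(d$width < 1)) abort_format("GFF3 feature with start > end")
  d$type <- as.character(d$type)
  d$Parent1 <- vapply(d$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))

  genes <- d[d$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    warn(paste0("no gene features in GFF3: ", path))
    return(empty_gene_tbl())
  }
  gene_ids <- genes$ID
  bty <- if ("biotype" %in% names(genes)) genes$biotype
         else if ("gene_biotype" %in% names(genes)) genes$gene_biotype
         else NA_character_
  gname <- if ("Name" %in% names(genes)) genes$Name else genes$ID
  gname <- ifelse(is.na(gname), genes$ID, gname)

  # transcript-level features map their children up to a gene
  tx <- d[!d$type %in% c("gene", "exon", "CDS") & d$Parent1 %in% gene_ids, ]
  tx2gene <- setNames(tx$Parent1, tx$ID)

  kids <- d[d$type %in% c("exon", "CDS"), , drop = FALSE]
  kid_gene <- ifelse(kids$Parent1 %in% gene_ids, kids$Parent1,
                     unname(tx2gene[kids$Parent1]))
  orphan <- is.na(kid_gene)
  if (any(orphan)) {
    warn(sprintf("skipping %d exon/CDS feature(s) without a resolvable gene parent",
                 sum(orphan)))
    kids <- kids[!orphan, , drop = FALSE]
    kid_gene <- kid_gene[!orphan]
  }

  merge_tier <- function(gid, tier) {
    sel <- kid_gene == gid & kids$type == tier
    if (!any(sel)) return(tibble(start = integer(0), end = integer(0)))
    ir <- IRanges::reduce(IRanges::IRanges(kids$start[sel], kids$end[sel]))
    tibble(start = IRanges::start(ir), end = IRanges::end(ir))
  }

  out <- tibble(
    gene_id = gene_ids,
    name = as.character(gname),
    chrom = as.character(genes$seqnames),
    strand = ifelse(as.character(genes$strand) == "-", "-", "+"),
    span_start = as.integer(genes$start),
    span_end = as.integer(genes$end),
    biotype = as.character(bty),
    exons = map(gene_ids, merge_tier, tier = "exon"),
    cds = map(gene_ids, merge_tier, tier = "CDS")
  )
  arrange(out, .data$chrom, .data$span_start, .data$gene_id)
}

empty_gene_tbl <- function() {
  tibble(gene_id = character(0), name = character(0), chrom = character(0),
         strand = character(0), span_start = integer(0),
         span_end = integer(0), biotype = character(0),
         exons = list(), cds = list())
}

#' Write gene models to GFF3
#'
#' Emits one gene, one synthetic transcript (`<gene_id>.t1`) and the merged
#' exon/CDS intervals per gene. Inverse of [read_gff3()] on the gene-level
#' model.
#'
#' @param genes Gene tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, s, e, strand, attrs) {
    sprintf("%s\tsubstrainr\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s, e, strand,
            if (type == "CDS") "0" else ".", attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      fmt(g$chrom, "gene", g$span_start, g$span_end, g$strand,
          sprintf("ID=%s;Name=%s;biotype=%s", g$gene_id, g$name, g$biotype)),
      fmt(g$chrom, "mRNA", g$span_start, g$span_end, g$strand,
          sprintf("ID=%s;Parent=%s", tid, g$gene_id))
    )
    ex <- g$exons[[1]]
    if (nrow(ex) > 0) {
      lines <- c(lines, fmt(g$chrom, "exon", ex$start, ex$end, g$strand,
                            sprintf("ID=%s.e%d;Parent=%s", g$gene_id,
                                    seq_len(nrow(ex)), tid)))
    }
    cd <- g$cds[[1]]
    if (nrow(cd) > 0) {
      lines <- c(lines, fmt(g$chrom, "CDS", cd$start, cd$end, g$strand,
                            sprintf("ID=%s.c%d;Parent=%s", g$gene_id,
                                    seq_len(nrow(cd)), tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read regulatory regions from BED
#'
#' BED is 0-based half-open on disk; internally regions are 1-based inclusive,
#' so a printed BED interval of length L becomes an internal interval of width
#' L. The BED `name` field (column 4), when present and not `"."`, is taken as
#' the region's target gene id.
#'
#' @param path BED3/BED6 file.
#' @param source_label Provenance label; defaults to the file name.
#' @return Tibble: `chrom`, `start`, `end` (1-based inclusive),
#'   `target_gene_id` (`NA` if none), `source_label`.
#' @export
read_bed <- function(path, source_label = basename(path)) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) abort_format(
                   paste0("malformed BED '", path, "': ",
                          conditionMessage(e))))
  d <- as.data.frame(gr, stringsAsFactors = FALSE)
  tgt <- if ("name" %in% names(d)) as.character(d$name) else
    rep(NA_character_, nrow(d))
  tgt[!is.na(tgt) & tgt == "."] <- NA_character_
  out <- tibble(
    chrom = as.character(d$seqnames),
    start = as.integer(d$start), end = as.integer(d$end),
    target_gene_id = tgt, source_label = source_label
  )
  if (any(out$start > out$end)) abort_format("BED region with zero/negative width")
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write regulatory regions to BED6
#'
#' @param regions Region tibble (1-based inclusive) as from [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- ifelse(is.na(regions$target_gene_id), ".", regions$target_gene_id)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", regions$chrom,
                     regions$start - 1L, regions$end, nm), path)
  invisible(path)
}

#' Validate region target genes against an annotation
#'
#' @param regions Region tibble.
#' @param genes Gene tibble.
#' @return `regions`, invisibly; errors if a `target_gene_id` is unknown.
#' @export
validate_regions <- function(regions, genes) {
  tg <- regions$target_gene_id[!is.na(regions$target_gene_id)]
  bad <- setdiff(tg, genes$gene_id)
  if (length(bad) > 0) {
    abort_integrity(paste0("region target gene(s) not in annotation: ",
                           paste(unique(bad), collapse = ", ")))
  }
  invisible(regions)
}

#' Read gene sets from GMT
#'
#' Tab-separated lines `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Gene ids are uppercased for matching consistency with the annotation.
#'
#' @param path GMT file.
#' @return Long tibble: `set_name`, `description`, `gene_id` (uppercase).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) abort_format(paste0("empty GMT: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    abort_format(sprintf("GMT line %d has fewer than 3 fields",
                         which(nfield < 3)[1]))
  }
  out <- list_rbind(map(parts, function(p) {
    tibble(set_name = p[1], description = p[2],
           gene_id = toupper(p[-(1:2)]))
  }))
  if (anyDuplicated(out[, c("set_name", "gene_id")])) {
    out <- distinct(out, .data$set_name, .data$description, .data$gene_id)
  }
  out
}

#' Write gene sets to GMT
#'
#' @param gene_sets Long tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  by_set <- gene_sets |>
    group_by(.data$set_name, .data$description) |>
    summarise(genes = paste(.data$gene_id, collapse = "\t"), .groups = "drop")
  writeLines(sprintf("%s\t%s\t%s", by_set$set_name, by_set$description,
                     by_set$genes), path)
  invisible(path)
}

#' Read an expression table
#'
#' TSV with columns `gene_id`, `population`, `value` (non-negative, finite).
#'
#' @param path TSV file.
#' @return Tibble with those three columns.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    population = readr::col_character(),
    value = readr::col_double()
  ))
  if (!all(c("gene_id", "population", "value") %in% names(x))) {
    abort_format("expression table needs columns gene_id, population, value")
  }
  if (any(!is.finite(x$value)) || any(x$value < 0)) {
    abort_format("expression values must be finite and >= 0")
  }
  if (anyDuplicated(x[, c("gene_id", "population")])) {
    abort_format("duplicate (gene_id, population) rows in expression table")
  }
  as_tibble(x[, c("gene_id", "population", "value")])
}

#' Write an expression table
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}
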