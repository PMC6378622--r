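#' Triage annotated variants into candidate genes
#'
#' A gene becomes a candidate when it (1) carries at least one line-exclusive
#' variant annotation, (2) belongs to at least one of the supplied gene sets
#' (pathway or ontology lists), and (3) shows expression above
#' `expr_threshold` in at least one designated population. Genes absent from
#' the expression table fail the expression check (counted, not an error).
#' Genes reached only through nearest-gene assignment of intergenic variants
#' are triaged identically, with the intergenic class retained.
#'
#' @param annotations Annotation tibble from [annotate_variants()].
#' @param gene_sets Long gene-set tibble from [read_gmt()].
#' @param expression Expression tibble from [read_expression()].
#' @param expr_threshold Expression cutoff (a value, not a paper-given
#'   constant; default 120).
#' @param populations Character vector of designated populations (default the
#'   two mature B-cell populations of the bundled simulator,
#'   `c("B.Fo", "B.GC")`).
#' @param no_expression_filter If `TRUE`, condition (3) is skipped.
#' @return Object of class `csr_candidates`: tibble with one row per
#'   candidate gene (`gene_id`, `n_variants`, `gene_sets`, `max_expression`,
#'   `passes_expression`, `region_classes`, nested `variants`), ordered by
#'   `gene_id`. Attribute `triage_report` counts genes dropped at each
#'   condition.
#' @export
triage_candidates <- function(annotations, gene_sets, expression,
                              expr_threshold = 120,
                              populations = c("B.Fo", "B.GC"),
                              no_expression_filter = FALSE) {
  miss_pop <- setdiff(populations, unique(expression$population))
  if (length(miss_pop) > 0) {
    abort_usage(paste0("designated population(s) absent from expression table: ",
                       paste(miss_pop, collapse = ", ")))
  }
  with_gene <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  by_gene <- with_gene |>
    group_by(gene_id_u = toupper(.data$gene_id), gene_id = .data$gene_id) |>
    summarise(
      n_variants = n(),
      region_classes = paste(sort(unique(.data$region_class)), collapse = ","),
      variants = list(pick(everything())),
      .groups = "drop"
    )

  sets <- gene_sets |>
    group_by(gene_id_u = .data$gene_id) |>
    summarise(gene_sets = paste(sort(unique(.data$set_name)), collapse = ","),
              .groups = "drop")
  expr <- expression[expression$population %in% populations, , drop = FALSE]
  emax <- expr |>
    group_by(gene_id_u = toupper(.data$gene_id)) |>
    summarise(max_expression = max(.data$value), .groups = "drop")

  cand <- by_gene |>
    inner_join(sets, by = "gene_id_u") |>
    left_join(emax, by = "gene_id_u")
  n_no_set <- nrow(by_gene) - nrow(cand)
  n_missing_expr <- sum(is.na(cand$max_expression))
  cand$max_expression[is.na(cand$max_expression)] <- 0
  cand$passes_expression <- cand$max_expression > expr_threshold
  n_fail_expr <- sum(!cand$passes_expression)
  if (!no_expression_filter) {
    cand <- cand[cand$passes_expression, , drop = FALSE]
  }
  out <- cand |>
    select("gene_id", "n_variants", "gene_sets", "max_expression",
           "passes_expression", "region_classes", "variants") |>
    arrange(.data$gene_id)
  structure(out, class = c("csr_candidates", class(out)),
            triage_report = list(
              n_genes_with_variants = nrow(by_gene),
              n_dropped_no_set = n_no_set,
              n_missing_from_expression = n_missing_expr,
              n_dropped_expression = if (no_expression_filter) 0L else n_fail_expr
            ))
}

#' Candidate table, one row per (gene, variant)
#'
#' Flattens triaged candidates into the familiar candidate-table layout: gene
#' rows repeated per variant with the variant's region class (CDS, nCDS, RR or
#' intergenic) and sub-context alongside.
#'
#' @param candidates A `csr_candidates` object.
#' @return Tibble with columns `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `vclass`, `region_class`, `sub_context`, `distance`, `gene_sets`,
#'   `max_expression`.
#' @export
tabulate_candidates <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble(gene_id = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  vclass = character(0), region_class = character(0),
                  sub_context = character(0), distance = double(0),
                  gene_sets = character(0), max_expression = double(0)))
  }
  tibble(candidates) |>
    select("gene_id", "gene_sets", "max_expression", "variants") |>
    unnest("variants", names_sep = NULL) |>
    select("gene_id", "chrom", "pos", "ref", "alt", "vclass",
           "region_class", "sub_context", "distance", "gene_sets",
           "max_expression")
}

#' @export
print.csr_candidates <- function(x, ...) {
  cat(sprintf("<csr_candidates> %d candidate gene(s)\n", nrow(x)))
  NextMethod()
}

#' Plot candidate region-class composition
#'
#' Stacked bar of variant region classes per candidate gene.
#'
#' @param object A `csr_candidates` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csr_candidates <- function(object, ...) {
  d <- tabulate_candidates(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id,
                                  fill = .data$region_class)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "exclusive variants",
                  fill = "region class",
                  title = "Candidate genes and their variant classes") +
    ggplot2::theme_minimal()
}
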