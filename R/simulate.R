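#' Configuration of the synthetic paired-genome study
#'
#' Describes a self-contained toy study: a random genome, a gene annotation,
#' regulatory regions, gene sets, an expression table, and two per-line VCFs
#' that share a set of common variants and carry line-private variants whose
#' filter fate, region class, gene assignment, motif effect and candidate
#' status are all planted and recorded in a ground-truth ledger.
#'
#' The defaults define the package's reference study conditions: one 200-kb
#' chromosome, 30 genes, 40 shared plus 30 private variants per line, 6
#' clustered pairs (gap drawn from 1..10 nt), 3 planted motif disruptions and
#' 1 motif creation, seed 7. Quality and alt-depth values are drawn from
#' two-component distributions straddling the filter thresholds (`qual_low`
#' spans up to 100 inclusive, `qual_high` starts at 101; depths likewise
#' around 10) so every filter branch is exercised; one planted variant per
#' line pins each boundary value exactly.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_chroms,chrom_length Number and length (nt) of chromosomes; genes
#'   are placed on the first chromosome.
#' @param n_genes Number of genes.
#' @param gene_length Length range (nt) of a gene span.
#' @param n_regions Number of regulatory regions (each targeting a flanking
#'   gene).
#' @param n_shared_variants Variants planted with identical keys in both
#'   lines.
#' @param n_private_variants Private variants per line; a length-2 vector
#'   gives lines A and B separately.
#' @param fraction_indel Probability that an eligible planted variant is an
#'   indel (1-4 nt, correct VCF anchor base).
#' @param qual_low,qual_high,depth_low,depth_high Integer ranges for the
#'   failing/passing quality and alt-depth draws.
#' @param n_fail_qual,n_fail_depth Planted low-quality / low-depth private
#'   variants per line.
#' @param n_clustered_pairs Total clustered pairs (split between lines),
#'   planted at gaps of 1..10 nt; both members are expected spacing-filter
#'   casualties.
#' @param n_motif_disruptions,n_motif_creations Line-A regulatory-region
#'   variants planted to destroy / create an exact motif instance.
#' @param motifs Named list of `pwm` objects to plant and scan.
#' @param scan_threshold Relative motif score threshold.
#' @param expr_threshold,populations Expression filter settings the study is
#'   built around.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 7, n_chroms = 1, chrom_length = 200000,
                       n_genes = 30, gene_length = c(2400, 4200),
                       n_regions = 12, n_shared_variants = 40,
                       n_private_variants = 30, fraction_indel = 0.2,
                       qual_low = c(20, 100), qual_high = c(101, 500),
                       depth_low = c(1, 10), depth_high = c(11, 60),
                       n_fail_qual = 5, n_fail_depth = 5,
                       n_clustered_pairs = 6,
                       n_motif_disruptions = 3, n_motif_creations = 1,
                       motifs = builtin_tf_motifs(),
                       scan_threshold = 0.8,
                       expr_threshold = 120,
                       populations = c("B.Fo", "B.GC")) {
  if (length(n_private_variants) == 1) {
    n_private_variants <- rep(n_private_variants, 2)
  }
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = as.integer(chrom_length), n_genes = n_genes,
              gene_length = gene_length, n_regions = n_regions,
              n_shared_variants = n_shared_variants,
              n_private_variants = as.integer(n_private_variants),
              fraction_indel = fraction_indel, qual_low = qual_low,
              qual_high = qual_high, depth_low = depth_low,
              depth_high = depth_high, n_fail_qual = n_fail_qual,
              n_fail_depth = n_fail_depth,
              n_clustered_pairs = n_clustered_pairs,
              n_motif_disruptions = n_motif_disruptions,
              n_motif_creations = n_motif_creations, motifs = motifs,
              scan_threshold = scan_threshold,
              expr_threshold = expr_threshold, populations = populations)
  counts <- unlist(cfg[c("n_chroms", "n_genes", "n_regions",
                         "n_shared_variants", "n_private_variants",
                         "n_fail_qual", "n_fail_depth", "n_clustered_pairs",
                         "n_motif_disruptions", "n_motif_creations")])
  if (any(counts < 0)) abort_usage("all sim counts must be >= 0")
  pairs_a <- ceiling(n_clustered_pairs / 2)
  pairs_b <- n_clustered_pairs - pairs_a
  pass_a <- cfg$n_private_variants[1] - n_fail_qual - n_fail_depth - 2 * pairs_a
  pass_b <- cfg$n_private_variants[2] - n_fail_qual - n_fail_depth - 2 * pairs_b
  if (cfg$n_private_variants[1] > 0 &&
      pass_a < n_motif_disruptions + n_motif_creations) {
    abort_usage("line-A private variants cannot accommodate fail/cluster/motif allocation")
  }
  if (cfg$n_private_variants[2] > 0 && pass_b < 0) {
    abort_usage("line-B private variants cannot accommodate fail/cluster allocation")
  }
  if (n_regions < n_motif_disruptions + n_motif_creations) {
    abort_usage("need at least one regulatory region per planted motif variant")
  }
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic study
#'
#' Deterministically (given `config$seed`) builds genome, annotation,
#' regulatory regions, gene sets, expression table, two per-line variant sets
#' and the per-variant ground truth. Planted motif instances are exact
#' maximal-score words of the configured matrices embedded in background that
#' is re-rolled if it spuriously produces scan hits in the disruption
#' windows; clustered pairs sit at gaps drawn from 1..10 nt; all other
#' planted variants are kept more than 30 nt apart so only the intended
#' pairs trip the spacing filter.
#'
#' @param config A [sim_config()].
#' @return A list of class `csr_sim`: `genome`, `genes`, `regions`,
#'   `gene_sets`, `expression`, `variants_a`, `variants_b`, `truth`,
#'   `motifs`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- setNames(vapply(chroms, function(ch) {
    paste(sample(BASES, config$chrom_length, replace = TRUE), collapse = "")
  }, character(1)), chroms)

  layout <- sim_place_genes(config, chroms[1])
  genes <- layout$genes
  gaps <- layout$gaps

  rr <- sim_place_regions(config, genes, gaps)
  regions <- rr$regions
  free_gaps <- gaps[!seq_len(nrow(gaps)) %in% rr$used_gaps, , drop = FALSE]

  # plant motif instances and keep the disruption/creation variant specs
  planted <- sim_plant_motifs(config, genome, regions)
  genome <- planted$genome

  built <- sim_place_variants(config, genome, genes, regions, free_gaps,
                              planted$motif_variants)
  genome <- built$genome

  sets_expr <- sim_gene_sets(config, genes, built$truth)
  truth <- built$truth
  cand_genes <- sets_expr$candidate_genes
  truth$candidate_gene <- truth$exclusivity == "private" &
    truth$fate == "pass" & truth$line == "A" &
    !is.na(truth$gene_id) & truth$gene_id %in% cand_genes
  truth$splice_verdict <- ifelse(
    truth$candidate_gene & truth$sub_context == "intronic",
    "no_predicted_effect", NA_character_)

  structure(list(
    genome = genome, genes = genes, regions = regions,
    gene_sets = sets_expr$gene_sets, expression = sets_expr$expression,
    variants_a = built$variants_a, variants_b = built$variants_b,
    truth = truth, motifs = config$motifs, config = config
  ), class = "csr_sim")
}

#' @export
print.csr_sim <- function(x, ...) {
  cat(sprintf(
    "<csr_sim> seed %d: %d chrom(s) x %d nt, %d genes, %d regions, %d + %d private / %d shared variants\n",
    x$config$seed, length(x$genome), x$config$chrom_length, nrow(x$genes),
    nrow(x$regions), x$config$n_private_variants[1],
    x$config$n_private_variants[2], x$config$n_shared_variants))
  invisible(x)
}

# --- placement helpers ------------------------------------------------------

sim_place_genes <- function(config, chrom) {
  if (config$n_genes == 0) {
    return(list(genes = empty_gene_tbl(),
                gaps = tibble(start = 1000L,
                              end = config$chrom_length - 1000L)))
  }
  cursor <- 2000L
  rows <- list()
  for (i in seq_len(config$n_genes)) {
    gap <- sample(1600:2600, 1)
    start <- cursor + gap
    L <- sample(config$gene_length[1]:config$gene_length[2], 1)
    end <- start + L - 1L
    if (end > config$chrom_length - 2000L) {
      abort_usage(sprintf(
        "constraint violated: %d genes of %d-%d nt do not fit in %d nt",
        config$n_genes, config$gene_length[1], config$gene_length[2],
        config$chrom_length))
    }
    e1 <- round(0.14 * L); i1 <- round(0.26 * L)
    e2 <- round(0.12 * L); i2 <- round(0.26 * L)
    ex_start <- as.integer(c(start, start + e1 + i1,
                             start + e1 + i1 + e2 + i2))
    ex_end <- as.integer(c(start + e1 - 1L, start + e1 + i1 + e2 - 1L, end))
    exon <- tibble(start = ex_start, end = ex_end)
    cds_start <- as.integer(c(ex_start[1] + floor(e1 / 2), ex_start[2],
                              ex_start[3]))
    cds_end <- as.integer(c(ex_end[1], ex_end[2],
                            ex_start[3] + floor((ex_end[3] - ex_start[3]) / 2)))
    cds <- tibble(start = cds_start, end = cds_end)
    rows[[i]] <- tibble(
      gene_id = sprintf("SGENE%03d", i), name = sprintf("Sgene%03d", i),
      chrom = chrom, strand = sample(c("+", "-"), 1),
      span_start = start, span_end = end, biotype = "protein_coding",
      exons = list(exon), cds = list(cds)
    )
    cursor <- end
  }
  genes <- bind_rows(rows)
  gaps <- tibble(
    start = genes$span_end[-nrow(genes)] + 1L,
    end = genes$span_start[-1] - 1L,
    left_gene = genes$gene_id[-nrow(genes)],
    right_gene = genes$gene_id[-1]
  )
  list(genes = genes, gaps = gaps)
}

sim_place_regions <- function(config, genes, gaps) {
  if (config$n_regions == 0 || nrow(gaps) == 0 ||
      !"left_gene" %in% names(gaps)) {
    return(list(regions = tibble(chrom = character(0), start = integer(0),
                                 end = integer(0),
                                 target_gene_id = character(0),
                                 source_label = character(0)),
                used_gaps = integer(0)))
  }
  if (nrow(gaps) < config$n_regions) {
    abort_usage("not enough intergenic gaps to place the regulatory regions")
  }
  picks <- sort(sample(seq_len(nrow(gaps)), config$n_regions))
  rr_len <- 130L
  rows <- list()
  for (k in seq_along(picks)) {
    g <- gaps[picks[k], ]
    left <- k %% 2 == 1
    if (left) {
      start <- g$start + 200L
      target <- g$left_gene
    } else {
      start <- g$end - 200L - rr_len + 1L
      target <- g$right_gene
    }
    rows[[k]] <- tibble(chrom = genes$chrom[1], start = start,
                        end = start + rr_len - 1L, target_gene_id = target,
                        source_label = "simulated")
  }
  list(regions = bind_rows(rows), used_gaps = picks)
}

# identifies the most informative ("core") column of a pwm and its extreme
# bases; used to design disruption/creation alleles
pwm_core_position <- function(p) {
  lo <- pwm_logodds(p)$lo
  rng <- apply(lo, 2, max) - apply(lo, 2, min)
  j <- which.max(rng)
  list(col = j, best = BASES[which.max(p$prob[, j])],
       worst = BASES[which.min(p$prob[, j])])
}

sim_plant_motifs <- function(config, genome, regions) {
  n_plant <- config$n_motif_disruptions + config$n_motif_creations
  specs <- list()
  if (n_plant == 0) {
    return(list(genome = genome, motif_variants = specs))
  }
  pwms <- config$motifs
  for (k in seq_len(n_plant)) {
    p <- pwms[[(k - 1) %% length(pwms) + 1]]
    core <- pwm_core_position(p)
    disrupt <- k <= config$n_motif_disruptions
    word <- strsplit(pwm_consensus(p), "", fixed = TRUE)[[1]]
    if (!disrupt) word[core$col] <- core$worst   # near-miss, below threshold
    rr <- regions[k, ]
    wstart <- rr$start + 40L
    vpos <- wstart + core$col - 1L
    v_ref <- if (disrupt) core$best else core$worst
    v_alt <- if (disrupt) core$worst else core$best
    chrom <- rr$chrom
    placed <- FALSE
    for (try in 1:50) {
      s <- genome[[chrom]]
      substr(s, wstart, wstart + length(word) - 1L) <- paste(word, collapse = "")
      genome[[chrom]] <- s
      v <- tibble(chrom = chrom, pos = vpos, ref = v_ref, alt = v_alt)
      d <- tfbs_delta(genome, v, pwms, config$scan_threshold)
      ok <- if (disrupt) {
        nrow(d) == 1 && d$status == "lost" && d$motif_id == p$motif_id
      } else {
        nrow(d) == 1 && d$status == "gained" && d$motif_id == p$motif_id
      }
      if (ok) { placed <- TRUE; break }
      # spurious background hit: re-roll the region's non-word bases
      bg_len <- rr$end - rr$start + 1L
      bg <- sample(BASES, bg_len, replace = TRUE)
      s <- genome[[chrom]]
      substr(s, rr$start, rr$end) <- paste(bg, collapse = "")
      genome[[chrom]] <- s
    }
    if (!placed) {
      abort_usage(sprintf(
        "constraint violated: could not plant a clean %s instance for %s",
        if (disrupt) "disruption" else "creation", p$motif_id))
    }
    specs[[k]] <- list(chrom = chrom, pos = vpos, ref = v_ref, alt = v_alt,
                       motif_id = p$motif_id,
                       status = if (disrupt) "lost" else "gained",
                       region_index = k, word_start = wstart,
                       word_end = wstart + length(word) - 1L,
                       target_gene = rr$target_gene_id)
  }
  list(genome = genome, motif_variants = specs)
}

# brute-force nearest gene used when recording planted truth
sim_nearest_gene <- function(genes, chrom, pos, pos_end = pos) {
  sel <- which(genes$chrom == chrom)
  if (length(sel) == 0) return(list(gene = NA_character_, dist = NA_real_))
  d <- interval_gap(pos, pos_end, genes$span_start[sel], genes$span_end[sel])
  o <- order(d, genes$span_start[sel], genes$gene_id[sel])
  list(gene = genes$gene_id[sel[o[1]]], dist = d[o[1]])
}

sim_place_variants <- function(config, genome, genes, regions, free_gaps,
                               motif_variants) {
  chrom <- names(genome)[1]
  chrom_len <- nchar(genome[[chrom]])
  occupied <- list()   # list of c(start, end) spans, 31-nt mutual buffer
  forbidden <- map(motif_variants, function(m) {
    c(m$word_start - 30L, m$word_end + 30L)
  })
  min_sep <- 31L

  clear <- function(s, e, sep = min_sep) {
    ok_occ <- all(vapply(occupied, function(iv) {
      interval_gap(s, e, iv[1], iv[2]) >= sep
    }, logical(1)))
    ok_forb <- all(vapply(forbidden, function(iv) {
      !overlaps(s, e, iv[1], iv[2])
    }, logical(1)))
    ok_occ && ok_forb
  }
  claim <- function(s, e) occupied[[length(occupied) + 1]] <<- c(s, e)

  draw_pos <- function(lo, hi, span = 1L, sep = min_sep) {
    if (hi - span + 1L < lo) return(NA_integer_)
    cand <- lo:(hi - span + 1L)
    for (try in 1:300) {
      p <- cand[sample.int(length(cand), 1)]
      if (clear(p, p + span - 1L, sep)) return(p)
    }
    NA_integer_
  }

  draw_gap_pos <- function(span = 1L) {
    for (try in 1:300) {
      g <- free_gaps[sample(nrow(free_gaps), 1), ]
      p <- draw_pos(g$start + 15L, g$end - 15L, span)
      if (!is.na(p)) return(p)
    }
    abort_usage("constraint violated: no room left in intergenic gaps")
  }

  qual_pass <- function() sample(config$qual_high[1]:config$qual_high[2], 1)
  qual_fail <- function() sample(config$qual_low[1]:config$qual_low[2], 1)
  depth_pass <- function() sample(config$depth_high[1]:config$depth_high[2], 1)
  depth_fail <- function() sample(config$depth_low[1]:config$depth_low[2], 1)

  rows <- list()
  emit <- function(line, pos, ref, alt, qual, depth, exclusivity, fate,
                   region_class, sub_context, gene_id, distance,
                   motif_effect = "none") {
    rows[[length(rows) + 1]] <<- tibble(
      line = line, chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      qual = as.numeric(qual), alt_depth = as.integer(depth),
      exclusivity = exclusivity, fate = fate, region_class = region_class,
      sub_context = sub_context, gene_id = gene_id,
      distance = as.numeric(distance), motif_effect = motif_effect
    )
  }

  # alleles: SNP at pos, or 1-4 nt indel with a VCF anchor base
  snp_allele <- function(pos) {
    ref <- subseq_chr(genome[[chrom]], pos, pos)
    list(ref = ref, alt = sample(setdiff(BASES, ref), 1), span = 1L)
  }
  indel_allele <- function(pos) {
    len <- sample(1:4, 1)
    anchor <- subseq_chr(genome[[chrom]], pos, pos)
    if (runif(1) < 0.5) {
      list(ref = anchor,
           alt = paste0(anchor, paste(sample(BASES, len, replace = TRUE),
                                      collapse = "")), span = 1L)
    } else {
      list(ref = subseq_chr(genome[[chrom]], pos, pos + len),
           alt = anchor, span = len + 1L)
    }
  }
  make_allele <- function(pos, allow_indel) {
    if (allow_indel && runif(1) < config$fraction_indel) indel_allele(pos)
    else snp_allele(pos)
  }
  # guard against an insertion whose added bases equal the following
  # reference bases (which would right-trim into a different key)
  sane_allele <- function(al, pos) {
    v <- normalize_variants(tibble(chrom = chrom, pos = as.integer(pos),
                                   ref = al$ref, alt = al$alt,
                                   qual = 1, alt_depth = 1L, line = "x"))
    v$pos[1] == pos && v$ref[1] == al$ref && v$alt[1] == al$alt
  }
  draw_allele <- function(pos, allow_indel) {
    for (try in 1:50) {
      al <- make_allele(pos, allow_indel)
      if (sane_allele(al, pos)) return(al)
    }
    snp_allele(pos)
  }

  pairs_a <- ceiling(config$n_clustered_pairs / 2)
  pairs_b <- config$n_clustered_pairs - pairs_a
  lines <- list(
    A = list(label = "A", pairs = pairs_a),
    B = list(label = "B", pairs = pairs_b)
  )
  n_priv <- setNames(config$n_private_variants, c("A", "B"))

  # pools of genes reserved per purpose so candidate truth stays unambiguous
  reserved <- unique(unlist(map(motif_variants, "target_gene")))
  gene_pool <- setdiff(genes$gene_id, c(reserved,
                                        regions$target_gene_id))
  take_gene <- function() {
    if (length(gene_pool) == 0) abort_usage("not enough genes for variant classes")
    g <- gene_pool[1]
    gene_pool <<- gene_pool[-1]
    g
  }

  place_genic <- function(line, cls) {
    gid <- take_gene()
    g <- genes[genes$gene_id == gid, ]
    ex <- g$exons[[1]]
    cd <- g$cds[[1]]
    iv <- switch(cls,
      CDS = cd[2, ],                                  # wholly coding exon
      intronic = tibble(start = ex$end[1] + 60L, end = ex$start[2] - 60L),
      UTR5 = if (g$strand == "+") {
        tibble(start = ex$start[1], end = cd$start[1] - 1L)
      } else {
        tibble(start = cd$end[3] + 1L, end = ex$end[3])
      },
      UTR3 = if (g$strand == "+") {
        tibble(start = cd$end[3] + 1L, end = ex$end[3])
      } else {
        tibble(start = ex$start[1], end = cd$start[1] - 1L)
      }
    )
    pos <- draw_pos(iv$start + 6L, iv$end - 6L, span = 5L)
    if (is.na(pos)) abort_usage("constraint violated: no room in genic interval")
    al <- draw_allele(pos, allow_indel = TRUE)
    claim(pos, pos + al$span - 1L)
    sub <- switch(cls, CDS = "exonic_CDS", intronic = "intronic",
                  UTR5 = "UTR5", UTR3 = "UTR3")
    emit(line, pos, al$ref, al$alt, qual_pass(), depth_pass(), "private",
         "pass", if (cls == "CDS") "CDS" else "nCDS", sub, gid, 0)
    gid
  }

  place_intergenic <- function(line, check_tfbs) {
    for (try in 1:100) {
      pos <- draw_gap_pos(span = 5L)
      al <- draw_allele(pos, allow_indel = TRUE)
      v <- tibble(chrom = chrom, pos = pos, ref = al$ref, alt = al$alt)
      if (!check_tfbs ||
          nrow(tfbs_delta(genome, v, config$motifs,
                          config$scan_threshold)) == 0) {
        claim(pos, pos + al$span - 1L)
        near <- sim_nearest_gene(genes, chrom, pos, pos + al$span - 1L)
        emit(line, pos, al$ref, al$alt, qual_pass(), depth_pass(), "private",
             "pass", "intergenic", "none", near$gene, near$dist)
        return(near$gene)
      }
    }
    abort_usage("constraint violated: could not place a motif-free intergenic variant")
  }

  place_rr_plain <- function(line) {
    n_plant <- length(motif_variants)
    free_rr <- regions[setdiff(seq_len(nrow(regions)),
                               seq_len(n_plant)), , drop = FALSE]
    for (try in 1:100) {
      r <- free_rr[sample(nrow(free_rr), 1), ]
      pos <- draw_pos(r$start + 5L, r$end - 5L, span = 1L)
      if (is.na(pos)) next
      al <- snp_allele(pos)
      claim(pos, pos)
      near <- sim_nearest_gene(genes, chrom, pos)
      emit(line, pos, al$ref, al$alt, qual_pass(), depth_pass(), "private",
           "pass", "RR", "regulatory", r$target_gene_id, near$dist)
      return(r$target_gene_id)
    }
    abort_usage("constraint violated: could not place a plain RR variant")
  }

  # --- line-A motif variants (already positioned by the planting step) ----
  for (m in motif_variants) {
    claim(m$pos, m$pos + nchar(m$ref) - 1L)
    near <- sim_nearest_gene(genes, chrom, m$pos)
    emit("A", m$pos, m$ref, m$alt, qual_pass(), depth_pass(), "private",
         "pass", "RR", "regulatory", m$target_gene, near$dist,
         motif_effect = paste0(m$status, ":", m$motif_id))
  }

  purpose_genes <- list(A = list(), B = list())
  class_cycle <- c("CDS", "intronic", "UTR5", "UTR3", "intergenic")

  for (ln in c("A", "B")) {
    info <- lines[[ln]]
    n_pass <- n_priv[[ln]] - config$n_fail_qual - config$n_fail_depth -
      2L * info$pairs
    if (n_priv[[ln]] == 0) next
    n_motif_here <- if (ln == "A") length(motif_variants) else 0L
    n_rest <- n_pass - n_motif_here
    cls_seq <- if (ln == "A") {
      rep(class_cycle, length.out = max(0L, n_rest))
    } else {
      rep(c(class_cycle, "RR"), length.out = max(0L, n_rest))
    }
    for (cls in cls_seq) {
      gid <- switch(cls,
        intergenic = place_intergenic(ln, check_tfbs = ln == "A"),
        RR = place_rr_plain(ln),
        place_genic(ln, cls)
      )
      purpose_genes[[ln]][[length(purpose_genes[[ln]]) + 1]] <-
        list(gene = gid, cls = cls)
    }
    # failing variants
    for (k in seq_len(config$n_fail_qual)) {
      pos <- draw_gap_pos(span = 5L)
      al <- draw_allele(pos, allow_indel = TRUE)
      claim(pos, pos + al$span - 1L)
      q <- if (k == 1) config$qual_low[2] else qual_fail()  # pin boundary
      emit(ln, pos, al$ref, al$alt, q, depth_pass(), "private", "fail_qual",
           "intergenic", "none", NA_character_, NA_real_)
    }
    for (k in seq_len(config$n_fail_depth)) {
      pos <- draw_gap_pos(span = 5L)
      al <- draw_allele(pos, allow_indel = TRUE)
      claim(pos, pos + al$span - 1L)
      d <- if (k == 1) config$depth_low[2] else depth_fail()
      emit(ln, pos, al$ref, al$alt, qual_pass(), d, "private", "fail_depth",
           "intergenic", "none", NA_character_, NA_real_)
    }
    # clustered pairs: both members expected spacing casualties
    for (k in seq_len(info$pairs)) {
      gap <- sample(1:10, 1)
      repeat {
        p1 <- draw_gap_pos(span = gap + 1L)
        if (!is.na(p1)) break
      }
      for (p in c(p1, p1 + gap)) {
        al <- snp_allele(p)
        emit(ln, p, al$ref, al$alt, qual_pass(), depth_pass(), "private",
             "fail_spacing", "intergenic", "none", NA_character_, NA_real_)
      }
      claim(p1, p1 + gap)
    }
  }

  # shared variants: identical keys in both lines
  for (k in seq_len(config$n_shared_variants)) {
    pos <- draw_gap_pos(span = 5L)
    al <- draw_allele(pos, allow_indel = TRUE)
    claim(pos, pos + al$span - 1L)
    for (ln in c("A", "B")) {
      emit(ln, pos, al$ref, al$alt, qual_pass(), depth_pass(), "shared",
           "pass", "intergenic", "none", NA_character_, NA_real_)
    }
  }

  if (length(rows) == 0) {
    rows <- list(tibble(
      line = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), qual = numeric(0),
      alt_depth = integer(0), exclusivity = character(0),
      fate = character(0), region_class = character(0),
      sub_context = character(0), gene_id = character(0),
      distance = numeric(0), motif_effect = character(0)
    ))
  }
  truth <- bind_rows(rows)
  truth$vclass <- variant_class(truth$ref, truth$alt)
  truth <- arrange(truth, .data$line, .data$chrom, .data$pos, .data$ref,
                   .data$alt)
  mk_vs <- function(ln) {
    t <- truth[truth$line == ln, ]
    validate_variants(normalize_variants(tibble(
      chrom = t$chrom, pos = t$pos, ref = t$ref, alt = t$alt,
      qual = t$qual, alt_depth = t$alt_depth, line = ln,
      vclass = t$vclass
    )))
  }
  list(genome = genome, truth = truth,
       variants_a = mk_vs("A"), variants_b = mk_vs("B"),
       purpose_genes = purpose_genes)
}

# gene sets + expression constructed around the planted line-A variants:
# most variant-bearing genes go into the sets with high expression; one CDS
# gene is left out of every set, one intronic gene is in a set but barely
# expressed, one intergenic nearest gene stays set-free, and two variant-free
# genes pad the sets.
sim_gene_sets <- function(config, genes, truth) {
  a_pass <- truth[truth$line == "A" & truth$exclusivity == "private" &
                    truth$fate == "pass" & !is.na(truth$gene_id), ]
  pick <- function(cls, sub = NULL) {
    sel <- a_pass$region_class == cls
    if (!is.null(sub)) sel <- sel & a_pass$sub_context == sub
    unique(a_pass$gene_id[sel])
  }
  rr_genes <- pick("RR")
  cds_genes <- pick("CDS")
  intr_genes <- pick("nCDS", "intronic")
  utr_genes <- unique(c(pick("nCDS", "UTR5"), pick("nCDS", "UTR3")))
  ig_genes <- pick("intergenic")

  # decoys: a set-free CDS gene, a set-free intergenic-nearest gene and a
  # barely expressed intronic gene — none may collide with a gene used by
  # another class (in particular a motif-bearing RR target), or the planted
  # effect would silently fall out of the candidate table
  other_than <- function(x, taken) setdiff(x, taken)[1]
  drop_set <- c(
    other_than(cds_genes, c(rr_genes, intr_genes, utr_genes, ig_genes)),
    other_than(rev(ig_genes), c(rr_genes, cds_genes, intr_genes, utr_genes))
  )
  drop_set <- drop_set[!is.na(drop_set)]
  low_expr <- if (length(intr_genes) > 1) {
    x <- other_than(rev(intr_genes), c(rr_genes, cds_genes, utr_genes,
                                       ig_genes, drop_set))
    x[!is.na(x)]
  } else character(0)
  in_sets <- setdiff(unique(c(rr_genes, cds_genes, intr_genes, utr_genes,
                              ig_genes)), drop_set[!is.na(drop_set)])
  spare <- head(setdiff(genes$gene_id, unique(a_pass$gene_id)), 2)

  pathway <- unique(c(rr_genes, setdiff(cds_genes, drop_set),
                      intr_genes, spare[1]))
  ontology <- unique(c(utr_genes, setdiff(ig_genes, drop_set), intr_genes[1],
                       if (length(spare) > 1) spare[2]))
  gene_sets <- bind_rows(
    tibble(set_name = "csr_pathway",
           description = "simulated class-switch pathway members",
           gene_id = toupper(pathway[!is.na(pathway)])),
    tibble(set_name = "csr_ontology",
           description = "simulated class-switch ontology terms",
           gene_id = toupper(ontology[!is.na(ontology)]))
  )

  pops <- unique(c(config$populations, "T.4"))
  expression <- tidyr::expand_grid(gene_id = genes$gene_id,
                                   population = pops)
  expression$value <- as.numeric(sample(130:900, nrow(expression),
                                        replace = TRUE))
  low_sel <- expression$gene_id %in% low_expr &
    expression$population %in% config$populations
  expression$value[low_sel] <- sample(0:20, sum(low_sel), replace = TRUE)

  candidate_genes <- setdiff(in_sets, low_expr)
  list(gene_sets = gene_sets, expression = expression,
       candidate_genes = candidate_genes)
}

#' Write the simulated study to disk
#'
#' Emits the study artifacts as plain-text files: `genome.fa`, `genes.gff3`,
#' `regions.bed`, `gene_sets.gmt`, `expression.tsv`, `line_A.vcf`,
#' `line_B.vcf`, the planted motif set `motifs.jaspar`, and the ground-truth
#' ledger `truth.tsv`.
#'
#' @param sim A `csr_sim` from [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_gff3(sim$genes, p("genes.gff3"))
  write_bed(sim$regions, p("regions.bed"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  write_expression(sim$expression, p("expression.tsv"))
  contigs <- setNames(nchar(sim$genome), names(sim$genome))
  write_vcf(sim$variants_a, p("line_A.vcf"), contigs)
  write_vcf(sim$variants_b, p("line_B.vcf"), contigs)
  write_motifs_jaspar(sim$motifs, p("motifs.jaspar"))
  readr::write_tsv(sim$truth, p("truth.tsv"), na = "")
  invisible(c(genome = p("genome.fa"), gff3 = p("genes.gff3"),
              bed = p("regions.bed"), gmt = p("gene_sets.gmt"),
              expression = p("expression.tsv"), vcf_a = p("line_A.vcf"),
              vcf_b = p("line_B.vcf"), motifs = p("motifs.jaspar"),
              truth = p("truth.tsv")))
}

#' Read a ground-truth ledger
#'
#' @param path `truth.tsv` written by [write_sim()].
#' @return The truth tibble.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    line = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), ref = readr::col_character(),
    alt = readr::col_character(), qual = readr::col_double(),
    alt_depth = readr::col_integer(), exclusivity = readr::col_character(),
    fate = readr::col_character(), region_class = readr::col_character(),
    sub_context = readr::col_character(), gene_id = readr::col_character(),
    distance = readr::col_double(), motif_effect = readr::col_character(),
    vclass = readr::col_character(), candidate_gene = readr::col_logical(),
    splice_verdict = readr::col_character()
  ), na = "")
}
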