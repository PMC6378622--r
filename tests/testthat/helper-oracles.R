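# Independent brute-force oracles and random-instance generators.
# These deliberately re-derive each quantity from its definition (all-pairs
# loops, per-offset rescoring, per-base membership) rather than calling the
# package's optimized paths.

BASES4 <- c("A", "C", "G", "T")

rc_str <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# random valid variant table with unique (chrom, pos) placements
rand_variant_set <- function(n, line = "A", chroms = c("chr1", "chr2"),
                             max_pos = 5000) {
  pos <- sample.int(max_pos, n)
  ref <- sample(BASES4, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES4, r), 1), character(1))
  variant_tbl(chrom = sample(chroms, n, replace = TRUE), pos = pos,
              ref = ref, alt = alt,
              qual = round(runif(n, 0, 500), 1),
              alt_depth = sample(0:60, n, replace = TRUE), line = line)
}

# O(n^2) all-pairs spacing filter (drop every variant with a neighbor <= gap)
oracle_spacing <- function(vs, gap) {
  if (nrow(vs) < 2) return(vs)
  d <- abs(outer(vs$pos, vs$pos, "-"))
  same <- outer(vs$chrom, vs$chrom, "==")
  too_close <- d <= gap & same
  diag(too_close) <- FALSE
  vs[rowSums(too_close) == 0, , drop = FALSE]
}

# hash-set difference on full allele keys
oracle_exclusive <- function(vs_a, vs_b) {
  ka <- paste(vs_a$chrom, vs_a$pos, vs_a$ref, vs_a$alt)
  kb <- paste(vs_b$chrom, vs_b$pos, vs_b$ref, vs_b$alt)
  list(a = vs_a[!(ka %in% kb), , drop = FALSE],
       b = vs_b[!(kb %in% ka), , drop = FALSE])
}

# exhaustive minimal representation: trim shared suffix then prefix, keeping
# one base per allele
oracle_minimal <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    changed <- FALSE
    if (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]; changed <- TRUE
    }
    if (!changed) break
  }
  repeat {
    if (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1
    } else break
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# per-offset, per-strand motif rescoring from the PWM definition
oracle_scan <- function(seq, p, thr) {
  W <- pwm_width(p)
  L <- nchar(seq)
  lo <- log2(p$prob / p$background)
  rng <- c(sum(apply(lo, 2, min)), sum(apply(lo, 2, max)))
  rows <- list()
  if (L >= W) {
    for (s in 1:(L - W + 1)) {
      win <- substr(seq, s, s + W - 1)
      for (strand in c("+", "-")) {
        word <- if (strand == "+") win else rc_str(win)
        b <- strsplit(word, "")[[1]]
        sc <- sum(vapply(seq_len(W), function(i) lo[b[i], i], numeric(1)))
        rel <- (sc - rng[1]) / (rng[2] - rng[1])
        if (rel >= thr) {
          rows[[length(rows) + 1]] <-
            data.frame(start = s, strand = strand, score = sc,
                       rel_score = rel)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), rel_score = numeric(0))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

rand_pwm <- function(width = sample(4:10, 1), id = "RND") {
  m <- matrix(sample(0:40, 4 * width, replace = TRUE), nrow = 4,
              dimnames = list(BASES4, NULL))
  zero <- colSums(m) == 0
  m[1, zero] <- 1
  pwm(m, id)
}

# small random gene layout on one 4-kb chromosome; returns genes + regions
rand_layout <- function(n_genes = 3, n_regions = 2, chrom_len = 4000) {
  cursor <- 50
  rows <- list()
  for (i in seq_len(n_genes)) {
    start <- cursor + sample(80:220, 1)
    L <- sample(300:700, 1)
    end <- start + L - 1
    if (end > chrom_len - 50) break
    e1e <- start + sample(60:110, 1)
    e2s <- e1e + sample(60:150, 1)
    ex <- tibble::tibble(start = c(start, e2s), end = c(e1e, end))
    has_cds <- runif(1) < 0.8
    cds <- if (has_cds) {
      tibble::tibble(start = c(start + 20, e2s), end = c(e1e, end - 20))
    } else {
      tibble::tibble(start = integer(0), end = integer(0))
    }
    rows[[i]] <- tibble::tibble(
      gene_id = sprintf("G%02d", i), name = sprintf("G%02d", i),
      chrom = "chr1", strand = sample(c("+", "-"), 1),
      span_start = as.integer(start), span_end = as.integer(end),
      biotype = if (has_cds) "protein_coding" else "lncRNA",
      exons = list(ex), cds = list(cds))
    cursor <- end
  }
  genes <- dplyr::bind_rows(rows)
  regions <- if (n_regions > 0) {
    st <- sample.int(chrom_len - 80, n_regions)
    tibble::tibble(chrom = "chr1", start = as.integer(st),
                   end = as.integer(st + sample(20:60, n_regions,
                                                replace = TRUE)),
                   target_gene_id = NA_character_, source_label = "rand")
  } else {
    tibble::tibble(chrom = character(0), start = integer(0),
                   end = integer(0), target_gene_id = character(0),
                   source_label = character(0))
  }
  list(genes = genes, regions = regions)
}

# per-base membership classification (CDS > nCDS > RR > intergenic)
oracle_classify <- function(v, genes, regions) {
  span <- v$pos:(v$pos + nchar(v$ref) - 1)
  in_iv <- function(iv) nrow(iv) > 0 &&
    any(vapply(span, function(b) any(b >= iv$start & b <= iv$end),
               logical(1)))
  gsel <- which(genes$chrom == v$chrom)
  for (g in gsel) {
    if (in_iv(genes$cds[[g]])) return("CDS")
  }
  for (g in gsel) {
    if (in_iv(tibble::tibble(start = genes$span_start[g],
                             end = genes$span_end[g]))) return("nCDS")
  }
  rsel <- regions[regions$chrom == v$chrom, , drop = FALSE]
  if (nrow(rsel) > 0 && in_iv(rsel)) return("RR")
  "intergenic"
}

# exhaustive all-gene nearest scan with the stated tie-breaks
oracle_nearest <- function(v, genes, cap) {
  best <- NULL
  vend <- v$pos + nchar(v$ref) - 1
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != v$chrom) next
    d <- max(0, genes$span_start[g] - vend, v$pos - genes$span_end[g])
    cand <- list(gene = genes$gene_id[g], d = d,
                 start = genes$span_start[g])
    if (is.null(best) || d < best$d ||
        (d == best$d && (cand$start < best$start ||
                         (cand$start == best$start &&
                          cand$gene < best$gene)))) {
      best <- cand
    }
  }
  if (is.null(best) || best$d > cap) {
    list(gene = NA_character_, d = NA_real_)
  } else {
    list(gene = best$gene, d = best$d)
  }
}

# minimal one-chromosome genome with a variant applied (for swap tests)
apply_variant <- function(genome, v) {
  s <- genome[[v$chrom]]
  genome[[v$chrom]] <- paste0(substr(s, 1, v$pos - 1), v$alt,
                              substr(s, v$pos + nchar(v$ref), nchar(s)))
  genome
}

# tiny simulated study shared by the slower tests (built once per run)
small_sim_config <- function(seed = 11) {
  sim_config(seed = seed, chrom_length = 135000, n_genes = 22,
             n_regions = 8, n_shared_variants = 15,
             n_private_variants = 18, n_fail_qual = 3, n_fail_depth = 3,
             n_clustered_pairs = 4)
}

run_sim_pipeline <- function(sim, dir, ...) {
  paths <- write_sim(sim, dir)
  cfg <- pipeline_config(
    vcf_a = paths[["vcf_a"]], vcf_b = paths[["vcf_b"]],
    genome = paths[["genome"]], gff3 = paths[["gff3"]],
    bed = paths[["bed"]], gmt = paths[["gmt"]],
    expression = paths[["expression"]], motifs = paths[["motifs"]],
    out_dir = file.path(dir, "out"), ...)
  run_pipeline(cfg, quiet = TRUE)
}
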