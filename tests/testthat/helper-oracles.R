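# Independent oracles and fixture builders. These deliberately use naive
# loop-based formulations so they share no code path with the package.

# Exhaustive two-segment least-squares search: evaluate every candidate
# breakpoint by plain loops and means.
brute_force_breakpoint <- function(mat, margin, stride = 1) {
  L <- ncol(mat)
  cands <- seq(margin, L - margin, by = stride)
  best <- NULL
  for (p in cands) {
    rss <- 0
    wl <- ws <- numeric(nrow(mat))
    for (s in seq_len(nrow(mat))) {
      x <- mat[s, ]
      wl[s] <- mean(x[(p + 1):L])
      ws[s] <- max(0, mean(x[1:p]) - wl[s])
      fitted <- c(rep(ws[s] + wl[s], p), rep(wl[s], L - p))
      rss <- rss + sum((x - fitted)^2)
    }
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(P = p, w_long = wl, w_short = ws, rss = rss)
    }
  }
  best
}

# Benjamini-Hochberg step-up computed literally from its definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail by direct summation of binomial coefficients.
hyper_tail_oracle <- function(overlap, size_a, size_b, universe) {
  ks <- seq(overlap, min(size_a, size_b))
  if (overlap > min(size_a, size_b)) return(0)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating the
# hypergeometric support and summing outcomes no more probable than the
# observed one (with the standard relative tolerance).
fisher_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, rs[1], rs[2], cs[1])
  obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- fixture builders -------------------------------------------------------

write_bed12 <- function(lines, path = withr::local_tempfile(fileext = ".bed",
                                                            .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

bed12_line <- function(chrom = "chr1", start = 100, end = 1000, name = "tx1",
                       strand = "+", thick_start = 100, thick_end = 700,
                       blocks = NULL) {
  if (is.null(blocks)) blocks <- list(sizes = end - start, starts = 0)
  paste(chrom, start, end, name, 0, strand, thick_start, thick_end, 0,
        length(blocks$sizes),
        paste0(paste(blocks$sizes, collapse = ","), ","),
        paste0(paste(blocks$starts, collapse = ","), ","),
        sep = "\t")
}

# A minimal transcript tibble without going through file parsing.
make_models <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      transcript_id = r$tx, gene_id = r$gene, chrom = r$chrom %||% "chr1",
      start = r$start, end = r$end, strand = r$strand %||% "+",
      cds_end_3p = r$cds,
      exon_starts = list(r$exon_starts %||% r$start),
      exon_ends = list(r$exon_ends %||% r$end))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An in-memory coverage tibble for one or more genes.
make_cov_tbl <- function(covs_by_gene_sample, groups, total_mapped_reads = 1e6) {
  rows <- list()
  for (gid in names(covs_by_gene_sample)) {
    covs <- covs_by_gene_sample[[gid]]
    for (sid in names(covs)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = gid, sample_id = sid, group = groups[[sid]],
        coverage = list(covs[[sid]]),
        depth_factor = 1e6 / total_mapped_reads, normalized = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

# Simple UTR tibble matching extract_3utrs() output shape.
make_utrs <- function(gene_id, start, end, strand = "+", chrom = "chr1") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand,
    distal_end = ifelse(strand == "+", end, start),
    utr_length = end - start,
    source_transcripts = lapply(gene_id, function(g) paste0(g, "_tx")),
    masked = FALSE)
}
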