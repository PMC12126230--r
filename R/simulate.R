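#' Configuration for the two-isoform 3'UTR coverage simulator
#'
#' Defines the study conditions for a synthetic APA experiment: per gene a
#' true proximal poly(A) site and per-condition true PDUIs; reads of fixed
#' length are placed uniformly along each isoform with Poisson (or negative
#' binomial) count noise, so coverage shows a soft, read-length-wide ramp at
#' the proximal site rather than an ideal step.
#'
#' Effect classes are assigned deterministically in the configured
#' proportions; lengthened genes gain `effect_size` PDUI in the perturbed
#' group, shortened genes lose it, null genes keep identical PDUIs in both
#' groups. Baseline PDUIs are drawn uniformly inside `base_pdui_range`,
#' restricted so that the perturbed PDUI stays within `[0.05, 0.95]`
#' without clamping (clamping would bias the true effect sizes).
#'
#' @param n_genes Number of genes (default 200).
#' @param n_replicates Replicates per condition (default 3).
#' @param groups Named character vector `c(ref = ..., alt = ...)` of
#'   condition labels (default control / knockdown).
#' @param effects Named fractions `c(null=, lengthened=, shortened=)`
#'   summing to 1 (default 0.6 / 0.3 / 0.1).
#' @param effect_size True |ΔPDUI| of non-null genes (default 0.3).
#' @param depth Mean coverage at the UTR 5' end, in x (default 100).
#' @param read_length Read length in nt (default 100).
#' @param dispersion Negative-binomial dispersion of read counts; 0 gives
#'   Poisson (default 0).
#' @param utr_length_range Integer range of UTR lengths in nt
#'   (default 600--1500).
#' @param base_pdui_range Range of baseline (reference) PDUIs
#'   (default 0.2--0.8).
#' @param bound_fraction Fraction of lengthened genes assigned a binding
#'   site within 75 nt upstream of the distal PAS, mirroring the repressive
#'   binding geometry (default 0.5).
#' @param margin Breakpoint-fit margin the truth respects (default 100).
#' @param total_mapped_reads Library size written to the sample sheet
#'   (default 1e6, so the depth factor is 1 and raw and CPM-normalized
#'   coverage coincide).
#' @param seed Global seed; per-gene substreams are derived by stable
#'   hashing of gene and sample ids, so subsets reproduce regardless of
#'   iteration order.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_replicates = 3,
                       groups = c(ref = "control", alt = "knockdown"),
                       effects = c(null = 0.6, lengthened = 0.3, shortened = 0.1),
                       effect_size = 0.3, depth = 100, read_length = 100,
                       dispersion = 0, utr_length_range = c(600, 1500),
                       base_pdui_range = c(0.2, 0.8), bound_fraction = 0.5,
                       margin = 100, total_mapped_reads = 1e6, seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 1, depth >= 0, read_length >= 1,
            dispersion >= 0, length(groups) == 2,
            all(c("null", "lengthened", "shortened") %in% names(effects)))
  if (abs(sum(effects) - 1) > 1e-9) {
    abort("effect fractions must sum to 1", class = "apascan_error")
  }
  if (utr_length_range[1] < 2 * (margin + read_length) + 10) {
    abort("UTR length range too short for margin + read length",
          class = "apascan_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate per-base coverage for one gene in one sample
#'
#' Expected short-isoform reads are proportional to `1 - pdui`, long-isoform
#' reads to `pdui`. Read start positions are uniform over each isoform
#' (including an upstream flank of one read length, so coverage at the UTR
#' 5' end is already at full height); counts are Poisson, or negative
#' binomial when `dispersion > 0`. Coverage is the per-base read pileup, so
#' the drop at `p_true` is smoothed over about one read length.
#'
#' @param utr_length UTR length L in nt.
#' @param p_true True proximal PAS offset from the UTR 5' end (nt).
#' @param pdui True distal-usage fraction in `[0, 1]`.
#' @param depth Expected coverage at the UTR 5' end.
#' @param read_length Read length in nt.
#' @param dispersion Count dispersion (0 = Poisson).
#' @param seed Integer substream seed.
#' @return Integer coverage vector of length `utr_length`, transcript
#'   orientation.
#' @export
simulate_gene <- function(utr_length, p_true, pdui, depth, read_length,
                          dispersion = 0, seed = 1) {
  stopifnot(p_true > 0, p_true < utr_length, pdui >= 0, pdui <= 1)
  L <- utr_length; rl <- read_length
  with_seed(seed, {
    lam_long <- depth * pdui * (L + rl - 1) / rl
    lam_short <- depth * (1 - pdui) * (p_true + rl - 1) / rl
    n_long <- draw_count(lam_long, dispersion)
    n_short <- draw_count(lam_short, dispersion)
    starts_long <- if (n_long > 0) {
      sample.int(L + rl - 1, n_long, replace = TRUE) - rl # in [-(rl-1), L-1]
    } else integer(0)
    starts_short <- if (n_short > 0) {
      sample.int(p_true + rl - 1, n_short, replace = TRUE) - rl
    } else integer(0)
    pileup(c(starts_long, starts_short), rl, L)
  })
}

draw_count <- function(lambda, dispersion) {
  if (lambda <= 0) return(0L)
  if (dispersion > 0) {
    stats::rnbinom(1, mu = lambda, size = 1 / dispersion)
  } else {
    stats::rpois(1, lambda)
  }
}

# Per-base pileup of reads [start, start + rl) clipped to [0, L).
pileup <- function(starts, rl, L) {
  if (length(starts) == 0) return(integer(L))
  a <- pmax(starts, 0L)
  b <- pmin(starts + rl, L)
  keep <- b > a
  a <- a[keep]; b <- b[keep]
  d <- tabulate(a + 1L, nbins = L + 1L) - tabulate(b + 1L, nbins = L + 1L)
  cumsum(d)[seq_len(L)]
}

#' Simulate a complete synthetic APA dataset
#'
#' Generates, deterministically for a given seed, everything the pipeline
#' consumes: a BED12 annotation (one single-exon transcript per gene, CDS
#' followed by the 3'UTR, random strand), per-sample per-base coverage, a
#' sample sheet, a ground-truth table, and a binding-site BED in which the
#' configured fraction of lengthened genes carries a site within 75 nt
#' upstream of the distal PAS.
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; when given, all files are written
#'   there (BED12, one bedGraph per sample, `samples.tsv`, `truth.tsv`,
#'   `binding.bed`) and the sample sheet's `coverage_path` points at them.
#' @return A list: `config`, `truth` (tibble of per-gene ground truth),
#'   `samples` (sample sheet tibble), `models` (transcript tibble as from
#'   [read_gene_models()]), `coverage` (long tibble as from
#'   [load_coverage()]), `sites` (binding-site tibble), and `paths` when
#'   files were written.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))

  # deterministic effect-class counts in the configured proportions
  n_len <- round(n * cfg$effects[["lengthened"]])
  n_sho <- round(n * cfg$effects[["shortened"]])
  n_null <- n - n_len - n_sho
  effect <- rep(c("lengthened", "shortened", "null"), c(n_len, n_sho, n_null))

  cds_len <- 300
  span <- cfg$utr_length_range[2] + cds_len + 2000

  truth <- purrr::map2(gene_ids, effect, function(gid, eff) {
    with_seed(derive_seed(cfg$seed, paste0("truth|", gid)), {
      L <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]), 1)
      lo_p <- cfg$margin + cfg$read_length
      p_true <- sample(seq(lo_p, L - lo_p), 1)
      d <- switch(eff, lengthened = cfg$effect_size,
                  shortened = -cfg$effect_size, null = 0)
      lo <- max(cfg$base_pdui_range[1], 0.05 - min(d, 0))
      hi <- min(cfg$base_pdui_range[2], 0.95 - max(d, 0))
      base <- stats::runif(1, lo, hi)
      strand <- sample(c("+", "-"), 1)
      tibble(gene_id = gid, effect = eff, utr_length = L, p_true = p_true,
             pdui_ref = base, pdui_alt = base + d, delta_true = d,
             strand = strand)
    })
  }) |> bind_rows()
  truth$depth <- cfg$depth
  truth$read_length <- cfg$read_length
  truth$dispersion <- cfg$dispersion
  truth$seed <- cfg$seed

  # genomic layout: one chromosome, genes spaced well apart
  off <- 1000 + (seq_len(n) - 1) * span
  truth$chrom <- "chrS1"
  plus <- truth$strand == "+"
  truth$tx_start <- off
  truth$tx_end <- off + cds_len + truth$utr_length
  truth$utr_start <- ifelse(plus, off + cds_len, off)
  truth$utr_end <- truth$utr_start + truth$utr_length
  thick_start <- ifelse(plus, off, off + truth$utr_length)
  thick_end <- ifelse(plus, off + cds_len, truth$tx_end)

  models <- tibble(
    transcript_id = paste0(gene_ids, "_tx1"),
    gene_id = gene_ids,
    chrom = truth$chrom, start = truth$tx_start, end = truth$tx_end,
    strand = truth$strand,
    cds_end_3p = ifelse(plus, thick_end, thick_start),
    exon_starts = as.list(truth$tx_start),
    exon_ends = as.list(truth$tx_end))

  samples <- tidyr::expand_grid(
    group = unname(cfg$groups),
    replicate = seq_len(cfg$n_replicates)) |>
    mutate(sample_id = paste0(.data$group, "_rep", .data$replicate),
           total_mapped_reads = cfg$total_mapped_reads,
           coverage_path = NA_character_) |>
    select("sample_id", "group", "total_mapped_reads", "coverage_path")
  samples <- validate_samples(samples)

  coverage <- tidyr::expand_grid(gene_id = gene_ids,
                                 sample_id = samples$sample_id) |>
    left_join(samples[, c("sample_id", "group", "depth_factor")],
              by = "sample_id") |>
    left_join(truth[, c("gene_id", "utr_length", "p_true",
                        "pdui_ref", "pdui_alt")], by = "gene_id")
  is_ref <- coverage$group == cfg$groups[["ref"]]
  coverage$pdui_cond <- ifelse(is_ref, coverage$pdui_ref, coverage$pdui_alt)
  coverage$coverage <- purrr::pmap(
    list(coverage$gene_id, coverage$sample_id, coverage$utr_length,
         coverage$p_true, coverage$pdui_cond),
    function(gid, sid, L, p, pd) {
      simulate_gene(L, p, pd, cfg$depth, cfg$read_length, cfg$dispersion,
                    seed = derive_seed(cfg$seed, paste0(gid, "|", sid)))
    })
  coverage <- coverage |>
    mutate(normalized = FALSE) |>
    select("gene_id", "sample_id", "group", "coverage",
           "depth_factor", "normalized")

  sites <- sim_binding_sites(truth, cfg)

  out <- list(config = cfg, truth = truth, samples = samples,
              models = models, coverage = coverage, sites = sites)
  if (!is.null(outdir)) out$paths <- write_sim_files(out, outdir)
  out
}

# Repressive-geometry binding sites: a 30-nt site whose transcript-3' edge
# lies 25 nt upstream of the distal PAS, for the configured fraction of
# lengthened genes.
sim_binding_sites <- function(truth, cfg) {
  len_genes <- truth[truth$effect == "lengthened", ]
  k <- floor(nrow(len_genes) * cfg$bound_fraction)
  if (k == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character()))
  }
  g <- len_genes[seq_len(k), ]
  plus <- g$strand == "+"
  pas <- ifelse(plus, g$utr_end - 1, g$utr_start)
  start <- ifelse(plus, pas - 54, pas + 25)
  end <- start + 30
  tibble(chrom = g$chrom, start = start, end = end,
         name = paste0("site_", g$gene_id), score = 1000,
         strand = g$strand)
}

write_sim_files <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  plus <- truth$strand == "+"
  bed12 <- data.frame(
    chrom = truth$chrom, start = truth$tx_start, end = truth$tx_end,
    name = paste0(truth$gene_id, "_tx1|", truth$gene_id),
    score = 0L, strand = truth$strand,
    thickStart = ifelse(plus, truth$tx_start, truth$utr_end),
    thickEnd = ifelse(plus, truth$utr_start, truth$tx_end),
    rgb = 0L, blockCount = 1L,
    blockSizes = paste0(truth$tx_end - truth$tx_start, ","),
    blockStarts = "0,")
  anno_path <- file.path(outdir, "annotation.bed")
  utils::write.table(bed12, anno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  cov_paths <- vapply(sim$samples$sample_id, function(sid) {
    path <- file.path(outdir, paste0(sid, ".bedgraph"))
    rows <- sim$coverage[sim$coverage$sample_id == sid, ]
    rows <- rows[match(truth$gene_id, rows$gene_id), ]
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(rows))) {
      v <- rows$coverage[[i]]
      if (truth$strand[i] == "-") v <- rev(v) # genomic orientation
      r <- rle(v)
      ends <- truth$utr_start[i] + cumsum(r$lengths)
      starts <- ends - r$lengths
      nz <- r$values != 0
      if (any(nz)) {
        writeLines(sprintf("%s\t%d\t%d\t%g", truth$chrom[i],
                           starts[nz], ends[nz], r$values[nz]), con)
      }
    }
    path
  }, character(1))

  samples <- sim$samples
  samples$coverage_path <- unname(cov_paths)
  sheet_path <- file.path(outdir, "samples.tsv")
  utils::write.table(
    samples[, c("sample_id", "group", "total_mapped_reads", "coverage_path")],
    sheet_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)

  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(
    truth[, c("gene_id", "effect", "chrom", "strand", "utr_start", "utr_end",
              "utr_length", "p_true", "pdui_ref", "pdui_alt", "delta_true",
              "depth", "read_length", "dispersion", "seed")],
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)

  bed_path <- file.path(outdir, "binding.bed")
  utils::write.table(sim$sites, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  list(annotation = anno_path, sample_sheet = sheet_path,
       truth = truth_path, binding = bed_path, coverage = unname(cov_paths))
}
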