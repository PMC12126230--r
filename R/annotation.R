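#' Read transcript models from a BED12 (or GTF) file
#'
#' Parses transcript gene models into a tibble of transcript records with
#' their exon blocks and the stop-codon-side CDS boundary. Coordinates are
#' 0-based half-open (BED convention) throughout the package; GTF input is
#' converted at this boundary.
#'
#' The BED12 `name` field supplies the transcript id. When it contains a
#' `|`, the second `|`-separated token is taken as the gene id (the
#' convention of refFlat-derived APA annotations, e.g.
#' `NM_001318848|CNPY3|chr6|+`); otherwise the gene id equals the
#' transcript id.
#'
#' @param path Path to an annotation file.
#' @param format `"bed12"` (default) or `"gtf"`. GTF reading requires the
#'   rtracklayer package and uses `exon` and `CDS` features grouped by
#'   `transcript_id`/`gene_id`.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `cds_end_3p` (coordinate of the CDS
#'   boundary on the stop-codon side: `thickEnd` on `+`, `thickStart` on
#'   `-`), and list-columns `exon_starts`, `exon_ends`.
#' @seealso [extract_3utrs()]
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "apascan_error")
  }
  if (format == "gtf") {
    return(read_gene_models_gtf(path))
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) abort("no BED12 records in file", class = "apascan_error")
  recs <- lapply(idx, function(i) parse_bed12_line(lines[[i]], i))
  models <- bind_rows(recs)
  validate_models(models)
  models
}

parse_bed12_line <- function(line, lineno) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) != 12) {
    abort(sprintf("line %d: expected 12 BED fields, found %d", lineno, length(f)),
          class = "apascan_parse_error")
  }
  start <- as.numeric(f[2]); end <- as.numeric(f[3])
  thick_start <- as.numeric(f[7]); thick_end <- as.numeric(f[8])
  n_blocks <- as.integer(f[10])
  sizes <- as.numeric(strsplit(sub(",$", "", f[11]), ",")[[1]])
  offsets <- as.numeric(strsplit(sub(",$", "", f[12]), ",")[[1]])
  if (anyNA(c(start, end, thick_start, thick_end, n_blocks, sizes, offsets))) {
    abort(sprintf("line %d: non-numeric coordinate field", lineno),
          class = "apascan_parse_error")
  }
  if (length(sizes) != n_blocks || length(offsets) != n_blocks) {
    abort(sprintf(
      "line %d: blockSizes/blockStarts inconsistent with blockCount (%d)",
      lineno, n_blocks), class = "apascan_parse_error")
  }
  strand <- f[6]
  check_strand(strand)
  name <- f[4]
  toks <- strsplit(name, "|", fixed = TRUE)[[1]]
  gene_id <- if (length(toks) >= 2) toks[2] else name
  tibble(
    transcript_id = toks[1],
    gene_id = gene_id,
    chrom = f[1],
    start = start, end = end, strand = strand,
    cds_end_3p = if (strand == "+") thick_end else thick_start,
    exon_starts = list(start + offsets),
    exon_ends = list(start + offsets + sizes)
  )
}

read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GTF input requires the rtracklayer package", class = "apascan_error")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), ]
  if (nrow(df) == 0) abort("no exon/CDS features in GTF", class = "apascan_error")
  df$start0 <- df$start - 1 # 1-based inclusive -> 0-based half-open
  split_tx <- split(df, df$transcript_id)
  recs <- lapply(split_tx, function(d) {
    ex <- d[d$type == "exon", ]
    cds <- d[d$type == "CDS", ]
    if (nrow(ex) == 0 || nrow(cds) == 0) return(NULL)
    strand <- as.character(ex$strand[1])
    ord <- order(ex$start0)
    tibble(
      transcript_id = d$transcript_id[1],
      gene_id = if ("gene_id" %in% names(d)) d$gene_id[1] else d$transcript_id[1],
      chrom = as.character(ex$seqnames[1]),
      start = min(ex$start0), end = max(ex$end),
      strand = strand,
      cds_end_3p = if (strand == "+") max(cds$end) else min(cds$start0),
      exon_starts = list(ex$start0[ord]),
      exon_ends = list(ex$end[ord])
    )
  })
  models <- bind_rows(recs)
  validate_models(models)
  models
}

validate_models <- function(models) {
  bad <- models$start < 0 | models$start >= models$end
  if (any(bad)) {
    abort(paste0("invalid transcript interval for: ",
                 paste(models$transcript_id[bad], collapse = ", ")),
          class = "apascan_error")
  }
  check_strand(models$strand)
  ok_cds <- models$cds_end_3p >= models$start & models$cds_end_3p <= models$end
  if (!all(ok_cds)) {
    abort("CDS boundary outside transcript interval", class = "apascan_error")
  }
  ok_ex <- purrr::pmap_lgl(
    list(models$exon_starts, models$exon_ends, models$start, models$end),
    function(s, e, ts, te) {
      all(e > s) && !is.unsorted(s, strictly = TRUE) &&
        all(s >= ts) && all(e <= te) && all(utils::head(e, -1) <= utils::tail(s, -1))
    })
  if (!all(ok_ex)) {
    abort("exon blocks must be sorted, non-overlapping and inside the transcript",
          class = "apascan_error")
  }
  invisible(models)
}

#' Extract one 3' UTR region per gene
#'
#' For each gene the UTR spans from the stop-codon-side CDS boundary of the
#' transcript carrying the most distal transcript end, to that distal end:
#' `[cds_end_3p, max txEnd)` on `+`, `[min txStart, cds_end_3p)` on `-`.
#' When several transcripts attain the distal end, the CDS boundary giving
#' the longest UTR is used. Regions overlapping an exon of a *different*
#' gene are flagged `masked` (intronic overlap is ignored, since it cannot
#' confound exonic coverage).
#'
#' Genes whose UTR would be shorter than `min_utr_length` are skipped with a
#' message: a breakpoint search window must remain after the fitting margins.
#'
#' @param models Transcript tibble from [read_gene_models()].
#' @param min_utr_length Minimum UTR length in nt (default 150).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `distal_end` (equals `end` on `+`, `start` on `-`),
#'   `utr_length`, `source_transcripts` (list-column), `masked`.
#' @examples
#' models <- tibble::tibble(
#'   transcript_id = c("tx1", "tx2"), gene_id = "g1", chrom = "chr1",
#'   start = 100, end = c(900, 1200), strand = "+", cds_end_3p = 700,
#'   exon_starts = list(100, 100), exon_ends = list(900, 1200))
#' extract_3utrs(models)
#' @export
extract_3utrs <- function(models, min_utr_length = 150) {
  stopifnot(nrow(models) > 0, min_utr_length >= 1)
  per_gene <- models |>
    group_by(.data$gene_id) |>
    group_split()
  utrs <- purrr::map(per_gene, function(g) {
    g <- arrange(g, .data$transcript_id) # order-independence
    chrom <- g$chrom[1]; strand <- g$strand[1]
    if (!all(g$chrom == chrom) || !all(g$strand == strand)) {
      abort(paste0("gene ", g$gene_id[1],
                   ": transcripts disagree on chromosome or strand"),
            class = "apascan_error")
    }
    if (strand == "+") {
      distal <- max(g$end)
      cds <- min(g$cds_end_3p[g$end == distal])
      utr_start <- cds; utr_end <- distal
    } else {
      distal <- min(g$start)
      cds <- max(g$cds_end_3p[g$start == distal])
      utr_start <- distal; utr_end <- cds
    }
    tibble(
      gene_id = g$gene_id[1], chrom = chrom,
      start = utr_start, end = utr_end, strand = strand,
      distal_end = distal,
      utr_length = utr_end - utr_start,
      source_transcripts = list(g$transcript_id)
    )
  }) |> bind_rows()

  short <- utrs$utr_length < min_utr_length
  if (any(short)) {
    inform(sprintf("skipping %d gene(s) with 3'UTR < %d nt: %s",
                   sum(short), min_utr_length,
                   paste(utrs$gene_id[short], collapse = ", ")))
    utrs <- utrs[!short, ]
  }
  if (nrow(utrs) == 0) abort("no 3'UTRs pass the length filter", class = "apascan_error")
  utrs$masked <- mask_overlaps(utrs, models)
  arrange(utrs, .data$chrom, .data$start)
}

# TRUE where a UTR shares >=1 base with an exon of a different gene.
mask_overlaps <- function(utrs, models) {
  ex <- tidyr::unnest(
    models[, c("gene_id", "chrom", "exon_starts", "exon_ends")],
    cols = c("exon_starts", "exon_ends"))
  ex_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$exon_starts + 1, ex$exon_ends))
  utr_gr <- GenomicRanges::GRanges(
    utrs$chrom, IRanges::IRanges(utrs$start + 1, utrs$end))
  hits <- GenomicRanges::findOverlaps(utr_gr, ex_gr)
  other <- utrs$gene_id[S4Vectors::queryHits(hits)] !=
    ex$gene_id[S4Vectors::subjectHits(hits)]
  masked <- logical(nrow(utrs))
  masked[unique(S4Vectors::queryHits(hits)[other])] <- TRUE
  masked
}

# Gene body spans (union of transcript intervals per gene), used for
# binding-site categorisation.
gene_spans <- function(models) {
  models |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), strand = .data$strand[1],
              .groups = "drop")
}

#' Write a 3' UTR annotation as BED6 plus extra columns
#'
#' @param utrs UTR tibble from [extract_3utrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_utr_annotation <- function(utrs, path) {
  out <- tibble(
    chrom = utrs$chrom, start = utrs$start, end = utrs$end,
    name = utrs$gene_id, score = 0L, strand = utrs$strand,
    gene_id = utrs$gene_id,
    source_transcripts = purrr::map_chr(utrs$source_transcripts,
                                        paste, collapse = ","),
    masked = utrs$masked)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
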