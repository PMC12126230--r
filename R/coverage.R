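#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `group`,
#' `total_mapped_reads` (the externally computed library size, e.g. the
#' `samtools flagstat` mapped-read count) and `coverage_path`.
#'
#' @param path Path to the TSV.
#' @return A tibble with the four columns above plus `depth_factor`
#'   (`1e6 / total_mapped_reads`, i.e. coverage-per-million scaling).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("sample sheet not found: ", path), class = "apascan_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "total_mapped_reads", "coverage_path")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing, collapse = ", ")),
          class = "apascan_error")
  }
  validate_samples(as_tibble(df))
}

validate_samples <- function(samples) {
  if (any(samples$total_mapped_reads <= 0)) {
    abort("total_mapped_reads must be > 0", class = "apascan_error")
  }
  if (any(!nzchar(samples$group))) {
    abort("group labels must be non-empty", class = "apascan_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in sample sheet", class = "apascan_error")
  }
  samples$depth_factor <- 1e6 / samples$total_mapped_reads
  samples
}

#' Read per-base coverage over UTR regions from a bedGraph file
#'
#' bedGraph intervals are 0-based half-open; `track`/`browser`/comment lines
#' are skipped. Bases not covered by any interval are 0. Minus-strand
#' arrays are reversed so index 1 is the transcript's 5' end.
#'
#' @param path bedGraph file (4 columns, tab- or space-separated).
#' @param regions UTR tibble from [extract_3utrs()].
#' @return A tibble `gene_id`, `coverage` (list-column of numeric vectors of
#'   length `utr_length`, oriented 5'->3' of the transcript).
#' @export
read_bedgraph <- function(path, regions) {
  iv <- parse_bedgraph(path)
  slice_regions(iv, regions)
}

parse_bedgraph <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("coverage file not found: ", path), class = "apascan_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(),
                  end = numeric(), value = numeric()))
  }
  df <- utils::read.table(text = lines[keep], header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (any(df$value < 0)) {
    abort("negative coverage value in bedGraph", class = "apascan_error")
  }
  if (any(df$end <= df$start)) {
    abort("bedGraph interval with end <= start", class = "apascan_error")
  }
  df <- df[order(df$chrom, df$start), ]
  ov <- df$chrom == c(df$chrom[-1], NA) & df$end > c(df$start[-1], NA)
  if (any(ov, na.rm = TRUE)) {
    abort("overlapping bedGraph intervals: coverage is ambiguous",
          class = "apascan_error")
  }
  as_tibble(df)
}

#' Read per-base coverage over UTR regions from a wiggle file
#'
#' Supports `fixedStep` and `variableStep` blocks (with optional `span`);
#' wiggle positions are 1-based and converted to the package's 0-based
#' half-open convention.
#'
#' @inheritParams read_bedgraph
#' @return Same shape as [read_bedgraph()].
#' @export
read_wiggle <- function(path, regions) {
  iv <- parse_wiggle(path)
  slice_regions(iv, regions)
}

parse_wiggle <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("coverage file not found: ", path), class = "apascan_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  mode <- NULL; chrom <- NULL; pos <- NA; step <- 1; span <- 1
  out <- vector("list", length(lines)); n <- 0
  get_attr <- function(line, key, default = NULL) {
    m <- regmatches(line, regexec(paste0(key, "=([^ \t]+)"), line))[[1]]
    if (length(m) == 2) m[2] else default
  }
  for (line in lines) {
    if (grepl("^fixedStep", line)) {
      mode <- "fixed"
      chrom <- get_attr(line, "chrom")
      pos <- as.numeric(get_attr(line, "start"))
      step <- as.numeric(get_attr(line, "step", "1"))
      span <- as.numeric(get_attr(line, "span", "1"))
    } else if (grepl("^variableStep", line)) {
      mode <- "variable"
      chrom <- get_attr(line, "chrom")
      span <- as.numeric(get_attr(line, "span", "1"))
    } else {
      if (is.null(mode)) {
        abort("wiggle data line before any step declaration",
              class = "apascan_parse_error")
      }
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (mode == "fixed") {
        v <- as.numeric(f[1])
        start0 <- pos - 1
        pos <- pos + step
      } else {
        v <- as.numeric(f[2])
        start0 <- as.numeric(f[1]) - 1
      }
      n <- n + 1
      out[[n]] <- list(chrom, start0, start0 + span, v)
    }
  }
  if (n == 0) {
    return(tibble(chrom = character(), start = numeric(),
                  end = numeric(), value = numeric()))
  }
  iv <- tibble(
    chrom = purrr::map_chr(out[seq_len(n)], 1),
    start = purrr::map_dbl(out[seq_len(n)], 2),
    end = purrr::map_dbl(out[seq_len(n)], 3),
    value = purrr::map_dbl(out[seq_len(n)], 4))
  if (any(iv$value < 0)) {
    abort("negative coverage value in wiggle", class = "apascan_error")
  }
  iv[order(iv$chrom, iv$start), ]
}

# Per-base extraction of each region from a sorted interval table.
slice_regions <- function(iv, regions) {
  cov <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end, regions$strand),
    function(chrom, rs, re, strand) {
      arr <- numeric(re - rs)
      sel <- iv$chrom == chrom & iv$start < re & iv$end > rs
      if (any(sel)) {
        sub <- iv[sel, ]
        for (i in seq_len(nrow(sub))) {
          a <- max(sub$start[i], rs) - rs
          b <- min(sub$end[i], re) - rs
          arr[(a + 1):b] <- sub$value[i]
        }
      }
      if (strand == "-") rev(arr) else arr
    })
  tibble(gene_id = regions$gene_id, coverage = cov)
}

#' Load coverage for all samples over all UTR regions
#'
#' Reads each sample's bedGraph (or wiggle, chosen by file extension `.wig`)
#' and returns a long tibble of raw per-base coverage in transcript
#' orientation, one row per gene x sample.
#'
#' @param samples Sample tibble from [read_sample_sheet()].
#' @param regions UTR tibble from [extract_3utrs()].
#' @return A tibble `gene_id`, `sample_id`, `group`, `coverage` (list-column),
#'   `depth_factor`, `normalized` (FALSE).
#' @export
load_coverage <- function(samples, regions) {
  if (!"depth_factor" %in% names(samples)) samples <- validate_samples(samples)
  purrr::pmap(
    list(samples$sample_id, samples$group, samples$coverage_path,
         samples$depth_factor),
    function(sid, grp, path, df) {
      reader <- if (grepl("\\.wig(\\.gz)?$", path)) read_wiggle else read_bedgraph
      cov <- reader(path, regions)
      cov$sample_id <- sid
      cov$group <- grp
      cov$depth_factor <- df
      cov
    }) |>
    bind_rows() |>
    mutate(normalized = FALSE) |>
    select("gene_id", "sample_id", "group", "coverage",
           "depth_factor", "normalized")
}

#' Scale coverage to reads per million mapped reads
#'
#' Multiplies each per-base array by its sample's `depth_factor`
#' (`1e6 / total_mapped_reads`). Depth normalization only affects the
#' expression filter and reported coverage; PDUI is a within-sample ratio
#' and is invariant to it.
#'
#' @param cov_tbl Coverage tibble from [load_coverage()].
#' @return The tibble with scaled arrays and `normalized = TRUE`.
#' @export
normalize_depth <- function(cov_tbl) {
  if (all(cov_tbl$normalized)) return(cov_tbl)
  cov_tbl |>
    mutate(coverage = purrr::map2(.data$coverage, .data$depth_factor,
                                  function(v, f) v * f),
           normalized = TRUE)
}

#' Expression filter on mean normalized coverage
#'
#' A gene passes only when its mean depth-normalized 3'UTR coverage reaches
#' the threshold in *every* sample (boundary inclusive): a breakpoint fit is
#' meaningless for a sample without signal.
#'
#' @param cov_tbl Coverage tibble from [load_coverage()] (raw or normalized).
#' @param min_mean_coverage Threshold in coverage-per-million units
#'   (default 15).
#' @return A tibble `gene_id`, `min_mean` (smallest per-sample mean), `pass`.
#' @export
expression_filter <- function(cov_tbl, min_mean_coverage = 15) {
  normalize_depth(cov_tbl) |>
    group_by(.data$gene_id) |>
    summarise(min_mean = min(purrr::map_dbl(.data$coverage, mean)),
              .groups = "drop") |>
    mutate(pass = .data$min_mean >= min_mean_coverage)
}
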