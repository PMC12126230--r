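#' Fit a de novo proximal poly(A) site by two-segment regression
#'
#' Models each sample's 3'UTR coverage as the superposition of a short
#' isoform (present on bases `[0, P)`) and a long isoform (present on the
#' whole UTR): expected coverage is `w_short + w_long` upstream of the
#' breakpoint `P` and `w_long` downstream. For each candidate `P` the
#' least-squares weights are closed-form segment means,
#' `w_long = mean(values[P:L])` and `w_short = max(0, mean(values[0:P]) -
#' w_long)`; the breakpoint is the candidate minimizing the residual sum of
#' squares summed over *all* samples jointly, so every sample shares one
#' proximal site and ΔPDUI compares like with like. Ties in RSS break
#' toward the most proximal (smallest) `P`. When the non-negativity clamp
#' on `w_short` binds, residuals are recomputed at `w_short = 0`.
#'
#' @param covs Coverage for one gene: a named list of equal-length numeric
#'   vectors (one per sample, transcript-oriented), or a matrix with samples
#'   in rows.
#' @param margin Exclusion zone at each UTR end in nt (default 100);
#'   candidates run over `[margin, L - margin]`.
#' @param stride Candidate spacing in nt (default 1).
#' @param gene_id Optional gene label carried into the result.
#' @return A `bp_fit` object: list with `gene_id`, `P` (breakpoint offset
#'   from the UTR 5' end), `L`, `margin`, `stride`, named vectors `w_long`,
#'   `w_short`, `rss_per_sample` and total `rss`.
#' @examples
#' cov <- c(rep(12, 150), rep(4, 150))
#' fit <- fit_breakpoint(list(s1 = cov), margin = 50)
#' fit$P          # 150
#' compute_pdui(fit)$pdui # 4 / 12
#' @export
fit_breakpoint <- function(covs, margin = 100, stride = 1, gene_id = NA_character_) {
  if (is.matrix(covs)) {
    m <- covs
    if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  } else {
    stopifnot(is.list(covs), length(covs) >= 1)
    lens <- lengths(covs)
    if (length(unique(lens)) != 1) {
      abort("all samples must have equal-length coverage arrays",
            class = "apascan_error")
    }
    m <- do.call(rbind, covs)
    if (is.null(names(covs))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  }
  L <- ncol(m)
  stopifnot(margin >= 1, stride >= 1)
  if (L <= 2 * margin) {
    abort(sprintf("UTR length %d <= 2 * margin (%d): no breakpoint window",
                  L, margin), class = "apascan_skip")
  }
  if (all(m == 0)) {
    abort("all-zero coverage in every sample", class = "apascan_skip")
  }
  p <- seq.int(margin, L - margin, by = stride)

  total_rss <- numeric(length(p))
  w_long <- w_short <- matrix(0, nrow(m), length(p))
  for (s in seq_len(nrow(m))) {
    x <- m[s, ]
    cs <- cumsum(x)
    cq <- cumsum(x^2)
    sum_left <- cs[p]
    sum_right <- cs[L] - cs[p]
    wl <- sum_right / (L - p)
    ws <- pmax(0, sum_left / p - wl)
    mu_left <- ws + wl
    ss_left <- cq[p] - 2 * mu_left * sum_left + p * mu_left^2
    ss_right <- (cq[L] - cq[p]) - 2 * wl * sum_right + (L - p) * wl^2
    total_rss <- total_rss + ss_left + ss_right
    w_long[s, ] <- wl
    w_short[s, ] <- ws
  }
  best <- which.min(total_rss) # first minimum = most proximal candidate
  structure(
    list(gene_id = gene_id,
         P = p[best], L = L, margin = margin, stride = stride,
         w_long = stats::setNames(w_long[, best], rownames(m)),
         w_short = stats::setNames(w_short[, best], rownames(m)),
         rss_per_sample = stats::setNames(
           vapply(seq_len(nrow(m)), function(s) {
             fitted <- ifelse(seq_len(L) <= p[best],
                              w_short[s, best] + w_long[s, best],
                              w_long[s, best])
             sum((m[s, ] - fitted)^2)
           }, numeric(1)), rownames(m)),
         rss = max(0, total_rss[best])),
    class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("<bp_fit> gene %s: P = %d of L = %d nt, %d sample(s), rss = %.4g\n",
              x$gene_id, x$P, x$L, length(x$w_long), x$rss))
  invisible(x)
}

#' Per-sample PDUI from a breakpoint fit
#'
#' PDUI (Percentage of Distal poly(A) site Usage Index) is the long-isoform
#' share of total abundance, `w_long / (w_long + w_short)`, computed per
#' sample. When both weights are zero the PDUI is undefined and returned as
#' `NA` (such gene x sample rows are dropped downstream).
#'
#' @param fit A `bp_fit` from [fit_breakpoint()].
#' @return A tibble `sample_id`, `w_long`, `w_short`, `pdui`.
#' @export
compute_pdui <- function(fit) {
  stopifnot(inherits(fit, "bp_fit"))
  tot <- unname(fit$w_long + fit$w_short)
  tibble(
    sample_id = names(fit$w_long),
    w_long = unname(fit$w_long),
    w_short = unname(fit$w_short),
    pdui = ifelse(tot > 0, unname(fit$w_long) / tot, NA_real_))
}

#' PDUI table for all genes passing the expression filter
#'
#' Runs the full per-gene computation: expression filter, joint breakpoint
#' fit across all samples, and per-sample PDUI. Genes with a UTR too short
#' for the margins, with all-zero coverage, or failing the filter are
#' skipped with a message. Deterministic given inputs and settings.
#'
#' @param utrs UTR tibble from [extract_3utrs()]. Masked regions are
#'   excluded with a message.
#' @param cov_tbl Raw coverage tibble from [load_coverage()].
#' @param margin,stride Breakpoint-search settings, see [fit_breakpoint()].
#' @param min_mean_coverage Expression-filter threshold
#'   (see [expression_filter()]).
#' @return A tibble with one row per gene x sample: `gene_id`, `sample_id`,
#'   `group`, `pdui`, `w_long`, `w_short`, `breakpoint_offset` (nt from the
#'   UTR 5' end), `breakpoint_coord` (genomic), `utr_length`, `chrom`,
#'   `strand`, `utr_start`, `utr_end`, `rss`.
#' @export
pdui_table <- function(utrs, cov_tbl, margin = 100, stride = 1,
                       min_mean_coverage = 15) {
  if (any(utrs$masked)) {
    inform(sprintf("excluding %d masked UTR region(s)", sum(utrs$masked)))
    utrs <- utrs[!utrs$masked, ]
  }
  keep <- expression_filter(
    semi_join(cov_tbl, utrs, by = "gene_id"), min_mean_coverage)
  failed <- keep$gene_id[!keep$pass]
  if (length(failed) > 0) {
    inform(sprintf("%d gene(s) fail the expression filter (min mean < %g)",
                   length(failed), min_mean_coverage))
  }
  utrs <- utrs[utrs$gene_id %in% keep$gene_id[keep$pass], ]
  if (nrow(utrs) == 0) {
    abort("no genes passed filters", class = "apascan_error")
  }
  rows <- purrr::pmap(
    list(utrs$gene_id, utrs$chrom, utrs$strand, utrs$start, utrs$end),
    function(gid, chrom, strand, ustart, uend) {
      g <- cov_tbl[cov_tbl$gene_id == gid, ]
      covs <- stats::setNames(g$coverage, g$sample_id)
      fit <- tryCatch(
        fit_breakpoint(covs, margin = margin, stride = stride, gene_id = gid),
        apascan_skip = function(e) {
          inform(paste0("skipping ", gid, ": ", conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) return(NULL)
      pd <- compute_pdui(fit)
      undef <- is.na(pd$pdui)
      if (any(undef)) {
        inform(sprintf("gene %s: PDUI undefined (zero weights) in sample(s) %s",
                       gid, paste(pd$sample_id[undef], collapse = ", ")))
        pd <- pd[!undef, ]
      }
      if (nrow(pd) == 0) return(NULL)
      bp_coord <- if (strand == "+") ustart + fit$P else uend - fit$P
      pd |>
        mutate(gene_id = gid, chrom = chrom, strand = strand,
               utr_start = ustart, utr_end = uend,
               utr_length = uend - ustart,
               breakpoint_offset = fit$P,
               breakpoint_coord = bp_coord,
               rss = fit$rss)
    }) |> bind_rows()
  if (nrow(rows) == 0) abort("no genes passed filters", class = "apascan_error")
  rows |>
    left_join(distinct(cov_tbl[, c("sample_id", "group")]), by = "sample_id") |>
    select("gene_id", "sample_id", "group", "pdui", "w_long", "w_short",
           "breakpoint_offset", "breakpoint_coord", "utr_length",
           "chrom", "strand", "utr_start", "utr_end", "rss")
}

#' Write a PDUI table as a wide TSV
#'
#' One row per gene with genomic context and one fixed 4-decimal PDUI column
#' per sample.
#'
#' @param pdui_tbl Long tibble from [pdui_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pdui_tsv <- function(pdui_tbl, path) {
  wide <- pdui_tbl |>
    mutate(pdui = sprintf("%.4f", .data$pdui)) |>
    select("gene_id", "chrom", "strand", "utr_start", "utr_end",
           "breakpoint_coord", "sample_id", "pdui") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "pdui",
                       names_prefix = "PDUI_")
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
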