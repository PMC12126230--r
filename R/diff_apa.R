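#' Replicate-averaged PDUI difference between two groups
#'
#' Group PDUIs are unweighted means over replicates;
#' `delta_pdui = mean(alt) - mean(ref)`, so a positive value denotes 3'UTR
#' *lengthening* (more distal poly(A) site usage) under the perturbed
#' condition. Genes quantified in only one group are dropped with a message.
#'
#' @param pdui_tbl Long tibble from [pdui_table()] (needs `gene_id`,
#'   `sample_id`, `group`, `pdui`).
#' @param ref_group,alt_group Group labels: reference (e.g. control) and
#'   perturbed (e.g. knockdown).
#' @return A tibble `gene_id`, `mean_pdui_ref`, `mean_pdui_alt`,
#'   `delta_pdui`, `n_ref`, `n_alt`.
#' @export
delta_pdui <- function(pdui_tbl, ref_group, alt_group) {
  groups <- unique(pdui_tbl$group)
  for (g in c(ref_group, alt_group)) {
    if (!g %in% groups) {
      abort(paste0("group not present in PDUI table: ", g),
            class = "apascan_error")
    }
  }
  means <- pdui_tbl |>
    filter(.data$group %in% c(ref_group, alt_group)) |>
    group_by(.data$gene_id, .data$group) |>
    summarise(mean_pdui = mean(.data$pdui), n = dplyr::n(), .groups = "drop")
  wide <- means |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean_pdui", "n"))
  mr <- paste0("mean_pdui_", ref_group); ma <- paste0("mean_pdui_", alt_group)
  nr <- paste0("n_", ref_group); na_ <- paste0("n_", alt_group)
  incomplete <- is.na(wide[[mr]]) | is.na(wide[[ma]])
  if (any(incomplete)) {
    inform(sprintf("dropping %d gene(s) quantified in only one group",
                   sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  tibble(
    gene_id = wide$gene_id,
    mean_pdui_ref = wide[[mr]],
    mean_pdui_alt = wide[[ma]],
    delta_pdui = wide[[ma]] - wide[[mr]],
    n_ref = wide[[nr]],
    n_alt = wide[[na_]])
}

#' Per-gene differential test on PDUIs
#'
#' With at least two replicates in both groups: two-sided Welch two-sample
#' t-test on per-sample PDUIs. With a single replicate in either group:
#' two-sided Fisher's exact test on the 2x2 table of rounded long/short
#' read mass (isoform weight x segment length) pooled per group. Groups
#' with zero variance and identical values give p = 1; zero-variance groups
#' with different constants (a noiseless edge case where the Welch statistic
#' is undefined) give p = 0.
#'
#' @param pduis_ref,pduis_alt Numeric PDUI vectors per group.
#' @param mass_ref,mass_alt Optional 2-vectors `c(long, short)` of pooled
#'   read mass per group, required for the single-replicate Fisher fallback.
#' @return A single two-sided p-value.
#' @export
test_gene <- function(pduis_ref, pduis_alt, mass_ref = NULL, mass_alt = NULL) {
  stopifnot(length(pduis_ref) >= 1, length(pduis_alt) >= 1)
  if (length(pduis_ref) >= 2 && length(pduis_alt) >= 2) {
    v1 <- stats::var(pduis_ref); v2 <- stats::var(pduis_alt)
    if (v1 == 0 && v2 == 0) {
      return(if (mean(pduis_ref) == mean(pduis_alt)) 1 else 0)
    }
    return(stats::t.test(pduis_alt, pduis_ref, var.equal = FALSE)$p.value)
  }
  if (is.null(mass_ref) || is.null(mass_alt)) {
    abort("single-replicate design: long/short read masses are required",
          class = "apascan_error")
  }
  tab <- matrix(round(c(mass_ref, mass_alt)), nrow = 2)
  if (any(tab < 0)) abort("negative read mass", class = "apascan_error")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_i = min over ranks j >= i of p_(j) * m / j`, capped
#' at 1, with input order preserved (delegates to [stats::p.adjust()] after
#' validation).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "apascan_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify differential-APA results
#'
#' A gene is significant when its (FDR-adjusted, or raw, per `p_mode`)
#' p-value is below `alpha` *and* `|delta_pdui|` reaches `delta_threshold`
#' (inclusive). Direction is assigned from the delta sign alone:
#' `lengthened` when `delta_pdui >= delta_threshold`, `shortened` when
#' `<= -delta_threshold`, otherwise `none`.
#'
#' @param results Tibble with `delta_pdui` and `p_value` columns.
#' @param delta_threshold Absolute ΔPDUI threshold (default 0.1, inclusive).
#' @param alpha Significance level (default 0.05).
#' @param p_mode `"fdr"` (default; gate on BH q-values) or `"raw"` (gate on
#'   unadjusted p-values, the convention used for low-replicate designs).
#' @return `results` with `q_value`, `direction`, `significant` columns.
#' @export
classify <- function(results, delta_threshold = 0.1, alpha = 0.05,
                     p_mode = c("fdr", "raw")) {
  p_mode <- match.arg(p_mode)
  stopifnot(delta_threshold > 0, delta_threshold < 1, alpha > 0, alpha < 1)
  results$q_value <- bh_fdr(results$p_value)
  gate <- if (p_mode == "fdr") results$q_value else results$p_value
  results$direction <- dplyr::case_when(
    results$delta_pdui >= delta_threshold ~ "lengthened",
    results$delta_pdui <= -delta_threshold ~ "shortened",
    TRUE ~ "none")
  results$significant <- gate < alpha & abs(results$delta_pdui) >= delta_threshold
  results
}

#' Differential APA between two conditions
#'
#' Combines [delta_pdui()], the per-gene test ([test_gene()]) and
#' [classify()] into a volcano-ready result table.
#'
#' @inheritParams delta_pdui
#' @inheritParams classify
#' @return An `apa_results` tibble: `gene_id`, `mean_pdui_ref`,
#'   `mean_pdui_alt`, `delta_pdui`, `p_value`, `q_value`, `direction`,
#'   `significant`, plus replicate counts. The call configuration is stored
#'   in attributes `ref_group`, `alt_group`, `config`.
#' @examples
#' pd <- tibble::tibble(
#'   gene_id = rep("g1", 6),
#'   sample_id = paste0("s", 1:6),
#'   group = rep(c("control", "kd"), each = 3),
#'   pdui = c(0.10, 0.12, 0.11, 0.60, 0.58, 0.63),
#'   w_long = 1, w_short = 1, utr_length = 300, breakpoint_offset = 150)
#' diff_apa(pd, "control", "kd")
#' @export
diff_apa <- function(pdui_tbl, ref_group, alt_group,
                     delta_threshold = 0.1, alpha = 0.05,
                     p_mode = c("fdr", "raw")) {
  p_mode <- match.arg(p_mode)
  deltas <- delta_pdui(pdui_tbl, ref_group, alt_group)
  pvals <- purrr::map_dbl(deltas$gene_id, function(gid) {
    g <- pdui_tbl[pdui_tbl$gene_id == gid, ]
    ref <- g[g$group == ref_group, ]
    alt <- g[g$group == alt_group, ]
    test_gene(ref$pdui, alt$pdui,
              mass_ref = pooled_mass(ref), mass_alt = pooled_mass(alt))
  })
  deltas$p_value <- pvals
  out <- classify(deltas, delta_threshold = delta_threshold,
                  alpha = alpha, p_mode = p_mode)
  out <- out[, c("gene_id", "mean_pdui_ref", "mean_pdui_alt", "delta_pdui",
                 "n_ref", "n_alt", "p_value", "q_value", "direction",
                 "significant")]
  structure(out,
            class = c("apa_results", class(out)),
            ref_group = ref_group, alt_group = alt_group,
            config = list(delta_threshold = delta_threshold,
                          alpha = alpha, p_mode = p_mode))
}

# Pooled long/short read mass for the Fisher fallback: long isoform spans
# the whole UTR, short isoform the proximal segment.
pooled_mass <- function(rows) {
  if (!all(c("w_long", "w_short", "utr_length", "breakpoint_offset")
           %in% names(rows))) {
    return(NULL)
  }
  c(long = sum(rows$w_long * rows$utr_length),
    short = sum(rows$w_short * rows$breakpoint_offset))
}

#' Direction summary of significant APA genes
#'
#' Counts and percentages of 3'UTR lengthening vs shortening among
#' significant genes. Percentages are rounded half-away-from-zero to one
#' decimal; the shortened percentage is reported as the complement so the
#' two always sum to 100.
#'
#' @param results An `apa_results` tibble (or any tibble with `direction`
#'   and `significant` columns).
#' @return A one-row tibble: `n_significant`, `n_lengthened`, `n_shortened`,
#'   `pct_lengthened`, `pct_shortened`.
#' @examples
#' res <- tibble::tibble(
#'   direction = rep(c("lengthened", "shortened"), c(460, 198)),
#'   significant = TRUE)
#' summarize_direction(res) # 69.9% lengthened
#' @export
summarize_direction <- function(results) {
  sig <- results[results$significant, ]
  if (nrow(sig) == 0) {
    abort("no significant genes to summarize", class = "apascan_error")
  }
  n <- nrow(sig)
  n_len <- sum(sig$direction == "lengthened")
  n_sho <- sum(sig$direction == "shortened")
  pct_len <- percent_of(n_len, n)
  tibble(n_significant = n, n_lengthened = n_len, n_shortened = n_sho,
         pct_lengthened = pct_len, pct_shortened = 100 - pct_len)
}

#' Write an APA results table as TSV
#'
#' @param results `apa_results` tibble from [diff_apa()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_apa_tsv <- function(results, path) {
  out <- as_tibble(results) |>
    mutate(across(c("mean_pdui_ref", "mean_pdui_alt", "delta_pdui"),
                  function(x) sprintf("%.4f", x)),
           across(c("p_value", "q_value"), function(x) sprintf("%.6g", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
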