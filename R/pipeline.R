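#' Run the full APA analysis pipeline
#'
#' Convenience driver chaining annotation extraction, coverage loading,
#' PDUI estimation and differential-APA calling, with optional binding-site
#' intersection. Accepts file paths or already-loaded tibbles, so it works
#' both on files written by [simulate_dataset()] and on in-memory objects.
#'
#' @param annotation BED12 path or transcript tibble
#'   (see [read_gene_models()]).
#' @param samples Sample-sheet path or tibble (see [read_sample_sheet()]).
#' @param coverage Optional pre-loaded coverage tibble; when `NULL`,
#'   coverage is read from the sample sheet's `coverage_path` files.
#' @param ref_group,alt_group Condition labels; defaults to the two groups
#'   in the sample sheet (reference first by sheet order). Exactly two
#'   groups are required.
#' @param binding Optional BED6 path or site tibble for
#'   [intersect_binding()].
#' @param min_utr_length,margin,stride,min_mean_coverage,delta_threshold,alpha,p_mode
#'   Stage settings, see [extract_3utrs()], [fit_breakpoint()],
#'   [pdui_table()] and [diff_apa()].
#' @param outdir Optional directory for result TSVs (`utr_annotation.tsv`,
#'   `pdui.tsv`, `apa_results.tsv`, `binding_annotation.tsv`) and a
#'   `run_manifest.tsv` echoing the configuration.
#' @return A list: `utrs`, `pdui`, `results` (an `apa_results` tibble),
#'   `direction` (from [summarize_direction()], `NULL` when nothing is
#'   significant), and `binding` when binding sites were supplied.
#' @export
apa_pipeline <- function(annotation, samples, coverage = NULL,
                         ref_group = NULL, alt_group = NULL,
                         binding = NULL, min_utr_length = 150,
                         margin = 100, stride = 1, min_mean_coverage = 15,
                         delta_threshold = 0.1, alpha = 0.05,
                         p_mode = c("fdr", "raw"), outdir = NULL) {
  p_mode <- match.arg(p_mode)
  models <- if (is.character(annotation)) read_gene_models(annotation) else annotation
  smp <- if (is.character(samples)) read_sample_sheet(samples) else validate_samples(samples)
  groups <- unique(smp$group)
  if (length(groups) != 2 && (is.null(ref_group) || is.null(alt_group))) {
    abort("two groups required", class = "apascan_error")
  }
  if (is.null(ref_group)) ref_group <- groups[1]
  if (is.null(alt_group)) alt_group <- setdiff(groups, ref_group)[1]

  utrs <- extract_3utrs(models, min_utr_length = min_utr_length)
  if (is.null(coverage)) coverage <- load_coverage(smp, utrs)
  pdui <- pdui_table(utrs, coverage, margin = margin, stride = stride,
                     min_mean_coverage = min_mean_coverage)
  results <- diff_apa(pdui, ref_group, alt_group,
                      delta_threshold = delta_threshold, alpha = alpha,
                      p_mode = p_mode)
  direction <- if (any(results$significant)) summarize_direction(results) else NULL

  out <- list(utrs = utrs, pdui = pdui, results = results,
              direction = direction)
  if (!is.null(binding)) {
    sites <- if (is.character(binding)) read_bed6(binding) else binding
    apa_genes <- results$gene_id[results$significant]
    if (length(apa_genes) > 0) {
      out$binding <- intersect_binding(apa_genes, utrs, gene_spans(models),
                                       sites)
    }
  }
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir, environment())
  out
}

write_pipeline_outputs <- function(out, outdir, call_env) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_utr_annotation(out$utrs, file.path(outdir, "utr_annotation.tsv"))
  write_pdui_tsv(out$pdui, file.path(outdir, "pdui.tsv"))
  write_apa_tsv(out$results, file.path(outdir, "apa_results.tsv"))
  if (!is.null(out$binding)) {
    utils::write.table(out$binding$genes,
                       file.path(outdir, "binding_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- attr(out$results, "config")
  manifest <- data.frame(
    key = c("package_version", "ref_group", "alt_group", "delta_threshold",
            "alpha", "p_mode", "n_genes_tested", "n_significant"),
    value = c(as.character(utils::packageVersion("apascan")),
              attr(out$results, "ref_group"), attr(out$results, "alt_group"),
              cfg$delta_threshold, cfg$alpha, cfg$p_mode,
              nrow(out$results), sum(out$results$significant)))
  utils::write.table(manifest, file.path(outdir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
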