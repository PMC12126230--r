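#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' Volcano plot of differential-APA results
#'
#' ΔPDUI against -log10 of the gating p-value (FDR q or raw p, matching the
#' call configuration), coloring significant 3'UTR lengthening and
#' shortening.
#'
#' @param object An `apa_results` tibble from [diff_apa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apa_results
#' @export
autoplot.apa_results <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(unclass_results(object))
  df$gate <- if (cfg$p_mode == "fdr") df$q_value else df$p_value
  df$call <- ifelse(df$significant, df$direction, "not significant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_pdui,
                                   y = -log10(pmax(.data$gate, 1e-300)),
                                   color = .data$call)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$delta_threshold,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(
      lengthened = "#c0392b", shortened = "#2e86c1",
      "not significant" = "grey70"), name = NULL) +
    ggplot2::labs(
      x = expression(Delta * "PDUI (perturbed - reference)"),
      y = if (cfg$p_mode == "fdr") expression(-log[10] ~ "FDR q")
          else expression(-log[10] ~ "p")) +
    ggplot2::theme_classic()
}

#' Coverage profile of one gene with its fitted two-segment model
#'
#' Per-base coverage (transcript orientation) for each sample, overlaid
#' with the fitted short+long / long-only step and the inferred proximal
#' poly(A) site.
#'
#' @param covs Named list of per-sample coverage vectors for one gene,
#'   transcript-oriented (as stored in the [load_coverage()] list-column).
#' @param fit The gene's `bp_fit` from [fit_breakpoint()].
#' @return A ggplot object.
#' @export
plot_utr_fit <- function(covs, fit) {
  stopifnot(inherits(fit, "bp_fit"))
  df <- purrr::imap(covs, function(v, sid) {
    tibble(sample_id = sid, pos = seq_along(v), coverage = v)
  }) |> bind_rows()
  fitted <- purrr::imap(covs, function(v, sid) {
    tibble(sample_id = sid, pos = seq_len(fit$L),
           fitted = ifelse(seq_len(fit$L) <= fit$P,
                           fit$w_short[[sid]] + fit$w_long[[sid]],
                           fit$w_long[[sid]]))
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step(color = "grey55", linewidth = 0.3) +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(y = .data$fitted), color = "#c0392b") +
    ggplot2::geom_vline(xintercept = fit$P, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "position in 3'UTR (nt, 5'->3')", y = "coverage",
                  title = sprintf("%s: proximal PAS at %d nt",
                                  fit$gene_id, fit$P)) +
    ggplot2::theme_classic()
}
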