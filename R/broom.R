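#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a breakpoint fit
#'
#' One row per sample with isoform weights and PDUI.
#'
#' @param x A `bp_fit` from [fit_breakpoint()].
#' @param ... Unused.
#' @return A tibble `sample_id`, `w_long`, `w_short`, `pdui`, `rss`.
#' @method tidy bp_fit
#' @export
tidy.bp_fit <- function(x, ...) {
  compute_pdui(x) |>
    mutate(rss = unname(x$rss_per_sample))
}

#' One-row summary of a breakpoint fit
#'
#' @param x A `bp_fit` from [fit_breakpoint()].
#' @param ... Unused.
#' @return A tibble `gene_id`, `breakpoint_offset`, `utr_length`, `margin`,
#'   `n_samples`, `rss`.
#' @method glance bp_fit
#' @export
glance.bp_fit <- function(x, ...) {
  tibble(gene_id = x$gene_id, breakpoint_offset = x$P, utr_length = x$L,
         margin = x$margin, n_samples = length(x$w_long), rss = x$rss)
}

#' Tidy an APA results table
#'
#' @param x An `apa_results` tibble from [diff_apa()].
#' @param ... Unused.
#' @return The results as a plain tibble.
#' @method tidy apa_results
#' @export
tidy.apa_results <- function(x, ...) {
  as_tibble(unclass_results(x))
}

#' One-row summary of a differential-APA analysis
#'
#' @param x An `apa_results` tibble from [diff_apa()].
#' @param ... Unused.
#' @return A tibble with gene counts, significant-call counts by direction,
#'   and the thresholds used.
#' @method glance apa_results
#' @export
glance.apa_results <- function(x, ...) {
  cfg <- attr(x, "config")
  sig <- x$significant
  tibble(
    n_genes = nrow(x),
    n_significant = sum(sig),
    n_lengthened = sum(sig & x$direction == "lengthened"),
    n_shortened = sum(sig & x$direction == "shortened"),
    delta_threshold = cfg$delta_threshold,
    alpha = cfg$alpha,
    p_mode = cfg$p_mode)
}

unclass_results <- function(x) {
  class(x) <- setdiff(class(x), "apa_results")
  attr(x, "config") <- NULL
  attr(x, "ref_group") <- NULL
  attr(x, "alt_group") <- NULL
  x
}
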