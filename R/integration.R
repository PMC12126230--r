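#' Read binding-site intervals from a BED6 file
#'
#' @param path BED6 file of RNA-binding-protein peak calls (e.g. eCLIP).
#' @return A tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path), class = "apascan_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  df <- utils::read.table(text = lines[keep], header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) abort("BED needs at least 3 columns", class = "apascan_error")
  tibble(
    chrom = as.character(df[[1]]), start = df[[2]], end = df[[3]],
    name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_,
    score = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_,
    strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>member...`.
#' @return A tibble `set`, `description`, `genes` (list-column), `size`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path), class = "apascan_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d: need name, description and >=1 member", i),
            class = "apascan_parse_error")
    }
    tibble(set = f[1], description = f[2],
           genes = list(unique(f[-(1:2)])))
  })
  out <- bind_rows(recs)
  out$size <- lengths(out$genes)
  out
}

#' Signed distance from a binding site to a poly(A) site
#'
#' Distance is 0 when the site overlaps the PAS base; otherwise the
#' nearest-edge distance in nt, negative when the site lies transcript-5'
#' (upstream) of the PAS. Binding within 75 nt of a PAS is flagged
#' `proximal` (the zone in which an RNA-binding protein such as TDP-43
#' represses PAS usage; binding further downstream enhances it).
#'
#' @param site_start,site_end Site interval, 0-based half-open (vectorized).
#' @param pas_coord Genomic coordinate of the PAS base.
#' @param strand `"+"` or `"-"` (transcript strand).
#' @return A tibble `distance` (signed nt), `proximal` (`|distance| <= 75`).
#' @examples
#' pas_distance(850, 950, 999, "+") # -50, proximal
#' pas_distance(1079, 1120, 999, "+") # +80, not proximal
#' @export
pas_distance <- function(site_start, site_end, pas_coord, strand) {
  check_strand(strand)
  genomic <- ifelse(
    site_start <= pas_coord & pas_coord < site_end, 0,
    ifelse(site_end <= pas_coord,
           (site_end - 1) - pas_coord,  # site genomic-left of PAS: negative
           site_start - pas_coord))     # site genomic-right of PAS: positive
  d <- ifelse(strand == "-", -genomic, genomic)
  tibble(distance = d, proximal = abs(d) <= 75)
}

#' Intersect APA genes with binding-site intervals
#'
#' Assigns each APA gene its most specific binding category: `utr3` when at
#' least one site overlaps (>= 1 shared base) the gene's 3'UTR region,
#' otherwise `other_region` when a site overlaps the gene body, otherwise
#' `none`. For `utr3` genes the signed distance from the nearest site to
#' the gene's distal PAS is reported along with the 75-nt proximity flag.
#' Sites on chromosomes absent from the annotation are ignored with a
#' warning.
#'
#' @param apa_genes Character vector of APA gene ids.
#' @param utrs UTR tibble from [extract_3utrs()].
#' @param gene_bodies Tibble `gene_id`, `chrom`, `start`, `end`, `strand`
#'   of whole-gene spans (see [read_gene_models()]; transcript spans
#'   suffice).
#' @param sites Binding-site tibble from [read_bed6()].
#' @return A list with `genes` (tibble `gene_id`, `category`,
#'   `min_distance_to_pas`, `proximal_to_pas`) and `summary` (one-row
#'   tibble: `n_genes`, `n_bound`, `n_utr3`, `pct_bound`, `pct_utr3`,
#'   percentages rounded half-away-from-zero to one decimal).
#' @export
intersect_binding <- function(apa_genes, utrs, gene_bodies, sites) {
  stopifnot(length(apa_genes) >= 1)
  known <- union(utrs$chrom, gene_bodies$chrom)
  unknown <- !(sites$chrom %in% known)
  if (any(unknown)) {
    warn(sprintf("ignoring %d binding site(s) on unknown chromosome(s): %s",
                 sum(unknown),
                 paste(unique(sites$chrom[unknown]), collapse = ", ")))
    sites <- sites[!unknown, ]
  }
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$start + 1, sites$end))

  utr_sub <- utrs[utrs$gene_id %in% apa_genes, ]
  utr_gr <- GenomicRanges::GRanges(
    utr_sub$chrom, IRanges::IRanges(utr_sub$start + 1, utr_sub$end))
  utr_hits <- GenomicRanges::findOverlaps(utr_gr, site_gr)

  body_sub <- gene_bodies[gene_bodies$gene_id %in% apa_genes, ]
  body_gr <- GenomicRanges::GRanges(
    body_sub$chrom, IRanges::IRanges(body_sub$start + 1, body_sub$end))
  body_hits <- GenomicRanges::findOverlaps(body_gr, site_gr)

  utr3_genes <- unique(utr_sub$gene_id[S4Vectors::queryHits(utr_hits)])
  body_genes <- unique(body_sub$gene_id[S4Vectors::queryHits(body_hits)])

  ann <- tibble(gene_id = apa_genes) |>
    mutate(category = dplyr::case_when(
      .data$gene_id %in% utr3_genes ~ "utr3",
      .data$gene_id %in% body_genes ~ "other_region",
      TRUE ~ "none"))

  # nearest-site PAS distance for genes with 3'UTR binding
  dist_tbl <- tibble(gene_id = apa_genes,
                     min_distance_to_pas = NA_real_,
                     proximal_to_pas = NA)
  if (length(utr_hits) > 0) {
    hit_df <- tibble(
      gene_id = utr_sub$gene_id[S4Vectors::queryHits(utr_hits)],
      strand = utr_sub$strand[S4Vectors::queryHits(utr_hits)],
      pas = ifelse(utr_sub$strand[S4Vectors::queryHits(utr_hits)] == "+",
                   utr_sub$end[S4Vectors::queryHits(utr_hits)] - 1,
                   utr_sub$start[S4Vectors::queryHits(utr_hits)]),
      s_start = sites$start[S4Vectors::subjectHits(utr_hits)],
      s_end = sites$end[S4Vectors::subjectHits(utr_hits)])
    hd <- pas_distance(hit_df$s_start, hit_df$s_end, hit_df$pas, hit_df$strand)
    hit_df$distance <- hd$distance
    nearest <- hit_df |>
      group_by(.data$gene_id) |>
      summarise(min_distance_to_pas = .data$distance[which.min(abs(.data$distance))],
                .groups = "drop") |>
      mutate(proximal_to_pas = abs(.data$min_distance_to_pas) <= 75)
    dist_tbl <- dist_tbl |>
      select("gene_id") |>
      left_join(nearest, by = "gene_id")
  }
  ann <- left_join(ann, dist_tbl, by = "gene_id")

  n <- nrow(ann)
  n_bound <- sum(ann$category != "none")
  n_utr3 <- sum(ann$category == "utr3")
  list(
    genes = ann,
    summary = tibble(
      n_genes = n, n_bound = n_bound, n_utr3 = n_utr3,
      pct_bound = percent_of(n_bound, n),
      pct_utr3 = percent_of(n_utr3, n)))
}

#' Hypergeometric test for the overlap of two gene sets
#'
#' Upper-tail (enrichment) probability `P[X >= overlap]` for
#' `X ~ Hypergeometric(universe, |A|, |B|)`, the test used for Venn-diagram
#' overlaps. The universe must be supplied explicitly: there is no
#' defensible silent default and it determines the p-value.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Universe size (a count), or a character vector of ids
#'   (sets are then intersected with it).
#' @return A one-row tibble `size_a`, `size_b`, `overlap`, `universe`,
#'   `p_value`.
#' @examples
#' overlap_test(letters[1:3], letters[1:3], 10) # p = 1/120
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (is.character(universe)) {
    universe <- unique(universe)
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
    n <- length(universe)
  } else {
    stopifnot(is.numeric(universe), length(universe) == 1)
    n <- universe
  }
  if (n < length(union(set_a, set_b))) {
    abort("universe smaller than the union of the two sets",
          class = "apascan_error")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), n - length(set_a),
                     length(set_b), lower.tail = FALSE)
  tibble(size_a = length(set_a), size_b = length(set_b),
         overlap = k, universe = n, p_value = p)
}

#' Over-representation test of a query gene set against GMT collections
#'
#' One hypergeometric upper-tail test per collection set
#' (via [overlap_test()]), with Benjamini-Hochberg adjustment across sets.
#'
#' @param query Character vector of query gene ids (non-empty).
#' @param collections GMT tibble from [read_gmt()], or a named list of
#'   character vectors.
#' @param universe Universe size or id vector (see [overlap_test()]).
#' @return A tibble sorted by `q_value`: `set`, `size_a` (query),
#'   `size_b` (set), `overlap`, `universe`, `p_value`, `q_value`.
#' @export
gene_set_enrichment <- function(query, collections, universe) {
  if (length(query) == 0) {
    abort("empty query gene set", class = "apascan_error")
  }
  if (is.list(collections) && !is.data.frame(collections)) {
    collections <- tibble(set = names(collections),
                          description = NA_character_,
                          genes = unname(collections))
  }
  res <- purrr::map2(collections$set, collections$genes, function(nm, members) {
    mutate(overlap_test(query, members, universe), set = nm, .before = 1)
  }) |> bind_rows()
  res$q_value <- bh_fdr(res$p_value)
  arrange(res, .data$q_value, .data$p_value)
}
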