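test_that("PAS distances are signed by transcript orientation with a 75-nt zone", {
  # site ending 50 nt upstream of the PAS: repressive zone
  d <- pas_distance(850, 950, 999, "+")
  expect_equal(d$distance, -50)
  expect_true(d$proximal)
  # overlap
  d <- pas_distance(990, 1010, 999, "+")
  expect_equal(d$distance, 0)
  expect_true(d$proximal)
  # 80 nt downstream: beyond the (inclusive) 75-nt zone
  d <- pas_distance(1079, 1120, 999, "+")
  expect_equal(d$distance, 80)
  expect_false(d$proximal)
  expect_true(pas_distance(1074, 1120, 999, "+")$proximal) # boundary 75
  # strand flip negates the sign (site genomic-right = upstream on -)
  expect_equal(pas_distance(1079, 1120, 999, "-")$distance, -80)
  expect_equal(pas_distance(850, 950, 999, "-")$distance, 50)
})

test_that("binding categories pick the most specific region and summarize fractions", {
  utrs <- make_utrs(c("g1", "g2", "g3"), c(1000, 5000, 9000),
                    c(1400, 5400, 9400), "+")
  bodies <- tibble::tibble(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                           start = c(0, 4000, 8000),
                           end = c(1400, 5400, 9400), strand = "+")
  sites <- tibble::tibble(
    chrom = c("chr1", "chr1", "chrUn"),
    start = c(1100, 4100, 1), end = c(1150, 4200, 50),
    name = "s", score = 0, strand = "+")
  expect_warning(
    res <- intersect_binding(c("g1", "g2", "g3"), utrs, bodies, sites),
    "unknown chromosome")
  expect_equal(res$genes$category, c("utr3", "other_region", "none"))
  expect_equal(res$summary$pct_bound, percent_of(2, 3))
  expect_equal(res$summary$pct_utr3, percent_of(1, 3))
  # distance to the distal PAS (base 1399) from site [1100,1150)
  expect_equal(res$genes$min_distance_to_pas[1], 1149 - 1399)
  expect_false(res$genes$proximal_to_pas[1])
  # no sites at all: everything unbound
  none <- intersect_binding(c("g1", "g2"), utrs, bodies, sites[0, ])
  expect_true(all(none$genes$category == "none"))
  expect_equal(none$summary$pct_bound, 0)
})

test_that("bound fractions are invariant to gene order and close with none to 100%", {
  utrs <- make_utrs(paste0("g", 1:6), seq(1000, 51000, by = 10000),
                    seq(1400, 51400, by = 10000), "+")
  bodies <- dplyr::mutate(utrs[, c("gene_id", "chrom", "start", "end", "strand")],
                          start = start - 500)
  sites <- tibble::tibble(chrom = "chr1",
                          start = utrs$start[c(1, 3)] + 10,
                          end = utrs$start[c(1, 3)] + 40,
                          name = "s", score = 0, strand = "+")
  a <- intersect_binding(paste0("g", 1:6), utrs, bodies, sites)
  b <- intersect_binding(paste0("g", c(4, 2, 6, 1, 3, 5)), utrs, bodies, sites)
  expect_equal(a$summary, b$summary)
  pct_none <- percent_of(sum(a$genes$category == "none"), nrow(a$genes))
  expect_equal(a$summary$pct_bound + pct_none, 100)
})

test_that("overlap tests match direct hypergeometric enumeration", {
  # identical 3-sets in a universe of 10: p = 1 / C(10,3) = 1/120
  r <- overlap_test(letters[1:3], letters[1:3], 10)
  expect_equal(r$overlap, 3)
  expect_equal(r$p_value, 1 / 120, tolerance = 1e-12)
  # hand enumeration of the k >= 4 tail for universe 20, |A|=5, |B|=8
  r <- overlap_test(letters[1:5], letters[2:9], 20)
  expect_equal(r$p_value, 7280 / 125970, tolerance = 1e-12)
  expect_equal(r$p_value, hyper_tail_oracle(4, 5, 8, 20), tolerance = 1e-12)
  # zero overlap has p = 1 under the upper tail
  expect_equal(overlap_test(c("a", "b"), c("x", "y"), 25)$p_value, 1)
  expect_error(overlap_test(letters[1:10], letters[11:20], 15),
               "universe", class = "apascan_error")
  # a character universe restricts the sets
  r <- overlap_test(c("a", "b", "zz"), c("a", "c"), c("a", "b", "c", "d"))
  expect_equal(r$size_a, 2)
  expect_equal(r$overlap, 1)
})

test_that("gene-set enrichment delegates to the overlap test and adjusts across sets", {
  sets <- list(hit = letters[1:5], miss = letters[20:24])
  res <- gene_set_enrichment(letters[1:5], sets, 26)
  expect_equal(res$set[1], "hit")
  expect_equal(res$p_value[res$set == "hit"],
               overlap_test(letters[1:5], letters[1:5], 26)$p_value)
  expect_equal(res$p_value[res$set == "miss"], 1)
  expect_equal(res$q_value, bh_fdr(res$p_value))
  expect_error(gene_set_enrichment(character(0), sets, 26),
               class = "apascan_error")
})

test_that("enrichment p-values are calibrated on random null queries", {
  set.seed(33)
  universe <- sprintf("u%03d", 1:200)
  collections <- lapply(1:20, function(i) sample(universe, 20))
  names(collections) <- paste0("set", 1:20)
  pvals <- unlist(lapply(1:50, function(i) {
    q <- sample(universe, 20)
    gene_set_enrichment(q, collections, universe)$p_value
  }))
  # null p-values must not be enriched for small values
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.4)
})

test_that("GMT files round-trip as set tibbles", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg9"), path)
  g <- read_gmt(path)
  expect_equal(g$set, c("setA", "setB"))
  expect_equal(g$genes[[1]], c("g1", "g2", "g3"))
  expect_equal(g$size, c(3L, 1L))
  writeLines("bad\tonlydesc", path)
  expect_error(read_gmt(path), class = "apascan_parse_error")
})
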