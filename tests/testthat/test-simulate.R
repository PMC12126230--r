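test_that("simulated coverage follows the two-isoform generative model", {
  # all-long limit: near-uniform coverage, fitted short weight ~ 0
  cov <- simulate_gene(600, 300, pdui = 1, depth = 100, read_length = 100,
                       seed = 5)
  f <- fit_breakpoint(list(s = cov))
  expect_lt(unname(f$w_short), 0.05 * unname(f$w_long))
  expect_gt(compute_pdui(f)$pdui, 0.95)

  # zero depth gives an all-zero array
  expect_equal(simulate_gene(600, 300, 0.5, depth = 0, read_length = 100),
               integer(600))

  # pdui 0.5 at depth 200: upstream mean ~ 2x downstream mean
  ratios <- sapply(1:50, function(s) {
    v <- simulate_gene(600, 300, 0.5, depth = 200, read_length = 100, seed = s)
    mean(v[1:300]) / mean(v[421:600]) # past the read-length ramp
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("count noise honours the dispersion parameter", {
  tots <- sapply(1:40, function(s)
    sum(simulate_gene(600, 300, 0.5, depth = 100, read_length = 100,
                      dispersion = 0.5, seed = s)))
  tots_pois <- sapply(1:40, function(s)
    sum(simulate_gene(600, 300, 0.5, depth = 100, read_length = 100,
                      dispersion = 0, seed = s + 1000)))
  expect_gt(var(tots), 3 * var(tots_pois))
})

test_that("datasets are deterministic and written files are byte-identical", {
  cfg <- sim_config(n_genes = 6, n_replicates = 2, seed = 99,
                    utr_length_range = c(600, 800))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, outdir = d1)
  s2 <- simulate_dataset(cfg, outdir = d2)
  expect_equal(s1$truth, s2$truth)
  for (f in c("annotation.bed", "truth.tsv", "binding.bed",
              basename(s1$paths$coverage))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # truth respects the fit margins
  expect_true(all(s1$truth$p_true > cfg$margin &
                  s1$truth$p_true < s1$truth$utr_length - cfg$margin))
})

test_that("a pure-null configuration has zero true effects", {
  cfg <- sim_config(n_genes = 10, effects = c(null = 1, lengthened = 0,
                                              shortened = 0), seed = 3,
                    utr_length_range = c(600, 700))
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$delta_true == 0))
  expect_equal(sim$truth$pdui_ref, sim$truth$pdui_alt)
})

test_that("generated bedGraphs round-trip losslessly through the coverage reader", {
  cfg <- sim_config(n_genes = 5, n_replicates = 1, seed = 12,
                    utr_length_range = c(600, 800))
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, outdir = d)
  utrs <- extract_3utrs(sim$models)
  smp <- read_sample_sheet(sim$paths$sample_sheet)
  loaded <- load_coverage(smp, utrs)
  for (g in sim$truth$gene_id) {
    for (s in smp$sample_id) {
      mem <- sim$coverage$coverage[[which(sim$coverage$gene_id == g &
                                          sim$coverage$sample_id == s)]]
      disk <- loaded$coverage[[which(loaded$gene_id == g &
                                     loaded$sample_id == s)]]
      expect_equal(disk, as.numeric(mem))
    }
  }
})

test_that("binding sites sit within 75 nt upstream of the distal PAS of lengthened genes", {
  cfg <- sim_config(n_genes = 20, seed = 8, bound_fraction = 1,
                    utr_length_range = c(600, 900))
  sim <- simulate_dataset(cfg)
  len_genes <- sim$truth[sim$truth$effect == "lengthened", ]
  expect_equal(nrow(sim$sites), nrow(len_genes))
  for (i in seq_len(nrow(sim$sites))) {
    g <- len_genes[i, ]
    pas <- if (g$strand == "+") g$utr_end - 1 else g$utr_start
    d <- pas_distance(sim$sites$start[i], sim$sites$end[i], pas, g$strand)
    expect_true(d$proximal)
    expect_lt(d$distance, 0) # upstream = repressive side
  }
})

test_that("delta estimates carry no additive bias under the null", {
  # Under true effects the read-length-smoothed breakpoint attenuates
  # |delta| multiplicatively (ramp mass past the fitted breakpoint counts
  # toward the long isoform), so additive unbiasedness is assessed where it
  # is well-posed: genes with no true effect.
  cfg <- sim_config(n_genes = 100, seed = 2024,
                    effects = c(null = 1, lengthened = 0, shortened = 0),
                    utr_length_range = c(600, 1000))
  sim <- simulate_dataset(cfg)
  utrs <- extract_3utrs(sim$models)
  pd <- suppressMessages(pdui_table(utrs, sim$coverage))
  res <- diff_apa(pd, "control", "knockdown")
  err <- res$delta_pdui - sim$truth$delta_true[match(res$gene_id,
                                                     sim$truth$gene_id)]
  # under the null the error distribution is symmetric about 0 by
  # exchangeability of the two groups; a 3-sigma interval keeps the
  # false-alarm rate of this stochastic check negligible
  ci <- mean(err) + c(-3, 3) * sd(err) / sqrt(length(err))
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("a 0.3 PDUI shift at study depth is detected in most genes", {
  cfg <- sim_config(n_genes = 100, seed = 31,
                    effects = c(null = 0, lengthened = 1, shortened = 0),
                    effect_size = 0.3, depth = 100, read_length = 100,
                    utr_length_range = c(600, 1200))
  sim <- simulate_dataset(cfg)
  pd <- suppressMessages(pdui_table(extract_3utrs(sim$models), sim$coverage))
  res <- diff_apa(pd, "control", "knockdown")
  expect_gte(mean(res$significant), 0.8)
})
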