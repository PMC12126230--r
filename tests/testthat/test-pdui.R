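test_that("degenerate coverage shapes give the expected fits", {
  # pure long isoform: constant coverage, tie broken to the most proximal P
  f <- fit_breakpoint(list(s1 = rep(10, 300)))
  expect_equal(f$P, 100)
  expect_equal(unname(f$w_long), 10)
  expect_equal(unname(f$w_short), 0)
  expect_equal(compute_pdui(f)$pdui, 1)

  # pure short isoform
  f <- fit_breakpoint(list(s1 = c(rep(10, 150), rep(0, 150))))
  expect_equal(f$P, 150)
  expect_equal(unname(f$w_long), 0)
  expect_equal(unname(f$w_short), 10)

  # mixed two-level step, rss = 0
  f <- fit_breakpoint(list(s1 = c(rep(12, 150), rep(4, 150))))
  expect_equal(f$P, 150)
  expect_equal(unname(f$w_long), 4)
  expect_equal(unname(f$w_short), 8)
  expect_equal(f$rss, 0)
  expect_equal(compute_pdui(f)$pdui, 1 / 3)
})

test_that("noiseless step coverage is recovered exactly for any breakpoint", {
  for (p0 in c(120, 151, 250, 380)) {
    a <- 7; b <- 3; L <- 500
    x <- a * (seq_len(L) <= p0) + b
    f <- fit_breakpoint(list(s1 = x))
    expect_equal(f$P, p0)
    expect_equal(unname(f$w_long), b)
    expect_equal(unname(f$w_short), a)
    expect_lt(f$rss, 1e-9)
    expect_equal(compute_pdui(f)$pdui, b / (a + b))
  }
})

test_that("fit equals exhaustive search on random multi-sample profiles", {
  set.seed(101)
  for (i in 1:20) {
    L <- sample(210:500, 1)
    n_s <- sample(1:3, 1)
    p0 <- sample(110:(L - 110), 1)
    mat <- t(sapply(seq_len(n_s), function(s) {
      a <- runif(1, 0, 10); b <- runif(1, 0, 10)
      a * (seq_len(L) <= p0) + b + rnorm(L, sd = runif(1, 0, 2))^2
    }))
    f <- fit_breakpoint(mat, margin = 100)
    o <- brute_force_breakpoint(mat, margin = 100)
    expect_equal(f$P, o$P)
    expect_equal(unname(f$w_long), o$w_long, tolerance = 1e-9)
    expect_equal(unname(f$w_short), o$w_short, tolerance = 1e-9)
    # absolute bound scaled to the data: near-zero rss makes relative
    # comparison ill-posed
    expect_lt(abs(f$rss - o$rss), 1e-6 * max(1, o$rss))
  }
})

test_that("PDUI is scale-invariant, bounded, and stable under sample duplication", {
  set.seed(7)
  x <- c(rep(9, 200), rep(3, 200)) + rpois(400, 2)
  y <- c(rep(6, 200), rep(2, 200)) + rpois(400, 2)
  f <- fit_breakpoint(list(s1 = x, s2 = y))
  pd <- compute_pdui(f)
  expect_true(all(pd$pdui >= 0 & pd$pdui <= 1))
  # scaling one sample's coverage by c > 0 leaves its PDUI unchanged
  for (c in c(0.25, 3, 117)) {
    fc <- fit_breakpoint(list(s1 = x * c, s2 = y))
    expect_equal(compute_pdui(fc)$pdui[1], pd$pdui[1], tolerance = 1e-12)
  }
  # joint fitting: duplicating a sample does not change the breakpoint
  fdup <- fit_breakpoint(list(s1 = x, s2 = y, s3 = y))
  expect_equal(fdup$P, f$P)
})

test_that("short UTRs and all-zero coverage are refused with skip conditions", {
  expect_error(fit_breakpoint(list(s1 = rep(1, 150))), "margin",
               class = "apascan_skip")
  expect_error(fit_breakpoint(list(s1 = rep(0, 300))), "all-zero",
               class = "apascan_skip")
  expect_error(fit_breakpoint(list(s1 = rep(1, 100), s2 = rep(1, 99))),
               "equal-length", class = "apascan_error")
})

test_that("pdui_table applies filters, is deterministic, and maps breakpoints to genomic coordinates", {
  x <- c(rep(60, 200), rep(20, 200))
  utrs <- dplyr::bind_rows(
    make_utrs("g1", 1000, 1400, "+"),
    make_utrs("g2", 5000, 5400, "-"),
    make_utrs("g3", 9000, 9400, "+"))
  cov <- make_cov_tbl(
    list(g1 = list(s1 = x, s2 = x),
         g2 = list(s1 = x, s2 = x),
         g3 = list(s1 = x * 0, s2 = x)), # fails filter in s1
    groups = c(s1 = "ctrl", s2 = "kd"))
  expect_message(tab <- pdui_table(utrs, cov), "expression filter")
  expect_setequal(unique(tab$gene_id), c("g1", "g2"))
  # identical coverage gives identical PDUIs across samples
  expect_equal(tab$pdui[tab$gene_id == "g1"][1],
               tab$pdui[tab$gene_id == "g1"][2])
  # genomic breakpoint: + strand counts from utr_start, - strand from utr_end
  expect_equal(unique(tab$breakpoint_coord[tab$gene_id == "g1"]), 1200)
  expect_equal(unique(tab$breakpoint_coord[tab$gene_id == "g2"]), 5200)
  expect_identical(tab, pdui_table(utrs, cov))
  # all genes filtered out is an explicit error
  cov0 <- make_cov_tbl(list(g1 = list(s1 = x * 0, s2 = x * 0)),
                       groups = c(s1 = "ctrl", s2 = "kd"))
  expect_error(suppressMessages(pdui_table(make_utrs("g1", 1000, 1400, "+"), cov0)),
               "no genes passed", class = "apascan_error")
})

test_that("estimated PDUI increases with the true distal fraction", {
  grid <- seq(0.05, 0.95, length.out = 10)
  est <- sapply(seq_along(grid), function(i) {
    covs <- lapply(1:3, function(r) {
      simulate_gene(600, 300, grid[i], depth = 100, read_length = 100,
                    seed = 1000 * i + r)
    })
    mean(compute_pdui(fit_breakpoint(covs))$pdui)
  })
  expect_gt(cor(grid, est, method = "spearman"), 0.95)
})

test_that("tidy and glance expose per-sample weights and fit summaries", {
  f <- fit_breakpoint(list(a = c(rep(12, 150), rep(4, 150)),
                           b = c(rep(6, 150), rep(2, 150))), gene_id = "gX")
  td <- tidy(f)
  expect_equal(td$sample_id, c("a", "b"))
  expect_equal(td$pdui, c(1 / 3, 1 / 3))
  gl <- glance(f)
  expect_equal(gl$breakpoint_offset, 150)
  expect_equal(gl$n_samples, 2)
  expect_equal(gl$rss, 0)
})
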