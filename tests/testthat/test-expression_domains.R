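mk_domains <- function(chrom, start, end) {
  structure(data.frame(domain_id = sprintf("d%03d", seq_along(start)),
                       chrom = chrom, start = start, end = end,
                       size = end - start, bounded = TRUE,
                       stringsAsFactors = FALSE),
            class = c("forum_domains", "data.frame"))
}

mk_expr <- function(chrom, start, value) {
  data.frame(gene_id = sprintf("g%03d", seq_along(start)), chrom = chrom,
             start = start, end = start + 100, value = value,
             stringsAsFactors = FALSE)
}

test_that("per-gene medians follow the mean-of-middles rule", {
  sig <- data.frame(gene_id = c("a", "a", "a", "b", "b"),
                    value = c(1, 5, 9, 1, 3))
  out <- gene_median_expression(sig, transform = "identity")
  expect_equal(out$value[out$gene_id == "a"], 5)
  expect_equal(out$value[out$gene_id == "b"], 2)
  logged <- gene_median_expression(sig)
  expect_equal(logged$value[logged$gene_id == "a"], log2(6))
})

test_that("gene medians match a sort-based oracle over many exon counts", {
  set.seed(60)
  ids <- rep(sprintf("g%02d", 1:30), times = sample(1:9, 30, TRUE))
  sig <- data.frame(gene_id = ids, value = stats::rexp(length(ids), 0.1))
  out <- gene_median_expression(sig, transform = "identity")
  for (g in unique(ids)) {
    v <- sort(sig$value[sig$gene_id == g])
    n <- length(v)
    want <- if (n %% 2) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(out$value[out$gene_id == g], want)
  }
})

test_that("genes with no finite signal are dropped with a warning", {
  sig <- data.frame(gene_id = c("a", "b"), value = c(2, NA))
  expect_warning(out <- gene_median_expression(sig, transform = "identity"),
                 "dropped")
  expect_equal(out$gene_id, "a")
})

test_that("domain activity is classed against the chromosome average", {
  d <- mk_domains("c1", c(0, 1000), c(1000, 2000))
  ex <- mk_expr("c1", c(100, 1100), c(2, 8))
  de <- domain_expression(d, ex)
  expect_equal(de$domains$median_value, c(2, 8))
  expect_equal(unique(de$domains$chrom_average), 5)
  expect_equal(de$domains$class, c("low_or_silent", "active"))
  expect_equal(de$chrom_summary$active_fraction, 0.5)
})

test_that("gene-less domains are silent and excluded from the average", {
  d <- mk_domains("c1", c(0, 1000, 2000), c(1000, 2000, 3000))
  ex <- mk_expr("c1", c(100, 1100), c(2, 8))
  de <- domain_expression(d, ex)
  expect_equal(de$domains$n_genes, c(1L, 1L, 0L))
  expect_equal(de$domains$class[3], "low_or_silent")
  expect_equal(unique(de$chrom_summary$chrom_average), 5)  # 2-gene mean
  sf <- silent_fraction(de)
  expect_equal(sf$pct_low_or_silent, 50)                   # gene-bearing
  sf_all <- silent_fraction(de, gene_bearing_only = FALSE)
  expect_equal(sf_all$pct_low_or_silent, 100 * 2 / 3)
})

test_that("multi-dataset silent fractions recover planted values", {
  set.seed(61)
  d <- mk_domains("c1", seq(0, 99000, 1000), seq(1000, 100000, 1000))
  datasets <- list()
  planted <- c(cells_a = 0.74, cells_b = 0.80, cells_c = 0.86,
               cells_d = 0.92)
  for (nm in names(planted)) {
    active <- stats::runif(100) < (1 - planted[[nm]])
    # active domains well above, silent at floor: classing is then driven
    # by the chromosome mean lying between the two groups
    vals <- ifelse(active, 10 + stats::rnorm(100, 0, 0.1),
                   stats::rnorm(100, 0, 0.1))
    ex <- mk_expr("c1", d$start + 450, vals)
    datasets[[nm]] <- domain_expression(d, ex)
  }
  sf <- silent_fraction(datasets)
  for (nm in names(planted)) {
    got <- sf$pct_low_or_silent[sf$dataset == nm] / 100
    ci <- stats::binom.test(round(100 * planted[[nm]]), 100)$conf.int
    expect_gt(got, ci[1] - 0.01)
    expect_lt(got, ci[2] + 0.01)
  }
})

test_that("all-identical expression gives D = 0 and p = 1", {
  d <- mk_domains("c1", c(0, 1000), c(1000, 2000))
  ex <- mk_expr("c1", c(100, 300, 1100, 1300), rep(4, 4))
  ct <- circular_shift_test(ex, d, reps = 200, seed = 1)
  expect_equal(ct$statistic_observed, 0)
  expect_true(all(ct$null_stats == 0))
  expect_equal(ct$p_value, 1)
})

test_that("exact enumeration reproduces the hand-counted rotation p-value", {
  # 6 genes in 2 domains of 3; values (1,1,1,9,9,9): only rotations 0 and 3
  # keep the blocks aligned, so p = 2/6 under the <= rule
  d <- mk_domains("c1", c(0, 3000), c(3000, 6000))
  ex <- mk_expr("c1", c(200, 1200, 2200, 3200, 4200, 5200),
                c(1, 1, 1, 9, 9, 9))
  ct <- circular_shift_test(ex, d, exact = TRUE)
  expect_equal(ct$p_value, 2 / 6)
  expect_equal(ct$reps, 6L)
  # rotation by offset 0 reproduces the observed statistic
  expect_equal(ct$null_stats[1], ct$statistic_observed)
})

test_that("the statistic ignores a constant shift of all values", {
  d <- mk_domains("c1", c(0, 2000, 4000), c(2000, 4000, 6000))
  set.seed(62)
  pos <- c(100, 700, 1400, 2100, 2800, 4100, 4900, 5600)
  v <- stats::rnorm(8)
  a <- circular_shift_test(mk_expr("c1", pos, v), d, reps = 50, seed = 3)
  b <- circular_shift_test(mk_expr("c1", pos, v + 100), d, reps = 50,
                           seed = 3)
  expect_equal(a$statistic_observed, b$statistic_observed)
  expect_equal(a$null_stats, b$null_stats)
})

test_that("Monte-Carlo and exact enumeration agree on a small instance", {
  d <- mk_domains("c1", c(0, 2500, 5000), c(2500, 5000, 8000))
  set.seed(63)
  pos <- seq(100, 7700, length.out = 9)
  ex <- mk_expr("c1", pos, stats::rnorm(9))
  exact <- circular_shift_test(ex, d, exact = TRUE)
  mc <- circular_shift_test(ex, d, reps = 4000, seed = 5)
  expect_lt(abs(mc$p_value - exact$p_value), 0.05)
})

test_that("the mean-absolute-deviation statistic is accepted", {
  d <- mk_domains("c1", c(0, 2000), c(2000, 4000))
  ex <- mk_expr("c1", c(100, 600, 1200, 2100, 2700, 3300),
                c(1, 2, 3, 7, 8, 9))
  ct <- circular_shift_test(ex, d, reps = 100, seed = 1,
                            statistic = "mad_median")
  expect_gt(ct$statistic_observed, 0)
  expect_lte(ct$p_value, 1)
})

test_that("the test refuses data without a multi-gene domain", {
  d <- mk_domains("c1", c(0, 1000), c(1000, 2000))
  ex <- mk_expr("c1", c(100, 1100), c(1, 2))
  expect_error(circular_shift_test(ex, d, reps = 10, seed = 1),
               "two or more genes")
})

test_that("simulated 30% active domains are recovered in the activity classing", {
  cfg <- sim_config(chrom_lengths = c(c1 = 2e7),
                    hotspot_spacing_median = 5e4,
                    domain_effect_sd = 3, gene_noise_sd = 0.3, seed = 64)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$truth, cfg)
  de <- domain_expression(
    structure(g$truth$domains, class = c("forum_domains", "data.frame")),
    ex)
  frac <- de$chrom_summary$active_fraction
  n <- de$chrom_summary$n_gene_bearing
  # classing against the chromosome mean undercounts weakly active domains,
  # so allow the planted 30% a generous band rather than a binomial CI
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
})
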