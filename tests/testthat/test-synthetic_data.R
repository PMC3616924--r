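test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(read_min_len = 300, read_max_len = 300),
               "read_min_len")
  expect_error(sim_config(frac_active_domains = 1.2), "frac_active")
  expect_error(sim_config(sau3a_spacing_mean = 0), "sau3a_spacing_mean")
})

test_that("hot-spot count matches the spacing model in expectation", {
  # 1 Mb chromosome, spacing median 100 kb, tight log-sd: ~9-10 hot spots
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(chrom_lengths = c(c1 = 1e6),
                      hotspot_spacing_median = 1e5,
                      hotspot_spacing_logsd = 0.1, seed = s)
    nrow(suppressWarnings(simulate_genome(cfg))$truth$hotspots)
  }, 0)
  expect_gt(mean(counts), 8.3)
  expect_lt(mean(counts), 10.5)
})

test_that("true domains tile the gaps between consecutive hot spots", {
  cfg <- sim_config(chrom_lengths = c(c1 = 2e6, c2 = 1e6),
                    hotspot_spacing_median = 5e4, seed = 7)
  tr <- simulate_genome(cfg)$truth
  for (chrom in unique(tr$domains$chrom)) {
    hs <- tr$hotspots$position[tr$hotspots$chrom == chrom]
    d <- tr$domains[tr$domains$chrom == chrom, ]
    expect_equal(d$start, hs[-length(hs)])
    expect_equal(d$end, hs[-1])
  }
  # every gene lies inside exactly one true domain
  for (i in seq_len(nrow(tr$genes))) {
    g <- tr$genes[i, ]
    hits <- which(tr$domains$chrom == g$chrom &
                    tr$domains$start <= g$start & tr$domains$end >= g$end)
    expect_length(hits, 1L)
  }
})

test_that("frac_active_domains = 0 classes every domain silent", {
  cfg <- sim_config(chrom_lengths = c(c1 = 2e6),
                    hotspot_spacing_median = 5e4,
                    frac_active_domains = 0, seed = 3)
  tr <- simulate_genome(cfg)$truth
  expect_true(all(tr$domains$activity == "silent"))
  expect_true(all(tr$domains$baseline == 0))
})

test_that("identical seed gives byte-identical truth and reads", {
  cfg <- sim_config(chrom_lengths = c(c1 = 5e5),
                    hotspot_spacing_median = 4e4, seed = 11)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a, b)
  ra <- simulate_raft_reads(a$genome, a$truth, cfg)
  rb <- simulate_raft_reads(b$genome, b$truth, cfg)
  expect_identical(ra, rb)
  ea <- simulate_expression(a$truth, cfg)
  expect_identical(ea, simulate_expression(b$truth, cfg))
  j1 <- jsonlite::toJSON(unclass(a$truth), digits = NA)
  j2 <- jsonlite::toJSON(unclass(b$truth), digits = NA)
  expect_identical(as.character(j1), as.character(j2))
})

test_that("short chromosomes get zero hot spots with a warning", {
  cfg <- sim_config(chrom_lengths = c(tiny = 5e4, big = 2e6),
                    hotspot_spacing_median = 1e5, seed = 2)
  expect_warning(g <- simulate_genome(cfg), "tiny")
  expect_false("tiny" %in% g$truth$hotspots$chrom)
  expect_true("big" %in% g$truth$hotspots$chrom)
})

test_that("median simulated gap converges to the configured median", {
  cfg <- sim_config(chrom_lengths = c(c1 = 4e7),
                    hotspot_spacing_median = 2e4, seed = 5)
  hs <- simulate_genome(cfg)$truth$hotspots
  gaps <- diff(hs$position)
  expect_gt(length(gaps), 500)
  expect_lt(abs(median(gaps) - 2e4) / 2e4, 0.10)
})

test_that("fragment geometry: cut at one end, Sau3A at the other", {
  sites <- c(9880, 10140)
  left <- forumdomains:::fragment_one_side(10000, "left", sites, 2e4, 300)
  right <- forumdomains:::fragment_one_side(10000, "right", sites, 2e4, 300)
  expect_equal(left[1:2], c(9880, 10000))
  expect_equal(right[1:2], c(10000, 10140))
  expect_equal(left[3], 0)  # not truncated

  # nearest site 400 bp away, max read 300: truncated to 300 from the cut
  far <- forumdomains:::fragment_one_side(10000, "left", c(9600), 2e4, 300)
  expect_equal(far[1:2], c(9700, 10000))
  expect_equal(far[3], 1)
  # brute-force fragment builder agrees on random cases
  set.seed(42)
  for (i in 1:50) {
    s <- sort(sample.int(5000, 8))
    cut <- sample.int(4999, 1)
    for (side in c("left", "right")) {
      got <- forumdomains:::fragment_one_side(cut, side, s, 5000, 120)
      exp <- oracle_fragment(cut, side, s, 5000, 120)
      expect_equal(got[1:2], exp, info = sprintf("cut=%d side=%s", cut, side))
    }
  }
})

test_that("with no background, all cuts sit within 4 jitter SD of the hot spot", {
  cfg <- sim_config(chrom_lengths = c(c1 = 1e5),
                    hotspot_spacing_median = 1e4, cut_jitter_sd = 20,
                    background_break_rate = 0, seed = 13)
  genome <- structure(list(chrom_lengths = c(c1 = 1e5),
                           sau3a = list(c1 = seq(100, 99900, by = 250)),
                           sequences = NULL), class = "raft_genome")
  truth <- structure(list(
    hotspots = data.frame(chrom = "c1", position = 5e4, intensity = 30),
    domains = data.frame(), genes = data.frame()), class = "sim_truth")
  rr <- simulate_raft_reads(genome, truth, cfg)
  cuts <- ifelse(rr$alignments$strand == "+", rr$alignments$start,
                 rr$alignments$end)
  expect_true(all(abs(cuts - 5e4) <= 4 * 20))
})

test_that("truth alignments have the cut at one end and a site at the other", {
  cfg <- sim_config(chrom_lengths = c(c1 = 1e6),
                    hotspot_spacing_median = 5e4, seed = 21)
  g <- simulate_genome(cfg)
  rr <- simulate_raft_reads(g$genome, g$truth, cfg)
  aln <- rr$alignments
  sites <- g$genome$sau3a$c1
  for (i in seq_len(nrow(aln))) {
    if (aln$strand[i] == "+") {        # cut at left end, site at right
      if (aln$score[i] == 0)
        expect_true(aln$end[i] %in% sites || aln$end[i] == 1e6)
      else
        expect_equal(aln$end[i] - aln$start[i], 300)
    } else {                           # cut at right end, site at left
      if (aln$score[i] == 0)
        expect_true(aln$start[i] %in% sites || aln$start[i] == 0)
      else
        expect_equal(aln$end[i] - aln$start[i], 300)
    }
  }
  # read sequences carry the DSB adaptor at the cut (5') end
  ad <- raft_adaptors()
  expect_true(all(startsWith(rr$reads$sequence, ad$dsb)))
  full <- aln$score == 0
  expect_true(all(endsWith(rr$reads$sequence[full], ad$sau3a)))
})

test_that("expression is domain baseline plus gene noise", {
  cfg <- sim_config(chrom_lengths = c(c1 = 3e6),
                    hotspot_spacing_median = 5e4, gene_noise_sd = 0,
                    frac_active_domains = 0.5, seed = 9)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g$truth, cfg)
  # zero noise: every gene equals its domain baseline exactly
  m <- match(ex$gene_id, g$truth$genes$gene_id)
  expect_equal(ex$value, g$truth$genes$true_log_expression[m])

  cfg2 <- sim_config(chrom_lengths = c(c1 = 3e6),
                     hotspot_spacing_median = 5e4, gene_noise_sd = 0.4,
                     seed = 9)
  ex2 <- simulate_expression(g$truth, cfg2)
  resid <- ex2$value - g$truth$genes$true_log_expression[m]
  expect_gt(sd(resid), 0.3)
  expect_lt(sd(resid), 0.5)
})

test_that("active-domain fraction is recovered near its planted value", {
  frac <- vapply(1:30, function(s) {
    cfg <- sim_config(chrom_lengths = c(c1 = 2e6),
                      hotspot_spacing_median = 1e5, seed = s)
    tr <- suppressWarnings(simulate_genome(cfg))$truth
    c(sum(tr$domains$activity == "active"), nrow(tr$domains))
  }, c(0, 0))
  n <- sum(frac[2, ])
  ci <- stats::binom.test(sum(frac[1, ]), n, 0.30)$conf.int
  expect_true(ci[1] <= 0.30 && 0.30 <= ci[2])
})

test_that("empty truth yields an empty expression table with a warning", {
  cfg <- sim_config(chrom_lengths = c(c1 = 1e5),
                    hotspot_spacing_median = 1e5, seed = 1)
  truth <- structure(list(hotspots = data.frame(),
                          domains = data.frame(),
                          genes = data.frame()), class = "sim_truth")
  expect_warning(ex <- simulate_expression(truth, cfg), "no genes")
  expect_equal(nrow(ex), 0L)
})
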