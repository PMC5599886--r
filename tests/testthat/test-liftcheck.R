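test_that("binning follows ceiling arithmetic per chromosome", {
  b <- genome_build("t", "sp", chrom_sizes = c(chr1 = 2500, chr2 = 1000))
  bins <- make_bins(b, 1000)
  expect_equal(bins[bins$chrom == "chr1", "start"], c(0, 1000, 2000))
  expect_equal(bins[bins$chrom == "chr1", "end"], c(1000, 2000, 2500))
  expect_equal(sum(bins$chrom == "chr2"), 1)  # exact division, one bin
  # brute-force enumeration oracle on random toy builds
  set.seed(11)
  for (i in 1:5) {
    sizes <- sample(500:5000, 3)
    names(sizes) <- paste0("chr", 1:3)
    tb <- genome_build("x", "sp", chrom_sizes = sizes)
    s <- sample(c(100, 250, 1000), 1)
    got <- make_bins(tb, s)
    brute <- 0L
    for (L in sizes) { k <- 0; while (k < L) { brute <- brute + 1L; k <- k + s } }
    expect_equal(nrow(got), brute)
    expect_true(all(got$end - got$start <= s & got$end - got$start > 0))
    expect_true(all(got$end <= sizes[got$chrom]))
  }
  expect_error(make_bins(b, 0), class = "buildprov_config_error")
})

test_that("bin distances classify identity, shift and cross-chromosome", {
  src <- list(chrom = "chr1", start = 0, end = 1000)
  same <- list(status = "mapped", chrom = "chr1", start = 0, end = 1000)
  expect_equal(bin_distance(src, same), 0)
  far <- list(status = "mapped", chrom = "chr1", start = 40000, end = 41000)
  expect_equal(bin_distance(src, far), 40000)
  cross <- list(status = "mapped", chrom = "chr9", start = 0, end = 1000)
  expect_identical(bin_distance(src, cross), "cross_chromosome")
  expect_identical(bin_distance(src, list(status = "unmapped")), "failed")
})

test_that("bin statistics tally and conserve", {
  bins <- data.frame(chrom = rep("chr1", 10), start = 0:9 * 1000,
                     end = 1:10 * 1000)
  res <- data.frame(
    status = c("unmapped", rep("mapped", 9)),
    chrom = c(NA, rep("chr1", 9)),
    start = c(NA, 1000, 2000, 50000, 60000, 70000, 4100, 5200, 6300, 9950),
    end = c(NA, 2000, 3000, 51000, 61000, 71000, 5100, 6200, 7300, 10950),
    matched_fraction = c(NA, rep(1, 9)), chain_id = c(NA, rep(1, 9)))
  s <- summarize_bins(bins, res)
  expect_equal(s$n_total, 10)
  expect_equal(s$n_failed, 1)
  expect_equal(s$n_identical, 2)
  expect_equal(s$n_beyond_threshold, 3)
  expect_equal(s$pct_failed, 10)
  expect_equal(s$pct_identical, 20)
  expect_equal(s$pct_beyond_threshold, 30)
  expect_equal(s$pct_erroneous, 80)
  # conservation: failed + mapped = total
  expect_equal(s$n_failed + s$n_mapped, s$n_total)
  expect_equal(sum(s$distance_histogram$count), s$n_mapped)
  expect_error(summarize_bins(bins, res[1:5, ]),
               class = "buildprov_internal_error")
})

test_that("degenerate chains give exact headline percentages", {
  reg <- the_registry
  toyA <- registry_lookup(reg, "toyA")
  # identity chain: every bin identical, nothing erroneous
  idf <- write_tmp(generate_chain(toyA, toyA), ".chain")
  rep1 <- liftcheck("toyA", "toyA", idf, bin_size = 1000, registry = reg)
  expect_equal(rep1$stats$pct_identical, 100)
  expect_equal(rep1$stats$pct_erroneous, 0)
  expect_equal(rep1$stats$n_failed, 0)

  # a +40,000 query shift puts every mapped bin beyond the 30-kb threshold
  tb <- genome_build("shiftT", "sp", chrom_sizes = c(chr1 = 1e6))
  qb <- genome_build("shiftQ", "sp", chrom_sizes = c(chr1 = 1.1e6))
  shf <- write_tmp(generate_chain(tb, qb,
                                  edits = data.frame(chrom = "chr1", pos = 0,
                                                     len = 40000, side = "q")),
                   ".chain")
  rep2 <- liftcheck(tb, qb, shf, bin_size = 1000, registry = reg)
  expect_equal(rep2$stats$n_mapped, rep2$stats$n_total)
  expect_equal(rep2$stats$n_beyond_threshold, rep2$stats$n_total)
  expect_equal(rep2$stats$pct_beyond_threshold, 100)
  expect_equal(rep2$stats$pct_identical, 0)

  # JSON serialization carries both threshold denominators
  out <- tempfile(fileext = ".json")
  write_liftcheck_report(rep2, out, "json")
  back <- jsonlite::fromJSON(out)
  expect_equal(back$pct_beyond_threshold, 100)
  expect_equal(back$pct_beyond_threshold_of_mapped, 100)
  expect_equal(back$n_total, 1000)
})

test_that("final short bins lift with their true length as denominator", {
  tb <- genome_build("shortT", "sp", chrom_sizes = c(chr1 = 2500))
  qb <- genome_build("shortQ", "sp", chrom_sizes = c(chr1 = 2500))
  cs <- chains_from_text(generate_chain(tb, qb))
  bins <- make_bins(tb, 1000)
  res <- lift_intervals(bins, cs)
  expect_equal(res$status, rep("mapped", 3))
  expect_equal(res$matched_fraction, rep(1, 3))
  expect_equal(res$end[3] - res$start[3], 500)
})

test_that("liftcheck agrees with rtracklayer liftOver on an indel chain", {
  skip_if_not_installed("rtracklayer")
  tb <- genome_build("xT", "sp", chrom_sizes = c(chr1 = 50000))
  qb <- genome_build("xQ", "sp", chrom_sizes = c(chr1 = 60000))
  edits <- data.frame(chrom = "chr1", pos = c(10000, 30000),
                      len = c(5000, 200), side = c("q", "t"))
  chf <- write_tmp(generate_chain(tb, qb, edits), ".chain")
  cs <- read_chain(chf)
  ch <- rtracklayer::import.chain(chf)
  set.seed(3)
  for (i in 1:30) {
    s <- sample(0:49000, 1); e <- s + sample(10:800, 1)
    ours <- lift_interval(list(chrom = "chr1", start = s, end = e), cs,
                          min_match = 1e-9)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1, e))
    theirs <- unlist(rtracklayer::liftOver(gr, ch))
    if (ours$status == "mapped" && length(theirs) == 1L) {
      expect_equal(ours$start, GenomicRanges::start(theirs) - 1)
      expect_equal(ours$end, GenomicRanges::end(theirs))
    } else if (ours$status == "split") {
      expect_gt(length(theirs), 1L)
    }
  }
})
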