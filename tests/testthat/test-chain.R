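test_that("chain parsing verifies header and block-sum integrity", {
  cs <- chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1000 + 0 1000 1",
                           "1000"))
  ch <- cs$chains[[1]]
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(ch$t_end - ch$t_start, 1000)
  # hand-traced gap arithmetic: 50 aligned, dt 0, dq 10, then 950 aligned
  cs2 <- chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1010 + 0 1010 1",
                            "50 0 10", "950"))
  expect_equal(cs2$chains[[1]]$blocks$dq, c(10, 0))

  # block sums inconsistent with the header span
  expect_error(
    chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1000 + 0 1000 1",
                       "900")),
    class = "buildprov_chain_integrity_error")
  # truncated chain (no terminal size-only block)
  expect_error(
    chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1010 + 0 1010 1",
                       "50 0 10")),
    regexp = "truncated")
  expect_error(chains_from_text("chain 1 2 3"), regexp = "12")
})

test_that("block-arithmetic lift handles gaps, thresholds and strands", {
  ident <- chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1000 + 0 1000 1",
                              "1000"))
  r <- lift_interval(list(chrom = "tA", start = 10, end = 20), ident)
  expect_identical(r$status, "mapped")
  expect_equal(c(r$start, r$end), c(10, 20))
  expect_equal(r$matched_fraction, 1.0)

  # after a 10-bp query insertion at 50, downstream offsets shift by +10
  gap <- chains_from_text(c("chain 100 tA 1000 + 0 1000 qA 1010 + 0 1010 1",
                            "50 0 10", "950"))
  r2 <- lift_interval(list(chrom = "tA", start = 60, end = 70), gap)
  expect_equal(c(r2$start, r2$end), c(70, 80))
  # an interval straddling the dq gap maps to discontiguous query runs
  expect_identical(lift_interval(list(chrom = "tA", start = 45, end = 55),
                                 gap)$status, "split")

  # a dt gap drops bases: 100 of 1000 unaligned
  del <- chains_from_text(c("chain 100 tA 1100 + 0 1100 qA 1000 + 0 1000 1",
                            "100 100 0", "900"))
  iv <- list(chrom = "tA", start = 0, end = 1000)
  r3 <- lift_interval(iv, del, min_match = 0.85)
  expect_identical(r3$status, "mapped")
  expect_equal(r3$matched_fraction, 0.9)
  expect_equal(c(r3$start, r3$end), c(0, 900))
  expect_identical(lift_interval(iv, del, min_match = 0.95)$status,
                   "partial_below_threshold")

  # minus-strand query coordinates are reflected to the plus strand
  minus <- chains_from_text(c("chain 5 tA 100 + 0 100 qA 200 - 20 120 1",
                              "100"))
  r4 <- lift_interval(list(chrom = "tA", start = 0, end = 10), minus)
  # strand position 20..29 -> plus strand [200-30, 200-20)
  expect_equal(c(r4$start, r4$end), c(170, 180))
  expect_identical(r4$strand, "+")

  expect_identical(lift_interval(list(chrom = "chrZ", start = 0, end = 5),
                                 ident)$status, "unmapped")
  expect_error(lift_interval(list(chrom = "tA", start = 0, end = 5), ident,
                             min_match = 0), class = "buildprov_config_error")
})

test_that("the best overlapping chain wins: score, overlap, then id", {
  two <- chains_from_text(c(
    "chain 900 tA 1000 + 0 500 qA 2000 + 0 500 7",
    "500",
    "",
    "chain 100 tA 1000 + 200 900 qA 2000 + 1000 1700 3",
    "700"))
  hi <- lift_interval(list(chrom = "tA", start = 250, end = 260), two)
  expect_equal(hi$chain_id, 7)          # higher score wins despite overlap
  lo <- lift_interval(list(chrom = "tA", start = 600, end = 610), two)
  expect_equal(lo$chain_id, 3)          # only chain covering the interval
  expect_equal(c(lo$start, lo$end), c(1400, 1410))
})

test_that("identity chains act as the identity on random sub-intervals", {
  reg <- the_registry
  toyA <- registry_lookup(reg, "toyA")
  cs <- chains_from_text(generate_chain(toyA, toyA))
  set.seed(99)
  for (i in 1:50) {
    chrom <- sample(names(toyA$chrom_sizes), 1)
    L <- toyA$chrom_sizes[[chrom]]
    s <- sample(0:(L - 2), 1)
    e <- s + sample(1:(L - s), 1)
    r <- lift_interval(list(chrom = chrom, start = s, end = e), cs)
    expect_identical(r$status, "mapped")
    expect_equal(c(r$start, r$end), c(s, e))
    expect_equal(r$matched_fraction, 1.0)
  }
})

test_that("block arithmetic agrees with the per-base oracle", {
  set.seed(123)
  for (seed in 1:6) {
    txt <- unlist(lapply(1:3, function(k) random_chain_text(seed * 10 + k)))
    cs <- chains_from_text(txt)
    maps <- lapply(cs$chains, oracle_base_map)
    names(maps) <- vapply(cs$chains, function(c) as.character(c$chain_id), "")
    for (i in 1:40) {
      s <- sample(0:19000, 1); e <- s + sample(1:900, 1)
      got <- lift_interval(list(chrom = "chrT", start = s, end = e), cs)
      want <- oracle_lift("chrT", s, e, cs$chains, maps = maps)
      expect_identical(got$status, want$status,
                       info = sprintf("seed %d iv [%d,%d)", seed, s, e))
      if (want$status == "mapped") {
        expect_equal(c(got$start, got$end), c(want$start, want$end),
                     info = sprintf("seed %d iv [%d,%d)", seed, s, e))
        expect_equal(got$matched_fraction, want$matched_fraction)
      }
    }
  }
})

test_that("matched_fraction is conserved under interval partitioning", {
  del <- chains_from_text(c("chain 100 tA 5000 + 0 5000 qA 5000 + 0 5000 1",
                            "1000 500 500", "800 700 700", "2000"))
  set.seed(5)
  for (i in 1:20) {
    s <- sample(0:4000, 1); e <- s + sample(100:900, 1)
    whole <- lift_interval(list(chrom = "tA", start = s, end = e), del,
                           min_match = 0.01)
    cut <- s + sample(seq_len(e - s - 1), 1)
    a <- lift_interval(list(chrom = "tA", start = s, end = cut), del,
                       min_match = 0.01)
    b <- lift_interval(list(chrom = "tA", start = cut, end = e), del,
                       min_match = 0.01)
    fr <- function(x) if (x$status == "unmapped" && is.na(x$matched_fraction))
      0 else x$matched_fraction
    expect_equal(fr(whole) * (e - s),
                 fr(a) * (cut - s) + fr(b) * (e - cut))
  }
})
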