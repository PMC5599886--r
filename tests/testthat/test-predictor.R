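test_that("compatibility scoring tallies bounds per build", {
  reg <- the_registry
  hg19 <- registry_lookup(reg, "hg19")
  hg38 <- registry_lookup(reg, "hg38")

  all_in <- bed_track(rep("chr1", 4), c(0, 10, 500, 900), c(5, 100, 600, 1000))
  expect_equal(score_against_build(all_in, hg19)$score, 1.0)
  expect_equal(score_against_build(all_in, hg38)$score, 1.0)

  # the hg19/hg38 chr1 length gap is discriminative
  edge <- bed_track("chr1", 248960000, 249000000)
  expect_equal(score_against_build(edge, hg38)$n_within_bounds, 0)
  expect_equal(score_against_build(edge, hg19)$n_within_bounds, 1)
  r <- score_against_build(edge, hg19, others = list(hg38))
  expect_equal(r$n_discriminative, 1)

  # unknown chromosome counts in n_records but not n_chrom_known
  sc <- score_against_build(bed_track(c("chr1", "scaffold_77"), c(0, 0),
                                      c(10, 10)), hg19)
  expect_equal(sc$n_records, 2)
  expect_equal(sc$n_chrom_known, 1)

  # tally ordering invariant on random fixtures
  for (seed in 1:5) {
    tr <- generate_track(fixture_spec("hg38", 60, seed = seed,
                                      discriminative_count = 3,
                                      malformed_fraction = 0.05,
                                      candidates = full_builds),
                         registry = reg)
    others <- lapply(setdiff(full_builds, "hg38"), registry_lookup,
                     registry = reg)
    rr <- score_against_build(tr, registry_lookup(reg, "hg38"), others)
    expect_true(rr$n_discriminative <= rr$n_within_bounds)
    expect_true(rr$n_within_bounds <= rr$n_chrom_known)
    expect_true(rr$n_chrom_known <= rr$n_records)
    expect_true(rr$score >= 0 && rr$score <= 1)
  }
  expect_error(score_against_build(bed_track(character(), numeric(),
                                             numeric()), hg19),
               class = "buildprov_empty_input_error")
})

test_that("score equals a brute-force per-record check", {
  reg <- the_registry
  tr <- generate_track(fixture_spec("mm10", 80, seed = 17,
                                    discriminative_count = 2,
                                    candidates = full_builds),
                       registry = reg)
  for (id in full_builds) {
    b <- registry_lookup(reg, id)
    # oracle: literal per-record loop over the size table
    ok <- 0L
    for (i in seq_len(nrow(tr$records))) {
      nm <- tr$records$chrom[i]
      len <- unname(b$chrom_sizes[nm])
      if (is.na(len)) len <- unname(b$chrom_sizes[paste0("chr", nm)])
      if (is.na(len)) len <- unname(b$chrom_sizes[sub("^chr", "", nm)])
      if (!is.na(len) && tr$records$end[i] <= len) ok <- ok + 1L
    }
    expect_equal(score_against_build(tr, b)$n_within_bounds, ok, info = id)
  }
})

test_that("prediction separates unique, ambiguous and incompatible", {
  reg <- the_registry
  # a build-unique interval forces a unique call with evidence
  tr <- generate_track(fixture_spec("hg19", 50, seed = 29,
                                    discriminative_count = 1,
                                    candidates = full_builds),
                       registry = reg)
  p <- predict_build(tr, candidates = full_builds, registry = reg)
  expect_identical(p$status, "unique")
  expect_identical(p$best_builds, "hg19")
  expect_true(nrow(p$evidence) >= 1)
  expect_true(all(p$evidence$source_line >= 1))

  # coordinates shared by every candidate are infeasible to attribute
  amb <- bed_track(paste0("chr", 1:5), rep(0, 5), rep(10000, 5))
  pa <- predict_build(amb, registry = reg)
  expect_identical(pa$status, "ambiguous")
  expect_true(length(pa$best_builds) >= 2)
  expect_true(all(c("hg19", "hg38") %in% pa$best_builds))

  # coordinates beyond every candidate's bounds
  pi <- predict_build(bed_track("chr1", 8e8, 9e8), registry = reg)
  expect_identical(pi$status, "incompatible")
  expect_length(pi$best_builds, 0)

  expect_error(predict_build(amb, candidates = character(), registry = reg),
               class = "buildprov_config_error")
})

test_that("prediction is independent of candidate order and monotone", {
  reg <- the_registry
  tr <- generate_track(fixture_spec("dm6", 40, seed = 31,
                                    discriminative_count = 1,
                                    candidates = full_builds),
                       registry = reg)
  p1 <- predict_build(tr, candidates = full_builds, registry = reg)
  p2 <- predict_build(tr, candidates = rev(full_builds), registry = reg)
  expect_identical(p1$status, p2$status)
  expect_identical(p1$best_builds, p2$best_builds)
  expect_identical(p1$scores, p2$scores)

  # appending an out-of-bounds record never increases a score;
  # appending an in-bounds record never decreases it beyond the 1/n shift
  hg19 <- registry_lookup(reg, "hg19")
  base <- score_against_build(tr, hg19)
  worse <- tr
  worse$records <- rbind(tr$records,
                         data.frame(chrom = "chr1", start = 9e8, end = 9.1e8,
                                    name = NA, score = NA, strand = ".",
                                    extra = "", source_line = 999L))
  s_worse <- score_against_build(worse, hg19)
  expect_lte(s_worse$score, base$score)
  expect_equal(s_worse$n_within_bounds, base$n_within_bounds)
  better <- tr
  better$records <- rbind(tr$records,
                          data.frame(chrom = "chr1", start = 0, end = 10,
                                     name = NA, score = NA, strand = ".",
                                     extra = "", source_line = 999L))
  s_better <- score_against_build(better, hg19)
  expect_equal(s_better$n_within_bounds, base$n_within_bounds + 1)
  expect_gte(s_better$score, base$score * base$n_records / (base$n_records + 1))
})

test_that("min_score gates acceptance", {
  reg <- the_registry
  # half the records are nonsense: score 0.5 falls below the default gate
  tr <- bed_track(c("chr1", "nonsense"), c(0, 0), c(100, 100))
  expect_identical(predict_build(tr, candidates = c("hg19", "hg38"),
                                 registry = reg)$status, "incompatible")
  p <- predict_build(tr, candidates = c("hg19", "hg38"), min_score = 0.4,
                     registry = reg)
  expect_identical(p$status, "ambiguous")
})
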