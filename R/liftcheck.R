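# Quantifying cross-build coordinate incompatibility: segment the source
# build's autosomes and sex chromosomes into fixed-size bins, lift every
# bin through the chain, and summarize how many bins fail, stay identical,
# or land more than a threshold away from where they started.

#' Segment a build into fixed-size bins
#'
#' Per chromosome of the build's primary set (autosomes and sex
#' chromosomes), emits consecutive intervals `[k*s, min((k+1)*s, L))`;
#' the final bin of each chromosome may be short. The bin count per
#' chromosome is `ceiling(L / s)`.
#'
#' @param build A `genome_build`.
#' @param bin_size Bin width in bp (default 1000).
#' @return Data frame of bins: chrom, start, end, in chromosome order.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(make_bins(registry_lookup(reg, "hg19"), 1000))  # 3095689
make_bins <- function(build, bin_size = 1000) {
  stopifnot(inherits(build, "genome_build"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    .err("buildprov_config_error", "bin_size must be a positive number")
  lens <- build$chrom_sizes[build$primary_set]
  counts <- ceiling(lens / bin_size)
  chrom <- rep(names(lens), counts)
  start <- unlist(lapply(counts, function(k) (seq_len(k) - 1) * bin_size),
                  use.names = FALSE)
  end <- pmin(start + bin_size, rep(unname(lens), counts))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Distance between a bin and its lifted image
#'
#' For a mapped same-chromosome bin, the absolute difference of the
#' midpoints (`floor((start + end) / 2)`); a bin mapped to another
#' chromosome is classified `"cross_chromosome"`, and a non-mapped bin
#' `"failed"`.
#'
#' @param src Source interval (list/one-row data frame: chrom, start, end).
#' @param lifted A `lift_result` (or one row of [lift_intervals()] output).
#' @return A number (bp), or the classification string.
#' @export
bin_distance <- function(src, lifted) {
  if (lifted$status != "mapped") return("failed")
  if (!identical(as.character(src$chrom), as.character(lifted$chrom)))
    return("cross_chromosome")
  abs(floor((src$start + src$end) / 2) - floor((lifted$start + lifted$end) / 2))
}

.default_breaks <- c(0, 1, 10, 100, 1000, 10000, 30000, 1e5, 1e6, Inf)

#' Summarize lifted bins
#'
#' Tallies, over one lift result per bin: failed bins (any non-mapped
#' status), identical bins (same chromosome, same start, same end),
#' mapped same-chromosome bins whose midpoints lie more than
#' `far_threshold` apart, and cross-chromosome mappings. The headline
#' percentages are reported over the total bin count; because "further
#' apart than `far_threshold`" can also be read over mapped bins only,
#' both denominators are exposed. The erroneous fraction is
#' `100 * (n_total - n_identical) / n_total`: any bin that does not keep
#' its exact coordinates would be mis-integrated by naive genome
#' arithmetic between the two builds.
#'
#' @param bins Bin table from [make_bins()].
#' @param results Lift results from [lift_intervals()], one row per bin.
#' @param far_threshold Distance threshold in bp (default 30000).
#' @param breaks Distance histogram breaks in bp.
#' @return List of class `bin_stats`.
#' @export
summarize_bins <- function(bins, results, far_threshold = 30000,
                           breaks = .default_breaks) {
  if (nrow(bins) != nrow(results))
    .err("buildprov_internal_error",
         "%d bins but %d lift results", nrow(bins), nrow(results))
  n_total <- nrow(bins)
  mapped <- results$status == "mapped"
  same <- mapped & !is.na(results$chrom) & results$chrom == bins$chrom
  identical_bin <- same & results$start == bins$start & results$end == bins$end
  mid_src <- floor((bins$start + bins$end) / 2)
  mid_q <- floor((results$start + results$end) / 2)
  dist <- ifelse(same, abs(mid_src - mid_q), NA_real_)
  beyond <- same & dist > far_threshold
  n_failed <- sum(!mapped)
  n_identical <- sum(identical_bin)
  n_mapped <- sum(mapped)
  n_cross <- sum(mapped & !same)
  n_beyond <- sum(beyond)
  pct <- function(x, d) if (d > 0) round(100 * x / d, 1) else NA_real_
  hist_counts <- if (any(same)) {
    as.vector(table(cut(dist[same], breaks = breaks, right = FALSE,
                        include.lowest = TRUE)))
  } else rep(0L, length(breaks) - 1L)
  structure(list(
    n_total = n_total,
    n_failed = n_failed,
    n_mapped = n_mapped,
    n_identical = n_identical,
    n_cross_chromosome = n_cross,
    n_beyond_threshold = n_beyond,
    far_threshold = far_threshold,
    pct_failed = pct(n_failed, n_total),
    pct_identical = pct(n_identical, n_total),
    pct_beyond_threshold = pct(n_beyond, n_total),
    pct_beyond_threshold_of_mapped = pct(n_beyond, n_mapped),
    pct_erroneous = pct(n_total - n_identical, n_total),
    distance_histogram = data.frame(
      lower = breaks[-length(breaks)], upper = breaks[-1],
      count = hist_counts)),
    class = "bin_stats")
}

#' @export
print.bin_stats <- function(x, ...) {
  cat(sprintf("<bin_stats> %s bins\n", format(x$n_total, big.mark = ",")))
  cat(sprintf("  failed:      %s (%.1f%%)\n",
              format(x$n_failed, big.mark = ","), x$pct_failed))
  cat(sprintf("  identical:   %s (%.1f%%)\n",
              format(x$n_identical, big.mark = ","), x$pct_identical))
  cat(sprintf("  > %s bp:     %s (%.1f%% of total, %.1f%% of mapped)\n",
              format(x$far_threshold, big.mark = ","),
              format(x$n_beyond_threshold, big.mark = ","),
              x$pct_beyond_threshold, x$pct_beyond_threshold_of_mapped))
  cat(sprintf("  erroneous:   %.1f%%\n", x$pct_erroneous))
  invisible(x)
}

#' Quantify coordinate incompatibility between two builds
#'
#' Bins the source build's primary chromosomes, lifts every bin through
#' the chain set, and summarizes failure/identity/distance statistics.
#'
#' @param from Source build (id/alias, or a `genome_build`).
#' @param to Destination build (id/alias, or a `genome_build`); used to
#'   sanity-check lifted chromosome names.
#' @param chains Path to a chain file, or a `chain_set`.
#' @param bin_size Bin width in bp (default 1000).
#' @param min_match Lift-over minimum-match threshold (default 0.95).
#' @param far_threshold Midpoint-distance threshold in bp (default 30000).
#' @param registry A `build_registry`.
#' @return List of class `liftcheck_report`: from, to, bin_size,
#'   min_match, stats (`bin_stats`), bins, results.
#' @export
liftcheck <- function(from, to, chains, bin_size = 1000, min_match = 0.95,
                      far_threshold = 30000, registry = load_registry()) {
  if (!inherits(from, "genome_build")) from <- registry_lookup(registry, from)
  if (!inherits(to, "genome_build")) to <- registry_lookup(registry, to)
  if (!inherits(chains, "chain_set")) chains <- read_chain(chains)
  bins <- make_bins(from, bin_size)
  results <- lift_intervals(bins, chains, min_match)
  stats <- summarize_bins(bins, results, far_threshold)
  structure(list(from = from$id, to = to$id, bin_size = bin_size,
                 min_match = min_match, stats = stats,
                 bins = bins, results = results),
            class = "liftcheck_report")
}

#' @export
print.liftcheck_report <- function(x, ...) {
  cat(sprintf("<liftcheck_report> %s -> %s, %s-bp bins, min_match %.2f\n",
              x$from, x$to, format(x$bin_size, big.mark = ","), x$min_match))
  print(x$stats)
  invisible(x)
}

#' Serialize a liftcheck report
#'
#' @param report A `liftcheck_report`.
#' @param path Destination path.
#' @param format `"json"` (full statistics incl. histogram) or `"tsv"`
#'   (flat key/value table).
#' @return `path`, invisibly.
#' @export
write_liftcheck_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  s <- report$stats
  flat <- list(from = report$from, to = report$to,
               bin_size = report$bin_size, min_match = report$min_match,
               n_total = s$n_total, n_failed = s$n_failed,
               n_mapped = s$n_mapped, n_identical = s$n_identical,
               n_cross_chromosome = s$n_cross_chromosome,
               n_beyond_threshold = s$n_beyond_threshold,
               far_threshold = s$far_threshold,
               pct_failed = s$pct_failed, pct_identical = s$pct_identical,
               pct_beyond_threshold = s$pct_beyond_threshold,
               pct_beyond_threshold_of_mapped = s$pct_beyond_threshold_of_mapped,
               pct_erroneous = s$pct_erroneous)
  if (format == "json") {
    flat$distance_histogram <- s$distance_histogram
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.table(
      data.frame(key = names(flat),
                 value = vapply(flat, function(v) format(v, scientific = FALSE),
                                "")),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
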