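# Deterministic generators for track files and chain files, so prediction,
# lift-over and audit can be exercised offline. Every generator takes an
# explicit seed and isolates its RNG state; identical specs give
# byte-identical output.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Specify a synthetic track fixture
#'
#' @param build_id Build the intervals are drawn from.
#' @param n_intervals Total number of data lines in the file.
#' @param interval_length Either one number (fixed length, bp) or a
#'   `c(min, max)` range sampled uniformly.
#' @param discriminative_count How many intervals must fall in coordinate
#'   space unique to `build_id` among `candidates` (on a chromosome where
#'   this build strictly exceeds every other candidate's length, with the
#'   interval end beyond the longest other candidate).
#' @param malformed_fraction Share of data lines deliberately broken;
#'   exactly `round(fraction * n_intervals)` lines are corrupted.
#' @param seed Random seed; identical specs (including seed) produce
#'   byte-identical files.
#' @param candidates Build ids the discriminative intervals must rule out;
#'   defaults to all registry builds other than `build_id`.
#' @param chroms Optional restriction of the sampled chromosomes.
#' @param max_end Optional coordinate cap: all non-discriminative
#'   intervals end at or below this, making tracks that are equally
#'   compatible with every build sharing those chromosomes.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(build_id, n_intervals, interval_length = c(100, 1000),
                         discriminative_count = 0L, malformed_fraction = 0,
                         seed = 1L, candidates = NULL, chroms = NULL,
                         max_end = NULL) {
  stopifnot(n_intervals >= 1, discriminative_count >= 0,
            discriminative_count <= n_intervals,
            malformed_fraction >= 0, malformed_fraction < 1,
            length(interval_length) %in% 1:2, all(interval_length >= 1))
  structure(list(build_id = build_id, n_intervals = as.integer(n_intervals),
                 interval_length = interval_length,
                 discriminative_count = as.integer(discriminative_count),
                 malformed_fraction = malformed_fraction,
                 seed = as.integer(seed), candidates = candidates,
                 chroms = chroms, max_end = max_end),
            class = "fixture_spec")
}

# chromosome on which `build` strictly exceeds every other candidate;
# returns list(chrom, floor) where floor is the longest other length
.discriminative_chrom <- function(build, others) {
  for (chrom in names(build$chrom_sizes)) {
    L <- build$chrom_sizes[[chrom]]
    other_max <- 0
    for (o in others) {
      canon <- normalize_chrom(chrom, o)
      if (!is.na(canon)) other_max <- max(other_max, o$chrom_sizes[[canon]])
    }
    if (L > other_max) return(list(chrom = chrom, floor = other_max))
  }
  NULL
}

#' Generate a synthetic track file
#'
#' Draws intervals uniformly within the build's chromosomes (weighted by
#' length), places exactly `discriminative_count` intervals in coordinate
#' space unique to the build among the candidate set, corrupts exactly
#' `round(malformed_fraction * n_intervals)` data lines, and writes the
#' requested format. Reproducible: the same spec yields byte-identical
#' files.
#'
#' @param spec A [fixture_spec()].
#' @param format Track format to emit.
#' @param path Output path (default: a tempfile with matching extension).
#' @param registry A `build_registry`.
#' @return The generated file read back as a `track_file` (with
#'   `max_malformed = 1` so deliberately broken lines are tolerated).
#' @export
generate_track <- function(spec, format = "bed", path = NULL,
                           registry = load_registry()) {
  stopifnot(inherits(spec, "fixture_spec"))
  format <- match.arg(format, .track_formats)
  build <- registry_lookup(registry, spec$build_id)
  cand_ids <- spec$candidates %||% setdiff(registry_ids(registry), build$id)
  others <- lapply(setdiff(cand_ids, build$id), registry_lookup,
                   registry = registry)
  if (is.null(path))
    path <- tempfile(fileext = switch(format, bed = ".bed", gff = ".gff",
                                      wig = ".wig",
                                      narrowPeak = ".narrowPeak",
                                      broadPeak = ".broadPeak"))
  disc_at <- NULL
  if (spec$discriminative_count > 0L) {
    disc_at <- .discriminative_chrom(build, others)
    if (is.null(disc_at))
      .err("buildprov_fixture_error",
           "build '%s' has no chromosome longer than every candidate's; discriminative placement infeasible",
           build$id)
  }

  .with_seed(spec$seed, {
    n <- spec$n_intervals
    draw_len <- function(k) {
      if (length(spec$interval_length) == 1L)
        rep(spec$interval_length, k)
      else
        floor(stats::runif(k, spec$interval_length[1],
                           spec$interval_length[2] + 1))
    }
    pool <- spec$chroms %||%
      (if (length(build$primary_set)) build$primary_set
       else names(build$chrom_sizes))
    lens <- build$chrom_sizes[pool]
    cap <- spec$max_end %||% Inf
    lens <- pmin(lens, cap)
    n_disc <- spec$discriminative_count
    n_reg <- n - n_disc
    chrom <- sample(pool, n_reg, replace = TRUE, prob = lens / sum(lens))
    len <- pmin(draw_len(n_reg), lens[chrom] - 1)
    start <- floor(stats::runif(n_reg) * (lens[chrom] - len))
    recs <- data.frame(chrom = chrom, start = start, end = start + len,
                       stringsAsFactors = FALSE)
    if (n_disc > 0L) {
      L <- build$chrom_sizes[[disc_at$chrom]]
      margin <- L - disc_at$floor
      dend <- disc_at$floor + ceiling(stats::runif(n_disc) * margin)
      dlen <- pmin(draw_len(n_disc), dend)
      recs <- rbind(recs,
                    data.frame(chrom = disc_at$chrom, start = dend - dlen,
                               end = dend, stringsAsFactors = FALSE))
    }
    recs <- recs[sample(nrow(recs)), , drop = FALSE]
    recs$name <- sprintf("iv%d", seq_len(nrow(recs)))
    recs$score <- as.integer(floor(stats::runif(nrow(recs), 0, 1000)))
    recs$strand <- sample(c("+", "-"), nrow(recs), replace = TRUE)
    recs$extra <- switch(format,
      narrowPeak = sprintf("%d\t%.2f\t%.2f\t%d", recs$score,
                           stats::runif(nrow(recs), 0, 10),
                           stats::runif(nrow(recs), 0, 10),
                           as.integer(floor((recs$end - recs$start) / 2))),
      broadPeak = sprintf("%d\t%.2f\t%.2f", recs$score,
                          stats::runif(nrow(recs), 0, 10),
                          stats::runif(nrow(recs), 0, 10)),
      gff = sprintf("buildprov\tregion\t.\tID=iv%d", seq_len(nrow(recs))),
      "")
    if (format == "wig") {
      # one value per interval; order by chrom/start so spans form blocks
      recs <- recs[order(match(recs$chrom, pool), recs$start), , drop = FALSE]
      recs$strand <- "."
    }
    recs$source_line <- seq_len(nrow(recs))  # placeholder, rewritten on read
    # header deliberately names no build: fixtures emulate orphan files
    tr <- track_file(recs, format,
                     header_lines = "# synthetic track fixture",
                     path = path)
    write_track(tr, path)
    n_bad <- round(spec$malformed_fraction * n)
    if (n_bad > 0L) {
      lines <- readLines(path, warn = FALSE)
      data_idx <- which(!.is_header_line(lines) &
                        !grepl("^(fixedStep|variableStep)\\b", lines) &
                        nzchar(lines))
      bad_idx <- sort(sample(data_idx, n_bad))
      lines[bad_idx] <- "chrBAD\tnot_a_number\tnot_a_number"
      writeLines(lines, path)
    }
  })
  read_track(path, format, max_malformed = 1)
}

#' Generate a synthetic chain between two builds
#'
#' Emits one chain per chromosome shared by the two builds. With no edits
#' each chain is the identity map; edits modify it with indels. An edit is
#' a row of `(chrom, pos, len, side)`: `side = "t"` inserts `len` target
#' bases at target position `pos` that are absent from the query (a `dt`
#' gap — downstream query coordinates fall behind), `side = "q"` inserts
#' `len` query bases (a `dq` gap — downstream query coordinates jump
#' ahead). An edit at `pos = 0` offsets the query start, shifting every
#' mapped coordinate. Edits must be ordered and non-overlapping per
#' chromosome.
#'
#' @param t_build Target-side `genome_build` (the build intervals are
#'   lifted *from*).
#' @param q_build Query-side `genome_build` (lifted *to*).
#' @param edits Optional data frame: chrom, pos, len, side.
#' @param base_score Chain score assigned to the longest chain; shorter
#'   chromosomes get proportionally smaller scores.
#' @return Character vector of chain-file lines (write with
#'   `writeLines()`, read with [read_chain()]).
#' @export
generate_chain <- function(t_build, q_build, edits = NULL,
                           base_score = 1e9) {
  stopifnot(inherits(t_build, "genome_build"),
            inherits(q_build, "genome_build"))
  if (!is.null(edits)) {
    stopifnot(all(c("chrom", "pos", "len", "side") %in% names(edits)),
              all(edits$side %in% c("t", "q")), all(edits$len > 0),
              all(edits$pos >= 0))
    for (ch in unique(edits$chrom)) {
      e <- edits[edits$chrom == ch, , drop = FALSE]
      if (is.unsorted(e$pos, strictly = TRUE))
        .err("buildprov_fixture_error",
             "edits on %s must be ordered and non-overlapping", ch)
    }
  }
  shared <- intersect(names(t_build$chrom_sizes), names(q_build$chrom_sizes))
  out <- character()
  cid <- 0L
  for (chrom in shared) {
    cid <- cid + 1L
    t_size <- t_build$chrom_sizes[[chrom]]
    q_size <- q_build$chrom_sizes[[chrom]]
    e <- if (is.null(edits)) NULL
         else edits[edits$chrom == chrom, , drop = FALSE]
    t_start <- 0; q_start <- 0
    size <- numeric(); dt <- numeric(); dq <- numeric()
    t_cur <- 0
    if (!is.null(e)) for (k in seq_len(nrow(e))) {
      if (e$pos[k] == 0 && t_cur == 0) {
        if (e$side[k] == "q") q_start <- q_start + e$len[k]
        else { t_start <- e$len[k]; t_cur <- e$len[k] }
        next
      }
      blk <- e$pos[k] - t_cur
      if (blk <= 0)
        .err("buildprov_fixture_error",
             "edit at %s:%s overlaps the previous edit", chrom,
             format(e$pos[k]))
      size <- c(size, blk)
      if (e$side[k] == "t") { dt <- c(dt, e$len[k]); dq <- c(dq, 0)
        t_cur <- e$pos[k] + e$len[k]
      } else { dt <- c(dt, 0); dq <- c(dq, e$len[k])
        t_cur <- e$pos[k]
      }
    }
    if (t_size - t_cur <= 0)
      .err("buildprov_fixture_error",
           "edits on %s leave no terminal aligned block", chrom)
    size <- c(size, t_size - t_cur)
    dt <- c(dt, 0); dq <- c(dq, 0)
    q_end <- q_start + sum(size + dq)
    if (q_end > q_size)
      .err("buildprov_fixture_error",
           "edits on %s push the query span past its %s-bp chromosome",
           chrom, format(q_size))
    score <- round(base_score * t_size / max(t_build$chrom_sizes))
    header <- sprintf("chain %s %s %s + %s %s %s %s + %s %s %d",
                      format(score, scientific = FALSE), chrom,
                      format(t_size, scientific = FALSE), format(t_start, scientific = FALSE),
                      format(t_size, scientific = FALSE), chrom,
                      format(q_size, scientific = FALSE), format(q_start, scientific = FALSE),
                      format(q_end, scientific = FALSE), cid)
    blocks <- c(paste(format(size[-length(size)], scientific = FALSE, trim = TRUE),
                      format(dt[-length(dt)], scientific = FALSE, trim = TRUE),
                      format(dq[-length(dq)], scientific = FALSE, trim = TRUE)),
                format(size[length(size)], scientific = FALSE, trim = TRUE))
    if (length(size) == 1L) blocks <- format(size, scientific = FALSE, trim = TRUE)
    out <- c(out, header, blocks, "")
  }
  out
}
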