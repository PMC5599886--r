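# Compatibility scoring: a record is compatible with a build when its
# chromosome name resolves in the build's size table and its end does not
# exceed the chromosome length. The score is the fraction of records
# within bounds; ties between builds are broken only by discriminative
# evidence — records valid in one candidate but invalid (out of bounds, or
# on a chromosome the other build lacks) in at least one other.

#' Score a track against one candidate build
#'
#' Each record's chromosome is normalized against the build
#' ([normalize_chrom()]) and its end compared with the chromosome length.
#'
#' @param track A `track_file` with at least one record.
#' @param build A `genome_build`.
#' @param others Optional list of other candidate `genome_build`s used to
#'   count discriminative records (within bounds here, out of bounds or on
#'   an unknown chromosome in at least one of `others`).
#' @return List of class `compat_report`: build_id, n_records,
#'   n_chrom_known, n_within_bounds, n_discriminative, score
#'   (= n_within_bounds / n_records), and `within` / `discriminative`
#'   logical vectors aligned with the records.
#' @export
score_against_build <- function(track, build, others = list()) {
  stopifnot(inherits(track, "track_file"), inherits(build, "genome_build"))
  r <- track$records
  if (nrow(r) == 0L)
    .err("buildprov_empty_input_error", "track has no records to score")
  within_build <- function(b) {
    canon <- normalize_chrom(r$chrom, b)
    known <- !is.na(canon)
    len <- rep(NA_real_, nrow(r))
    len[known] <- b$chrom_sizes[canon[known]]
    within <- known & r$end <= len
    list(known = known, within = within)
  }
  self <- within_build(build)
  disc <- rep(FALSE, nrow(r))
  for (b in others) {
    if (identical(b$id, build$id)) next
    o <- within_build(b)
    disc <- disc | (self$within & !o$within)
  }
  structure(list(
    build_id = build$id,
    n_records = nrow(r),
    n_chrom_known = sum(self$known),
    n_within_bounds = sum(self$within),
    n_discriminative = sum(disc),
    score = sum(self$within) / nrow(r),
    within = self$within,
    discriminative = disc), class = "compat_report")
}

#' @export
print.compat_report <- function(x, ...) {
  cat(sprintf("<compat_report> %s: score %.3f (%d/%d within bounds, %d chrom known, %d discriminative)\n",
              x$build_id, x$score, x$n_within_bounds, x$n_records,
              x$n_chrom_known, x$n_discriminative))
  invisible(x)
}

#' Predict the genome build of an orphan track file
#'
#' Scores the track against every candidate build and calls the build(s)
#' with the maximal score at or above `min_score`. A score tie is broken
#' only by a strictly greater discriminative-record count; remaining ties
#' are reported as `ambiguous` — prediction is infeasible when all input
#' coordinates are equally compatible with two or more builds. When no
#' candidate reaches `min_score` the track is `incompatible` with the
#' registry.
#'
#' @param track A `track_file` (or a path, read with [read_track()]).
#' @param candidates Character vector of build ids/aliases; defaults to
#'   every build in the registry.
#' @param min_score Minimum acceptable within-bounds fraction (default
#'   0.95, leaving the same slack as the reader's malformed-line
#'   tolerance).
#' @param registry A `build_registry`.
#' @param max_evidence Maximum number of discriminative records listed as
#'   evidence for a unique call.
#' @return List of class `build_prediction`: status (`unique`,
#'   `ambiguous` or `incompatible`), best_builds, reports (per candidate),
#'   evidence (data frame of discriminative records with source lines).
#' @export
#' @examples
#' reg <- load_registry()
#' tr <- track_file(data.frame(chrom = "chr1", start = 249000000,
#'                             end = 249100000, name = NA, score = NA,
#'                             strand = ".", extra = "", source_line = 1L),
#'                  "bed")
#' predict_build(tr, candidates = c("hg19", "hg38"), registry = reg)$status
predict_build <- function(track, candidates = NULL, min_score = 0.95,
                          registry = load_registry(), max_evidence = 10L) {
  if (is.character(track) && length(track) == 1L) track <- read_track(track)
  stopifnot(inherits(track, "track_file"))
  if (nrow(track$records) == 0L)
    .err("buildprov_empty_input_error", "track has no records to score")
  if (is.null(candidates)) candidates <- registry_ids(registry)
  if (length(candidates) == 0L)
    .err("buildprov_config_error", "empty candidate set")
  builds <- lapply(candidates, registry_lookup, registry = registry)
  ids <- vapply(builds, `[[`, "", "id")
  if (anyDuplicated(ids))
    .err("buildprov_config_error", "duplicate candidates: %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # canonical candidate order so the outcome is independent of input order
  ord <- order(ids)
  builds <- builds[ord]; ids <- ids[ord]

  reports <- lapply(builds, function(b)
    score_against_build(track, b, others = builds))
  names(reports) <- ids
  scores <- vapply(reports, `[[`, 0, "score")
  ndisc <- vapply(reports, `[[`, 0, "n_discriminative")

  eligible <- scores >= min_score
  if (!any(eligible)) {
    status <- "incompatible"; best <- character()
  } else {
    top <- eligible & scores == max(scores[eligible])
    if (sum(top) > 1L) {
      # tie on score: a strictly greater discriminative count wins
      best_disc <- max(ndisc[top])
      if (sum(top & ndisc == best_disc) == 1L &&
          best_disc > max(ndisc[top][ndisc[top] != best_disc], -Inf)) {
        top <- top & ndisc == best_disc
      }
    }
    best <- ids[top]
    status <- if (length(best) == 1L) "unique" else "ambiguous"
  }

  evidence <- NULL
  if (status == "unique") {
    rep1 <- reports[[best]]
    sel <- which(rep1$discriminative)
    sel <- utils::head(sel, max_evidence)
    evidence <- track$records[sel, c("chrom", "start", "end", "source_line")]
    rownames(evidence) <- NULL
  }
  structure(list(status = status, best_builds = best, reports = reports,
                 scores = scores, min_score = min_score,
                 evidence = evidence),
            class = "build_prediction")
}

#' @export
print.build_prediction <- function(x, ...) {
  cat(sprintf("<build_prediction> status: %s", x$status))
  if (length(x$best_builds))
    cat(" [", paste(x$best_builds, collapse = ", "), "]", sep = "")
  cat("\n  scores:",
      paste(sprintf("%s=%.3f", names(x$scores), x$scores), collapse = " "),
      "\n")
  if (!is.null(x$evidence) && nrow(x$evidence))
    cat(sprintf("  %d discriminative record(s), first at line %d\n",
                nrow(x$evidence), x$evidence$source_line[1]))
  invisible(x)
}
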