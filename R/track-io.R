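# Internal interval representation: one row per record, 0-based half-open
# coordinates regardless of source dialect. `extra` preserves the
# non-coordinate fields verbatim (tab-joined) so writing restores the
# source dialect.

.err <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "buildprov_error")))
}

.track_formats <- c("bed", "gff", "wig", "narrowPeak", "broadPeak")

.empty_records <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             extra = character(), source_line = integer(),
             stringsAsFactors = FALSE)
}

.empty_malformed <- function() {
  data.frame(line = integer(), text = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' Construct a track file object
#'
#' @param records Data frame with columns chrom, start, end, name, score,
#'   strand, extra, source_line; coordinates 0-based half-open.
#' @param format One of `"bed"`, `"gff"`, `"wig"`, `"narrowPeak"`,
#'   `"broadPeak"`.
#' @param header_lines Character vector of leading comment/track/browser
#'   lines, kept verbatim.
#' @param path Source or destination path (may be `NA`).
#' @param malformed Data frame of rejected lines (line, text, reason).
#' @return An object of class `track_file`.
#' @export
track_file <- function(records, format, header_lines = character(),
                       path = NA_character_, malformed = .empty_malformed()) {
  format <- match.arg(format, .track_formats)
  if (nrow(records) > 0L) {
    stopifnot(all(records$start >= 0), all(records$start < records$end),
              all(records$source_line >= 1L))
  }
  structure(list(path = path, format = format,
                 header_lines = header_lines,
                 records = records, malformed = malformed),
            class = "track_file")
}

#' @export
print.track_file <- function(x, ...) {
  cat(sprintf("<track_file> %s format=%s: %d records, %d header lines",
              if (is.na(x$path)) "<in memory>" else basename(x$path),
              x$format, nrow(x$records), length(x$header_lines)))
  if (nrow(x$malformed)) cat(sprintf(", %d malformed", nrow(x$malformed)))
  cat("\n")
  invisible(x)
}

.is_header_line <- function(line) {
  grepl("^\\s*#", line) | grepl("^(track|browser)([ \t]|$)", line)
}

#' Detect the format of a track file
#'
#' Uses the file extension when recognised (`.bed`, `.gff`/`.gff3`/`.gtf`,
#' `.wig`, `.narrowPeak`, `.broadPeak`), otherwise sniffs the first data
#' lines.
#'
#' @param path File path.
#' @param lines Optional pre-read lines (avoids a second read).
#' @return Format string.
#' @export
detect_format <- function(path, lines = NULL) {
  ext <- tolower(tools::file_ext(path))
  known <- c(bed = "bed", gff = "gff", gff3 = "gff", gtf = "gff",
             wig = "wig", narrowpeak = "narrowPeak", broadpeak = "broadPeak")
  if (ext %in% names(known)) return(unname(known[ext]))
  if (is.null(lines)) lines <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("^##gff-version", lines))) return("gff")
  if (any(grepl("^(fixedStep|variableStep)\\b", lines))) return("wig")
  data <- lines[!.is_header_line(lines) & nzchar(trimws(lines))]
  if (length(data)) {
    f <- strsplit(data[1], "\t", fixed = TRUE)[[1]]
    num <- function(i) !is.na(suppressWarnings(as.numeric(f[i])))
    if (length(f) == 9L && num(4) && num(5) && !num(1)) return("gff")
    if (length(f) >= 10L && num(2) && num(3)) return("narrowPeak")
    if (length(f) >= 3L && num(2) && num(3)) return("bed")
  }
  .err("buildprov_format_error", "cannot detect track format of '%s'", path)
}

#' Read a genomic track file
#'
#' Normalizes all supported dialects to 0-based half-open intervals:
#' BED/narrowPeak/broadPeak are taken as-is, GFF (1-based inclusive) has
#' its starts shifted down by one, and WIG fixedStep/variableStep blocks
#' are expanded to one interval per value honouring `step` and `span`.
#' Leading `#`, `track` and `browser` lines are captured as header lines.
#' Data lines that do not parse are collected (with their line numbers)
#' rather than silently dropped; a file whose malformed fraction exceeds
#' `max_malformed` raises a strictness error, mirroring how build
#' prediction must fail on files that do not adhere to the format
#' specification.
#'
#' @param path File path.
#' @param format Optional format override; auto-detected when `NULL`.
#' @param max_malformed Maximum tolerated fraction of malformed data lines
#'   (default 0.05).
#' @param strict If `TRUE`, any malformed line is an error
#'   (`max_malformed = 0`).
#' @return A `track_file`.
#' @export
read_track <- function(path, format = NULL, max_malformed = 0.05,
                       strict = FALSE) {
  if (!file.exists(path)) .err("buildprov_io_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(format)) format <- detect_format(path, lines)
  format <- match.arg(format, .track_formats)

  is_head <- .is_header_line(lines)
  n_head <- 0L
  while (n_head < length(lines) && is_head[n_head + 1L]) n_head <- n_head + 1L
  # WIG declaration lines are structure, not header
  if (format == "wig" && n_head > 0L) {
    decl <- grepl("^(fixedStep|variableStep)\\b", lines[seq_len(n_head)])
    if (any(decl)) n_head <- min(which(decl)) - 1L
  }
  header <- if (n_head) lines[seq_len(n_head)] else character()
  body_idx <- if (n_head < length(lines)) (n_head + 1L):length(lines) else integer()

  parsed <- switch(format,
    bed        = .parse_bed(lines, body_idx, min_fields = 3L),
    narrowPeak = .parse_bed(lines, body_idx, min_fields = 10L),
    broadPeak  = .parse_bed(lines, body_idx, min_fields = 9L),
    gff        = .parse_gff(lines, body_idx),
    wig        = .parse_wig(lines, body_idx))

  n_data <- parsed$n_data
  if (n_data > 0L) {
    frac <- nrow(parsed$malformed) / n_data
    limit <- if (strict) 0 else max_malformed
    if (frac > limit)
      .err("buildprov_strictness_error",
           "%d of %d data lines (%.1f%%) in '%s' do not adhere to the %s specification (limit %.1f%%)",
           nrow(parsed$malformed), n_data, 100 * frac, path, format,
           100 * limit)
  }
  track_file(parsed$records, format, header, path, parsed$malformed)
}

.split_fields <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) strsplit(line, "\t", fixed = TRUE)[[1]]
  else strsplit(trimws(line), "[ \t]+")[[1]]
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

.parse_bed <- function(lines, idx, min_fields) {
  recs <- list(); bad <- list(); n_data <- 0L
  for (i in idx) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (.is_header_line(line)) next     # mid-file comments tolerated
    n_data <- n_data + 1L
    f <- .split_fields(line)
    reason <- NULL
    s <- .num_or_na(f[2]); e <- .num_or_na(f[3])
    if (length(f) < min_fields)
      reason <- sprintf("expected >= %d fields, got %d", min_fields, length(f))
    else if (is.na(s) || is.na(e)) reason <- "non-numeric coordinates"
    else if (s < 0)                reason <- "negative start"
    else if (s >= e)               reason <- "start not less than end"
    if (!is.null(reason)) {
      bad[[length(bad) + 1L]] <- list(i, line, reason); next
    }
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-", ".")) f[6] else "."
    recs[[length(recs) + 1L]] <- list(
      chrom = f[1], start = s, end = e,
      name = if (length(f) >= 4L) f[4] else NA_character_,
      score = if (length(f) >= 5L) .num_or_na(f[5]) else NA_real_,
      strand = strand,
      extra = if (length(f) > 6L) paste(f[7:length(f)], collapse = "\t") else "",
      source_line = i)
  }
  .assemble(recs, bad, n_data)
}

.parse_gff <- function(lines, idx) {
  recs <- list(); bad <- list(); n_data <- 0L
  for (i in idx) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (.is_header_line(line)) next
    n_data <- n_data + 1L
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    reason <- NULL
    s <- .num_or_na(f[4]); e <- .num_or_na(f[5])
    if (length(f) < 8L) reason <- sprintf("expected 9 fields, got %d", length(f))
    else if (is.na(s) || is.na(e)) reason <- "non-numeric coordinates"
    else if (s < 1)                reason <- "start below 1 (GFF is 1-based)"
    else if (e < s)                reason <- "end before start"
    if (!is.null(reason)) {
      bad[[length(bad) + 1L]] <- list(i, line, reason); next
    }
    attrs <- if (length(f) >= 9L) f[9] else ""
    recs[[length(recs) + 1L]] <- list(
      chrom = f[1], start = s - 1, end = e,
      name = NA_character_, score = .num_or_na(f[6]),
      strand = if (f[7] %in% c("+", "-", ".")) f[7] else ".",
      extra = paste(f[2], f[3], f[8], attrs, sep = "\t"),
      source_line = i)
  }
  .assemble(recs, bad, n_data)
}

.parse_wig_decl <- function(line) {
  kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1]]
  vals <- sub("^[A-Za-z]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

.parse_wig <- function(lines, idx) {
  recs <- list(); bad <- list(); n_data <- 0L
  mode <- NULL; chrom <- NULL; span <- 1; step <- NULL; nextstart <- NULL
  for (i in idx) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (grepl("^\\s*#", line) || grepl("^(track|browser)([ \t]|$)", line)) next
    if (grepl("^(fixedStep|variableStep)\\b", line)) {
      kv <- .parse_wig_decl(line)
      if (!"chrom" %in% names(kv)) {
        bad[[length(bad) + 1L]] <- list(i, line, "declaration lacks chrom=")
        mode <- NULL; next
      }
      mode <- sub("\\s.*$", "", line)
      chrom <- kv[["chrom"]]
      span <- if ("span" %in% names(kv)) .num_or_na(kv[["span"]]) else 1
      if (mode == "fixedStep") {
        step <- if ("step" %in% names(kv)) .num_or_na(kv[["step"]]) else 1
        nextstart <- .num_or_na(kv[["start"]])
        if (is.na(nextstart) || nextstart < 1) {
          bad[[length(bad) + 1L]] <- list(i, line, "bad fixedStep start")
          mode <- NULL
        }
      }
      next
    }
    n_data <- n_data + 1L
    if (is.null(mode)) {
      bad[[length(bad) + 1L]] <- list(i, line, "value before declaration"); next
    }
    f <- .split_fields(line)
    if (mode == "variableStep") {
      pos <- .num_or_na(f[1]); val <- .num_or_na(f[2])
      if (length(f) < 2L || is.na(pos) || is.na(val) || pos < 1) {
        bad[[length(bad) + 1L]] <- list(i, line, "bad variableStep line"); next
      }
      s0 <- pos - 1
    } else {
      val <- .num_or_na(f[1])
      if (length(f) != 1L || is.na(val)) {
        bad[[length(bad) + 1L]] <- list(i, line, "bad fixedStep value"); next
      }
      s0 <- nextstart - 1
      nextstart <- nextstart + step
    }
    recs[[length(recs) + 1L]] <- list(
      chrom = chrom, start = s0, end = s0 + span,
      name = NA_character_, score = val, strand = ".",
      extra = "", source_line = i)
  }
  .assemble(recs, bad, n_data)
}

.assemble <- function(recs, bad, n_data) {
  records <- if (length(recs)) {
    data.frame(chrom = vapply(recs, `[[`, "", "chrom"),
               start = vapply(recs, `[[`, 0, "start"),
               end = vapply(recs, `[[`, 0, "end"),
               name = vapply(recs, `[[`, "", "name"),
               score = vapply(recs, `[[`, 0, "score"),
               strand = vapply(recs, `[[`, "", "strand"),
               extra = vapply(recs, `[[`, "", "extra"),
               source_line = vapply(recs, function(r) as.integer(r$source_line), 1L),
               stringsAsFactors = FALSE)
  } else .empty_records()
  malformed <- if (length(bad)) {
    data.frame(line = vapply(bad, function(b) as.integer(b[[1]]), 1L),
               text = vapply(bad, function(b) as.character(b[[2]]), ""),
               reason = vapply(bad, function(b) as.character(b[[3]]), ""),
               stringsAsFactors = FALSE)
  } else .empty_malformed()
  list(records = records, malformed = malformed, n_data = n_data)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE,
                               justify = "none"))
}

#' Write a track file
#'
#' Serializes header lines then records in the source dialect's coordinate
#' convention (GFF starts are restored to 1-based; WIG records are emitted
#' as variableStep blocks). Reading the written file back reproduces the
#' chrom/start/end/strand of every record.
#'
#' @param track A `track_file`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "track_file"))
  r <- track$records
  body <- switch(track$format,
    bed = , narrowPeak = , broadPeak = {
      if (nrow(r) == 0L) character() else {
        base <- paste(r$chrom, .fmt_num(r$start), .fmt_num(r$end), sep = "\t")
        need6 <- !is.na(r$name) | !is.na(r$score) | r$strand != "." |
          nzchar(r$extra) | track$format != "bed"
        six <- paste(base,
                     ifelse(is.na(r$name), ".", r$name),
                     .fmt_num(r$score), r$strand, sep = "\t")
        out <- ifelse(need6, six, base)
        ifelse(nzchar(r$extra), paste(out, r$extra, sep = "\t"), out)
      }
    },
    gff = {
      if (nrow(r) == 0L) character() else {
        ex <- strsplit(ifelse(nzchar(r$extra), r$extra, ".\t.\t.\t"),
                       "\t", fixed = TRUE)
        ex <- lapply(ex, function(f) c(f, rep(".", 4))[1:4])
        paste(r$chrom,
              vapply(ex, `[`, "", 1), vapply(ex, `[`, "", 2),
              .fmt_num(r$start + 1), .fmt_num(r$end),
              .fmt_num(r$score), r$strand,
              vapply(ex, `[`, "", 3), vapply(ex, `[`, "", 4),
              sep = "\t")
      }
    },
    wig = {
      if (nrow(r) == 0L) character() else {
        span <- r$end - r$start
        block <- cumsum(c(TRUE, r$chrom[-1] != r$chrom[-nrow(r)] |
                                span[-1] != span[-nrow(r)]))
        out <- character()
        for (b in unique(block)) {
          sel <- block == b
          out <- c(out,
                   sprintf("variableStep chrom=%s span=%s",
                           r$chrom[sel][1], .fmt_num(span[sel][1])),
                   paste(.fmt_num(r$start[sel] + 1), .fmt_num(r$score[sel])))
        }
        out
      }
    })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(track$header_lines, body), con)
  invisible(path)
}
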