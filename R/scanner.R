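# Build-token vocabulary used by repository surveys of human, mouse and
# Drosophila datasets. Matching is case-insensitive, needs no word
# boundaries, and resolves overlaps longest-token-first (bdgp5.25 beats
# bdgp5, build5.41 beats build5, ncbi36 beats ncbi).
.build_tokens <- c(
  "hg17", "hg18", "hg19", "hg38",
  "grch36", "grch37", "grch38",
  "build37.2", "build37.1", "build36.3",
  "ncbi35", "ncbi36", "ncbi37",
  "mm8", "mm9", "mm10", "grcm38",
  "bdgp6", "bdgp5", "bdgp5.25",
  "build5.41", "build5.3", "build5", "build4.1",
  "dm6", "dm3", "ncbi")

# tokens carrying little information about a specific build
.low_specificity_tokens <- "ncbi"

#' Build tokens recognised by the scanner
#'
#' @return Character vector of genome-build tokens (lower case).
#' @export
build_tokens <- function() .build_tokens

.token_regex <- function() {
  toks <- .build_tokens[order(-nchar(.build_tokens), .build_tokens)]
  paste0("(?i)(", paste(gsub(".", "\\.", toks, fixed = TRUE),
                        collapse = "|"), ")")
}

#' Scan text for genome-build tokens
#'
#' Finds all non-overlapping, case-insensitive matches of the build-token
#' vocabulary, longest token first, so `"BDGP5.25"` yields `bdgp5.25`, not
#' `bdgp5`. Tokens containing a dot match the literal dot.
#'
#' @param text Character vector; each element is scanned independently
#'   (e.g. one header line per element).
#' @param where `"filename"` or `"header"` — recorded in the hits.
#' @return Data frame of hits: token (lower case), where, line (index into
#'   `text`; `NA` for filenames), start/end character offsets, and a
#'   low_specificity flag (the bare `ncbi` token names no build).
#' @export
#' @examples
#' scan_tokens("peaks_hg19_rep1.bed", "filename")$token  # "hg19"
scan_tokens <- function(text, where = c("filename", "header")) {
  where <- match.arg(where)
  hits <- list()
  rx <- .token_regex()
  for (i in seq_along(text)) {
    m <- gregexpr(rx, text[i], perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      tok <- tolower(substr(text[i], m[j], m[j] + len[j] - 1L))
      hits[[length(hits) + 1L]] <- list(tok, i, as.integer(m[j]),
                                        as.integer(m[j] + len[j] - 1L))
    }
  }
  data.frame(
    token = vapply(hits, `[[`, "", 1),
    where = rep(where, length(hits)),
    line = if (where == "header") vapply(hits, function(h) as.integer(h[[2]]), 1L)
           else rep(NA_integer_, length(hits)),
    start = vapply(hits, function(h) h[[3]], 1L),
    end = vapply(hits, function(h) h[[4]], 1L),
    low_specificity = vapply(hits, `[[`, "", 1) %in% .low_specificity_tokens,
    stringsAsFactors = FALSE)
}

# number of leading lines inspected for build tokens
.audit_header_lines <- 50L

#' Audit one file for genome-build annotation
#'
#' Scans the basename (never the directory path, which is disrupted by
#' almost any transfer) and the first 50 lines of the file for build
#' tokens, and classifies the file as `filename_only`, `header_only`,
#' `both` or `neither`.
#'
#' @param path File path.
#' @return List of class `audit_record`: path, classification, hits (data
#'   frame of token hits), and error (NA, or the I/O error message — an
#'   unreadable file is classified `error`, never `neither`).
#' @export
audit_file <- function(path) {
  fn_hits <- scan_tokens(basename(path), "filename")
  lines <- tryCatch(readLines(path, n = .audit_header_lines, warn = FALSE),
                    error = function(e) e, warning = function(w) w)
  if (inherits(lines, "condition")) {
    return(structure(list(path = path, classification = "error",
                          hits = fn_hits, error = conditionMessage(lines)),
                     class = "audit_record"))
  }
  hd_hits <- scan_tokens(lines, "header")
  cls <- if (nrow(fn_hits) && nrow(hd_hits)) "both"
    else if (nrow(fn_hits)) "filename_only"
    else if (nrow(hd_hits)) "header_only"
    else "neither"
  structure(list(path = path, classification = cls,
                 hits = rbind(fn_hits, hd_hits), error = NA_character_),
            class = "audit_record")
}

#' @export
print.audit_record <- function(x, ...) {
  cat(sprintf("<audit_record> %s: %s", basename(x$path), x$classification))
  if (nrow(x$hits))
    cat(" [", paste(unique(x$hits$token), collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

.format_of_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  known <- c(bed = "bed", gff = "gff", gff3 = "gff", gtf = "gff",
             wig = "wig", narrowpeak = "narrowPeak", broadpeak = "broadPeak")
  if (ext %in% names(known)) unname(known[ext]) else "other"
}

#' Audit a directory tree of track files
#'
#' Applies [audit_file()] to every matching file and aggregates the
#' four-way classification per track format, with counts and percentages
#' (computed over readable files; unreadable files are tallied in an
#' `errors` column and excluded from the percentages).
#'
#' @param root Directory to search (recursively).
#' @param glob Filename glob, e.g. `"*.bed"`; default matches all files.
#' @return List of class `audit_report`: `summary` (one row per format:
#'   format, total, the four class counts and percentages, errors) and
#'   `records` (per-file audit records).
#' @export
audit_directory <- function(root, glob = "*") {
  if (!dir.exists(root)) .err("buildprov_io_error", "no such directory: %s", root)
  files <- list.files(root, pattern = utils::glob2rx(glob),
                      recursive = TRUE, full.names = TRUE)
  records <- lapply(files, audit_file)
  cls <- vapply(records, `[[`, "", "classification")
  fmt <- vapply(files, .format_of_path, "")
  classes <- c("filename_only", "header_only", "both", "neither")
  rows <- lapply(unique(fmt), function(f) {
    sel <- fmt == f
    n_err <- sum(cls[sel] == "error")
    n_ok <- sum(sel) - n_err
    counts <- vapply(classes, function(k) sum(cls[sel] == k), 1L)
    pct <- if (n_ok > 0) round(100 * counts / n_ok, 1) else rep(0, 4)
    c(list(format = f, total = sum(sel)), as.list(counts),
      stats::setNames(as.list(pct), paste0("pct_", classes)),
      list(errors = n_err))
  })
  summary <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(summary))
    summary <- data.frame(format = character(), total = integer(),
                          filename_only = integer(), header_only = integer(),
                          both = integer(), neither = integer(),
                          pct_filename_only = numeric(),
                          pct_header_only = numeric(), pct_both = numeric(),
                          pct_neither = numeric(), errors = integer(),
                          stringsAsFactors = FALSE)
  structure(list(summary = summary, records = records),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Serialize an audit report
#'
#' @param report An `audit_report`.
#' @param path Destination; extension decides nothing — use `format`.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$summary, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(report$summary, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
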