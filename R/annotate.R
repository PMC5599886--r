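# The three recommended ways to keep the genome build with the data:
#  - a leading "# genome=<id>" comment line,
#  - a genome=<id> attribute on the browser "track" line,
#  - a ".<id>" tag in the filename.

.genome_comment_rx <- "^\\s*#+\\s*genome\\s*=\\s*([^\\s]+)\\s*$"
.genome_attr_rx <- "genome\\s*=\\s*\"?([^\\s\"]+)\"?"

.existing_comment_build <- function(header_lines) {
  m <- regmatches(header_lines, regexec(.genome_comment_rx, header_lines,
                                        perl = TRUE))
  hits <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  tolower(hits[!is.na(hits)])
}

.existing_trackline_build <- function(header_lines) {
  tl <- grepl("^track([ \t]|$)", header_lines)
  out <- character()
  for (line in header_lines[tl]) {
    m <- regmatches(line, regexec(.genome_attr_rx, line, perl = TRUE))[[1]]
    if (length(m) == 2L) out <- c(out, tolower(m[2]))
  }
  out
}

#' Annotate a track file with its genome build
#'
#' Injects the build id via one of three mechanisms: `comment` makes
#' `# genome=<id>` the first header line; `trackline` adds a
#' `genome=<id>` attribute to the `track` header line (creating the line
#' if absent); `filename` inserts `.<id>` before the file extension in
#' `track$path`. Annotation is idempotent — annotating twice with the
#' same build leaves a single annotation — and refuses to silently
#' overwrite a conflicting annotation for a different build.
#'
#' @param track A `track_file`.
#' @param build_id Build id or alias; must resolve in `registry`.
#' @param mechanism `"comment"`, `"trackline"` or `"filename"`.
#' @param registry A `build_registry` (default: the bundled registry).
#' @return The annotated `track_file` (with an updated `path` for the
#'   filename mechanism).
#' @export
#' @examples
#' tr <- track_file(data.frame(chrom = "chr1", start = 0, end = 100,
#'                             name = NA, score = NA, strand = ".",
#'                             extra = "", source_line = 1L), "bed")
#' annotate_build(tr, "hg38", "comment")$header_lines[1]  # "# genome=hg38"
annotate_build <- function(track, build_id,
                           mechanism = c("comment", "trackline", "filename"),
                           registry = load_registry()) {
  stopifnot(inherits(track, "track_file"))
  mechanism <- match.arg(mechanism)
  build <- registry_lookup(registry, build_id)
  id <- build$id
  same_build <- function(tok) {
    tok <- tolower(tok)
    tok == tolower(id) | tok %in% build$aliases
  }

  if (mechanism == "comment") {
    existing <- .existing_comment_build(track$header_lines)
    if (length(existing)) {
      if (all(same_build(existing))) return(track)
      .err("buildprov_conflict_error",
           "refusing to overwrite existing genome annotation '%s' with '%s'",
           existing[1], id)
    }
    track$header_lines <- c(sprintf("# genome=%s", id), track$header_lines)
    return(track)
  }

  if (mechanism == "trackline") {
    existing <- .existing_trackline_build(track$header_lines)
    if (length(existing)) {
      if (all(same_build(existing))) return(track)
      .err("buildprov_conflict_error",
           "refusing to overwrite existing genome annotation '%s' with '%s'",
           existing[1], id)
    }
    tl <- grep("^track([ \t]|$)", track$header_lines)
    if (length(tl)) {
      track$header_lines[tl[1]] <-
        paste0(track$header_lines[tl[1]], " genome=", id)
    } else {
      track$header_lines <- c(track$header_lines, sprintf("track genome=%s", id))
    }
    return(track)
  }

  # filename
  path <- track$path
  if (is.na(path)) .err("buildprov_io_error",
                        "filename annotation needs a track with a path")
  hits <- scan_tokens(basename(path), "filename")
  hits <- hits[!hits$low_specificity, , drop = FALSE]
  if (nrow(hits)) {
    if (all(same_build(hits$token))) return(track)
    .err("buildprov_conflict_error",
         "filename already names build '%s'; refusing to tag with '%s'",
         hits$token[1], id)
  }
  ext <- tools::file_ext(path)
  track$path <- if (nzchar(ext)) {
    sub(paste0("\\.", ext, "$"), paste0(".", id, ".", ext), path)
  } else paste0(path, ".", id)
  track
}
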