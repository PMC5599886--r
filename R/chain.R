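# UCSC chain format: a header line
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
# followed by alignment blocks "size dt dq" (the final block carries size
# only). Target strand is always "+"; a "-" query strand expresses query
# coordinates on the reversed sequence. Block sums must reconcile with the
# header spans: sum(size + dt) = tEnd - tStart, sum(size + dq) = qEnd - qStart.

.chain_alignment <- function(header, blocks, line) {
  ch <- list(score = header[1],
             t_name = header[2], t_size = header[3], t_strand = header[4],
             t_start = header[5], t_end = header[6],
             q_name = header[7], q_size = header[8], q_strand = header[9],
             q_start = header[10], q_end = header[11],
             chain_id = header[12])
  num <- c("score", "t_size", "t_start", "t_end", "q_size", "q_start",
           "q_end", "chain_id")
  ch[num] <- lapply(ch[num], as.numeric)
  if (any(is.na(unlist(ch[num]))))
    .err("buildprov_parse_error", "malformed chain header at line %d", line)
  if (ch$t_strand != "+")
    .err("buildprov_parse_error",
         "chain %s: target strand must be '+'", ch$chain_id)
  if (any(blocks$size <= 0) || any(blocks$dt < 0) || any(blocks$dq < 0))
    .err("buildprov_chain_integrity_error",
         "chain %s: block sizes must be positive and gaps non-negative",
         ch$chain_id)
  if (sum(blocks$size + blocks$dt) != ch$t_end - ch$t_start ||
      sum(blocks$size + blocks$dq) != ch$q_end - ch$q_start)
    .err("buildprov_chain_integrity_error",
         "chain %s: block sums inconsistent with header spans", ch$chain_id)
  ch$blocks <- blocks
  # precomputed block geometry for O(log n) per-interval lookup
  ch$tb <- ch$t_start + cumsum(c(0, blocks$size + blocks$dt))[seq_len(nrow(blocks))]
  ch$qb <- ch$q_start + cumsum(c(0, blocks$size + blocks$dq))[seq_len(nrow(blocks))]
  ch$cum_aligned <- cumsum(c(0, blocks$size))[seq_len(nrow(blocks))]
  ch$dq_breaks <- cumsum(blocks$dq > 0)
  structure(ch, class = "chain_alignment")
}

#' Read a UCSC chain file
#'
#' Parses every chain and verifies per-chain block-sum integrity (the
#' aligned block and gap lengths must reconcile exactly with the header's
#' target and query spans).
#'
#' @param path Path to an uncompressed chain file.
#' @return A `chain_set`: the chains plus an index by target sequence
#'   name.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) .err("buildprov_io_error", "no such file: %s", path)
  chain_set(.parse_chain_lines(readLines(path, warn = FALSE)))
}

.parse_chain_lines <- function(lines) {
  chains <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    if (!grepl("^chain\\b", line))
      .err("buildprov_parse_error", "expected chain header at line %d", i)
    header <- strsplit(line, "[ \t]+")[[1]][-1]
    if (length(header) != 12L)
      .err("buildprov_parse_error",
           "chain header at line %d has %d fields, expected 12", i,
           length(header))
    hline <- i; i <- i + 1L
    size <- numeric(); dt <- numeric(); dq <- numeric()
    done <- FALSE
    while (i <= n && nzchar(trimws(lines[i]))) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
      if (any(is.na(f)) || !length(f) %in% c(1L, 3L))
        .err("buildprov_parse_error", "malformed chain block at line %d", i)
      size <- c(size, f[1])
      dt <- c(dt, if (length(f) == 3L) f[2] else 0)
      dq <- c(dq, if (length(f) == 3L) f[3] else 0)
      i <- i + 1L
      if (length(f) == 1L) { done <- TRUE; break }
    }
    if (!done)
      .err("buildprov_parse_error",
           "chain starting at line %d is truncated (no terminal block)", hline)
    chains[[length(chains) + 1L]] <-
      .chain_alignment(header, data.frame(size = size, dt = dt, dq = dq),
                       hline)
  }
  chains
}

#' Bundle chains into an indexed set
#'
#' @param chains List of `chain_alignment` objects.
#' @return A `chain_set` indexed by target sequence name.
#' @export
chain_set <- function(chains) {
  t_names <- vapply(chains, `[[`, "", "t_name")
  structure(list(chains = chains,
                 index = split(seq_along(chains), t_names)),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %d chains over %d target sequences\n",
              length(x$chains), length(x$index)))
  invisible(x)
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf("<chain> id=%s score=%s %s:[%s,%s) -> %s:[%s,%s)%s, %d blocks\n",
              format(x$chain_id), format(x$score),
              x$t_name, format(x$t_start), format(x$t_end),
              x$q_name, format(x$q_start), format(x$q_end),
              if (x$q_strand == "-") " (-)" else "", nrow(x$blocks)))
  invisible(x)
}

# Best chain for an interval: highest score among chains overlapping
# [start,end) on the target, ties by longest target overlap, then lowest
# chain id. Returns the chain index or 0.
.best_chain <- function(chains, idx, chrom, start, end) {
  cand <- idx[[chrom]]
  if (is.null(cand)) return(0L)
  ts <- vapply(chains[cand], `[[`, 0, "t_start")
  te <- vapply(chains[cand], `[[`, 0, "t_end")
  ov <- pmin(te, end) - pmax(ts, start)
  keep <- ov > 0
  if (!any(keep)) return(0L)
  cand <- cand[keep]; ov <- ov[keep]
  sc <- vapply(chains[cand], `[[`, 0, "score")
  id <- vapply(chains[cand], `[[`, 0, "chain_id")
  cand[order(-sc, -ov, id)][1]
}

# Map one interval through one chain by block arithmetic.
.lift_via_chain <- function(ch, start, end, min_match) {
  len <- end - start
  nb <- nrow(ch$blocks)
  # aligned bases strictly before target position x
  A <- function(x) {
    i <- findInterval(x, ch$tb)
    if (i == 0L) return(0)
    ch$cum_aligned[i] + min(max(x - ch$tb[i], 0), ch$blocks$size[i])
  }
  matched <- A(end) - A(start)
  frac <- matched / len
  if (matched == 0)
    return(.lift_result("unmapped", matched_fraction = 0, chain_id = ch$chain_id))
  # first and last matched target base and their block indices
  i0 <- findInterval(start, ch$tb)
  if (i0 >= 1L && start < ch$tb[i0] + ch$blocks$size[i0]) {
    b0 <- i0; fs <- max(start, ch$tb[i0])
  } else {
    b0 <- i0 + 1L; fs <- ch$tb[b0]
  }
  i1 <- findInterval(end - 1, ch$tb)
  if (end - 1 < ch$tb[i1] + ch$blocks$size[i1]) {
    b1 <- i1; ls <- end - 1
  } else {
    b1 <- i1; ls <- ch$tb[i1] + ch$blocks$size[i1] - 1
  }
  # query-gap between the blocks spanned => discontiguous query runs
  split <- b1 > b0 &&
    (ch$dq_breaks[b1 - 1L] - (if (b0 > 1L) ch$dq_breaks[b0 - 1L] else 0)) > 0
  if (split)
    return(.lift_result("split", matched_fraction = frac,
                        chain_id = ch$chain_id))
  fq <- ch$qb[b0] + (fs - ch$tb[b0])
  lq <- ch$qb[b1] + (ls - ch$tb[b1])
  if (ch$q_strand == "-") {
    qs <- ch$q_size - (lq + 1); qe <- ch$q_size - fq
  } else {
    qs <- fq; qe <- lq + 1
  }
  status <- if (frac < min_match) "partial_below_threshold" else "mapped"
  .lift_result(status, chrom = ch$q_name, start = qs, end = qe,
               matched_fraction = frac, chain_id = ch$chain_id)
}

.lift_result <- function(status, chrom = NA_character_, start = NA_real_,
                         end = NA_real_, matched_fraction = NA_real_,
                         chain_id = NA_real_) {
  structure(list(status = status, chrom = chrom, start = start, end = end,
                 strand = "+", matched_fraction = matched_fraction,
                 chain_id = chain_id),
            class = "lift_result")
}

#' @export
print.lift_result <- function(x, ...) {
  if (x$status == "mapped")
    cat(sprintf("<lift_result> mapped %s:[%s,%s) (matched %.3f, chain %s)\n",
                x$chrom, format(x$start), format(x$end),
                x$matched_fraction, format(x$chain_id)))
  else
    cat(sprintf("<lift_result> %s (matched %s)\n", x$status,
                ifelse(is.na(x$matched_fraction), "-",
                       sprintf("%.3f", x$matched_fraction))))
  invisible(x)
}

#' Lift one interval between builds through a chain set
#'
#' The interval's bases are mapped through the aligned blocks of the
#' best-scoring overlapping chain (score, then longest target overlap,
#' then lowest chain id). The lift is `mapped` when the mapped bases form
#' one contiguous query run covering at least `min_match` of the interval;
#' `split` when the matched bases span discontiguous query runs;
#' `partial_below_threshold` when contiguous but under `min_match`; and
#' `unmapped` when no base maps. Coordinates on a minus-strand query are
#' reflected to the plus strand, so results are always plus-strand
#' intervals. Mapping to a different chromosome is legal and reported as
#' `mapped`; downstream distance statistics classify it.
#'
#' @param iv A list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open, target-build coordinates).
#' @param chains A `chain_set` (see [read_chain()]).
#' @param min_match Minimum fraction of the interval's bases that must map
#'   (default 0.95, the usual same-species lift-over threshold).
#' @return A `lift_result`: status, mapped chrom/start/end (NA unless
#'   mapped), matched_fraction, chain_id.
#' @export
lift_interval <- function(iv, chains, min_match = 0.95) {
  stopifnot(inherits(chains, "chain_set"))
  if (!is.numeric(min_match) || length(min_match) != 1L ||
      min_match <= 0 || min_match > 1)
    .err("buildprov_config_error", "min_match must be in (0, 1]")
  start <- as.numeric(iv$start); end <- as.numeric(iv$end)
  stopifnot(start >= 0, start < end)
  k <- .best_chain(chains$chains, chains$index, as.character(iv$chrom),
                   start, end)
  if (k == 0L) return(.lift_result("unmapped"))
  .lift_via_chain(chains$chains[[k]], start, end, min_match)
}

#' Lift many intervals
#'
#' Applies [lift_interval()] to every row of an interval table.
#'
#' @param ivs Data frame with `chrom`, `start`, `end`.
#' @param chains A `chain_set`.
#' @param min_match See [lift_interval()].
#' @return Data frame with one row per input interval: status, chrom,
#'   start, end, matched_fraction, chain_id.
#' @export
lift_intervals <- function(ivs, chains, min_match = 0.95) {
  stopifnot(inherits(chains, "chain_set"))
  if (!is.numeric(min_match) || length(min_match) != 1L ||
      min_match <= 0 || min_match > 1)
    .err("buildprov_config_error", "min_match must be in (0, 1]")
  n <- nrow(ivs)
  # per-chromosome chain geometry, computed once
  geom <- lapply(chains$index, function(cand) {
    list(cand = cand,
         ts = vapply(chains$chains[cand], `[[`, 0, "t_start"),
         te = vapply(chains$chains[cand], `[[`, 0, "t_end"),
         sc = vapply(chains$chains[cand], `[[`, 0, "score"),
         id = vapply(chains$chains[cand], `[[`, 0, "chain_id"))
  })
  status <- character(n); chrom <- rep(NA_character_, n)
  qs <- rep(NA_real_, n); qe <- rep(NA_real_, n)
  frac <- rep(NA_real_, n); cid <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- geom[[ivs$chrom[i]]]
    s <- ivs$start[i]; e <- ivs$end[i]
    if (is.null(g)) { status[i] <- "unmapped"; next }
    ov <- pmin(g$te, e) - pmax(g$ts, s)
    keep <- ov > 0
    if (!any(keep)) { status[i] <- "unmapped"; next }
    pick <- which(keep)[order(-g$sc[keep], -ov[keep], g$id[keep])][1]
    r <- .lift_via_chain(chains$chains[[g$cand[pick]]], s, e, min_match)
    status[i] <- r$status; chrom[i] <- r$chrom
    qs[i] <- r$start; qe[i] <- r$end
    frac[i] <- r$matched_fraction; cid[i] <- r$chain_id
  }
  data.frame(status = status, chrom = chrom, start = qs, end = qe,
             matched_fraction = frac, chain_id = cid,
             stringsAsFactors = FALSE)
}
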