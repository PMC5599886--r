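# Shared fixtures and independent oracles for the test suite.

the_registry <- load_registry()

# the seven real bundled builds (toyA/toyB excluded)
full_builds <- c("hg18", "hg19", "hg38", "mm9", "mm10", "dm3", "dm6")

bed_track <- function(chrom, start, end, strand = ".") {
  n <- length(chrom)
  track_file(data.frame(chrom = chrom, start = start, end = end,
                        name = rep(NA_character_, n),
                        score = rep(NA_real_, n),
                        strand = rep(strand, length.out = n),
                        extra = rep("", n), source_line = seq_len(n),
                        stringsAsFactors = FALSE),
             "bed")
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

chains_from_text <- function(lines) read_chain(write_tmp(lines, ".chain"))

# --- independent per-base lift-over oracle -------------------------------
# Enumerates the image of every target base of a chain (query coordinates
# on the aligned strand), then answers lifts by slicing that map. Shares
# no arithmetic with the block-walking implementation.

oracle_base_map <- function(ch) {
  img <- rep(NA_real_, ch$t_end - ch$t_start)
  t <- ch$t_start; q <- ch$q_start
  for (i in seq_len(nrow(ch$blocks))) {
    sz <- ch$blocks$size[i]
    img[(t - ch$t_start) + seq_len(sz)] <- q + seq_len(sz) - 1
    t <- t + sz + ch$blocks$dt[i]
    q <- q + sz + ch$blocks$dq[i]
  }
  img
}

oracle_lift <- function(chrom, start, end, chains, min_match = 0.95,
                        maps = NULL) {
  keep <- vapply(chains, function(ch)
    ch$t_name == chrom && ch$t_start < end && ch$t_end > start, TRUE)
  cand <- chains[keep]
  if (!length(cand)) return(list(status = "unmapped"))
  ov <- vapply(cand, function(ch) min(ch$t_end, end) - max(ch$t_start, start), 0)
  sc <- vapply(cand, `[[`, 0, "score")
  id <- vapply(cand, `[[`, 0, "chain_id")
  pick <- order(-sc, -ov, id)[1]
  ch <- cand[[pick]]
  map <- if (is.null(maps)) oracle_base_map(ch)
         else maps[[as.character(ch$chain_id)]]
  lo_t <- max(start, ch$t_start); hi_t <- min(end, ch$t_end)
  img <- if (hi_t > lo_t)
    map[(lo_t - ch$t_start + 1):(hi_t - ch$t_start)] else numeric()
  img <- img[!is.na(img)]
  frac <- length(img) / (end - start)
  if (length(img) == 0L)
    return(list(status = "unmapped", matched_fraction = 0))
  if (any(diff(img) != 1))
    return(list(status = "split", matched_fraction = frac))
  if (frac < min_match)
    return(list(status = "partial_below_threshold", matched_fraction = frac))
  lo <- min(img); hi <- max(img) + 1
  if (ch$q_strand == "-") {
    s <- ch$q_size - hi; e <- ch$q_size - lo
  } else { s <- lo; e <- hi }
  list(status = "mapped", chrom = ch$q_name, start = s, end = e,
       matched_fraction = frac)
}

# Random, hand-assembled chain text (independent of generate_chain):
# several chains per target sequence, random gaps, random query strand.
random_chain_text <- function(seed, t_name = "chrT", t_size = 20000,
                              q_name = "chrQ", q_size = 40000,
                              n_chains = 3) {
  set.seed(seed)
  out <- character()
  for (k in seq_len(n_chains)) {
    t_start <- sample(0:(t_size - 2000), 1)
    span <- sample(500:(t_size - t_start), 1)
    nb <- sample(1:6, 1)
    # split span into nb blocks plus dt gaps
    cuts <- sort(sample(seq_len(span - 1), nb - 1))
    seg <- diff(c(0, cuts, span))
    size <- pmax(1, floor(seg * stats::runif(nb, 0.4, 0.9)))
    dt <- seg - size
    dt[nb] <- 0
    size[nb] <- seg[nb]
    dq <- c(sample(0:30, nb - 1, replace = TRUE), 0)
    t_end <- t_start + sum(size + dt)
    q_span <- sum(size + dq)
    q_strand <- sample(c("+", "-"), 1)
    q_start <- sample(0:(q_size - q_span), 1)
    header <- sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                      sample(1e3:1e6, 1), t_name, t_size, t_start, t_end,
                      q_name, q_size, q_strand, q_start, q_start + q_span,
                      seed * 100 + k)
    blocks <- c(if (nb > 1) paste(size[-nb], dt[-nb], dq[-nb]),
                as.character(size[nb]))
    out <- c(out, header, blocks, "")
  }
  out
}
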