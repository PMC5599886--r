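# Chromosomes counted as "autosomes and sex chromosomes": chr1..chrN,
# chromosome arms (chr2L, chr3R, ...), chrX, chrY. Excludes chrM and any
# random/alt/Het/U contig.
.primary_pattern <- "^chr([0-9]+[LR]?|X|Y)$"

#' Construct a genome build
#'
#' A `genome_build` bundles a build id, its species, a set of alternative
#' names (aliases) and the chromosome-size table against which track-file
#' coordinates are validated.
#'
#' @param id Short build name, e.g. `"hg19"`.
#' @param species Binomial species name.
#' @param aliases Character vector of alternative names (e.g. `"grch37"`).
#' @param chrom_sizes Named integer-like vector mapping canonical chromosome
#'   names to lengths in base pairs; all lengths must be positive.
#' @param primary_set Optional character vector naming the chromosomes that
#'   count as autosomes and sex chromosomes. Defaults to the members of
#'   `chrom_sizes` matching `chr1..chrN`, arm names (`chr2L`, ...), `chrX`,
#'   `chrY`; `chrM` and scaffold/Het/alt contigs are excluded from binning
#'   but remain available for compatibility scoring.
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(id, species, aliases = character(), chrom_sizes,
                         primary_set = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sizes <- as.numeric(chrom_sizes)
  names(sizes) <- names(chrom_sizes)
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all chromosome lengths must be positive, finite numbers")
  if (anyDuplicated(names(sizes)))
    stop("duplicate chromosome name in sizes table for build '", id, "'")
  if (is.null(primary_set))
    primary_set <- names(sizes)[grepl(.primary_pattern, names(sizes))]
  if (!all(primary_set %in% names(sizes)))
    stop("primary_set contains chromosomes absent from chrom_sizes")
  structure(
    list(id = id, species = species,
         aliases = unique(tolower(as.character(aliases))),
         chrom_sizes = sizes, primary_set = primary_set),
    class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s (%s)\n", x$id, x$species))
  if (length(x$aliases))
    cat("  aliases:", paste(x$aliases, collapse = ", "), "\n")
  cat(sprintf("  %d chromosomes (%d primary), %s bp total\n",
              length(x$chrom_sizes), length(x$primary_set),
              format(sum(x$chrom_sizes), big.mark = ",")))
  invisible(x)
}

#' Read a two-column chrom.sizes table
#'
#' Parses the `<name> <length>` tab-separated format produced by UCSC's
#' fetchChromSizes utility.
#'
#' @param path Path to the table.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "[ \t]+")
  sizes <- numeric(length(fields))
  nm <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    val <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2L || is.na(val) || val <= 0)
      stop(sprintf("malformed chrom.sizes line %d in %s: '%s'",
                   lineno[i], path, lines[i]))
    nm[i] <- f[1]
    sizes[i] <- val
  }
  stats::setNames(sizes, nm)
}

.bundled_dir <- function() system.file("extdata", package = "buildprov")

#' Load the genome-build registry
#'
#' Returns the bundled registry (hg18, hg19, hg38, mm9, mm10, dm3, dm6 plus
#' the toy builds toyA/toyB used for fast tests), optionally extended with
#' user builds. Lookup by id or alias is case-insensitive.
#'
#' @param extra Optional extension: either a path to a YAML config file with
#'   a top-level `builds:` list (each entry: `id`, `species`, `aliases`,
#'   `sizes`), or a list of `genome_build` objects.
#' @return An object of class `build_registry`.
#' @export
#' @examples
#' reg <- load_registry()
#' registry_lookup(reg, "GRCh38")$id
registry_load <- function(extra = NULL) {
  dir <- .bundled_dir()
  meta <- utils::read.delim(file.path(dir, "builds.tsv"),
                            stringsAsFactors = FALSE)
  builds <- lapply(seq_len(nrow(meta)), function(i) {
    aliases <- strsplit(meta$aliases[i], ",", fixed = TRUE)[[1]]
    genome_build(meta$id[i], meta$species[i], aliases,
                 read_chrom_sizes(file.path(dir, "chromsizes",
                                            meta$sizes_file[i])))
  })
  reg <- .registry_from_builds(builds)
  if (!is.null(extra)) {
    if (is.character(extra) && length(extra) == 1L) {
      reg <- registry_extend(reg, config = extra)
    } else if (is.list(extra)) {
      for (b in extra) reg <- registry_add(reg, b)
    } else stop("extra must be a config path or a list of genome_build")
  }
  reg
}

#' @rdname registry_load
#' @export
load_registry <- registry_load

.registry_from_builds <- function(builds) {
  reg <- structure(list(builds = list(), alias_map = character()),
                   class = "build_registry")
  for (b in builds) reg <- registry_add(reg, b)
  reg
}

#' Add a build to a registry
#'
#' Ids and aliases must be globally unique across the registry,
#' case-insensitively.
#'
#' @param registry A `build_registry`.
#' @param build A `genome_build`.
#' @return The extended registry.
#' @export
registry_add <- function(registry, build) {
  stopifnot(inherits(registry, "build_registry"),
            inherits(build, "genome_build"))
  keys <- tolower(c(build$id, build$aliases))
  clash <- keys %in% names(registry$alias_map)
  if (any(clash))
    stop("registry conflict: '", paste(keys[clash], collapse = "', '"),
         "' already registered")
  registry$builds[[build$id]] <- build
  registry$alias_map[keys] <- build$id
  registry
}

#' Extend a registry from a YAML config file
#'
#' The config lists builds as `builds: [{id, species, aliases, sizes}, ...]`
#' where `sizes` is a path (absolute, or relative to the config file) to a
#' two-column chrom.sizes table.
#'
#' @param registry A `build_registry`.
#' @param config Path to the YAML file.
#' @return The extended registry.
#' @export
registry_extend <- function(registry, config) {
  if (!file.exists(config)) stop("registry config not found: ", config)
  conf <- yaml::read_yaml(config)
  entries <- conf$builds
  if (is.null(entries)) stop("registry config has no 'builds' entry")
  for (e in entries) {
    path <- e$sizes
    if (!file.exists(path))
      path <- file.path(dirname(config), e$sizes)
    b <- genome_build(e$id, e$species %||% "unknown",
                      unlist(e$aliases) %||% character(),
                      read_chrom_sizes(path))
    registry <- registry_add(registry, b)
  }
  registry
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up a build by id or alias
#'
#' @param registry A `build_registry`.
#' @param name Build id or alias, matched case-insensitively.
#' @return The `genome_build`; errors if the name is unknown.
#' @export
registry_lookup <- function(registry, name) {
  stopifnot(inherits(registry, "build_registry"))
  id <- registry$alias_map[tolower(name)]
  if (is.na(id))
    stop("unknown genome build: '", name, "'")
  registry$builds[[unname(id)]]
}

#' List registered build ids
#' @param registry A `build_registry`.
#' @return Character vector of build ids in registration order.
#' @export
registry_ids <- function(registry) names(registry$builds)

#' @export
print.build_registry <- function(x, ...) {
  cat(sprintf("<build_registry> %d builds: %s\n", length(x$builds),
              paste(names(x$builds), collapse = ", ")))
  invisible(x)
}

#' Normalize a chromosome name against a build
#'
#' Maps common naming-dialect variants onto the build's canonical names:
#' the `chr` prefix is added or stripped as needed, `MT`/`M` map to `chrM`,
#' and case differences are tolerated. Anything else must match exactly;
#' names with no canonical counterpart return `NA` (unknown is a value,
#' not an error). Normalization is idempotent and never returns a name
#' absent from the build's table.
#'
#' @param name Character vector of raw chromosome labels.
#' @param build A `genome_build`.
#' @return Character vector of canonical names, `NA` where unknown.
#' @export
#' @examples
#' reg <- load_registry()
#' normalize_chrom("1", registry_lookup(reg, "hg19"))   # "chr1"
normalize_chrom <- function(name, build) {
  stopifnot(inherits(build, "genome_build"))
  canon <- names(build$chrom_sizes)
  lut <- stats::setNames(canon, tolower(canon))
  key <- tolower(as.character(name))
  # dialect variants: bare name -> chr-prefixed, MT -> chrM
  key[key == "mt" | key == "m"] <- "chrm"
  hit <- lut[key]
  miss <- is.na(hit)
  if (any(miss)) {
    alt <- ifelse(startsWith(key[miss], "chr"),
                  substring(key[miss], 4L),
                  paste0("chr", key[miss]))
    hit[miss] <- lut[alt]
  }
  unname(hit)
}
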