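# Core data containers: haplotype datasets (mtDNA), diploid microsatellite
# genotype tables, and site coordinate tables, plus plain-text readers/writers.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a haplotype dataset
#'
#' A haplotype dataset holds one row per individual with its population label,
#' a haplotype identifier and, optionally, the aligned mtDNA sequence. When
#' sequences are supplied and `haplotype` is `NULL`, haplotype identifiers are
#' derived by collapsing identical sequences; labels (`Hap01`, `Hap02`, ...)
#' are assigned in order of first occurrence after sorting individual ids, so
#' the labelling is reproducible and independent of input row order.
#'
#' @param individual Character vector of unique individual ids.
#' @param population Character vector of population labels (one per
#'   individual).
#' @param haplotype Optional character vector of haplotype ids. Required when
#'   `sequence` is absent.
#' @param sequence Optional character vector of aligned sequences, all of the
#'   same length, using the alphabet `A,C,G,T,N,-`.
#' @return A data frame of class `haplotype_dataset` with columns
#'   `individual`, `population`, `haplotype` and (if given) `sequence`.
#' @examples
#' haplotype_dataset(c("a", "b", "c"), rep("P1", 3),
#'                   sequence = c("ACGT", "ACGT", "ACGA"))
#' @export
haplotype_dataset <- function(individual, population, haplotype = NULL,
                              sequence = NULL) {
  individual <- as.character(individual)
  population <- as.character(population)
  if (length(individual) == 0L) stop("empty haplotype dataset")
  if (anyDuplicated(individual)) stop("duplicate individual ids")
  if (length(population) != length(individual))
    stop("population labels must match individuals")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != length(individual))
      stop("sequences must match individuals")
    if (length(unique(nchar(sequence))) != 1L)
      stop("alignment error: sequences have unequal lengths")
    bad <- grepl(paste0("[^", paste(SEQ_ALPHABET, collapse = ""), "]"),
                 sequence)
    if (any(bad)) stop("invalid sequence characters (expected A,C,G,T,N,-)")
    if (is.null(haplotype)) {
      haplotype <- collapse_haplotypes(individual, sequence)
    } else {
      haplotype <- as.character(haplotype)
      same_seq <- outer(sequence, sequence, "==")
      same_hap <- outer(haplotype, haplotype, "==")
      if (!all(same_seq == same_hap))
        stop("haplotype ids inconsistent with sequence identity")
    }
  } else if (is.null(haplotype)) {
    stop("either haplotype ids or sequences are required")
  } else {
    haplotype <- as.character(haplotype)
  }
  out <- data.frame(individual = individual, population = population,
                    haplotype = haplotype, stringsAsFactors = FALSE)
  if (!is.null(sequence)) out$sequence <- sequence
  class(out) <- c("haplotype_dataset", "data.frame")
  out
}

# Deterministic haplotype labels: first occurrence after sorting individual ids.
collapse_haplotypes <- function(individual, sequence) {
  ord <- order(individual)
  uniq <- unique(sequence[ord])
  ids <- sprintf("Hap%02d", seq_along(uniq))
  ids[match(sequence, uniq)]
}

#' Read aligned sequences from a FASTA file
#'
#' Headers are expected to encode the individual and its population as
#' `id|population`. Identical sequences are collapsed to shared haplotype ids.
#'
#' @param path Path to a FASTA file.
#' @return A [haplotype_dataset()].
#' @export
read_haplotype_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("format error: no FASTA records in ", path)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(gsub("\\s", "", lines[starts[i]:ends[i]]), collapse = "")
  }, character(1))
  if (any(!nzchar(seqs))) stop("format error: FASTA record with no sequence")
  labels <- sub("^>\\s*", "", lines[hdr])
  parts <- strsplit(labels, "|", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("format error: FASTA headers must be 'id|population'")
  haplotype_dataset(
    individual = vapply(parts, `[[`, character(1), 1L),
    population = vapply(parts, `[[`, character(1), 2L),
    sequence = seqs
  )
}

#' Write a haplotype dataset to FASTA
#'
#' @param x A [haplotype_dataset()] carrying sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(x, path) {
  stopifnot(inherits(x, "haplotype_dataset"))
  if (is.null(x$sequence)) stop("dataset carries no sequences")
  writeLines(paste0(">", x$individual, "|", x$population, "\n", x$sequence),
             path)
  invisible(path)
}

#' Construct a diploid genotype table
#'
#' Allele sizes are positive integers; missing genotypes are `NA` internally
#' (the GenAlEx `0` sentinel is applied on read/write). A genotype with exactly
#' one missing allele is treated as fully missing, so no half-calls enter
#' frequency estimation.
#'
#' @param individual Character vector of unique individual ids.
#' @param population Character vector of population labels.
#' @param alleles Integer matrix with `2 * length(loci)` columns: two adjacent
#'   columns per locus.
#' @param loci Character vector of locus names.
#' @return A data frame of class `genotype_table` with columns `individual`,
#'   `population` and `<locus>.1`/`<locus>.2` allele columns; locus names are
#'   stored in `attr(, "loci")`.
#' @export
genotype_table <- function(individual, population, alleles, loci) {
  individual <- as.character(individual)
  population <- as.character(population)
  loci <- as.character(loci)
  if (length(loci) == 0L) stop("at least one locus is required")
  if (anyDuplicated(individual)) stop("duplicate individual ids")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != 2L * length(loci))
    stop("format error: expected two allele columns per locus")
  if (nrow(alleles) != length(individual))
    stop("allele rows must match individuals")
  storage.mode(alleles) <- "double"
  if (any(!is.na(alleles) & (alleles != round(alleles) | alleles <= 0)))
    stop("format error: allele sizes must be positive integers")
  # one missing allele -> whole genotype missing
  for (l in seq_along(loci)) {
    a <- alleles[, 2L * l - 1L]
    b <- alleles[, 2L * l]
    miss <- is.na(a) | is.na(b)
    alleles[miss, c(2L * l - 1L, 2L * l)] <- NA_real_
  }
  storage.mode(alleles) <- "integer"
  out <- data.frame(individual = individual, population = population,
                    stringsAsFactors = FALSE)
  am <- as.data.frame(alleles)
  names(am) <- paste0(rep(loci, each = 2L), c(".1", ".2"))
  out <- cbind(out, am)
  attr(out, "loci") <- loci
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' Locus names of a genotype table
#' @param x A [genotype_table()].
#' @return Character vector of locus names.
#' @export
loci <- function(x) attr(x, "loci")

# n x 2 matrix of allele sizes at one locus (NA = missing)
locus_alleles <- function(x, locus) {
  stopifnot(locus %in% loci(x))
  as.matrix(x[, paste0(locus, c(".1", ".2")), drop = FALSE])
}

#' Read a GenAlEx-style genotype CSV
#'
#' The expected layout is a header row `individual,population` followed by the
#' locus names, each repeated for its two allele columns, then one row per
#' individual with integer allele sizes and `0` for missing alleles.
#'
#' @param path Path to a CSV file.
#' @param drop Optional character vector of locus names to drop after reading
#'   (see [drop_loci()]).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, drop = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("format error: expected id, population and loci")
  acols <- names(raw)[-(1:2)]
  if (length(acols) %% 2L != 0L)
    stop("format error: odd number of allele columns")
  loci <- acols[seq(1L, length(acols), by = 2L)]
  vals <- as.matrix(raw[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(is.na(vals)) || any(vals != round(vals)) || any(vals < 0))
    stop("format error: alleles must be non-negative integers (0 = missing)")
  vals[vals == 0] <- NA_real_
  tab <- genotype_table(raw[[1L]], raw[[2L]], vals, loci)
  if (!is.null(drop)) tab <- drop_loci(tab, drop)
  tab
}

#' Write a genotype table as GenAlEx-style CSV
#'
#' @param x A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  l <- loci(x)
  m <- as.matrix(x[, -(1:2), drop = FALSE])
  m[is.na(m)] <- 0L
  header <- paste(c("individual", "population", rep(l, each = 2L)),
                  collapse = ",")
  rows <- apply(cbind(x$individual, x$population, m), 1L, paste,
                collapse = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Drop loci from a genotype table
#'
#' @param x A [genotype_table()].
#' @param locus_names Loci to remove; must exist in `x`, and at least one
#'   locus must remain.
#' @return The table without the named loci; individuals unchanged.
#' @export
drop_loci <- function(x, locus_names) {
  stopifnot(inherits(x, "genotype_table"))
  if (length(locus_names) == 0L) return(x)
  unknown <- setdiff(locus_names, loci(x))
  if (length(unknown) > 0L)
    stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(loci(x), locus_names)
  if (length(keep) == 0L) stop("cannot drop all loci")
  cols <- c("individual", "population", paste0(rep(keep, each = 2L),
                                               c(".1", ".2")))
  out <- x[, cols, drop = FALSE]
  attr(out, "loci") <- keep
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' Construct a site coordinate table
#'
#' @param site Character vector of unique site codes.
#' @param lat,lon Decimal-degree coordinates (`|lat| <= 90`, `|lon| <= 180`).
#' @return A data frame of class `site_table`.
#' @export
site_table <- function(site, lat, lon) {
  site <- as.character(site)
  if (anyDuplicated(site)) stop("duplicate site codes")
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  out <- data.frame(site = site, lat = lat, lon = lon,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

#' Read a site coordinate CSV (`site,lat,lon`)
#' @param path Path to a CSV file.
#' @return A [site_table()].
#' @export
read_sites <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  site_table(raw[[1L]], raw[[2L]], raw[[3L]])
}

#' Read a YAML analysis configuration
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a JSON run manifest
#'
#' Records the parameters and seed of an analysis step so runs can be
#' reproduced.
#'
#' @param path Output JSON path.
#' @param step Name of the analysis step.
#' @param params Named list of parameters.
#' @param seed Integer seed used (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, step, params = list(), seed = NULL) {
  manifest <- list(step = step, params = params, seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
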