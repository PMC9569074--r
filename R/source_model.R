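# Source-population model: the frequency spectra used to seed simulations.

#' Construct a source population model
#'
#' Holds the haplotype frequency spectrum and per-locus allele frequency
#' vectors of the (possibly synthetic) source population from which founders
#' are drawn.
#'
#' @param haplotype_freqs Numeric vector of haplotype frequencies summing
#'   to 1. Names are optional haplotype labels.
#' @param allele_freqs Named list with one numeric vector per locus; each
#'   vector sums to 1 and its names are the integer allele sizes.
#' @return A list of class `source_population_model`.
#' @export
source_population_model <- function(haplotype_freqs, allele_freqs) {
  haplotype_freqs <- as.numeric_named(haplotype_freqs)
  if (length(haplotype_freqs) < 1L) stop("at least one haplotype is required")
  check_freqs(haplotype_freqs, "haplotype_freqs")
  if (!is.list(allele_freqs) || length(allele_freqs) < 1L)
    stop("at least one locus is required")
  if (is.null(names(allele_freqs)))
    names(allele_freqs) <- sprintf("L%02d", seq_along(allele_freqs))
  allele_freqs <- lapply(allele_freqs, as.numeric_named)
  for (l in names(allele_freqs)) {
    f <- allele_freqs[[l]]
    check_freqs(f, paste0("allele_freqs[", l, "]"))
    sizes <- suppressWarnings(as.numeric(names(f)))
    if (is.null(names(f)) || any(is.na(sizes)) || any(sizes <= 0) ||
        any(sizes != round(sizes)))
      stop("allele frequency names must be positive integer sizes")
  }
  structure(list(haplotype_freqs = haplotype_freqs,
                 allele_freqs = allele_freqs),
            class = "source_population_model")
}

as.numeric_named <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

check_freqs <- function(f, what) {
  if (any(f < 0) || any(f > 1)) stop(what, ": frequencies must be in [0,1]")
  if (abs(sum(f) - 1) > 1e-9) stop(what, ": frequencies must sum to 1")
  invisible(f)
}

#' Estimate a source model from observed data
#'
#' Builds a [source_population_model()] from the empirical haplotype and
#' allele frequencies of one population.
#'
#' @param haplotypes A [haplotype_dataset()] (or `NULL` to skip mtDNA).
#' @param genotypes A [genotype_table()] (or `NULL` to skip microsatellites).
#' @param population Population label to use.
#' @return A [source_population_model()]. When one of the two inputs is
#'   `NULL` a single dummy haplotype or locus is substituted so the object
#'   remains valid.
#' @export
estimate_source_model <- function(haplotypes = NULL, genotypes = NULL,
                                  population) {
  if (is.null(haplotypes) && is.null(genotypes))
    stop("at least one of haplotypes/genotypes is required")
  if (!is.null(haplotypes)) {
    sub <- haplotypes[haplotypes$population == population, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no individuals in population ", population)
    cnt <- table(sub$haplotype)
    hf <- as.numeric(cnt) / sum(cnt)
    names(hf) <- names(cnt)
  } else {
    hf <- c(Hap01 = 1)
  }
  if (!is.null(genotypes)) {
    sub <- genotypes[genotypes$population == population, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no individuals in population ", population)
    af <- lapply(loci(genotypes), function(l) {
      a <- locus_alleles(sub, l)
      a <- a[!is.na(a)]
      if (length(a) == 0L) stop("all genotypes missing at locus ", l)
      cnt <- table(a)
      f <- as.numeric(cnt) / sum(cnt)
      names(f) <- names(cnt)
      f
    })
    names(af) <- loci(genotypes)
  } else {
    af <- list(L01 = c(`100` = 1))
  }
  source_population_model(hf, af)
}

#' @export
print.source_population_model <- function(x, ...) {
  cat("Source population model\n")
  cat(sprintf("  haplotypes: %d (1 - sum p^2 = %.4f)\n",
              length(x$haplotype_freqs), 1 - sum(x$haplotype_freqs^2)))
  k <- lengths(x$allele_freqs)
  he <- vapply(x$allele_freqs, function(f) 1 - sum(f^2), numeric(1))
  cat(sprintf("  loci: %d (alleles per locus %.1f, mean gene diversity %.3f)\n",
              length(k), mean(k), mean(he)))
  invisible(x)
}
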