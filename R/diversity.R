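# Within-population diversity statistics: haplotype and nucleotide diversity,
# allele counts, rarefied allelic richness, heterozygosities and F_IS.

#' Haplotype diversity
#'
#' Unbiased haplotype (gene) diversity `h = n(1 - sum p_i^2)/(n - 1)` with its
#' standard deviation from Nei's (1987) sampling variance.
#'
#' @param counts Positive integer vector of haplotype counts (total `n >= 2`).
#' @return List with elements `h`, `sd`, `n` and `n_haplotypes`.
#' @examples
#' haplotype_diversity(c(103, 47))
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  n <- sum(counts)
  if (n < 2) stop("at least two sampled sequences are required")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd = sqrt(max(v, 0)), n = n, n_haplotypes = length(counts))
}

# Pairwise differences between two aligned sequences, per pairwise-valid site
# (sites with N or - in either sequence are excluded).
pairwise_site_diff <- function(a, b) {
  va <- strsplit(a, "")[[1L]]
  vb <- strsplit(b, "")[[1L]]
  ok <- !(va %in% c("N", "-")) & !(vb %in% c("N", "-"))
  nv <- sum(ok)
  if (nv == 0L) return(c(diff = 0, valid = 0))
  c(diff = sum(va[ok] != vb[ok]), valid = nv)
}

# Distance matrices among unique haplotypes of a dataset: per-site (for pi)
# and raw difference counts (for Phi_ST).
haplotype_distances <- function(x) {
  stopifnot(inherits(x, "haplotype_dataset"))
  if (is.null(x$sequence)) stop("dataset carries no sequences")
  hap <- unique(x$haplotype)
  seqs <- x$sequence[match(hap, x$haplotype)]
  k <- length(hap)
  dcount <- matrix(0, k, k, dimnames = list(hap, hap))
  dsite <- matrix(0, k, k, dimnames = list(hap, hap))
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      d <- pairwise_site_diff(seqs[i], seqs[j])
      dcount[i, j] <- dcount[j, i] <- d[["diff"]]
      dsite[i, j] <- dsite[j, i] <- if (d[["valid"]] > 0)
        d[["diff"]] / d[["valid"]] else 0
    }
  }
  list(haplotypes = hap, count = dcount, per_site = dsite,
       length = nchar(seqs[1L]))
}

#' Nucleotide diversity
#'
#' Mean per-site nucleotide difference over all pairs of sampled sequences
#' (the unbiased estimator), with Nei's (1987) standard deviation. Sites with
#' `N` or a gap in either member of a pair are excluded pairwise.
#'
#' @param x A [haplotype_dataset()] carrying sequences.
#' @param population Optional population label to subset to.
#' @return List with elements `pi`, `sd` and `n`.
#' @export
nucleotide_diversity <- function(x, population = NULL) {
  stopifnot(inherits(x, "haplotype_dataset"))
  if (!is.null(population))
    x <- x[x$population == population, , drop = FALSE]
  if (is.null(x$sequence)) stop("dataset carries no sequences")
  n <- nrow(x)
  if (n < 2L) stop("at least two sequences are required")
  hd <- haplotype_distances(x)
  cnt <- table(factor(x$haplotype, levels = hd$haplotypes))
  cnt <- as.numeric(cnt)
  # sum over unordered individual pairs of per-site differences
  tot <- 0
  k <- length(cnt)
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k)
      tot <- tot + cnt[i] * cnt[j] * hd$per_site[i, j]
  }
  pi_hat <- tot / (n * (n - 1) / 2)
  L <- hd$length
  v <- (n + 1) / (3 * (n - 1)) * pi_hat / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  list(pi = pi_hat, sd = sqrt(max(v, 0)), n = n)
}

#' Allele counts and private alleles
#'
#' Total number of distinct alleles `N_A`, number of private alleles `N_PA`
#' (present in the focal population, absent from every comparison population)
#' and mean alleles per locus `N_a = N_A / L` for one population.
#'
#' @param x A [genotype_table()].
#' @param focal Focal population label.
#' @param others Comparison population labels; defaults to all other
#'   populations in `x`.
#' @return List with `N_A`, `N_PA`, `N_a` and the per-locus allele counts.
#' @export
allele_summary <- function(x, focal, others = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(others)) others <- setdiff(unique(x$population), focal)
  sub <- x[x$population == focal, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no individuals in population ", focal)
  osub <- x[x$population %in% others, , drop = FALSE]
  per_locus <- integer(0)
  na_tot <- 0L
  npa <- 0L
  for (l in loci(x)) {
    af <- locus_alleles(sub, l)
    af <- unique(af[!is.na(af)])
    ao <- locus_alleles(osub, l)
    ao <- unique(ao[!is.na(ao)])
    per_locus[l] <- length(af)
    na_tot <- na_tot + length(af)
    npa <- npa + sum(!(af %in% ao))
  }
  list(N_A = na_tot, N_PA = npa, N_a = na_tot / length(loci(x)),
       per_locus = per_locus)
}

#' Observed and expected heterozygosity
#'
#' `H_O` is the fraction of heterozygous individuals among those typed;
#' `H_E` is the unbiased expected heterozygosity
#' `(2n/(2n - 1)) (1 - sum p^2)`.
#'
#' @param x A [genotype_table()].
#' @param population Population label.
#' @return List with a per-locus data frame (`locus`, `n`, `H_O`, `H_E`) and
#'   the across-locus means `H_O` and `H_E`. Loci with no typed individuals
#'   are dropped with a message.
#' @export
heterozygosities <- function(x, population) {
  stopifnot(inherits(x, "genotype_table"))
  sub <- x[x$population == population, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no individuals in population ", population)
  rows <- lapply(loci(x), function(l) {
    a <- locus_alleles(sub, l)
    typed <- !is.na(a[, 1L])
    n <- sum(typed)
    if (n == 0L) {
      message("locus ", l, ": all genotypes missing; locus dropped")
      return(NULL)
    }
    ho <- mean(a[typed, 1L] != a[typed, 2L])
    p <- table(a[typed, , drop = FALSE]) / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = l, n = n, H_O = ho, H_E = he,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  if (is.null(per_locus)) stop("no typed loci in population ", population)
  list(per_locus = per_locus, H_O = mean(per_locus$H_O),
       H_E = mean(per_locus$H_E))
}

#' Within-population inbreeding coefficient (Weir & Cockerham f)
#'
#' Multi-allelic Weir & Cockerham (1984) estimator of F_IS for a single
#' population, combined across loci by summing variance components
#' (`f = 1 - sum(c) / sum(b + c)`).
#'
#' @param x A [genotype_table()].
#' @param population Population label (needs at least two typed individuals).
#' @return List with `fis` and the per-locus components. `fis` is `NA` (with
#'   a warning) when every locus is monomorphic.
#' @export
fis <- function(x, population) {
  stopifnot(inherits(x, "genotype_table"))
  sub <- x[x$population == population, , drop = FALSE]
  if (nrow(sub) < 2L) stop("at least two individuals are required")
  bsum <- 0
  csum <- 0
  per_locus <- list()
  for (l in loci(x)) {
    a <- locus_alleles(sub, l)
    typed <- !is.na(a[, 1L])
    n <- sum(typed)
    if (n < 2L) next
    a <- a[typed, , drop = FALSE]
    alleles <- sort(unique(as.vector(a)))
    if (length(alleles) < 2L) next
    bl <- 0
    cl <- 0
    for (al in alleles) {
      p <- mean(a == al)                     # frequency of allele al
      htil <- mean(xor(a[, 1L] == al, a[, 2L] == al))  # het. involving al
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * htil)
      bl <- bl + b
      cl <- cl + htil / 2
    }
    per_locus[[l]] <- c(b = bl, c = cl,
                        f = if (bl + cl > 0) 1 - cl / (bl + cl) else NA)
    bsum <- bsum + bl
    csum <- csum + cl
  }
  if (length(per_locus) == 0L || bsum + csum == 0) {
    warning("F_IS undefined: no polymorphic locus in ", population)
    return(list(fis = NA_real_, per_locus = per_locus))
  }
  list(fis = 1 - csum / (bsum + csum), per_locus = per_locus)
}

# Per-allele retention probability under rarefaction to g gene copies:
# 1 - C(N - Ni, g) / C(N, g), exact in log space.
rarefaction_keep_prob <- function(Ni, N, g) {
  miss <- ifelse(N - Ni < g, 0, exp(lchoose(N - Ni, g) - lchoose(N, g)))
  1 - miss
}

#' Rarefied allelic richness and private allelic richness
#'
#' Expected number of alleles (`A_R`) and of private alleles (`A_P`) in a
#' standardized sample of `g` gene copies per population, averaged over loci
#' (HP-RARE style). Privacy means the allele appears in the focal rarefied
#' sample and in none of the other populations' rarefied samples.
#'
#' @param x A [genotype_table()].
#' @param g Rarefaction size in gene copies (>= 2). Defaults to the smallest
#'   per-locus typed gene-copy count over all populations.
#' @param populations Populations to evaluate; defaults to all.
#' @return Data frame with one row per population: `population`, `g`, `A_R`,
#'   `A_P`.
#' @export
rarefied_richness <- function(x, g = NULL, populations = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(populations)) populations <- unique(x$population)
  copies <- function(pop, l) {
    a <- locus_alleles(x[x$population == pop, , drop = FALSE], l)
    a[!is.na(a)]
  }
  min_copies <- min(vapply(populations, function(p)
    min(vapply(loci(x), function(l) length(copies(p, l)), numeric(1))),
    numeric(1)))
  if (is.null(g)) g <- min_copies
  if (g < 2) stop("rarefaction size g must be at least 2")
  if (g > min_copies)
    stop("g exceeds the smallest per-locus gene-copy count (", min_copies, ")")
  res <- lapply(populations, function(focal) {
    ar <- ap <- numeric(0)
    for (l in loci(x)) {
      cf <- copies(focal, l)
      tab <- table(cf)
      keep <- rarefaction_keep_prob(as.numeric(tab), length(cf), g)
      ar[l] <- sum(keep)
      absent_elsewhere <- rep(1, length(tab))
      for (other in setdiff(populations, focal)) {
        co <- copies(other, l)
        nij <- as.numeric(table(factor(co, levels = names(tab))))
        absent_elsewhere <- absent_elsewhere *
          (1 - rarefaction_keep_prob(nij, length(co), g))
      }
      ap[l] <- sum(keep * absent_elsewhere)
    }
    data.frame(population = focal, g = g, A_R = mean(ar), A_P = mean(ap),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-population diversity summary table
#'
#' Combines the mtDNA statistics (sample size, haplotype count, haplotype and
#' nucleotide diversity) and microsatellite statistics (allele counts, private
#' alleles, rarefied richness, heterozygosities, F_IS) into one table, one row
#' per population.
#'
#' @param haplotypes A [haplotype_dataset()] with sequences, or `NULL`.
#' @param genotypes A [genotype_table()], or `NULL`.
#' @param populations Populations to summarize; defaults to all present.
#' @param g Rarefaction size passed to [rarefied_richness()].
#' @return A data frame with one row per population.
#' @export
diversity_summary <- function(haplotypes = NULL, genotypes = NULL,
                              populations = NULL, g = NULL) {
  if (is.null(haplotypes) && is.null(genotypes))
    stop("at least one of haplotypes/genotypes is required")
  if (is.null(populations))
    populations <- unique(c(if (!is.null(haplotypes)) haplotypes$population,
                            if (!is.null(genotypes)) genotypes$population))
  rar <- if (!is.null(genotypes))
    rarefied_richness(genotypes, g = g, populations = populations)
  rows <- lapply(populations, function(pop) {
    out <- data.frame(population = pop, stringsAsFactors = FALSE)
    if (!is.null(haplotypes)) {
      sub <- haplotypes[haplotypes$population == pop, , drop = FALSE]
      out$N <- nrow(sub)
      if (nrow(sub) >= 2L) {
        cnt <- as.numeric(table(sub$haplotype))
        hd <- haplotype_diversity(cnt)
        out$n_hap <- length(cnt)
        out$h <- hd$h
        out$h_sd <- hd$sd
        if (!is.null(sub$sequence)) {
          nd <- nucleotide_diversity(sub)
          out$pi <- nd$pi
          out$pi_sd <- nd$sd
        }
      } else {
        out$n_hap <- nrow(sub)
        out$h <- NA_real_
        out$h_sd <- NA_real_
        if (!is.null(haplotypes$sequence)) {
          out$pi <- NA_real_
          out$pi_sd <- NA_real_
        }
      }
    }
    if (!is.null(genotypes)) {
      asum <- allele_summary(genotypes, pop,
                             others = setdiff(populations, pop))
      het <- heterozygosities(genotypes, pop)
      f <- suppressWarnings(fis(genotypes, pop))
      out$N_A <- asum$N_A
      out$N_PA <- asum$N_PA
      out$N_a <- asum$N_a
      out$A_R <- rar$A_R[rar$population == pop]
      out$A_P <- rar$A_P[rar$population == pop]
      out$H_O <- het$H_O
      out$H_E <- het$H_E
      out$F_IS <- f$fis
    }
    out
  })
  do.call(rbind, rows)
}
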