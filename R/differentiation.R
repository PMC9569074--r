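# Pairwise population differentiation by AMOVA: Phi_ST on inter-haplotype
# nucleotide distances and R_ST on squared microsatellite allele-size
# differences, with permutation p-values.

new_differentiation_result <- function(statistic, value, p, permutations,
                                       components) {
  structure(list(statistic = statistic, value = value, p = p,
                 permutations = permutations, components = components),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (p = %.4g, %d permutations)\n", x$statistic,
              x$value, x$p, x$permutations))
  invisible(x)
}

# Two-level AMOVA from a squared-distance matrix between types, given a
# k x P matrix of type counts per population. Returns sigma2 components.
amova_components <- function(d2, counts) {
  np <- colSums(counts)
  n <- sum(np)
  P <- ncol(counts)
  ctot <- rowSums(counts)
  ssd_total <- as.numeric(ctot %*% d2 %*% ctot) / (2 * n)
  ssd_within <- sum(vapply(seq_len(P), function(g) {
    if (np[g] == 0) return(0)
    cg <- counts[, g]
    as.numeric(cg %*% d2 %*% cg) / (2 * np[g])
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1
  df_within <- n - P
  ms_within <- if (df_within > 0) ssd_within / df_within else 0
  nprime <- (n - sum(np^2) / n) / df_among
  sigma_w <- ms_within
  sigma_a <- (ssd_among / df_among - ms_within) / nprime
  c(sigma_a = sigma_a, sigma_w = sigma_w)
}

#' Pairwise Phi-ST between two populations (mtDNA)
#'
#' AMOVA-based fixation index with inter-haplotype distance equal to the
#' number of pairwise nucleotide differences;
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`. The p-value is
#' obtained by permuting individuals between the two populations.
#'
#' @param x A [haplotype_dataset()] with sequences.
#' @param popA,popB Population labels (each with at least two individuals).
#' @param permutations Number of label permutations.
#' @return A `differentiation_result` (statistic, value, permutation p-value,
#'   variance components). Set the RNG seed with [set.seed()] for
#'   reproducible p-values.
#' @export
pairwise_phist <- function(x, popA, popB, permutations = 10000) {
  stopifnot(inherits(x, "haplotype_dataset"))
  sub <- x[x$population %in% c(popA, popB), , drop = FALSE]
  if (sum(sub$population == popA) < 2L || sum(sub$population == popB) < 2L)
    stop("both populations need at least two sequences")
  hd <- haplotype_distances(sub)
  d2 <- hd$count
  hap_idx <- match(sub$haplotype, hd$haplotypes)
  grp <- as.integer(sub$population == popB) + 1L
  k <- length(hd$haplotypes)
  count_mat <- function(g) {
    m <- matrix(0, k, 2)
    for (gi in 1:2) {
      t <- tabulate(hap_idx[g == gi], nbins = k)
      m[, gi] <- t
    }
    m
  }
  comp <- amova_components(d2, count_mat(grp))
  tot <- sum(comp)
  if (tot <= 0 && all(d2 == 0)) {
    warning("Phi_ST undefined: no haplotype variation in either population")
    return(new_differentiation_result("Phi_ST", NA_real_, NA_real_,
                                      permutations, comp))
  }
  obs <- comp[["sigma_a"]] / tot
  b <- 0L
  for (r in seq_len(permutations)) {
    cperm <- amova_components(d2, count_mat(sample(grp)))
    stat <- cperm[["sigma_a"]] / sum(cperm)
    if (!is.na(stat) && stat >= obs - 1e-12) b <- b + 1L
  }
  new_differentiation_result("Phi_ST", obs, (b + 1) / (permutations + 1),
                             permutations, comp)
}

# Per-locus variance components of a gene-copy ANOVA on allele sizes.
rst_locus_components <- function(sizes, grp) {
  np <- tabulate(grp, nbins = 2)
  if (any(np == 0)) return(c(sigma_a = 0, sigma_w = 0))
  n <- length(sizes)
  gm <- mean(sizes)
  means <- vapply(1:2, function(g) mean(sizes[grp == g]), numeric(1))
  ss_within <- sum((sizes - means[grp])^2)
  ss_among <- sum(np * (means - gm)^2)
  df_within <- n - 2
  if (df_within <= 0) return(c(sigma_a = 0, sigma_w = 0))
  ms_within <- ss_within / df_within
  nprime <- n - sum(np^2) / n
  c(sigma_a = (ss_among - ms_within) / nprime, sigma_w = ms_within)
}

#' Pairwise R-ST between two populations (microsatellites)
#'
#' Slatkin's R_ST computed as a distance-based AMOVA on squared allele-size
#' differences at the gene-copy level, with variance components summed over
#' loci before forming the ratio, and a permutation p-value obtained by
#' shuffling individuals (both gene copies together) between populations.
#'
#' @param x A [genotype_table()].
#' @param popA,popB Population labels.
#' @param permutations Number of permutations.
#' @return A `differentiation_result`. Set the RNG seed with [set.seed()]
#'   for reproducible p-values.
#' @export
pairwise_rst <- function(x, popA, popB, permutations = 10000) {
  stopifnot(inherits(x, "genotype_table"))
  sub <- x[x$population %in% c(popA, popB), , drop = FALSE]
  grp_ind <- as.integer(sub$population == popB) + 1L
  L <- loci(x)
  locus_data <- lapply(L, function(l) {
    a <- locus_alleles(sub, l)
    typed <- which(!is.na(a[, 1L]))
    list(sizes = as.numeric(t(a[typed, , drop = FALSE])), ind = typed)
  })
  poly <- vapply(locus_data, function(d)
    length(unique(d$sizes)) > 1L && length(unique(grp_ind[d$ind])) > 1L,
    logical(1))
  if (!any(poly)) {
    warning("R_ST undefined: no shared polymorphic locus")
    return(new_differentiation_result("R_ST", NA_real_, NA_real_,
                                      permutations, NULL))
  }
  locus_data <- locus_data[poly]
  rst_stat <- function(g_of_ind) {
    comp <- rowSums(vapply(locus_data, function(d) {
      grp <- rep(g_of_ind[d$ind], each = 2L)
      rst_locus_components(d$sizes, grp)
    }, numeric(2)))
    comp[["sigma_a"]] / sum(comp)
  }
  obs <- rst_stat(grp_ind)
  b <- 0L
  for (r in seq_len(permutations)) {
    stat <- rst_stat(sample(grp_ind))
    if (!is.na(stat) && stat >= obs - 1e-12) b <- b + 1L
  }
  new_differentiation_result("R_ST", obs, (b + 1) / (permutations + 1),
                             permutations, NULL)
}
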