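# Exact tests of Hardy-Weinberg proportions (complete enumeration for small
# problems, Monte-Carlo permutation of gene copies otherwise) and Bonferroni
# correction.

# Table-dependent part of the conditional probability of a genotype table
# given its allele counts: log( 2^H / prod f_ij! ). The full log-probability
# adds a constant in the margins.
hwe_log_kernel <- function(f_hom, f_het) {
  sum(f_het) * log(2) - sum(lfactorial(f_hom)) - sum(lfactorial(f_het))
}

# Genotype count matrix (upper triangle used) from an n x 2 allele matrix.
genotype_count_matrix <- function(a, alleles) {
  k <- length(alleles)
  f <- matrix(0L, k, k)
  i1 <- match(pmin(a[, 1L], a[, 2L]), alleles)
  i2 <- match(pmax(a[, 1L], a[, 2L]), alleles)
  for (r in seq_along(i1)) f[i1[r], i2[r]] <- f[i1[r], i2[r]] + 1L
  f
}

# Enumerate all genotype tables with the given allele-count margins, calling
# fn(f) for each. Returns TRUE if complete, FALSE if aborted after max_tables.
enumerate_hwe_tables <- function(allele_counts, fn, max_tables = 1e5) {
  k <- length(allele_counts)
  cells <- do.call(rbind, lapply(1:k, function(i)
    cbind(i, i:k)))
  f <- matrix(0L, k, k)
  seen <- 0L
  rec <- function(idx, rem) {
    if (seen > max_tables) return(FALSE)
    if (idx > nrow(cells)) {
      if (all(rem == 0L)) {
        seen <<- seen + 1L
        if (seen > max_tables) return(FALSE)
        fn(f)
      }
      return(TRUE)
    }
    i <- cells[idx, 1L]; j <- cells[idx, 2L]
    top <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:top) {
      f[i, j] <<- v
      rem2 <- rem
      rem2[i] <- rem2[i] - v * (if (i == j) 2L else 1L)
      if (i != j) rem2[j] <- rem2[j] - v
      # after the last cell of row i, allele i must be exhausted
      if (j == k && rem2[i] != 0L) { next }
      if (!rec(idx + 1L, rem2)) { f[i, j] <<- 0L; return(FALSE) }
    }
    f[i, j] <<- 0L
    TRUE
  }
  rec(1L, as.integer(allele_counts))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test on the genotype counts of one locus in one
#' population. All genotype tables compatible with the observed allele counts
#' are enumerated when their number does not exceed `max_tables`; otherwise a
#' Monte-Carlo test permutes the gene copies (Guo-Thompson style) and reports
#' `p = (b + 1)/(m + 1)`.
#'
#' @param x A [genotype_table()].
#' @param population Population label.
#' @param locus Locus name.
#' @param reps Monte-Carlo permutations.
#' @param max_tables Enumeration limit before switching to Monte-Carlo.
#' @return List with `p`, `method` (`"enumeration"`, `"monte-carlo"` or
#'   `"skipped"` for a monomorphic locus), `n` and `k` (allele count). Set the
#'   RNG seed with [set.seed()] for reproducible Monte-Carlo p-values.
#' @export
hwe_exact <- function(x, population, locus, reps = 10000, max_tables = 1e5) {
  stopifnot(inherits(x, "genotype_table"))
  sub <- x[x$population == population, , drop = FALSE]
  a <- locus_alleles(sub, locus)
  a <- a[!is.na(a[, 1L]), , drop = FALSE]
  if (nrow(a) < 2L) stop("fewer than two typed individuals")
  alleles <- sort(unique(as.vector(a)))
  if (length(alleles) < 2L) {
    message("locus ", locus, " is monomorphic in ", population,
            "; HWE test skipped")
    return(list(p = NA_real_, method = "skipped", n = nrow(a),
                k = length(alleles)))
  }
  fobs <- genotype_count_matrix(a, alleles)
  kern_obs <- hwe_log_kernel(diag(fobs), fobs[upper.tri(fobs)])
  counts <- vapply(seq_along(alleles), function(i)
    2L * fobs[i, i] + sum(fobs[i, -i]) + sum(fobs[-i, i]), integer(1))
  n <- nrow(a)
  tol <- 1e-9
  # try complete enumeration
  acc <- 0
  norm <- 0
  complete <- enumerate_hwe_tables(counts, function(f) {
    kern <- hwe_log_kernel(diag(f), f[upper.tri(f)])
    pr <- exp(lfactorial(n) + kern)     # margins constant cancels in ratio
    norm <<- norm + pr
    if (kern <= kern_obs + tol) acc <<- acc + pr
  }, max_tables = max_tables)
  if (complete) {
    return(list(p = acc / norm, method = "enumeration", n = n,
                k = length(alleles)))
  }
  copies <- rep(alleles, counts)
  b <- 0L
  for (r in seq_len(reps)) {
    s <- sample(copies)
    sim <- matrix(s, ncol = 2L)
    fsim <- genotype_count_matrix(sim, alleles)
    kern <- hwe_log_kernel(diag(fsim), fsim[upper.tri(fsim)])
    if (kern <= kern_obs + tol) b <- b + 1L
  }
  list(p = (b + 1) / (reps + 1), method = "monte-carlo", n = n,
       k = length(alleles))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests (capped at 1) and reports
#' the rejection decision at level `alpha`.
#'
#' @param pvals Numeric vector of p-values (`NA`s allowed for skipped tests).
#' @param alpha Family-wise error rate.
#' @return Data frame with columns `p`, `p_adjusted`, `reject`.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  m <- sum(!is.na(pvals))
  adj <- pmin(1, pvals * m)
  data.frame(p = pvals, p_adjusted = adj,
             reject = !is.na(adj) & adj <= alpha)
}
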