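# Linkage-disequilibrium effective population size: Burrows' composite
# disequilibrium, the bias-corrected LD method with MAF screening, and
# jackknife confidence intervals over locus pairs.

# Alleles at a locus retained under a MAF cutoff (frequencies from typed
# copies of the population sample).
maf_screened_alleles <- function(a, maf_cutoff) {
  copies <- a[!is.na(a)]
  if (length(copies) == 0L) return(numeric(0))
  f <- table(copies) / length(copies)
  as.numeric(names(f)[f >= maf_cutoff & f < 1])
}

#' Burrows' composite disequilibrium between two loci
#'
#' Computes Burrows' composite disequilibrium coefficient from unphased
#' diploid genotypes for every retained allele pair of two loci:
#' `Delta = cov(X, Y) / 2` with `X`, `Y` the per-individual gene counts
#' (0/1/2) of the two alleles (unbiased covariance, denominator `n - 1`),
#' and
#' `r^2 = Delta^2 / (pA(1-pA) pB(1-pB))`. Alleles with sample frequency
#' below `maf_cutoff` are dropped (not pooled); individuals missing either
#' genotype are excluded pairwise.
#'
#' @param x A [genotype_table()].
#' @param locusA,locusB Locus names.
#' @param maf_cutoff Minimum allele frequency in `[0, 0.5)`.
#' @param population Optional population label to subset to.
#' @return Data frame with one row per allele pair: `alleleA`, `alleleB`,
#'   `delta`, `r2` and `S` (individuals typed at both loci), or `NULL` (with
#'   a message) when either locus is monomorphic after screening.
#' @export
burrows_r2 <- function(x, locusA, locusB, maf_cutoff = 0,
                       population = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (!is.null(population))
    x <- x[x$population == population, , drop = FALSE]
  ga <- locus_alleles(x, locusA)
  gb <- locus_alleles(x, locusB)
  both <- !is.na(ga[, 1L]) & !is.na(gb[, 1L])
  if (sum(both) < 2L) stop("fewer than two individuals typed at both loci")
  ga <- ga[both, , drop = FALSE]
  gb <- gb[both, , drop = FALSE]
  aA <- maf_screened_alleles(ga, maf_cutoff)
  aB <- maf_screened_alleles(gb, maf_cutoff)
  if (length(aA) < 2L || length(aB) < 2L) {
    message("locus pair ", locusA, "/", locusB,
            " skipped: monomorphic after MAF screening")
    return(NULL)
  }
  S <- nrow(ga)
  # per-individual gene-count matrices for the retained alleles
  XA <- vapply(aA, function(A) rowSums(ga == A), numeric(S))
  XB <- vapply(aB, function(B) rowSums(gb == B), numeric(S))
  mA <- colMeans(XA)
  mB <- colMeans(XB)
  # unbiased covariance of gene counts, halved (Burrows composite Delta)
  delta <- (crossprod(XA, XB) / S - outer(mA, mB)) * (S / (S - 1)) / 2
  pq <- outer(mA / 2 * (1 - mA / 2), mB / 2 * (1 - mB / 2))
  r2 <- delta^2 / pq
  data.frame(alleleA = rep(aA, times = length(aB)),
             alleleB = rep(aB, each = length(aA)),
             delta = as.vector(delta), r2 = as.vector(r2), S = S)
}

# Sampling expectation of r^2 under random mating (Waples 2006).
expected_r2 <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

# Drift signal -> Ne transform (random-mating model); +Inf when there is no
# usable drift signal.
ne_from_r2prime <- function(r2prime, S) {
  if (is.na(r2prime) || r2prime <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2prime
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2prime)
  } else {
    disc <- 0.308^2 - 2.08 * r2prime
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2prime)
  }
}

# All allele-pair r^2 rows across locus pairs, tagged by pair id.
ldne_pairs <- function(x, population, maf_cutoff) {
  sub <- x[x$population == population, , drop = FALSE]
  L <- loci(x)
  if (length(L) < 2L) stop("at least two loci are required")
  out <- list()
  pid <- 0L
  for (i in 1:(length(L) - 1L)) for (j in (i + 1L):length(L)) {
    rows <- suppressMessages(
      burrows_r2(sub, L[i], L[j], maf_cutoff = maf_cutoff))
    if (is.null(rows)) next
    pid <- pid + 1L
    rows$pair <- pid
    rows$locusA <- L[i]
    rows$locusB <- L[j]
    out[[pid]] <- rows
  }
  if (length(out) == 0L) stop("fewer than two usable loci after screening")
  do.call(rbind, out)
}

# Weighted mean r2, harmonic mean S and Ne from a set of allele-pair rows.
ldne_from_rows <- function(rows) {
  w <- rows$S
  r2_mean <- sum(w * rows$r2) / sum(w)
  S <- sum(w) / sum(w / rows$S)       # harmonic mean weighted by S
  er2 <- expected_r2(S)
  r2p <- r2_mean - er2
  list(r2_mean = r2_mean, S = S, r2_expected = er2, r2_prime = r2p,
       ne_hat = ne_from_r2prime(r2p, S))
}

#' LD effective population size estimate
#'
#' Single-sample contemporary Ne from the linkage disequilibrium among
#' unlinked microsatellite loci. Allele-pair `r^2` values from
#' [burrows_r2()] are combined as a mean weighted by the number of
#' individuals typed at both loci; the small-sample expectation
#' `E[r^2] = 1/S + 3.19/S^2` (for harmonic mean sample size `S >= 30`;
#' `0.0018 + 0.907/S + 4.44/S^2` below 30) is subtracted, and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')` under the random-mating
#' model. A non-positive drift signal yields `Inf`. Confidence bounds are a
#' delete-one jackknife over locus pairs on the weighted mean `r^2`,
#' propagated through the Ne transform (see [jackknife_ci()]).
#'
#' @param x A [genotype_table()].
#' @param population Population label.
#' @param maf_cutoff Minimum allele frequency (the screening cutoffs 0,
#'   0.01, 0.02 and 0.05 are conventional).
#' @param ci Logical: also compute the jackknife confidence interval.
#' @param level Confidence level.
#' @return A list of class `ne_estimate` with `maf_cutoff`, `r2_mean`,
#'   `r2_expected`, `S`, `n_pairs`, `ne_hat`, and `ci_low`/`ci_high` when
#'   `ci = TRUE` (`ci_high` may be `Inf`).
#' @export
ldne_estimate <- function(x, population, maf_cutoff = 0.02, ci = TRUE,
                          level = 0.95) {
  rows <- ldne_pairs(x, population, maf_cutoff)
  est <- ldne_from_rows(rows)
  out <- c(list(maf_cutoff = maf_cutoff, n_pairs = max(rows$pair)), est)
  if (ci) {
    jk <- jackknife_rows(rows, level)
    out$ci_low <- jk[[1L]]
    out$ci_high <- jk[[2L]]
  }
  class(out) <- "ne_estimate"
  out
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD Ne estimate (MAF cutoff %.2f)\n", x$maf_cutoff))
  cat(sprintf("  mean r^2 = %.5f (expected %.5f, S = %.1f, %d locus pairs)\n",
              x$r2_mean, x$r2_expected, x$S, x$n_pairs))
  cat(sprintf("  Ne = %s", format(round(x$ne_hat, 1))))
  if (!is.null(x$ci_low))
    cat(sprintf("  [%s, %s]", format(round(x$ci_low, 1)),
                format(round(x$ci_high, 1))))
  cat("\n")
  invisible(x)
}

# Delete-one jackknife on the weighted mean r^2, endpoints transformed
# through the (monotone decreasing) Ne map. The deletion unit is the locus:
# dropping one locus removes every pair it participates in, which respects
# the correlation between pairs sharing a locus (a pairwise jackknife
# ignores it and its intervals come out far too narrow). unit = "pair"
# retains the naive version.
jackknife_rows <- function(rows, level = 0.95, unit = c("locus", "pair")) {
  unit <- match.arg(unit)
  if (length(unique(rows$pair)) < 3L)
    stop("jackknife needs at least three locus pairs")
  full <- ldne_from_rows(rows)
  groups <- if (unit == "locus" && !is.null(rows$locusA)) {
    lapply(unique(c(rows$locusA, rows$locusB)), function(l)
      rows$locusA != l & rows$locusB != l)
  } else {
    lapply(unique(rows$pair), function(p) rows$pair != p)
  }
  theta <- vapply(groups, function(keep) {
    if (!any(keep)) return(full$r2_mean)
    ldne_from_rows(rows[keep, , drop = FALSE])$r2_mean
  }, numeric(1))
  m <- length(theta)
  se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  r2_lo <- full$r2_mean - z * se
  r2_hi <- full$r2_mean + z * se
  c(ci_low = ne_from_r2prime(r2_hi - full$r2_expected, full$S),
    ci_high = ne_from_r2prime(r2_lo - full$r2_expected, full$S))
}

#' Jackknife confidence interval for the LD Ne estimate
#'
#' Delete-one jackknife on the weighted mean `r^2`, propagated through the
#' Ne transform. The deletion unit is the locus (removing all pairs the
#' locus participates in), which accounts for the correlation between
#' overlapping locus pairs; `unit = "pair"` gives the naive pairwise
#' jackknife, whose intervals are anti-conservative. The upper bound is
#' `Inf` whenever the lower bound on the drift signal `r^2 - E[r^2]` is
#' non-positive.
#'
#' @inheritParams ldne_estimate
#' @param level Confidence level.
#' @param unit Deletion unit, `"locus"` (default) or `"pair"`.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
jackknife_ci <- function(x, population, maf_cutoff = 0.02, level = 0.95,
                         unit = c("locus", "pair")) {
  rows <- ldne_pairs(x, population, maf_cutoff)
  jackknife_rows(rows, level, unit)
}
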