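# Female-founder simulation: how many founding females are needed to retain
# the observed number of mtDNA haplotypes, with an analytic oracle.

#' Simulate haplotype retention by k founder females
#'
#' Draws `k` maternal haplotypes from the source spectrum and records how
#' many distinct haplotypes the founding females carry, repeated `reps`
#' times. By default draws are i.i.d. from the haplotype frequencies (exact
#' in the limit of a large source population); setting `source_size` uses a
#' finite source of that many females (multivariate-hypergeometric draws)
#' for sensitivity analysis.
#'
#' @param source A [source_population_model()].
#' @param k Number of founding females (>= 1).
#' @param reps Number of simulation repetitions.
#' @param source_size Optional finite number of females in the source
#'   population; haplotype copy numbers are `round(p * source_size)` with
#'   remainders assigned to the most frequent haplotypes.
#' @return List of class `founder_female_result` with `k`, the vector
#'   `counts` of retained-haplotype numbers per replicate, and boxplot
#'   summaries (`median`, `q1`, `q3`, `min`, `max`). Set the RNG seed with
#'   [set.seed()] for reproducibility.
#' @export
draw_females <- function(source, k, reps = 100, source_size = NULL) {
  stopifnot(inherits(source, "source_population_model"))
  if (k < 1) stop("at least one female must be drawn")
  p <- source$haplotype_freqs
  if (is.null(source_size)) {
    counts <- vapply(seq_len(reps), function(r) {
      length(unique(sample.int(length(p), k, replace = TRUE, prob = p)))
    }, integer(1))
  } else {
    copies <- finite_copy_numbers(p, source_size)
    if (k > sum(copies)) stop("k exceeds the finite source size")
    pool <- rep(seq_along(p), copies)
    counts <- vapply(seq_len(reps), function(r) {
      length(unique(sample(pool, k, replace = FALSE)))
    }, integer(1))
  }
  q <- quantile(counts, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(k = k, counts = counts, median = q[2L], q1 = q[1L],
                 q3 = q[3L], min = min(counts), max = max(counts)),
            class = "founder_female_result")
}

# Integer copy numbers approximating p * size (each haplotype keeps >= 1
# copy; the rounding remainder goes to the most frequent haplotypes).
finite_copy_numbers <- function(p, size) {
  m <- pmax(1L, round(p * size))
  diff <- size - sum(m)
  if (diff != 0) {
    ord <- order(p, decreasing = TRUE)
    i <- 1L
    while (diff != 0 && i <= length(m)) {
      step <- sign(diff)
      if (m[ord[i]] + step >= 1L) {
        m[ord[i]] <- m[ord[i]] + step
        diff <- diff - step
      }
      i <- if (i == length(m)) 1L else i + 1L
    }
  }
  m
}

#' @export
print.founder_female_result <- function(x, ...) {
  cat(sprintf(
    "k = %d females: retained haplotypes median %g [IQR %g-%g, range %g-%g] (%d reps)\n",
    x$k, x$median, x$q1, x$q3, x$min, x$max, length(x$counts)))
  invisible(x)
}

#' Expected number of distinct haplotypes among k draws
#'
#' Analytic expectation `E[H] = sum_h (1 - (1 - p_h)^k)` under i.i.d. draws
#' from the haplotype spectrum; the closed-form oracle for [draw_females()].
#'
#' @param source A [source_population_model()].
#' @param k Number of draws (>= 1).
#' @return Expected distinct haplotype count.
#' @export
expected_haplotypes <- function(source, k) {
  stopifnot(inherits(source, "source_population_model"))
  if (k < 1) stop("k must be at least 1")
  sum(1 - (1 - source$haplotype_freqs)^k)
}

#' Infer the plausible number of founding females
#'
#' Runs (or accepts) [draw_females()] results over a contiguous grid of
#' female numbers and returns the `k` values whose replicate distribution is
#' compatible with the observed haplotype count. The default rule accepts
#' `k` when the observed count lies within the interquartile range of the
#' replicates (the boxplot-box criterion); `rule = "median"` requires
#' median equality.
#'
#' @param results List of `founder_female_result` objects over a contiguous
#'   k grid, or a [source_population_model()] (in which case the grid is
#'   simulated with `reps` repetitions for `k = k_grid`).
#' @param observed Observed number of haplotypes.
#' @param rule Acceptance rule: `"iqr"` (default) or `"median"`.
#' @param k_grid,reps Grid and repetitions used when `results` is a source
#'   model.
#' @return Integer vector of accepted `k` (possibly empty).
#' @export
infer_female_range <- function(results, observed, rule = c("iqr", "median"),
                               k_grid = 1:10, reps = 100) {
  rule <- match.arg(rule)
  if (inherits(results, "source_population_model"))
    results <- lapply(k_grid, function(k) draw_females(results, k, reps))
  if (length(results) == 0L) stop("empty simulation grid")
  ks <- vapply(results, `[[`, numeric(1), "k")
  if (length(ks) > 1L && any(diff(sort(ks)) != 1))
    stop("k grid must be contiguous")
  ok <- vapply(results, function(r) {
    if (rule == "iqr") r$q1 <= observed && observed <= r$q3
    else r$median == observed
  }, logical(1))
  as.integer(sort(ks[ok]))
}
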