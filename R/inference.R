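# Grid-matching inference: which founder sizes and growth rates are
# compatible with the observed diversity and census size, and the model
# object tying the pipeline together.

grid_cell <- function(grid, B, lambda) {
  i <- which(grid$cells$B == B & abs(grid$cells$lambda - lambda) < 1e-9)
  grid$results[[i]]
}

grid_stat <- function(res, eval_year, what) {
  s <- res$summary
  row <- s[s$year == eval_year, ]
  if (nrow(row) == 0L) stop("evaluation year outside the simulated range")
  row[[what]]
}

#' Accepted growth rates from the census-size comparison
#'
#' A growth rate `lambda` is accepted when, for at least one non-extinct
#' founder size in the grid (extinction fraction below
#' `extinct_threshold`), the mean census among surviving iterations at the
#' evaluation year (i) lies within `nc_range` widened by the relative
#' tolerance `tol` (the census window is a rough field estimate) and
#' (ii) sits below `plateau_frac` of the carrying capacity -- a census
#' already at the capacity plateau exceeds the field estimate and carries
#' no information about `lambda`.
#'
#' @param grid A [run_grid()] result.
#' @param nc_range Length-2 census-size range (e.g. `c(1500, 4000)`).
#' @param eval_year Evaluation year (default 90).
#' @param tol Relative widening of `nc_range`.
#' @param plateau_frac Fraction of capacity above which a census is treated
#'   as saturated.
#' @param extinct_threshold Scenarios at or above this extinction fraction
#'   are ignored.
#' @return Sorted numeric vector of accepted `lambda` values.
#' @export
match_lambda <- function(grid, nc_range, eval_year = 90, tol = 0.2,
                         plateau_frac = 0.95, extinct_threshold = 0.5) {
  stopifnot(inherits(grid, "founder_grid"))
  if (nrow(grid$cells) == 0L) stop("empty scenario grid")
  nc_range <- range(nc_range)
  lo <- nc_range[1L] * (1 - tol)
  hi <- nc_range[2L] * (1 + tol)
  ok <- vapply(seq_len(nrow(grid$cells)), function(i) {
    res <- grid$results[[i]]
    if (res$extinct_frac >= extinct_threshold) return(FALSE)
    nc <- grid_stat(res, eval_year, "mean_census")
    !is.na(nc) && nc >= lo && nc <= hi &&
      nc < plateau_frac * res$config$capacity
  }, logical(1))
  sort(unique(grid$cells$lambda[ok]))
}

#' Accepted founder sizes from the diversity comparison
#'
#' A founder size `B` is accepted when the observed mean alleles per locus
#' lies within the central interval of the simulated terminal `N_a`
#' distribution (mean +/- 1 sd by default, or the 2.5-97.5% quantile band
#' with `rule = "quantile"`) for at least one accepted growth rate.
#'
#' @param grid A [run_grid()] result.
#' @param observed_na Observed mean number of alleles per locus.
#' @param lambdas Growth rates to consider (typically the output of
#'   [match_lambda()]); defaults to all in the grid.
#' @param eval_year Evaluation year (default 90).
#' @param rule `"mean_sd"` (default) or `"quantile"`.
#' @param extinct_threshold Scenarios at or above this extinction fraction
#'   are ignored.
#' @return Sorted numeric vector of accepted founder sizes (empty, with a
#'   warning, when every candidate scenario is extinct).
#' @export
match_founder_size <- function(grid, observed_na, lambdas = NULL,
                               eval_year = 90,
                               rule = c("mean_sd", "quantile"),
                               extinct_threshold = 0.5) {
  stopifnot(inherits(grid, "founder_grid"))
  rule <- match.arg(rule)
  if (observed_na <= 0) stop("observed_na must be positive")
  if (is.null(lambdas)) lambdas <- unique(grid$cells$lambda)
  cand <- which(grid$cells$lambda %in% lambdas)
  if (length(cand) == 0L) stop("no grid cells at the requested lambdas")
  usable <- 0L
  ok <- logical(nrow(grid$cells))
  for (i in cand) {
    res <- grid$results[[i]]
    if (res$extinct_frac >= extinct_threshold) next
    usable <- usable + 1L
    na_term <- res$na[res$summary$year == eval_year, ]
    na_term <- na_term[!is.na(na_term)]
    if (length(na_term) < 2L) next
    band <- if (rule == "mean_sd") {
      mean(na_term) + c(-1, 1) * sd(na_term)
    } else {
      quantile(na_term, c(0.025, 0.975), names = FALSE)
    }
    ok[i] <- observed_na >= band[1L] && observed_na <= band[2L]
  }
  if (usable == 0L)
    warning("all candidate scenarios went extinct; no founder size accepted")
  sort(unique(grid$cells$B[ok]))
}

#' Fit the introduction-history model
#'
#' Runs the full grid-matching inference: simulates the founder-size by
#' growth-rate grid from the source population model, accepts growth rates
#' whose census trajectory passes through the observed census window at the
#' evaluation year ([match_lambda()]), accepts founder sizes whose terminal
#' diversity is compatible with the observed mean alleles per locus at the
#' accepted growth rates ([match_founder_size()]), and summarises the
#' effective-to-census size ratio ([ne_nc_ratio()]) when an `ne_range` is
#' supplied.
#'
#' @param source A [source_population_model()] for the source population.
#' @param observed_na Observed mean alleles per locus in the descendant
#'   population.
#' @param nc_range Observed census-size range.
#' @param founder_sizes,lambdas Grid of founder sizes and growth rates.
#' @param config Template [demographic_config()].
#' @param eval_year Evaluation year for both comparisons.
#' @param ne_range Optional observed effective-size range.
#' @param rule Acceptance rule for the diversity comparison.
#' @return An object of class `founder_fit` with the simulated `grid`, the
#'   accepted sets, and the inputs. Set the RNG seed with [set.seed()] for
#'   reproducibility.
#' @export
fit_founder_history <- function(source, observed_na, nc_range,
                                founder_sizes = c(20, 40, 60, 80),
                                lambdas = c(1.02, 1.04, 1.06, 1.08, 1.10),
                                config = demographic_config(),
                                eval_year = 90, ne_range = NULL,
                                rule = "mean_sd") {
  grid <- run_grid(source, founder_sizes, lambdas, config)
  acc_lambda <- match_lambda(grid, nc_range, eval_year)
  acc_B <- match_founder_size(grid, observed_na,
                              lambdas = if (length(acc_lambda)) acc_lambda,
                              eval_year = eval_year, rule = rule)
  ratio <- if (!is.null(ne_range)) ne_nc_ratio(ne_range, nc_range)
  structure(list(grid = grid, accepted_lambda = acc_lambda,
                 accepted_B = acc_B, observed_na = observed_na,
                 nc_range = range(nc_range), ne_range = ne_range,
                 ne_nc = ratio, eval_year = eval_year, rule = rule),
            class = "founder_fit")
}

#' @export
print.founder_fit <- function(x, ...) {
  cat("Founder-history grid match\n")
  cat(sprintf("  observed N_a = %.2f, census window %g-%g (year %d)\n",
              x$observed_na, x$nc_range[1L], x$nc_range[2L], x$eval_year))
  cat("  accepted lambda:",
      if (length(x$accepted_lambda)) paste(x$accepted_lambda, collapse = ", ")
      else "(none)", "\n")
  cat("  accepted founder size:",
      if (length(x$accepted_B)) paste(x$accepted_B, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$ne_nc)) cat("  Ne/Nc:", x$ne_nc$label, "\n")
  invisible(x)
}

#' @export
summary.founder_fit <- function(object, ...) {
  cells <- object$grid$cells
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    res <- object$grid$results[[i]]
    data.frame(B = cells$B[i], lambda = cells$lambda[i],
               na_eval = grid_stat(res, object$eval_year, "mean_na"),
               na_sd = grid_stat(res, object$eval_year, "sd_na"),
               census_eval = grid_stat(res, object$eval_year, "mean_census"),
               extinct_frac = res$extinct_frac)
  })
  out <- do.call(rbind, rows)
  out$lambda_accepted <- out$lambda %in% object$accepted_lambda
  out$B_accepted <- out$B %in% object$accepted_B
  out
}

#' @export
coef.founder_fit <- function(object, ...) {
  c(B_min = if (length(object$accepted_B)) min(object$accepted_B) else NA,
    B_max = if (length(object$accepted_B)) max(object$accepted_B) else NA,
    lambda_min = if (length(object$accepted_lambda))
      min(object$accepted_lambda) else NA,
    lambda_max = if (length(object$accepted_lambda))
      max(object$accepted_lambda) else NA)
}

#' @export
plot.founder_fit <- function(x, ...) {
  cells <- x$grid$cells
  lambdas <- sort(unique(cells$lambda))
  Bs <- sort(unique(cells$B))
  old <- graphics::par(mfrow = c(1, length(Bs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (B in Bs) {
    first <- TRUE
    for (li in seq_along(lambdas)) {
      res <- grid_cell(x$grid, B, lambdas[li])
      s <- res$summary
      if (first) {
        graphics::plot(s$year, s$mean_na, type = "l", col = li,
                       ylim = c(0, max(s$mean_na, na.rm = TRUE) * 1.1),
                       xlab = "Year", ylab = "Mean alleles per locus",
                       main = paste("B =", B), ...)
        first <- FALSE
      } else {
        graphics::lines(s$year, s$mean_na, col = li)
      }
    }
    graphics::abline(h = x$observed_na, lty = 2)
  }
  invisible(x)
}
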