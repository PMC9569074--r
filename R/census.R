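# Census size: Lincoln-Petersen mark-recapture estimation, extrapolation to
# multiple breeding sites, and the Ne/Nc ratio summary.

#' Lincoln-Petersen mark-recapture estimate
#'
#' Point estimate of abundance from a single mark-recapture session:
#' `N = M * C / R`, rounded to the nearest integer.
#'
#' @param M Number marked at the first visit.
#' @param C Number captured at the second visit.
#' @param R Number of marked recaptures (`1 <= R <= min(M, C)`).
#' @return A list of class `census_estimate` with `M`, `C`, `R` and the
#'   point estimate `N_c_hat`.
#' @examples
#' lincoln_petersen(81, 51, 21)  # 197 toads at one waterhole
#' @export
lincoln_petersen <- function(M, C, R) {
  stopifnot(length(M) == 1L, length(C) == 1L, length(R) == 1L)
  if (R < 1) stop("estimate undefined: no marked recaptures (R = 0)")
  if (R > min(M, C)) stop("recaptures cannot exceed min(M, C)")
  est <- round(M * C / R)
  structure(list(M = M, C = C, R = R, N_c_hat = est),
            class = "census_estimate")
}

#' @export
print.census_estimate <- function(x, ...) {
  cat(sprintf("Lincoln-Petersen: N = %d x %d / %d = %d\n",
              x$M, x$C, x$R, x$N_c_hat))
  invisible(x)
}

#' Extrapolate a per-site abundance to a total census range
#'
#' Multiplies a per-site abundance range by a breeding-site count range.
#'
#' @param per_site Numeric length-2 range of animals per site.
#' @param n_sites Numeric length-2 range of breeding-site counts.
#' @return Length-2 numeric range of total census size.
#' @examples
#' extrapolate_nc(c(150, 200), c(10, 20))  # about 1500-4000
#' @export
extrapolate_nc <- function(per_site, n_sites) {
  per_site <- range(per_site)
  n_sites <- range(n_sites)
  if (any(per_site <= 0) || any(n_sites <= 0))
    stop("ranges must be positive")
  c(per_site[1L] * n_sites[1L], per_site[2L] * n_sites[2L])
}

#' Ratio of effective to census population size
#'
#' Range of `N_e / N_c` obtained as `[min(ne)/max(nc), max(ne)/min(nc)]`.
#' The printed label rounds each bound to one significant figure, the
#' precision at which such ratios are conventionally reported.
#'
#' @param ne_range Length-2 positive range of effective sizes.
#' @param nc_range Length-2 positive range of census sizes.
#' @return List of class `ne_nc_ratio` with `lower`, `upper` and the
#'   formatted `label`.
#' @examples
#' ne_nc_ratio(c(20, 57), c(1500, 4000))  # 0.005-0.04
#' @export
ne_nc_ratio <- function(ne_range, nc_range) {
  ne_range <- range(ne_range)
  nc_range <- range(nc_range)
  if (any(ne_range <= 0) || any(nc_range <= 0))
    stop("ranges must be positive")
  lower <- ne_range[1L] / nc_range[2L]
  upper <- ne_range[2L] / nc_range[1L]
  label <- if (abs(lower - upper) < 1e-12) {
    format(signif(lower, 1))
  } else {
    paste0(format(signif(lower, 1)), "-", format(signif(upper, 1)))
  }
  structure(list(lower = lower, upper = upper, label = label),
            class = "ne_nc_ratio")
}

#' @export
print.ne_nc_ratio <- function(x, ...) {
  cat("Ne/Nc ratio:", x$label, "\n")
  invisible(x)
}
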