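# Isolation by distance: Nei genetic distance between individuals vs
# Vincenty geodesic distance between their sites, tested with Spearman's rho.

#' Vincenty ellipsoid distance between coordinates
#'
#' Geodesic distance on the WGS-84 ellipsoid, in kilometres.
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates.
#' @return Distance in km.
#' @export
vincenty_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distVincentyEllipsoid(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Individual-level Nei (1972) standard genetic distance from diploid
# genotypes: allele frequency vectors take values 0, 0.5, 1 per individual;
# J-terms are averaged over loci before the log-ratio. Infinite when two
# individuals share no alleles at any locus.
nei_individual_distance <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  L <- loci(x)
  n <- nrow(x)
  # per-locus: identity-coefficient contributions for each individual pair
  jxy <- matrix(0, n, n)
  jx <- matrix(0, n, n)  # accumulates Jx per pair (same for all partners)
  nl <- matrix(0, n, n)  # loci typed in both
  for (l in L) {
    a <- locus_alleles(x, l)
    typed <- !is.na(a[, 1L])
    alleles <- sort(unique(as.vector(a[typed, , drop = FALSE])))
    if (length(alleles) == 0L) next
    # frequency matrix n x k with rows 0/0.5/1
    fm <- matrix(0, n, length(alleles))
    t_idx <- which(typed)
    i1 <- cbind(t_idx, match(a[t_idx, 1L], alleles))
    i2 <- cbind(t_idx, match(a[t_idx, 2L], alleles))
    fm[i1] <- fm[i1] + 0.5
    fm[i2] <- fm[i2] + 0.5
    jl <- fm %*% t(fm)                    # pairwise sum x_i y_i
    diag_j <- rowSums(fm^2)
    tt <- outer(typed, typed, "&")
    jxy <- jxy + jl * tt
    jx <- jx + outer(diag_j, rep(1, n)) * tt
    nl <- nl + tt
  }
  jxy <- jxy / pmax(nl, 1)
  jx <- jx / pmax(nl, 1)
  d <- -log(pmax(jxy, 0) / sqrt(jx * t(jx)))
  d[nl == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(x$individual, x$individual)
  d
}

#' Isolation-by-distance test against a reference site
#'
#' For every pair made of one individual from a non-reference site and one
#' individual from the reference site, the individual-level Nei genetic
#' distance is compared with the Vincenty geodesic distance between their
#' sites; association is measured with Spearman's rho. The permutation test
#' shuffles individuals among the non-reference sites (keeping site sample
#' sizes) and reports a one-sided `p = (b + 1)/(m + 1)` for positive
#' correlation; an asymptotic p-value from [stats::cor.test()] is also given.
#'
#' @param x A [genotype_table()] whose population labels are site codes.
#' @param sites A [site_table()] covering all site codes in `x`.
#' @param reference_site Site code of the origin (e.g. the release site).
#' @param permutations Number of permutations.
#' @return List with `rho`, `p` (permutation), `p_asymptotic`, `n_pairs`,
#'   `permutations`. Set the RNG seed with [set.seed()] for reproducibility.
#' @export
ibd_spearman <- function(x, sites, reference_site, permutations = 10000) {
  stopifnot(inherits(x, "genotype_table"), inherits(sites, "site_table"))
  if (!reference_site %in% x$population)
    stop("reference site absent from the data")
  missing_sites <- setdiff(unique(x$population), sites$site)
  if (length(missing_sites) > 0L)
    stop("sites without coordinates: ", paste(missing_sites, collapse = ", "))
  if (length(setdiff(unique(x$population), reference_site)) < 2L)
    stop("at least two non-reference sites are required")
  gd_all <- nei_individual_distance(x)
  is_ref <- x$population == reference_site
  ref_idx <- which(is_ref)
  oth_idx <- which(!is_ref)
  site_of <- x$population
  geo_site <- function(code) {
    i <- match(code, sites$site)
    j <- match(reference_site, sites$site)
    vincenty_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j])
  }
  site_codes <- unique(site_of[oth_idx])
  site_dist <- vapply(site_codes, geo_site, numeric(1))
  names(site_dist) <- site_codes
  if (max(site_dist) - min(site_dist) < 1e-9) {
    warning("all sites co-located: isolation-by-distance is degenerate")
    return(list(rho = NA_real_, p = NA_real_, p_asymptotic = NA_real_,
                n_pairs = 0L, permutations = permutations))
  }
  gd <- gd_all[oth_idx, ref_idx, drop = FALSE]   # rows: non-ref individuals
  gvec <- as.vector(gd)
  rho_for <- function(codes) {
    geo <- rep(site_dist[codes], times = length(ref_idx))
    suppressWarnings(cor(gvec, geo, method = "spearman",
                         use = "complete.obs"))
  }
  obs_codes <- site_of[oth_idx]
  rho <- rho_for(obs_codes)
  b <- 0L
  for (r in seq_len(permutations)) {
    if (rho_for(sample(obs_codes)) >= rho - 1e-12) b <- b + 1L
  }
  ct <- suppressWarnings(stats::cor.test(
    gvec, rep(site_dist[obs_codes], times = length(ref_idx)),
    method = "spearman", alternative = "greater", exact = FALSE))
  list(rho = rho, p = (b + 1) / (permutations + 1),
       p_asymptotic = ct$p.value,
       n_pairs = sum(!is.na(gvec)), permutations = permutations)
}
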