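# Synthetic-data generation: haplotype spectra, source models, sampled
# datasets with synthetic sequences, and radial site layouts with a serial
# founder chain, so every analysis stage is testable without external data.

#' Specification for a synthetic source population
#'
#' Targets for the generator: the haplotype spectrum size and diversity,
#' and the per-locus allele-count and heterozygosity structure of the
#' microsatellite panel. Diversity targets are what a sample of
#' `sample_size` diploids is expected to show, matching how such summaries
#' are reported.
#'
#' @param n_haplotypes Number of haplotypes in the source spectrum.
#' @param haplotype_diversity Target (sample) haplotype diversity.
#' @param sample_size Reference number of diploid individuals.
#' @param n_loci Number of microsatellite loci.
#' @param mean_alleles Target mean number of alleles per locus observed in
#'   the reference sample.
#' @param expected_het Target (unbiased sample) expected heterozygosity.
#' @param seq_length Length of the synthetic alignment (default 1827).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_haplotypes = 38, haplotype_diversity = 0.967,
                           sample_size = 89, n_loci = 11,
                           mean_alleles = 17.3, expected_het = 0.795,
                           seq_length = 1827) {
  stopifnot(n_haplotypes >= 1, n_loci >= 1, sample_size >= 2,
            haplotype_diversity >= 0, haplotype_diversity <= 1,
            expected_het >= 0, expected_het < 1, mean_alleles >= 1)
  # sample-level targets back-transformed to the underlying spectra
  hap_target <- haplotype_diversity * (sample_size - 1) / sample_size
  het_target <- expected_het * (2 * sample_size - 1) / (2 * sample_size)
  if (n_haplotypes > 1 && hap_target > 1 - 1 / n_haplotypes + 1e-9)
    stop("haplotype diversity unachievable for ", n_haplotypes,
         " haplotypes")
  if (n_haplotypes == 1 && haplotype_diversity > 1e-9)
    stop("a single haplotype forces zero diversity")
  if (het_target > 1 - 1 / mean_alleles + 1e-9)
    stop("incompatible targets: expected_het too high for mean_alleles")
  structure(list(n_haplotypes = n_haplotypes,
                 haplotype_diversity = haplotype_diversity,
                 hap_target = hap_target, sample_size = sample_size,
                 n_loci = n_loci, mean_alleles = mean_alleles,
                 expected_het = expected_het, het_target = het_target,
                 seq_length = seq_length),
            class = "synthetic_spec")
}

#' Built-in synthetic population presets
#'
#' `"yantai-like"` emulates a large, diverse native source (89 diploids, 38
#' haplotypes, haplotype diversity 0.967, 11 loci, 17.3 alleles/locus,
#' expected heterozygosity 0.795); `"beijing-like"` a severely bottlenecked
#' descendant (150 diploids, 2 haplotypes, h 0.433, 6 alleles/locus, H_E
#' 0.581).
#'
#' @param name Preset name.
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("yantai-like", "beijing-like")) {
  name <- match.arg(name)
  switch(name,
    "yantai-like" = synthetic_spec(38, 0.967, 89, 11, 17.3, 0.795),
    "beijing-like" = synthetic_spec(2, 0.433, 150, 11, 6.0, 0.581))
}

#' Generate a haplotype frequency spectrum
#'
#' Dirichlet-perturbed geometric frequencies whose base ratio is rescaled by
#' bisection until the sample-free diversity `1 - sum p^2` matches the
#' target within `1e-3`; when the skewed spectrum cannot reach a
#' near-uniform target it is blended toward the uniform spectrum, again by
#' bisection. Geometric bases keep rare haplotypes in the spectrum, as in
#' real source populations.
#'
#' @param n_haplotypes Number of haplotypes (>= 1).
#' @param diversity Target sample-free diversity `1 - sum p^2` (at most
#'   `1 - 1/n_haplotypes`).
#' @param concentration Dirichlet concentration of the perturbation.
#' @return Frequency vector summing to 1, decreasing. Set the RNG seed with
#'   [set.seed()] for reproducibility.
#' @export
make_haplotype_spectrum <- function(n_haplotypes, diversity,
                                    concentration = 100) {
  H <- n_haplotypes
  if (H < 1) stop("need at least one haplotype")
  if (H == 1) {
    if (diversity > 1e-9) stop("one haplotype forces zero diversity")
    return(1)
  }
  if (diversity > 1 - 1 / H + 1e-9)
    stop("diversity unachievable for ", H, " haplotypes")
  w <- rgamma(H, concentration, concentration)
  p_of <- function(q) {
    p <- w * q^(seq_len(H) - 1L)
    p / sum(p)
  }
  dvr <- function(p) 1 - sum(p^2)
  target <- diversity
  # bisect the geometric ratio on (0, 1]
  lo <- 1e-6; hi <- 1
  if (dvr(p_of(hi)) < target) {
    # blend the q = 1 spectrum toward uniform
    base <- p_of(1)
    mix <- function(a) (1 - a) * base + a / H
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (dvr(mix(mid)) < target) lo <- mid else hi <- mid
    }
    p <- mix((lo + hi) / 2)
  } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (dvr(p_of(mid)) < target) lo <- mid else hi <- mid
    }
    p <- p_of((lo + hi) / 2)
  }
  if (abs(dvr(p) - target) > 1e-3)
    stop("spectrum tuning failed to reach the diversity target")
  sort(p, decreasing = TRUE)
}

# One locus' allele frequencies hitting (i) a sample-free gene diversity
# target and (ii) an expected observed-allele-count target at `copies` gene
# copies. Structure: a geometric "head" of common alleles plus a flatter
# jittered tail of rare alleles (frequency ~tail_freq), the combination
# found in diverse microsatellite panels.
fit_locus_spectrum <- function(target_alleles, target_div, copies,
                               tail_freq = 0.015, max_iter = 30) {
  Kh <- max(2L, min(round(target_alleles / 3), 8L))
  w <- rgamma(Kh, 60, 60)
  head_of <- function(q) {
    p <- w * q^(seq_len(Kh) - 1L)
    p / sum(p)
  }
  p_obs_tail <- 1 - (1 - tail_freq)^copies
  Kt <- max(0L, round((target_alleles - Kh) / p_obs_tail))
  spectrum <- NULL
  for (iter in seq_len(max_iter)) {
    eps <- Kt * tail_freq
    if (eps > 0.7) { Kt <- floor(0.7 / tail_freq); eps <- Kt * tail_freq }
    # bisect head ratio for the diversity target given the tail
    div_of <- function(q) {
      ph <- head_of(q) * (1 - eps)
      1 - (sum(ph^2) + Kt * tail_freq^2)
    }
    lo <- 1e-6; hi <- 1
    if (div_of(hi) < target_div) {
      q <- 1  # head as flat as the perturbation allows
    } else {
      for (i in 1:50) {
        mid <- (lo + hi) / 2
        if (div_of(mid) < target_div) lo <- mid else hi <- mid
      }
      q <- (lo + hi) / 2
    }
    p <- c(head_of(q) * (1 - eps), rep(tail_freq, Kt))
    e_obs <- sum(1 - (1 - p)^copies)
    if (abs(e_obs - target_alleles) < 0.25) { spectrum <- p; break }
    Kt <- max(0L, Kt + round((target_alleles - e_obs) / p_obs_tail))
    spectrum <- p
  }
  if (is.null(spectrum))
    stop("locus spectrum tuning failed")
  e_obs <- sum(1 - (1 - spectrum)^copies)
  if (abs(e_obs - target_alleles) > 1)
    stop("incompatible targets: cannot reach ", target_alleles,
         " observed alleles at gene diversity ", round(target_div, 3))
  # mild multiplicative jitter on the tail so rare alleles are not equifrequent
  if (Kt > 0) {
    tail <- spectrum[(Kh + 1):(Kh + Kt)] * rgamma(Kt, 25, 25)
    spectrum[(Kh + 1):(Kh + Kt)] <- tail / sum(tail) * (Kt * tail_freq)
  }
  spectrum / sum(spectrum)
}

#' Build a synthetic source population model
#'
#' Generates the haplotype spectrum with [make_haplotype_spectrum()] and
#' per-locus allele frequency vectors tuned so that a reference sample of
#' `sample_size` diploids is expected to show the target mean allele count
#' and expected heterozygosity. Allele sizes are even-spaced
#' (dinucleotide-like) starting at 100.
#'
#' @param spec A [synthetic_spec()].
#' @return A [source_population_model()]. Set the RNG seed with
#'   [set.seed()] for reproducibility.
#' @export
make_source_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  hap <- make_haplotype_spectrum(spec$n_haplotypes, spec$hap_target)
  names(hap) <- sprintf("Hap%02d", seq_along(hap))
  copies <- 2 * spec$sample_size
  af <- lapply(seq_len(spec$n_loci), function(l) {
    p <- fit_locus_spectrum(spec$mean_alleles, spec$het_target, copies)
    names(p) <- as.character(100 + 2 * (seq_along(p) - 1L))
    p
  })
  names(af) <- sprintf("L%02d", seq_len(spec$n_loci))
  model <- source_population_model(hap, af)
  attr(model, "spec") <- spec
  model
}

# Synthetic sequences: one random reference plus a distinct random mutation
# set per haplotype (collision-checked), so pairwise differences are
# positive and variable.
synth_sequences <- function(n_haplotypes, seq_length, mean_mutations = 6) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, seq_length, replace = TRUE)
  keys <- character(0)
  seqs <- character(n_haplotypes)
  for (h in seq_len(n_haplotypes)) {
    repeat {
      nm <- 1L + stats::rpois(1, mean_mutations)
      pos <- sort(sample.int(seq_length, nm))
      key <- paste(pos, collapse = ",")
      if (!key %in% keys) break
    }
    keys <- c(keys, key)
    s <- ref
    for (p in pos) s[p] <- sample(setdiff(bases, ref[p]), 1L)
    seqs[h] <- paste(s, collapse = "")
  }
  seqs
}

#' Sample a synthetic dataset from a source model
#'
#' Draws `n` diploid individuals allele-wise from the model (linkage
#' equilibrium), assigns each a maternal haplotype, realizes synthetic
#' aligned sequences for the haplotypes, and optionally masks genotypes at
#' random.
#'
#' @param model A [source_population_model()].
#' @param n Number of individuals (>= 1).
#' @param population Population label.
#' @param missingness Per-genotype missing probability.
#' @param sequences Logical: attach synthetic aligned sequences.
#' @param seq_length Alignment length (defaults to the model's spec, or
#'   1827).
#' @return List with `genotypes` (a [genotype_table()]) and `haplotypes`
#'   (a [haplotype_dataset()]). Set the RNG seed with [set.seed()] for
#'   reproducibility.
#' @export
sample_dataset <- function(model, n, population = "P1", missingness = 0,
                           sequences = TRUE, seq_length = NULL) {
  stopifnot(inherits(model, "source_population_model"))
  if (n < 1) stop("n must be at least 1")
  if (is.null(seq_length)) {
    sp <- attr(model, "spec")
    seq_length <- if (!is.null(sp)) sp$seq_length else 1827L
  }
  L <- length(model$allele_freqs)
  ids <- sprintf("%s_%03d", population, seq_len(n))
  alleles <- matrix(0L, n, 2L * L)
  for (l in seq_len(L)) {
    f <- model$allele_freqs[[l]]
    sizes <- as.integer(names(f))
    alleles[, 2L * l - 1L] <- sizes[draw_from(f, n)]
    alleles[, 2L * l] <- sizes[draw_from(f, n)]
    if (missingness > 0) {
      miss <- runif(n) < missingness
      alleles[miss, c(2L * l - 1L, 2L * l)] <- NA_integer_
    }
  }
  gt <- genotype_table(ids, rep(population, n), alleles,
                       names(model$allele_freqs))
  hap_idx <- draw_from(model$haplotype_freqs, n)
  hap_names <- names(model$haplotype_freqs)
  if (is.null(hap_names))
    hap_names <- sprintf("Hap%02d", seq_along(model$haplotype_freqs))
  hd <- if (sequences) {
    seqs <- synth_sequences(length(model$haplotype_freqs), seq_length)
    haplotype_dataset(ids, rep(population, n),
                      haplotype = hap_names[hap_idx],
                      sequence = seqs[hap_idx])
  } else {
    haplotype_dataset(ids, rep(population, n),
                      haplotype = hap_names[hap_idx])
  }
  list(genotypes = gt, haplotypes = hd)
}

# Empirical re-estimation of a model after a founder bottleneck of
# `b_copies` gene copies per locus (and `b_copies` haplotype draws):
# one step of a serial founder chain.
bottleneck_model <- function(model, b_copies) {
  hap <- model$haplotype_freqs
  hcnt <- tabulate(draw_from(hap, b_copies), nbins = length(hap))
  hf <- hcnt / sum(hcnt)
  names(hf) <- names(hap)
  keep_h <- hf > 0
  af <- lapply(model$allele_freqs, function(f) {
    cnt <- tabulate(draw_from(f, b_copies), nbins = length(f))
    g <- cnt / sum(cnt)
    names(g) <- names(f)
    g[g > 0]
  })
  source_population_model(hf[keep_h], af)
}

#' Radial site layout with a serial founder chain
#'
#' Places `n_sites` sites at increasing geodesic distances east of an
#' origin and generates genotypes through a serial founder chain: site 1
#' samples the source model, and each subsequent site samples a model
#' re-founded from its predecessor through a bottleneck of `b_copies` gene
#' copies, so genetic distance from the origin increases along the chain
#' (an embedded isolation-by-distance signal).
#'
#' @param model A [source_population_model()].
#' @param n_sites Number of sites (>= 2).
#' @param origin `c(lat, lon)` of the first site.
#' @param max_km Distance of the farthest site from the origin.
#' @param n_per_site Individuals sampled per site.
#' @param b_copies Bottleneck size in gene copies between successive sites
#'   (default 8: a handful of colonizing pairs, the strong expansion-front
#'   drift regime the layout is meant to emulate).
#' @return List with `sites` (a [site_table()]), `genotypes` (a combined
#'   [genotype_table()] with site codes as population labels) and
#'   `models` (per-site frequency models). Set the RNG seed with
#'   [set.seed()] for reproducibility.
#' @export
make_radial_layout <- function(model, n_sites = 5,
                               origin = c(40.0, 116.2), max_km = 13,
                               n_per_site = 15, b_copies = 8) {
  if (n_sites < 2) stop("need at least two sites")
  km <- seq(0, max_km, length.out = n_sites)
  lat <- rep(origin[1L], n_sites)
  lon <- origin[2L] + km / (111.32 * cos(origin[1L] * pi / 180))
  codes <- sprintf("S%02d", seq_len(n_sites))
  sites <- site_table(codes, lat, lon)
  models <- vector("list", n_sites)
  models[[1L]] <- model
  for (i in 2:n_sites)
    models[[i]] <- bottleneck_model(models[[i - 1L]], b_copies)
  tabs <- lapply(seq_len(n_sites), function(i)
    sample_dataset(models[[i]], n_per_site, population = codes[i],
                   sequences = FALSE)$genotypes)
  combined <- do.call(rbind, lapply(tabs, as.data.frame))
  gt <- genotype_table(combined$individual, combined$population,
                       as.matrix(combined[, -(1:2)]), loci(tabs[[1L]]))
  list(sites = sites, genotypes = gt, models = models)
}
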