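# Shared builders for the test suite: all fixtures are generated in code.

# Source model with L loci of K equifrequent alleles (no mtDNA variation):
# the neutral panel used for Wright-Fisher calibration checks.
wf_source <- function(L = 20, K = 10) {
  af <- lapply(seq_len(L), function(l) {
    p <- rep(1 / K, K)
    names(p) <- as.character(100 + 2 * (0:(K - 1)))
    p
  })
  names(af) <- sprintf("L%02d", seq_len(L))
  source_population_model(c(Hap01 = 1), af)
}

# Progeny sample of S diploids whose parents are drawn from a genotype
# table: the standard sampling design for evaluating the LD-Ne estimator
# (drift signal from the N parents, sampling noise from S offspring).
progeny_sample <- function(gt, S, population = "SIM") {
  n <- nrow(gt)
  L <- loci(gt)
  am <- as.matrix(gt[, -(1:2)])
  mo <- sample.int(n, S, replace = TRUE)
  fa <- sample.int(n, S, replace = TRUE)
  out <- matrix(0L, S, ncol(am))
  for (l in seq_along(L)) {
    c1 <- 2L * l - 1L
    out[, c1] <- am[cbind(mo, c1 + (runif(S) < 0.5))]
    out[, c1 + 1L] <- am[cbind(fa, c1 + (runif(S) < 0.5))]
  }
  genotype_table(sprintf("off%04d", seq_len(S)), rep(population, S), out, L)
}

# One terminal genotype table from a constant-size Wright-Fisher run.
wf_population <- function(src, N, generations = 30) {
  cfg <- demographic_config(
    founder_size = N, sex_ratio = c(1, 1), lambda = 1.01,
    capacity = N + 1000, years = generations, iterations = 1,
    pre_bottleneck_size = N, generations = "discrete", fecundity = 0)
  r <- run_scenario(src, cfg, return_genotypes = TRUE)
  terminal_genotype_table(r, 1)
}

# Small two-population genotype table built from explicit allele rows.
toy_genotypes <- function(allele_rows, pops, loci_names) {
  genotype_table(sprintf("i%03d", seq_len(nrow(allele_rows))), pops,
                 allele_rows, loci_names)
}
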