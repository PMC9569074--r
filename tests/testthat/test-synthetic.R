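test_that("haplotype spectra hit their diversity targets", {
  expect_equal(make_haplotype_spectrum(1, 0), 1)
  expect_error(make_haplotype_spectrum(1, 0.3), "zero")
  expect_error(make_haplotype_spectrum(4, 0.9), "unachievable")
  set.seed(701)
  # two haplotypes near the maximal diversity 0.5 -> close to (0.5, 0.5)
  p2 <- make_haplotype_spectrum(2, 0.4999)
  expect_equal(p2, c(0.5, 0.5), tolerance = 0.02)
  p38 <- make_haplotype_spectrum(38, 0.956)
  expect_equal(sum(p38), 1)
  expect_equal(1 - sum(p38^2), 0.956, tolerance = 1e-3)
  # expected sample haplotype diversity at n = 89
  expect_equal(89 / 88 * (1 - sum(p38^2)), 0.967, tolerance = 0.012)
})

test_that("source models recover allele-count and heterozygosity targets", {
  set.seed(702)
  m <- make_source_model(synthetic_preset("yantai-like"))
  expect_length(m$allele_freqs, 11L)
  draws <- replicate(50, {
    d <- sample_dataset(m, 89, sequences = FALSE)$genotypes
    s <- allele_summary(d, "P1", others = character(0))
    c(s$N_a, heterozygosities(d, "P1")$H_E)
  })
  expect_equal(mean(draws[1, ]), 17.3, tolerance = 0.1)   # within 10%
  expect_equal(mean(draws[2, ]), 0.795, tolerance = 0.05)

  # a single locus with two equifrequent alleles has H_E -> 0.5 at large n
  m2 <- source_population_model(c(H1 = 1),
                                list(L1 = c(`100` = 0.5, `102` = 0.5)))
  d2 <- sample_dataset(m2, 2000, sequences = FALSE)$genotypes
  expect_equal(heterozygosities(d2, "P1")$H_E, 0.5, tolerance = 0.05)

  expect_error(synthetic_spec(10, 0.9, 50, 5, 2, 0.9), "incompatible")
})

test_that("the bottlenecked preset matches the descendant's summaries", {
  set.seed(703)
  m <- make_source_model(synthetic_preset("beijing-like"))
  d <- sample_dataset(m, 150)
  cnt <- as.numeric(table(d$haplotypes$haplotype))
  expect_equal(length(cnt), 2L)
  expect_equal(haplotype_diversity(cnt)$h, 0.433, tolerance = 0.15)
})

test_that("sampled datasets satisfy the container invariants", {
  set.seed(704)
  m <- make_source_model(synthetic_spec(6, 0.7, 30, 4, 6, 0.65))
  expect_error(sample_dataset(m, 0), "at least 1")
  d <- sample_dataset(m, 25, missingness = 0)
  expect_false(anyNA(as.matrix(d$genotypes[, -(1:2)])))
  expect_equal(nrow(d$haplotypes), 25L)
  expect_equal(length(unique(nchar(d$haplotypes$sequence))), 1L)
  # distinct haplotypes have distinct sequences
  agg <- unique(d$haplotypes[, c("haplotype", "sequence")])
  expect_equal(anyDuplicated(agg$sequence), 0L)
  dm <- sample_dataset(m, 200, missingness = 0.2, sequences = FALSE)
  miss <- mean(is.na(as.matrix(dm$genotypes[, -(1:2)])))
  expect_gt(miss, 0.1)
  expect_lt(miss, 0.3)
})

test_that("generation is reproducible under a fixed seed", {
  spec <- synthetic_spec(6, 0.7, 30, 4, 6, 0.65)
  set.seed(705)
  m1 <- make_source_model(spec)
  set.seed(705)
  m2 <- make_source_model(spec)
  expect_identical(m1$allele_freqs, m2$allele_freqs)
  expect_identical(m1$haplotype_freqs, m2$haplotype_freqs)
})

test_that("radial layouts place sites at the requested distances", {
  set.seed(706)
  m <- make_source_model(synthetic_spec(6, 0.7, 30, 4, 6, 0.65))
  lay <- make_radial_layout(m, n_sites = 2, max_km = 10, n_per_site = 5)
  d <- vincenty_km(lay$sites$lat[1], lay$sites$lon[1],
                   lay$sites$lat[2], lay$sites$lon[2])
  expect_equal(d, 10, tolerance = 0.01)
})

test_that("stronger bottlenecks create stronger differentiation", {
  set.seed(707)
  src <- make_source_model(synthetic_spec(4, 0.6, 40, 6, 8, 0.72))
  rst_after <- function(B) {
    cfg <- demographic_config(founder_size = B, sex_ratio = c(1, 1),
                              lambda = 1.2, capacity = 400, years = 10,
                              iterations = 1, fecundity = 0)
    r <- run_scenario(src, cfg, return_genotypes = TRUE)
    gt <- terminal_genotype_table(r, 1, population = "DESC")
    if (is.null(gt)) return(NA_real_)
    ref <- sample_dataset(src, 40, population = "SRC",
                          sequences = FALSE)$genotypes
    both <- genotype_table(c(ref$individual, gt$individual),
                           c(ref$population, gt$population),
                           rbind(as.matrix(ref[, -(1:2)]),
                                 as.matrix(gt[, -(1:2)])),
                           loci(ref))
    pairwise_rst(both, "SRC", "DESC", permutations = 0)$value
  }
  res <- replicate(30, c(rst_after(6), rst_after(50)))
  expect_gt(mean(res[1, ], na.rm = TRUE), mean(res[2, ], na.rm = TRUE))
  expect_gt(mean(res[1, ], na.rm = TRUE), 0)
})
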