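test_that("haplotype diversity matches its closed form and edge cases", {
  expect_equal(haplotype_diversity(c(15))$h, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  # brute-force search: among two-haplotype splits of 150 samples, (103, 47)
  # is the unique composition whose diversity rounds to 0.433
  hs <- vapply(1:75, function(c1)
    haplotype_diversity(c(c1, 150 - c1))$h, numeric(1))
  expect_equal(which(abs(hs - 0.433) < 0.0005), 47L)
  hd <- haplotype_diversity(c(103, 47))
  expect_equal(hd$h, 0.433, tolerance = 0.0015)
  expect_equal(hd$sd, 0.029, tolerance = 0.05)
  expect_error(haplotype_diversity(c(1)), "two")
  expect_error(haplotype_diversity(c(2.5, 1)), "integer")
})

test_that("nucleotide diversity equals the exhaustive all-pairs average", {
  ids <- letters[1:4]
  seqs <- c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAC", "TCGTACGTAC")
  hd <- haplotype_dataset(ids, rep("P", 4), sequence = seqs)
  pairs <- combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(p) {
    a <- strsplit(seqs[p[1]], "")[[1]]
    b <- strsplit(seqs[p[2]], "")[[1]]
    mean(a != b)
  }))
  expect_equal(nucleotide_diversity(hd)$pi, oracle)

  same <- haplotype_dataset(ids, rep("P", 4), sequence = rep(seqs[1], 4))
  expect_equal(nucleotide_diversity(same)$pi, 0)

  two <- haplotype_dataset(c("a", "b"), c("P", "P"),
                           sequence = c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(two)$pi, 0.1)
})

test_that("sites with N or gaps are excluded pairwise from differences", {
  hd <- haplotype_dataset(c("a", "b"), c("P", "P"),
                          sequence = c("ACGTNNACGT", "ACCT--ACGA"))
  # valid sites: positions 1-4 and 7-10; differences at positions 3 and 10
  expect_equal(nucleotide_diversity(hd)$pi, 2 / 8)
})

test_that("allele summaries count totals, private alleles and means", {
  gt <- toy_genotypes(rbind(c(100L, 102L), c(104L, 104L)),
                      c("A", "B"), "L1")
  s <- allele_summary(gt, "A")
  expect_equal(s$N_A, 2L)
  expect_equal(s$N_PA, 2L)
  expect_equal(s$N_a, 2)
  # focal contained in the union of others -> no private alleles
  gt2 <- toy_genotypes(rbind(c(100L, 102L), c(100L, 102L), c(104L, 104L)),
                       c("A", "B", "B"), "L1")
  expect_equal(allele_summary(gt2, "A")$N_PA, 0L)
  expect_error(allele_summary(gt, "missing-pop"), "no individuals")
})

test_that("heterozygosities follow the unbiased formulas", {
  gt <- toy_genotypes(matrix(100L, 4, 2), rep("P", 4), "L1")
  h <- heterozygosities(gt, "P")
  expect_equal(h$H_O, 0)
  expect_equal(h$H_E, 0)
  # a single typed heterozygote: H_O = 1 and unbiased H_E = (2/1)(1 - 0.5)
  gt1 <- toy_genotypes(rbind(c(100L, 102L), c(NA_integer_, NA_integer_)),
                       rep("P", 2), "L1")
  h1 <- heterozygosities(gt1, "P")
  expect_equal(h1$H_O, 1)
  expect_equal(h1$H_E, 1)
})

test_that("Weir-Cockerham f matches direct variance-component arithmetic", {
  # 6 AA, 2 AB, 2 BB: p = 0.7, h_obs = 0.2, n = 10; per allele
  # b = n/(n-1) (p(1-p) - (2n-1)/(4n) h), c = h/2, f = 1 - Sc/S(b+c)
  rows <- rbind(matrix(100L, 6, 2),
                matrix(c(100L, 102L), 2, 2, byrow = TRUE),
                matrix(102L, 2, 2))
  gt <- toy_genotypes(rows, rep("P", 10), "L1")
  b <- 10 / 9 * (0.7 * 0.3 - 19 / 40 * 0.2)
  f_hand <- 1 - (0.1 + 0.1) / (2 * b + 0.2)
  expect_equal(fis(gt, "P")$fis, f_hand)

  # complete heterozygote excess at two alleles -> f = -1
  het <- toy_genotypes(matrix(c(100L, 102L), 40, 2, byrow = TRUE),
                       rep("P", 40), "L1")
  expect_equal(fis(het, "P")$fis, -1)

  # near-exact HWE proportions at large n -> f ~ 0
  hwe <- toy_genotypes(rbind(matrix(100L, 25, 2),
                             matrix(c(100L, 102L), 50, 2, byrow = TRUE),
                             matrix(102L, 25, 2)),
                       rep("P", 100), "L1")
  expect_lt(abs(fis(hwe, "P")$fis), 0.01)

  mono <- toy_genotypes(matrix(100L, 5, 2), rep("P", 5), "L1")
  expect_warning(fis(mono, "P"), "undefined")
})

test_that("rarefied richness equals exhaustive subset enumeration", {
  # one locus, 6 gene copies with allele counts {3, 2, 1}, rarefied to g = 4
  gt <- toy_genotypes(rbind(c(100L, 100L), c(100L, 102L), c(102L, 104L)),
                      rep("P", 3), "L1")
  copies <- c(100, 100, 100, 102, 102, 104)
  subs <- combn(6, 4)
  oracle <- mean(apply(subs, 2, function(s) length(unique(copies[s]))))
  expect_equal(rarefied_richness(gt, g = 4)$A_R, oracle)
  # g equal to the full gene-copy count recovers the observed allele count
  expect_equal(rarefied_richness(gt, g = 6)$A_R, 3)
  # monomorphic locus -> A_R = 1 at any g
  mono <- toy_genotypes(matrix(100L, 4, 2), rep("P", 4), "L1")
  expect_equal(rarefied_richness(mono, g = 4)$A_R, 1)
  expect_error(rarefied_richness(gt, g = 1), "at least 2")
  expect_error(rarefied_richness(gt, g = 8), "exceeds")
})

test_that("private allelic richness matches two-population enumeration", {
  gt <- toy_genotypes(rbind(c(100L, 100L), c(100L, 102L), c(102L, 104L),
                            c(100L, 100L), c(100L, 106L), c(106L, 106L)),
                      rep(c("A", "B"), each = 3), "L1")
  g <- 4
  copies_a <- c(100, 100, 100, 102, 102, 104)
  copies_b <- c(100, 100, 100, 106, 106, 106)
  subs <- combn(6, g)
  # P(allele in focal rarefied draw) x P(absent from the other's draw)
  oracle_ap <- function(focal, other) {
    alleles <- unique(focal)
    sum(vapply(alleles, function(al) {
      p_in <- mean(apply(subs, 2, function(s) al %in% focal[s]))
      p_out <- mean(apply(subs, 2, function(s) !al %in% other[s]))
      p_in * p_out
    }, numeric(1)))
  }
  rr <- rarefied_richness(gt, g = g)
  expect_equal(rr$A_P[rr$population == "A"], oracle_ap(copies_a, copies_b))
  expect_equal(rr$A_P[rr$population == "B"], oracle_ap(copies_b, copies_a))
})

test_that("rarefied richness is non-decreasing in g", {
  set.seed(71)
  d <- sample_dataset(make_source_model(synthetic_spec(
    5, 0.6, 30, 4, 6, 0.7)), 30, sequences = FALSE)
  ar <- vapply(2:20, function(g)
    rarefied_richness(d$genotypes, g = g)$A_R, numeric(1))
  expect_true(all(diff(ar) >= -1e-9))
})

test_that("h and pi are invariant under relabeling and reordering", {
  set.seed(72)
  d <- sample_dataset(make_source_model(synthetic_spec(
    8, 0.8, 40, 3, 5, 0.6)), 40)
  hd <- d$haplotypes
  perm <- sample(nrow(hd))
  hd2 <- hd[perm, , drop = FALSE]
  class(hd2) <- class(hd)
  cnt <- function(x) as.numeric(table(x$haplotype))
  expect_equal(haplotype_diversity(sort(cnt(hd2)))$h,
               haplotype_diversity(sort(cnt(hd)))$h)
  expect_equal(nucleotide_diversity(hd2)$pi, nucleotide_diversity(hd)$pi)
})

test_that("diversity_summary assembles one row per population", {
  set.seed(73)
  m <- make_source_model(synthetic_spec(6, 0.7, 30, 4, 6, 0.65))
  d1 <- sample_dataset(m, 25, population = "A")
  d2 <- sample_dataset(m, 20, population = "B", sequences = FALSE)
  hap <- d1$haplotypes
  gt <- genotype_table(c(d1$genotypes$individual, d2$genotypes$individual),
                       c(d1$genotypes$population, d2$genotypes$population),
                       rbind(as.matrix(d1$genotypes[, -(1:2)]),
                             as.matrix(d2$genotypes[, -(1:2)])),
                       loci(d1$genotypes))
  s <- diversity_summary(hap, gt, populations = c("A", "B"))
  expect_equal(nrow(s), 2L)
  expect_true(all(c("h", "N_a", "A_R", "H_O", "H_E", "F_IS") %in% names(s)))
  expect_true(all(s$A_R <= s$N_a + 1e-9, na.rm = TRUE))
  expect_true(all(s$H_E >= 0 & s$H_E <= 1, na.rm = TRUE))
})
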