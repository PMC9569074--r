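test_that("Burrows delta equals a direct covariance computation", {
  set.seed(401)
  g <- cbind(sample(c(100L, 102L), 10, TRUE), sample(c(100L, 102L), 10, TRUE),
             sample(c(200L, 202L), 10, TRUE), sample(c(200L, 202L), 10, TRUE))
  gt <- toy_genotypes(g, rep("P", 10), c("A", "B"))
  br <- burrows_r2(gt, "A", "B", maf_cutoff = 0)
  X <- rowSums(g[, 1:2] == 100)
  Y <- rowSums(g[, 3:4] == 200)
  d_direct <- stats::cov(X, Y) / 2       # cov() is the n-1 estimator
  pA <- mean(X) / 2
  pB <- mean(Y) / 2
  r2_direct <- d_direct^2 / (pA * (1 - pA) * pB * (1 - pB))
  row <- br[br$alleleA == 100 & br$alleleB == 200, ]
  expect_equal(row$delta, d_direct)
  expect_equal(row$r2, r2_direct)
  expect_equal(row$S, 10)
})

test_that("perfect coupling at Hardy-Weinberg proportions gives r2 ~ 1", {
  n <- 200
  gc <- rbind(matrix(100L, n / 4, 2),
              matrix(c(100L, 102L), n / 2, 2, byrow = TRUE),
              matrix(102L, n / 4, 2))
  gt <- toy_genotypes(cbind(gc, gc + 100L), rep("P", n), c("A", "B"))
  r2 <- burrows_r2(gt, "A", "B", maf_cutoff = 0)$r2
  expect_equal(mean(r2), 1, tolerance = 0.02)
})

test_that("independent loci in large samples give r2 near zero", {
  set.seed(402)
  m <- wf_source(L = 2, K = 4)
  d <- sample_dataset(m, 2000, sequences = FALSE)$genotypes
  r2 <- burrows_r2(d, "L01", "L02", maf_cutoff = 0)$r2
  expect_lt(mean(r2), 0.005)
})

test_that("the Ne transform matches its closed form and monotonicity", {
  # r2' = 0.01 at S >= 30: Ne = (1/3 + sqrt(1/9 - 0.0276)) / 0.02
  expect_equal(foundertrace:::ne_from_r2prime(0.01, 100),
               (1 / 3 + sqrt(1 / 9 - 0.0276)) / 0.02)
  expect_identical(foundertrace:::ne_from_r2prime(0, 100), Inf)
  expect_identical(foundertrace:::ne_from_r2prime(-0.003, 100), Inf)
  r2p <- seq(0.001, 0.03, by = 0.001)
  ne <- vapply(r2p, foundertrace:::ne_from_r2prime, numeric(1), S = 100)
  expect_true(all(diff(ne[is.finite(ne)]) < 0))
  # small-sample branch
  expect_equal(foundertrace:::ne_from_r2prime(0.02, 20),
               (0.308 + sqrt(0.308^2 - 2.08 * 0.02)) / 0.04)
})

test_that("raising the MAF cutoff never increases the allele pairs used", {
  set.seed(403)
  m <- make_source_model(synthetic_spec(5, 0.7, 40, 5, 9, 0.75))
  d <- sample_dataset(m, 40, sequences = FALSE)$genotypes
  n_pairs <- vapply(c(0, 0.01, 0.02, 0.05, 0.1), function(maf)
    nrow(foundertrace:::ldne_pairs(d, "P1", maf)), numeric(1))
  expect_true(all(diff(n_pairs) <= 0))
})

test_that("identical r2 across locus pairs gives a zero-width jackknife CI", {
  # four copies of the same locus content: every pair has the same r2
  gc <- rbind(matrix(100L, 10, 2),
              matrix(c(100L, 102L), 20, 2, byrow = TRUE),
              matrix(102L, 10, 2))
  gt <- toy_genotypes(cbind(gc, gc + 50L, gc + 100L, gc + 150L),
                      rep("P", 40), sprintf("L%d", 1:4))
  est <- ldne_estimate(gt, "P", maf_cutoff = 0, ci = TRUE)
  expect_equal(est$ci_low, est$ci_high)
  expect_equal(est$ci_low, est$ne_hat)
  # same property with a drift-scale r2, checked on constructed pairs
  rows <- data.frame(alleleA = 100, alleleB = 100, delta = 0,
                     r2 = 0.03, S = 60, pair = rep(1:5, each = 1))
  jk <- foundertrace:::jackknife_rows(rows)
  full <- foundertrace:::ldne_from_rows(rows)
  expect_equal(unname(jk[1L]), unname(jk[2L]))
  expect_equal(unname(jk[1L]), full$ne_hat)
  expect_true(is.finite(full$ne_hat))
})

test_that("no drift signal yields an infinite estimate and open CI", {
  set.seed(404)
  m <- wf_source(L = 8, K = 6)
  d <- sample_dataset(m, 3000, sequences = FALSE)$genotypes
  est <- ldne_estimate(d, "P1", maf_cutoff = 0.02)
  # drift-free data: the point estimate is unbounded up to sampling noise
  # and the jackknife upper bound is open
  expect_true(!is.finite(est$ne_hat) || est$ne_hat > 300)
  expect_identical(est$ci_high, Inf)
})

test_that("jackknife CIs cover a known Ne at close to nominal rate", {
  set.seed(405)
  src <- wf_source(L = 20, K = 10)
  covered <- replicate(60, {
    gt <- wf_population(src, N = 50, generations = 25)
    if (is.null(gt)) return(NA)
    s <- progeny_sample(gt, 100)
    est <- ldne_estimate(s, "SIM", maf_cutoff = 0.02)
    est$ci_low <= 50 && 50 <= est$ci_high
  })
  expect_gte(mean(covered, na.rm = TRUE), 0.85)
})
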