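test_that("founder sex counts honour the configured ratio exactly", {
  expect_equal(demographic_config(founder_size = 40,
                                  sex_ratio = c(1, 3))[c("n_females",
                                                         "n_males")],
               list(n_females = 10, n_males = 30))
  expect_equal(demographic_config(founder_size = 20,
                                  sex_ratio = c(1, 1))[c("n_females",
                                                         "n_males")],
               list(n_females = 10, n_males = 10))
  expect_error(demographic_config(founder_size = 10, sex_ratio = c(1, 99)),
               "configuration error")
  expect_error(demographic_config(founder_size = 40, lambda = 1),
               "lambda")
  expect_error(demographic_config(founder_size = 200,
                                  pre_bottleneck_size = 100))
})

test_that("founders carry source-frequency genotypes and valid ages", {
  set.seed(601)
  src <- wf_source(L = 1, K = 4)
  cfg <- demographic_config(founder_size = 20, sex_ratio = c(1, 1))
  st <- init_founders(src, cfg)
  expect_equal(length(st$age), 20L)
  expect_true(all(st$age %in% 1:3))
  expect_equal(sum(st$sex == "F"), 10L)
  # founder allele-frequency expectation equals the source vector
  pool <- unlist(replicate(400, init_founders(src, cfg)$geno,
                           simplify = FALSE))
  freq <- tabulate(pool, nbins = 4) / length(pool)
  se <- sqrt(0.25 * 0.75 / length(pool))
  expect_true(all(abs(freq - 0.25) < 4 * se))
})

test_that("one year of growth follows the logistic schedule arithmetic", {
  expect_equal(logistic_schedule(40, 1.06, 5000, 1)[2], 42)
  expect_gte(min(logistic_schedule(20, 1.02, 5000, 100)), 20)
  set.seed(602)
  src <- wf_source(L = 2, K = 4)
  cfg <- demographic_config(founder_size = 40, sex_ratio = c(1, 1),
                            lambda = 1.06, fecundity = 0)
  st <- init_founders(src, cfg)
  st$age <- rep(2L, 40)              # all mature, none at the lifespan edge
  st2 <- step_year(st, cfg)
  expect_equal(length(st2$age), 42L)
  expect_equal(sum(st2$age == 0L), 2L)
})

test_that("a single-sex population fails at the first required breeding", {
  set.seed(603)
  src <- wf_source(L = 1, K = 2)
  cfg <- demographic_config(founder_size = 10, sex_ratio = c(1, 1),
                            lambda = 1.10)
  st <- init_founders(src, cfg)
  st$sex <- rep("M", 10)
  st$age <- rep(2L, 10)
  st2 <- step_year(st, cfg)
  expect_equal(length(st2$age), 0L)
})

test_that("newborns inherit alleles from their parents' genotypes", {
  set.seed(604)
  src <- wf_source(L = 3, K = 8)
  cfg <- demographic_config(founder_size = 10, sex_ratio = c(1, 1),
                            lambda = 1.10, fecundity = 0)
  st <- init_founders(src, cfg)
  st$age <- rep(2L, 10)
  for (y in 1:6) {
    st2 <- step_year(st, cfg, target = length(st$age) + 5L)
    for (l in 1:3) {
      cols <- c(2 * l - 1, 2 * l)
      expect_true(all(st2$geno[, cols] %in% st$geno[, cols]))
    }
    st <- st2
  }
})

test_that("compiled and reference engines agree on summaries", {
  src <- wf_source(L = 3, K = 5)
  cfg <- demographic_config(founder_size = 16, sex_ratio = c(1, 1),
                            lambda = 1.08, capacity = 400, years = 12,
                            iterations = 150)
  set.seed(605)
  a <- run_scenario(src, cfg, engine = "cpp")
  set.seed(606)
  b <- run_scenario(src, cfg, engine = "r")
  ya <- a$summary[nrow(a$summary), ]
  yb <- b$summary[nrow(b$summary), ]
  expect_equal(ya$mean_na, yb$mean_na, tolerance = 0.1)
  expect_equal(ya$mean_census, yb$mean_census, tolerance = 0.15)
  expect_lt(abs(a$extinct_frac - b$extinct_frac), 0.12)
})

test_that("census never exceeds capacity and N_a never increases", {
  set.seed(607)
  src <- wf_source(L = 4, K = 6)
  cfg <- demographic_config(founder_size = 30, sex_ratio = c(1, 1),
                            lambda = 1.10, capacity = 150, years = 60,
                            iterations = 40)
  r <- run_scenario(src, cfg)
  expect_true(all(r$census <= cfg$capacity))
  diffs <- apply(r$na, 2, diff)
  expect_true(all(diffs[!is.na(diffs)] <= 1e-9))
})

test_that("allele frequencies are martingales under balanced drift", {
  set.seed(608)
  src <- wf_source(L = 1, K = 2)
  cfg <- demographic_config(founder_size = 40, sex_ratio = c(1, 1),
                            lambda = 1.01, capacity = 1040, years = 5,
                            iterations = 400, pre_bottleneck_size = 40,
                            generations = "discrete", fecundity = 0)
  r <- run_scenario(src, cfg, return_genotypes = TRUE)
  freqs <- vapply(seq_len(cfg$iterations), function(i) {
    gm <- r$terminal[[i]]
    if (is.null(gm) || nrow(gm) == 0) return(NA_real_)
    mean(gm == 1L)
  }, numeric(1))
  se <- stats::sd(freqs, na.rm = TRUE) / sqrt(sum(!is.na(freqs)))
  expect_lt(abs(mean(freqs, na.rm = TRUE) - 0.5), 3 * se)
})

test_that("a zero-year scenario reports the founder sample's diversity", {
  set.seed(609)
  src <- wf_source(L = 2, K = 6)
  cfg <- demographic_config(founder_size = 12, sex_ratio = c(1, 1),
                            lambda = 1.05, years = 0, iterations = 30)
  r <- run_scenario(src, cfg, engine = "r")
  expect_equal(nrow(r$summary), 1L)
  expect_true(all(r$census[1, ] == 12))
  expect_true(all(r$na[1, ] >= 1 & r$na[1, ] <= 6))
})

test_that("fixed seeds reproduce trajectories exactly", {
  src <- wf_source(L = 2, K = 4)
  cfg <- demographic_config(founder_size = 20, sex_ratio = c(1, 3),
                            lambda = 1.06, years = 30, iterations = 20)
  set.seed(610)
  a <- run_scenario(src, cfg)
  set.seed(610)
  b <- run_scenario(src, cfg)
  expect_identical(a$census, b$census)
  expect_identical(a$na, b$na)
})
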