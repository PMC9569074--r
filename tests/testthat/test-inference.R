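test_that("the deterministic schedule saturates at high growth", {
  # lambda = 1.10 from B = 40 reaches 90% of capacity well before year 90
  s <- logistic_schedule(40, 1.10, 5000, 90)
  expect_gte(s[91], 0.9 * 5000)
  # and lambda = 1.02 from B = 80 stays far below the observed window
  expect_lt(logistic_schedule(80, 1.02, 5000, 90)[91], 1500)
})

test_that("lambda matching accepts censuses inside the observed window", {
  set.seed(801)
  src <- wf_source(L = 4, K = 6)
  cfg <- demographic_config(founder_size = 10, sex_ratio = c(1, 1),
                            capacity = 2000, years = 40, iterations = 30)
  grid <- run_grid(src, founder_sizes = c(10, 30),
                   lambdas = c(1.05, 1.15), config = cfg)
  # a window covering every outcome accepts the full grid
  all_nc <- range(vapply(grid$results, function(r)
    r$summary$mean_census[r$summary$year == 35], numeric(1)))
  acc <- match_lambda(grid, all_nc, eval_year = 35, tol = 0,
                      plateau_frac = 1.01)
  expect_equal(acc, c(1.05, 1.15))
  # an empty window accepts nothing
  expect_length(match_lambda(grid, c(1e6, 2e6), eval_year = 35), 0)
  expect_error(match_lambda(structure(list(cells = data.frame()),
                                      class = "founder_grid"), c(1, 2)),
               "empty")
})

test_that("widening the tolerance never removes an accepted lambda", {
  set.seed(802)
  src <- wf_source(L = 3, K = 5)
  cfg <- demographic_config(founder_size = 12, sex_ratio = c(1, 1),
                            capacity = 1500, years = 40, iterations = 25)
  grid <- run_grid(src, founder_sizes = c(12, 24),
                   lambdas = c(1.04, 1.08, 1.12), config = cfg)
  prev <- numeric(0)
  for (tol in c(0, 0.1, 0.25, 0.5)) {
    acc <- match_lambda(grid, c(200, 600), eval_year = 35, tol = tol,
                        plateau_frac = 1.01)
    expect_true(all(prev %in% acc))
    prev <- acc
  }
})

test_that("founder-size matching brackets the observed diversity", {
  set.seed(803)
  src <- make_source_model(synthetic_spec(4, 0.6, 40, 6, 10, 0.75))
  cfg <- demographic_config(sex_ratio = c(1, 1), capacity = 800,
                            years = 40, iterations = 60)
  grid <- run_grid(src, founder_sizes = c(12, 60),
                   lambdas = c(1.08), config = cfg)
  na_small <- grid$results[[1]]$summary$mean_na[41]
  na_large <- grid$results[[2]]$summary$mean_na[41]
  expect_lt(na_small, na_large)
  acc <- match_founder_size(grid, observed_na = na_large, eval_year = 40)
  expect_true(60 %in% acc)
  # an observation far above anything simulated accepts nothing
  expect_length(match_founder_size(grid, observed_na = 50,
                                   eval_year = 40), 0)
  # every candidate extinct -> warning and empty set
  expect_warning(
    none <- match_founder_size(grid, observed_na = 5, eval_year = 40,
                               extinct_threshold = 0),
    "extinct")
  expect_length(none, 0)
})

test_that("the fitted model object carries accepted sets and methods", {
  set.seed(804)
  src <- make_source_model(synthetic_spec(4, 0.6, 40, 5, 8, 0.7))
  cfg <- demographic_config(sex_ratio = c(1, 1), capacity = 500,
                            years = 30, iterations = 30)
  fit <- fit_founder_history(src, observed_na = 4, nc_range = c(100, 500),
                             founder_sizes = c(10, 40),
                             lambdas = c(1.05, 1.10), config = cfg,
                             eval_year = 30, ne_range = c(20, 57))
  expect_s3_class(fit, "founder_fit")
  expect_true(all(fit$accepted_B %in% c(10, 40)))
  expect_output(print(fit), "accepted lambda")
  s <- summary(fit)
  expect_equal(nrow(s), 4L)
  cf <- coef(fit)
  expect_named(cf, c("B_min", "B_max", "lambda_min", "lambda_max"))
  expect_equal(fit$ne_nc$label, "0.04-0.6")
})
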