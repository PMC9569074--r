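# Individual-based forward simulation of the founding bottleneck and
# subsequent drift: configuration, a reference R engine for single years,
# and scenario/grid runners backed by the compiled core.

#' Demographic configuration for the forward simulator
#'
#' Life-history and growth settings for the age-structured simulator:
#' overlapping generations with a fixed lifespan, age at sexual maturity,
#' dioecious random mating with female-limited annual recruitment, a 1:1
#' newborn sex ratio, and a deterministic logistic size schedule
#' ([logistic_schedule()]) the population is filled toward each year.
#'
#' @param founder_size Number of founders `B` (the bottleneck size).
#' @param sex_ratio Length-2 numeric `c(females, males)` ratio of the
#'   founder group, e.g. `c(1, 3)`; founder counts are rounded
#'   (`B = 40`, 1:3 gives 10 females, 30 males).
#' @param lambda Annual population growth rate (> 1).
#' @param capacity Logistic carrying capacity (> founder size).
#' @param years Number of simulated years.
#' @param iterations Number of independent iterations.
#' @param lifespan Maximum age in years; individuals die after exceeding it.
#' @param maturation_age Age (years) at sexual maturity.
#' @param pre_bottleneck_size Size of the pre-bottleneck pool founders are
#'   sampled from without replacement.
#' @param fecundity Maximum recruits per mature female per year (annual
#'   births are `min(N* - survivors, fecundity * mature females)`); `0`
#'   disables the cap.
#' @param generations `"overlapping"` (default) or `"discrete"` for the
#'   constant-size Wright-Fisher mode used in calibration checks (no ages,
#'   whole-population replacement each year, no recruitment cap).
#' @return A validated list of class `demographic_config`.
#' @export
demographic_config <- function(founder_size = 40, sex_ratio = c(1, 3),
                               lambda = 1.06, capacity = 5000, years = 100,
                               iterations = 1000, lifespan = 4,
                               maturation_age = 2, pre_bottleneck_size = 100,
                               fecundity = 1,
                               generations = c("overlapping", "discrete")) {
  generations <- match.arg(generations)
  stopifnot(founder_size >= 1, founder_size <= pre_bottleneck_size,
            maturation_age <= lifespan, lifespan >= 2,
            capacity > founder_size, years >= 0, iterations >= 1,
            fecundity >= 0)
  if (generations == "overlapping" && lambda <= 1)
    stop("lambda must exceed 1")
  if (length(sex_ratio) != 2L || any(sex_ratio < 0))
    stop("sex_ratio must be c(females, males)")
  n_f <- round(founder_size * sex_ratio[1L] / sum(sex_ratio))
  n_m <- founder_size - n_f
  if (founder_size >= 2L && (n_f == 0L || n_m == 0L))
    stop("configuration error: founder sex ratio leaves one sex empty")
  structure(list(founder_size = founder_size, sex_ratio = sex_ratio,
                 n_females = n_f, n_males = n_m, lambda = lambda,
                 capacity = capacity, years = years,
                 iterations = iterations, lifespan = lifespan,
                 maturation_age = maturation_age,
                 pre_bottleneck_size = pre_bottleneck_size,
                 fecundity = fecundity, generations = generations),
            class = "demographic_config")
}

# Cumulative-probability allele draw from a frequency vector (index).
draw_from <- function(freq, n) {
  sample.int(length(freq), n, replace = TRUE, prob = freq)
}

#' Deterministic logistic size schedule
#'
#' The discrete logistic recurrence
#' `N[y+1] = round(N[y] + (lambda - 1) N[y] (1 - N[y]/capacity))` anchored
#' at the founder size. This schedule is the yearly target the simulator
#' fills toward: shortfalls caused by female-limited recruitment are made
#' up in later years rather than resetting the trajectory.
#'
#' @param founder_size Starting size.
#' @param lambda Annual growth rate.
#' @param capacity Carrying capacity.
#' @param years Number of years.
#' @return Integer vector of length `years + 1` (year 0 first).
#' @export
logistic_schedule <- function(founder_size, lambda, capacity, years) {
  out <- integer(years + 1L)
  out[1L] <- founder_size
  for (y in seq_len(years)) {
    N <- out[y]
    out[y + 1L] <- round(N + (lambda - 1) * N * (1 - N / capacity))
  }
  out
}

#' Initialise a founder population
#'
#' Creates the pre-bottleneck pool (genotypes drawn allele-wise from the
#' source frequencies, i.e. at linkage equilibrium), samples the founders
#' without replacement, assigns sexes to honour the configured founder sex
#' ratio exactly, draws founder ages uniformly on `1..lifespan-1`, and
#' assigns each founder a maternal haplotype from the source spectrum.
#'
#' @param source A [source_population_model()].
#' @param config A [demographic_config()].
#' @return A population state: list with `age`, `sex` (`"F"`/`"M"`),
#'   `geno` (matrix `B x 2L` of allele indices), `hap` and `loci`.
#' @export
init_founders <- function(source, config) {
  stopifnot(inherits(source, "source_population_model"),
            inherits(config, "demographic_config"))
  L <- length(source$allele_freqs)
  P <- config$pre_bottleneck_size
  pool <- matrix(0L, P, 2L * L)
  for (l in seq_len(L)) {
    f <- source$allele_freqs[[l]]
    pool[, 2L * l - 1L] <- draw_from(f, P)
    pool[, 2L * l] <- draw_from(f, P)
  }
  pick <- sample.int(P, config$founder_size)
  B <- config$founder_size
  list(age = sample(seq_len(config$lifespan - 1L), B, replace = TRUE),
       sex = rep(c("F", "M"), c(config$n_females, config$n_males)),
       geno = pool[pick, , drop = FALSE],
       hap = draw_from(source$haplotype_freqs, B),
       loci = names(source$allele_freqs))
}

#' Advance a population state by one year (reference implementation)
#'
#' The yearly cycle of the overlapping-generation model: survivors age by
#' one and die past the lifespan; `births = max(0, target - survivors)`,
#' capped at `fecundity x mature females` (and zero when either mature sex
#' is absent); each newborn takes a uniformly chosen mature mother and
#' father, inherits one uniformly chosen allele per locus from each, takes
#' the mother's haplotype, and is female with probability 1/2. A year that
#' requires births while no mature female or no mature male exists is a
#' reproductive failure: the population is recorded as extinct.
#'
#' When `target` is `NULL` it is computed from the current census by one
#' step of the logistic recurrence; [run_scenario()] instead passes the
#' year's value of the precomputed [logistic_schedule()], so that
#' recruitment shortfalls are pulled back to the schedule.
#'
#' This R implementation is the documented reference for the compiled
#' engine used by [run_scenario()].
#'
#' @param state A population state as returned by [init_founders()].
#' @param config A [demographic_config()].
#' @param target Target census after this year; `NULL` recomputes it from
#'   the current census.
#' @return The updated state; a census of zero means extinction.
#' @export
step_year <- function(state, config, target = NULL) {
  N <- length(state$age)
  if (N == 0L) return(state)
  nstar <- if (is.null(target)) {
    round(N + (config$lambda - 1) * N * (1 - N / config$capacity))
  } else {
    target
  }
  age <- state$age + 1L
  keep <- age <= config$lifespan
  age <- age[keep]
  sex <- state$sex[keep]
  geno <- state$geno[keep, , drop = FALSE]
  hap <- state$hap[keep]
  births <- max(0L, nstar - sum(keep))
  if (births > 0L) {
    matF <- which(sex == "F" & age >= config$maturation_age)
    matM <- which(sex == "M" & age >= config$maturation_age)
    if (length(matF) == 0L || length(matM) == 0L) {
      # reproductive failure: births required with a mature sex missing
      return(list(age = integer(0), sex = character(0),
                  geno = state$geno[0, , drop = FALSE], hap = integer(0),
                  loci = state$loci))
    } else if (config$fecundity > 0) {
      births <- min(births, config$fecundity * length(matF))
    }
    if (births > 0L) {
      mo <- matF[sample.int(length(matF), births, replace = TRUE)]
      fa <- matM[sample.int(length(matM), births, replace = TRUE)]
      L <- ncol(geno) / 2L
      newg <- matrix(0L, births, 2L * L)
      for (l in seq_len(L)) {
        cm <- 2L * l - 1L + (runif(births) < 0.5)
        cf <- 2L * l - 1L + (runif(births) < 0.5)
        newg[, 2L * l - 1L] <- geno[cbind(mo, cm)]
        newg[, 2L * l] <- geno[cbind(fa, cf)]
      }
      newhap <- hap[mo]
      age <- c(age, rep(0L, births))
      sex <- c(sex, ifelse(runif(births) < 0.5, "F", "M"))
      geno <- rbind(geno, newg)
      hap <- c(hap, newhap)
    }
  }
  list(age = age, sex = sex, geno = geno, hap = hap, loci = state$loci)
}

state_na <- function(state) {
  if (length(state$age) == 0L) return(NA_real_)
  L <- ncol(state$geno) / 2L
  mean(vapply(seq_len(L), function(l)
    length(unique(as.vector(state$geno[, c(2L * l - 1L, 2L * l)]))),
    numeric(1)))
}

#' Run a bottleneck-and-drift scenario
#'
#' Simulates `iterations` independent replicates of the founding bottleneck
#' followed by `years` years of drift, recording the census size, the mean
#' number of distinct alleles per locus (`N_a`) and the mean expected
#' heterozygosity among living individuals after each year (year 0 is the
#' founder state). Extinction (census zero) is a recorded outcome.
#'
#' @param source A [source_population_model()].
#' @param config A [demographic_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; slow, intended for small checks).
#' @param return_genotypes Logical: also keep each iteration's terminal
#'   genotypes (1-based allele codes), retrievable with
#'   [terminal_genotype_table()]. Compiled engine only.
#' @return A list of class `trajectory_result` with matrices `census`,
#'   `na`, `het` (`years + 1` rows, one column per iteration; `NA` after
#'   extinction), `extinct_year`, `extinct_frac`, a per-year `summary` data
#'   frame (mean/sd of `N_a` and mean census among surviving iterations,
#'   mean census over all iterations, surviving fraction) and the `config`.
#'   Set the RNG seed with [set.seed()] for reproducibility.
#' @export
run_scenario <- function(source, config, engine = c("cpp", "r"),
                         return_genotypes = FALSE) {
  stopifnot(inherits(source, "source_population_model"),
            inherits(config, "demographic_config"))
  engine <- match.arg(engine)
  if (engine == "cpp") {
    res <- run_scenario_cpp(
      lapply(source$allele_freqs, as.numeric),
      config$founder_size, config$n_females, config$n_males,
      config$pre_bottleneck_size, config$lifespan, config$maturation_age,
      config$lambda, config$capacity, config$years, config$iterations,
      config$fecundity, config$generations == "discrete",
      return_genotypes)
  } else {
    ny <- config$years + 1L
    census <- matrix(0L, ny, config$iterations)
    na <- matrix(NA_real_, ny, config$iterations)
    het <- matrix(NA_real_, ny, config$iterations)
    extinct <- rep(NA_integer_, config$iterations)
    sched <- logistic_schedule(config$founder_size, config$lambda,
                               config$capacity, config$years)
    for (it in seq_len(config$iterations)) {
      st <- init_founders(source, config)
      for (y in 0:config$years) {
        if (y > 0L) st <- step_year(st, config, target = sched[y + 1L])
        n <- length(st$age)
        census[y + 1L, it] <- n
        if (n > 0L) {
          na[y + 1L, it] <- state_na(st)
          L <- ncol(st$geno) / 2L
          het[y + 1L, it] <- mean(vapply(seq_len(L), function(l) {
            p <- table(st$geno[, c(2L * l - 1L, 2L * l)]) / (2 * n)
            1 - sum(p^2)
          }, numeric(1)))
        } else if (is.na(extinct[it])) {
          extinct[it] <- y
        }
      }
    }
    res <- list(census = census, na = na, het = het, extinct_year = extinct)
  }
  alive <- res$census > 0L
  n_alive <- rowSums(alive)
  summary <- data.frame(
    year = 0:config$years,
    mean_na = rowMeans(res$na, na.rm = TRUE),
    sd_na = apply(res$na, 1L, sd, na.rm = TRUE),
    mean_census = ifelse(n_alive > 0,
                         rowSums(res$census * alive) / pmax(n_alive, 1),
                         NA_real_),
    mean_census_all = rowMeans(res$census),
    surviving = n_alive / config$iterations)
  structure(list(census = res$census, na = res$na, het = res$het,
                 extinct_year = res$extinct_year,
                 extinct_frac = mean(!is.na(res$extinct_year)),
                 summary = summary, config = config,
                 terminal = res$terminal,
                 allele_sizes = lapply(source$allele_freqs, function(f)
                   as.integer(names(f))),
                 loci = names(source$allele_freqs)),
            class = "trajectory_result")
}

#' Terminal genotypes of one simulated iteration as a genotype table
#'
#' Converts the terminal population of a [run_scenario()] call made with
#' `return_genotypes = TRUE` into a [genotype_table()], optionally
#' down-sampling to `sample_size` individuals.
#'
#' @param result A `trajectory_result` carrying terminal genotypes.
#' @param iteration Iteration index.
#' @param population Population label for the table.
#' @param sample_size Optional number of individuals to sample without
#'   replacement.
#' @return A [genotype_table()]; `NULL` when the iteration went extinct.
#' @export
terminal_genotype_table <- function(result, iteration = 1,
                                    population = "SIM",
                                    sample_size = NULL) {
  stopifnot(inherits(result, "trajectory_result"))
  if (length(result$terminal) == 0L)
    stop("scenario was run without return_genotypes = TRUE")
  gm <- result$terminal[[iteration]]
  if (is.null(gm) || nrow(gm) == 0L) return(NULL)
  if (!is.null(sample_size)) {
    if (sample_size > nrow(gm)) stop("sample_size exceeds the population")
    gm <- gm[sample.int(nrow(gm), sample_size), , drop = FALSE]
  }
  sizes <- matrix(0L, nrow(gm), ncol(gm))
  for (l in seq_along(result$loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    sizes[, cols] <- result$allele_sizes[[l]][gm[, cols]]
  }
  genotype_table(sprintf("sim%04d", seq_len(nrow(gm))),
                 rep(population, nrow(gm)), sizes, result$loci)
}

#' @export
print.trajectory_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Forward simulation: B = %d (%d F / %d M), lambda = %.2f, %d years, %d iterations\n",
    cfg$founder_size, cfg$n_females, cfg$n_males, cfg$lambda, cfg$years,
    cfg$iterations))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "  terminal N_a = %.2f (sd %.2f), census %.0f, extinction fraction %.3f\n",
    last$mean_na, last$sd_na, last$mean_census, x$extinct_frac))
  invisible(x)
}

#' @export
plot.trajectory_result <- function(x, what = c("na", "census"), ...) {
  what <- match.arg(what)
  s <- x$summary
  if (what == "na") {
    graphics::plot(s$year, s$mean_na, type = "l", xlab = "Year",
                   ylab = "Mean alleles per locus", ...)
    graphics::lines(s$year, s$mean_na + s$sd_na, lty = 3)
    graphics::lines(s$year, pmax(s$mean_na - s$sd_na, 0), lty = 3)
  } else {
    graphics::plot(s$year, s$mean_census, type = "l", xlab = "Year",
                   ylab = "Census size", ...)
  }
  invisible(x)
}

#' Run a founder-size by growth-rate scenario grid
#'
#' @param source A [source_population_model()].
#' @param founder_sizes Vector of founder sizes `B`.
#' @param lambdas Vector of annual growth rates.
#' @param config Template [demographic_config()]; its `founder_size` and
#'   `lambda` are overridden cell by cell.
#' @return A list of class `founder_grid`: data frame `cells` (B, lambda)
#'   and the list of [run_scenario()] results in the same order.
#' @export
run_grid <- function(source, founder_sizes = c(20, 40, 60, 80),
                     lambdas = c(1.02, 1.04, 1.06, 1.08, 1.10),
                     config = demographic_config()) {
  cells <- expand.grid(B = founder_sizes, lambda = lambdas,
                       KEEP.OUT.ATTRS = FALSE)
  results <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$founder_size <- cells$B[i]
    cfg$lambda <- cells$lambda[i]
    cfg$n_females <- round(cfg$founder_size * cfg$sex_ratio[1L] /
                             sum(cfg$sex_ratio))
    cfg$n_males <- cfg$founder_size - cfg$n_females
    run_scenario(source, cfg)
  })
  structure(list(cells = cells, results = results),
            class = "founder_grid")
}

#' Extinction and terminal diversity across founder sex ratios
#'
#' Runs [run_scenario()] for each founder female:male ratio and reports the
#' extinction fraction and terminal mean `N_a`.
#'
#' @param source A [source_population_model()].
#' @param config Template [demographic_config()].
#' @param ratios List of length-2 `c(females, males)` ratios.
#' @return Data frame with one row per ratio.
#' @export
sex_ratio_sweep <- function(source, config,
                            ratios = list(c(1, 1), c(1, 3), c(1, 6),
                                          c(1, 9))) {
  rows <- lapply(ratios, function(r) {
    cfg <- demographic_config(
      founder_size = config$founder_size, sex_ratio = r,
      lambda = config$lambda, capacity = config$capacity,
      years = config$years, iterations = config$iterations,
      lifespan = config$lifespan, maturation_age = config$maturation_age,
      pre_bottleneck_size = config$pre_bottleneck_size,
      fecundity = config$fecundity, generations = config$generations)
    res <- run_scenario(source, cfg)
    last <- res$summary[nrow(res$summary), ]
    data.frame(females = r[1L], males = r[2L],
               extinct_frac = res$extinct_frac,
               terminal_na = last$mean_na,
               terminal_census = last$mean_census)
  })
  do.call(rbind, rows)
}
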