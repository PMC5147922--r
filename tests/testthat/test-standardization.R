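test_that("direct standardization is the reference-weighted mean of rates", {
  cfg <- stratum_config(age_classes = c("young", "old"), sexes = "all")
  ref <- as_reference_population(
    data.frame(sex = "all", age_class = c("young", "old"),
               weight = c(0.25, 0.75)), cfg)
  rates <- data.frame(department_id = "X", sex = "all",
                      age_class = c("young", "old"),
                      rate = c(1e-3, 3e-3))
  out <- direct_standardized_prevalence(rates, ref)
  expect_equal(out$prevalence, 250)

  # uniform rate: any reference gives rate x 1e5
  runi <- transform(rates, rate = 2e-3)
  for (w in list(c(0.25, 0.75), c(0.5, 0.5), c(7, 3))) {
    refw <- as_reference_population(
      data.frame(sex = "all", age_class = c("young", "old"), weight = w),
      cfg)
    expect_equal(direct_standardized_prevalence(runi, refw)$prevalence, 200)
  }

  expect_error(direct_standardized_prevalence(rates[1, ], ref),
               "lack strata|lacks rates")
})

test_that("reference rescaling before normalization changes nothing", {
  cfg <- stratum_config()
  st <- strata_table(cfg)
  set.seed(10)
  w <- runif(nrow(st), 0.1, 2)
  r1 <- as_reference_population(data.frame(st, weight = w), cfg)
  r7 <- as_reference_population(data.frame(st, weight = 7 * w), cfg)
  rates <- data.frame(department_id = "X", st,
                      rate = runif(nrow(st), 1e-5, 3e-3))
  expect_equal(direct_standardized_prevalence(rates, r1)$prevalence,
               direct_standardized_prevalence(rates, r7)$prevalence,
               tolerance = 1e-12)
})

test_that("standardized prevalence obeys the convex-combination bound", {
  cfg <- stratum_config()
  st <- strata_table(cfg)
  set.seed(77)
  for (nm in c("french_2004", "european", "world")) {
    ref <- bundled_reference(nm, cfg)
    rates <- data.frame(department_id = "X", st,
                        rate = runif(nrow(st), 1e-5, 5e-3))
    p <- direct_standardized_prevalence(rates, ref)$prevalence
    expect_gte(p, 1e5 * min(rates$rate))
    expect_lte(p, 1e5 * max(rates$rate))
  }
})

test_that("crude prevalence equals the division oracle at both levels", {
  fx <- flat_fixture("X", cases = 150, pops = 1e5)
  cp <- crude_prevalence(fx$uc, fx$pop)
  expect_equal(cp$by_department$crude, 150)

  set.seed(55)
  cfg <- stratum_config(age_classes = c("0-39", "40+"))
  for (k in 1:20) {
    n_dep <- sample(2:6, 1)
    grid <- merge(data.frame(department_id = sprintf("d%d", 1:n_dep)),
                  strata_table(cfg))
    uc <- make_unique_cases(
      data.frame(grid, unique_cases_real = runif(nrow(grid), 0, 300),
                 unique_cases_int = 0L), cfg)
    pop <- as_population(data.frame(grid,
                                    population = sample(1e3:1e5, nrow(grid))),
                         cfg)
    cp <- crude_prevalence(uc, pop)
    for (d in cp$by_department$department_id) {
      o <- sum(uc$unique_cases_real[uc$department_id == d])
      p <- sum(pop$population[pop$department_id == d])
      expect_equal(cp$by_department$crude[cp$by_department$department_id == d],
                   1e5 * o / p, tolerance = 1e-12)
    }
    # overall crude is the population-weighted mean of department crudes
    wmean <- with(cp$by_department, sum(crude * population) / sum(population))
    expect_equal(cp$overall$crude, wmean, tolerance = 1e-9)
  }

  bad <- flat_fixture(c("X", "Y"), cases = c(1, 0), pops = c(100, 0))
  expect_error(crude_prevalence(bad$uc, bad$pop), "zero total population")
})

test_that("re-binning five-year tables to ten-year classes conserves weight", {
  for (f in c("ref_esp1976_5yr.csv", "ref_who2000_5yr.csv")) {
    src <- read.csv(system.file("extdata", f, package = "msprev"))
    out <- rebin_age_weights(src, default_age_classes())
    expect_equal(sum(out), sum(src$weight), tolerance = 1e-12)
    expect_length(out, 9)
  }
  # the 1976 European standard: known ten-year aggregation spot check
  esp <- read.csv(system.file("extdata", "ref_esp1976_5yr.csv",
                              package = "msprev"))
  out <- rebin_age_weights(esp, default_age_classes())
  expect_equal(unname(out["0-9"]), 15000)
  expect_equal(unname(out["80+"]), 2000)
})

test_that("standardizing to the study's own structure recovers the crude rate", {
  cfg <- stratum_config(age_classes = c("young", "old"), sexes = "all")
  pop <- as_population(data.frame(department_id = "X", sex = "all",
                                  age_class = c("young", "old"),
                                  population = c(3000, 1000)), cfg)
  ref <- as_reference_population(
    data.frame(sex = "all", age_class = c("young", "old"),
               weight = pop$population), cfg)
  rates <- data.frame(department_id = "X", sex = "all",
                      age_class = c("young", "old"), rate = c(2e-3, 6e-3))
  uc <- make_unique_cases(
    data.frame(department_id = "X", sex = "all",
               age_class = c("young", "old"),
               unique_cases_real = rates$rate * pop$population,
               unique_cases_int = 0L), cfg)
  std <- direct_standardized_prevalence(rates, ref)$prevalence
  crude <- crude_prevalence(uc, pop)$by_department$crude
  expect_equal(std, crude, tolerance = 1e-9)
})

test_that("proportional rate profiles rank identically under any reference", {
  cfg <- stratum_config()
  st <- strata_table(cfg)
  set.seed(3)
  base <- runif(nrow(st), 1e-5, 2e-3)
  mult <- c(A = 0.5, B = 1.1, C = 2.0, D = 0.8)
  rates <- do.call(rbind, lapply(names(mult), function(d)
    data.frame(department_id = d, st, rate = base * mult[[d]])))
  ranks <- lapply(c("french_2004", "european", "world"), function(nm) {
    p <- direct_standardized_prevalence(rates, bundled_reference(nm, cfg))
    rank(-p$prevalence)
  })
  expect_equal(ranks[[1]], ranks[[2]])
  expect_equal(ranks[[1]], ranks[[3]])
})
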