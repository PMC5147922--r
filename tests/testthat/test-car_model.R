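test_that("model builder validates structure, flags islands, counts degrees", {
  fx <- flat_fixture(c("A", "B", "C"), cases = c(5, 6, 7),
                     pops = c(1e4, 1e4, 1e4))
  g <- adjacency_graph(c("A", "B", "C"), rbind(c("A", "B")))
  expect_warning(spec <- build_model(fx$uc, fx$pop, g), "island")
  expect_equal(unname(spec$degrees), c(1, 1, 0))
  expect_equal(spec$car_rank, 1)

  plain <- build_model(fx$uc, fx$pop, g,
                       components = list(u = FALSE, v = FALSE))
  expect_false(plain$components$u)
  expect_false(plain$components$v)

  g2 <- adjacency_graph(c("A", "B"), rbind(c("A", "B")))
  expect_error(build_model(fx$uc, fx$pop, g2), "absent from the adjacency")

  # the shipped 21-department graph: known degree sequence spot checks
  cfg <- stratum_config()
  g21 <- bundled_adjacency()
  deg <- graph_degrees(g21)
  expect_equal(unname(deg[c("31", "57", "69", "15")]), c(5L, 1L, 0L, 4L))
})

test_that("mcmc settings enforce the sampling contract", {
  expect_error(mcmc_settings(n_chains = 1), "2 chains")
  expect_error(mcmc_settings(n_iter = 100, n_burn = 100), "exceed")
  expect_error(mcmc_settings(thin = 0), "thin")
})

test_that("sampler is bit-reproducible and pins island spatial effects", {
  fx <- flat_fixture(c("A", "B", "C", "D"), cases = c(40, 50, 60, 45),
                     pops = rep(5e4, 4))
  g <- adjacency_graph(c("A", "B", "C", "D"),
                       rbind(c("A", "B"), c("B", "C")))
  spec <- suppressWarnings(build_model(fx$uc, fx$pop, g))
  st <- mcmc_settings(n_chains = 2, n_iter = 300, n_burn = 100, thin = 1,
                      seed = 42)
  f1 <- run_mcmc(spec, st)
  f2 <- run_mcmc(spec, st)
  expect_identical(f1$chains, f2$chains)
  dr <- do.call(rbind, f1$chains)
  expect_true(all(dr[, "v:D"] == 0))
  # sum-to-zero of the CAR field in every retained draw
  vsum <- rowSums(dr[, c("v:A", "v:B", "v:C")])
  expect_true(all(abs(vsum + dr[, "v:D"]) < 1e-8))
})

test_that("exchangeable departments get exchangeable posterior rates", {
  n <- 6
  deps <- sprintf("s%d", 1:n)
  g <- adjacency_graph(deps, cbind(deps, deps[c(2:n, 1)]))
  fx <- flat_fixture(deps, cases = rep(50, n), pops = rep(1e5, n))
  spec <- build_model(fx$uc, fx$pop, g)
  fit <- run_mcmc(spec, mcmc_settings(2, 1200, 400, 2, seed = 17))
  th <- summarize_fit(fit, "theta")
  expect_lt(diff(range(th$mean)) / mean(th$mean), 0.06)
  rr <- relative_risks(fit)
  expect_true(all(abs(rr$mean - 1) < 0.05))
  expect_true(all(rr$ci_low <= 1 & rr$ci_high >= 1))
})

test_that("Poisson-limit posterior matches the conjugate gamma oracle", {
  fx <- flat_fixture("solo", cases = 150, pops = 1e5)
  g <- adjacency_graph("solo")
  spec <- build_model(fx$uc, fx$pop, g,
                      components = list(u = FALSE, v = FALSE),
                      priors = list(fix_r = 1e6, beta_sd = 1e3))
  fit <- run_mcmc(spec, mcmc_settings(2, 3000, 1000, 2, seed = 11))
  theta <- exp(do.call(rbind, fit$chains)[, "alpha"])
  # flat prior on log(theta) + Poisson(150) => Gamma(150, 1e5)
  oracle_mean <- 150 / 1e5
  oracle_sd <- sqrt(150) / 1e5
  ess <- sum(vapply(fit$chains, function(m) msprev:::ess_one(exp(m[, "alpha"])),
                    numeric(1)))
  mc_se <- oracle_sd / sqrt(ess)
  expect_lt(abs(mean(theta) - oracle_mean), 3 * mc_se + 1e-7)
  expect_lt(abs(sd(theta) - oracle_sd) / oracle_sd, 0.15)
})

test_that("split-Rhat and ESS behave on degenerate chains", {
  mk_fit <- function(chains) structure(list(chains = chains),
                                       class = "msprev_fit")
  const <- matrix(1.5, 200, 2, dimnames = list(NULL, c("alpha", "r")))
  d <- convergence_diagnostics(mk_fit(list(const, const)))
  expect_true(all(d$rhat == 1))

  c2 <- const; c2[] <- 9.5
  d2 <- convergence_diagnostics(mk_fit(list(const, c2)))
  expect_true(all(d2$rhat > 10))

  set.seed(3)
  m1 <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("alpha", "r")))
  d3 <- convergence_diagnostics(mk_fit(list(m1, m1)))
  expect_true(all(abs(d3$rhat - 1) < 0.1))

  expect_error(convergence_diagnostics(mk_fit(list(const))), "2 chains")
  expect_error(convergence_diagnostics(mk_fit(list(const[1:10, ],
                                                   const[1:10, ]))),
               "100 retained")
})

test_that("posterior summaries respect quantile order and a normal oracle", {
  set.seed(19)
  m <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "X"))
  s <- msprev:::summarize_draw_matrix(m)
  expect_lt(abs(s$ci_low - (-1.96)), 0.02)
  expect_lt(abs(s$ci_high - 1.96), 0.02)

  cm <- matrix(2.5, 50, 1, dimnames = list(NULL, "X"))
  sc <- msprev:::summarize_draw_matrix(cm)
  expect_equal(unlist(sc[c("mean", "median", "ci_low", "ci_high")]),
               c(mean = 2.5, median = 2.5, ci_low = 2.5, ci_high = 2.5))
})

test_that("relative risks recover known rate ratios and scale invariance", {
  deps <- c("lo", "hi")
  g <- adjacency_graph(deps, rbind(deps))
  rate <- c(1e-4, 1e-3)
  pops <- c(2e6, 2e6)
  set.seed(23)
  y <- rpois(2, rate * pops)
  fx <- flat_fixture(deps, cases = y, pops = pops)
  # two observations cannot identify the dispersion: use the Poisson limit
  spec <- build_model(fx$uc, fx$pop, g, components = list(u = TRUE, v = FALSE),
                      priors = list(fix_r = 1e6))
  fit <- run_mcmc(spec, mcmc_settings(2, 1500, 500, 2, seed = 29))
  rr <- relative_risks(fit)
  # true mean rate 5.5e-4: ratios 2/11 and 20/11
  expect_lt(abs(rr$mean[rr$department_id == "lo"] - 2 / 11), 0.03)
  expect_lt(abs(rr$mean[rr$department_id == "hi"] - 20 / 11), 0.12)

  fx10 <- flat_fixture(deps, cases = y * 10, pops = pops * 10)
  spec10 <- build_model(fx10$uc, fx10$pop, g,
                        components = list(u = TRUE, v = FALSE),
                        priors = list(fix_r = 1e6))
  fit10 <- run_mcmc(spec10, mcmc_settings(2, 1500, 500, 2, seed = 29))
  rr10 <- relative_risks(fit10)
  expect_lt(max(abs(rr10$mean - rr$mean)), 0.05)
})

test_that("posterior means are data-dominated under prior rescaling", {
  deps <- c("p", "q")
  g <- adjacency_graph(deps, rbind(deps))
  fx <- flat_fixture(deps, cases = c(4000, 5000), pops = c(2e6, 2e6))
  run <- function(priors) {
    spec <- build_model(fx$uc, fx$pop, g,
                        components = list(u = TRUE, v = FALSE),
                        priors = c(priors, list(fix_r = 1e6)))
    fit <- run_mcmc(spec, mcmc_settings(2, 1200, 400, 2, seed = 31))
    summarize_fit(fit, "theta")
  }
  t1 <- run(list())
  t2 <- run(list(beta_sd = 200, sigma_u_sd = 20))
  mc_se <- (t1$ci_high - t1$ci_low) / (2 * 1.96) / sqrt(100)
  expect_true(all(abs(t1$mean - t2$mean) < pmax(3 * mc_se,
                                                0.02 * t1$mean)))
})
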