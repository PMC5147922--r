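#' Build the spatial negative-binomial model specification
#'
#' The count likelihood for department d, stratum s is negative binomial
#' with mean `mu_{d,s} = pop_{d,s} exp(alpha + beta_sex + beta_age + u_d +
#' v_d)` and variance `mu + mu^2 / r` (dispersion r; the Poisson limit is
#' r -> infinity). The department effects follow the Besag-York-Mollie
#' convolution: `u_d` is unstructured Normal(0, sigma_u) heterogeneity and
#' `v` an intrinsic CAR field on the contiguity graph (each `v_d`
#' conditionally Normal around the mean of its neighbors with variance
#' `sigma_v^2 / degree_d`, constrained to sum to zero). Weakly informative
#' priors: Normal(0, 100) on alpha and the betas, half-Normal(10) on the
#' scales, Normal(0, 10) on log r. The first sex and first age class are the
#' reference categories.
#'
#' @param cases `msprev_unique_cases` (the rounded integer column is the
#'   response).
#' @param pop `msprev_population` paired with `cases`.
#' @param graph `msprev_graph` covering every department in `cases`.
#' @param components list of flags `u`, `v` switching the unstructured and
#'   CAR components.
#' @param priors list overriding `beta_sd`, `sigma_u_sd`, `sigma_v_sd`,
#'   `logr_sd`, and optionally `fix_r` (a numeric value freezes the
#'   dispersion, e.g. `1e6` for a practical Poisson limit).
#' @return list of class `msprev_model` (data vectors, index maps, degrees,
#'   priors).
#' @export
build_model <- function(cases, pop, graph,
                        components = list(u = TRUE, v = TRUE),
                        priors = list()) {
  stopifnot(inherits(cases, "msprev_unique_cases"),
            inherits(pop, "msprev_population"),
            inherits(graph, "msprev_graph"))
  pr <- utils::modifyList(list(beta_sd = 100, sigma_u_sd = 10,
                               sigma_v_sd = 10, logr_sd = 10,
                               fix_r = NULL), priors)
  key_c <- paste(cases$department_id, stratum_key(cases))
  key_p <- paste(pop$department_id, stratum_key(pop))
  idx <- match(key_c, key_p)
  if (anyNA(idx)) stop("case rows without matching population rows")
  df <- data.frame(department_id = cases$department_id, sex = cases$sex,
                   age_class = cases$age_class,
                   y = cases$unique_cases_int,
                   pop = pop$population[idx], stringsAsFactors = FALSE)
  drop <- df$pop == 0
  if (any(drop & df$y > 0))
    stop("cases recorded in a zero-population stratum")
  df <- df[!drop, , drop = FALSE]
  deps <- sort(unique(df$department_id))
  miss <- setdiff(deps, graph$nodes)
  if (length(miss))
    stop("department(s) absent from the adjacency graph: ",
         paste(miss, collapse = ", "))
  config <- attr(cases, "strata")
  if (is.null(config)) config <- stratum_config()
  sex_lv <- config$sexes[config$sexes %in% unique(df$sex)]
  age_lv <- config$age_classes[config$age_classes %in% unique(df$age_class)]
  coef_names <- as.character(
    c(if (length(sex_lv) > 1) paste0("beta_sex:", sex_lv[-1]),
      if (length(age_lv) > 1) paste0("beta_age:", age_lv[-1])))
  beta_rows <- lapply(coef_names, function(nm) {
    val <- sub("^beta_(sex|age):", "", nm)
    if (startsWith(nm, "beta_sex:")) which(df$sex == val)
    else which(df$age_class == val)
  })
  names(beta_rows) <- coef_names
  nb <- graph_neighbors(graph)[deps]
  nb <- lapply(nb, function(v) intersect(v, deps))
  deg <- lengths(nb)
  if (isTRUE(components$v) && any(deg == 0))
    warning("island department(s) with CAR enabled; their spatial effect ",
            "is pinned at zero: ",
            paste(deps[deg == 0], collapse = ", "))
  # rank of the intrinsic CAR precision among connected (non-island) nodes
  sub_nodes <- deps[deg > 0]
  car_rank <- 0L
  if (length(sub_nodes)) {
    keep <- graph$edges[, 1] %in% deps & graph$edges[, 2] %in% deps
    sub <- adjacency_graph(sub_nodes, graph$edges[keep, , drop = FALSE])
    car_rank <- length(sub_nodes) -
      length(unique(graph_components(sub)[sub_nodes]))
  }
  structure(list(
    data = df, deps = deps, dep_row = split(seq_len(nrow(df)),
                                            factor(df$department_id, deps)),
    coef_names = coef_names, beta_rows = beta_rows,
    neighbors = nb, degrees = deg, car_rank = car_rank,
    components = list(u = isTRUE(components$u), v = isTRUE(components$v)),
    priors = pr, strata = config,
    sex_levels = sex_lv, age_levels = age_lv), class = "msprev_model")
}

#' MCMC settings
#'
#' Defaults: 2 chains of 20,000 iterations, the first 10,000 discarded as
#' burn-in, thinning by 5, adaptive random-walk scaling targeting a 0.44
#' acceptance rate during burn-in.
#'
#' @param n_chains number of chains (>= 2).
#' @param n_iter iterations per chain.
#' @param n_burn burn-in iterations (< n_iter); also the adaptation window.
#' @param thin thinning interval (>= 1).
#' @param seed integer seed; per-chain streams derive from it.
#' @return list of class `msprev_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2, n_iter = 20000, n_burn = 10000,
                          thin = 5, seed = 1) {
  if (n_chains < 2) stop("at least 2 chains are required")
  if (n_iter <= n_burn) stop("n_iter must exceed n_burn")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "msprev_mcmc_settings")
}

nb_loglik <- function(y, mu, r) {
  sum(stats::dnbinom(y, size = r, mu = mu, log = TRUE))
}

# Univariate stepping-out slice sampler (Neal 2003), used for the log scale
# hyperparameters whose full conditionals are one-dimensional and cheap.
slice_sample <- function(x0, logf, w = 1, m = 20) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 - stats::rexp(1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  j <- floor(stats::runif(1) * m); k <- m - 1 - j
  while (j > 0 && logf(lo) > logy) { lo <- lo - w; j <- j - 1 }
  while (k > 0 && logf(hi) > logy) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

run_one_chain <- function(spec, settings, chain_seed, dispersal = 1) {
  set.seed(chain_seed)
  df <- spec$data
  y <- df$y; popn <- df$pop
  n <- nrow(df)
  deps <- spec$deps; n_dep <- length(deps)
  cn <- spec$coef_names; n_beta <- length(cn)
  use_u <- spec$components$u; use_v <- spec$components$v
  pr <- spec$priors
  fix_r <- !is.null(pr$fix_r)

  alpha <- log((sum(y) + 0.5) / sum(popn)) + stats::rnorm(1, 0, 0.3 * dispersal)
  beta <- stats::setNames(stats::rnorm(n_beta, 0, 0.2 * dispersal), cn)
  u <- stats::setNames(if (use_u) stats::rnorm(n_dep, 0, 0.05 * dispersal)
                       else numeric(n_dep), deps)
  v <- stats::setNames(numeric(n_dep), deps)
  log_r <- if (fix_r) log(pr$fix_r) else
    log(10) + stats::rnorm(1, 0, 0.3 * dispersal)
  sigma_u <- exp(stats::rnorm(1, log(0.2), 0.2 * dispersal))
  sigma_v <- exp(stats::rnorm(1, log(0.2), 0.2 * dispersal))

  dep_of_row <- match(df$department_id, deps)
  x_beta <- numeric(n)
  for (k in seq_len(n_beta)) x_beta[spec$beta_rows[[k]]] <-
      x_beta[spec$beta_rows[[k]]] + beta[k]
  eta <- alpha + x_beta + u[dep_of_row] + v[dep_of_row]
  r <- exp(log_r)

  # proposal sds, adapted toward 0.44 acceptance during burn-in
  s_alpha <- 0.1; s_beta <- rep(0.1, n_beta); s_u <- rep(0.1, n_dep)
  s_v <- rep(0.1, n_dep); s_logr <- 0.2
  s_shift_u <- 0.1
  shift_blocks <- list()
  if (any(startsWith(cn, "beta_sex:")))
    shift_blocks <- c(shift_blocks, list(list(
      id = "sex", coefs = cn[startsWith(cn, "beta_sex:")],
      ref_rows = which(df$sex == spec$sex_levels[1]))))
  if (any(startsWith(cn, "beta_age:")))
    shift_blocks <- c(shift_blocks, list(list(
      id = "age", coefs = cn[startsWith(cn, "beta_age:")],
      ref_rows = which(df$age_class == spec$age_levels[1]))))
  s_shift_b <- c(sex = 0.1, age = 0.1)

  n_keep <- floor((settings$n_iter - settings$n_burn) / settings$thin)
  par_names <- c("alpha", cn, paste0("u:", deps), paste0("v:", deps),
                 "r", "sigma_u", "sigma_v")
  out <- matrix(NA_real_, n_keep, length(par_names),
                dimnames = list(NULL, par_names))
  keep_i <- 0L

  mh_scalar <- function(rows, delta, log_prior_diff) {
    # generic delta-MH on a subset of rows of the linear predictor
    eta_new <- eta[rows] + delta
    ll_new <- nb_loglik(y[rows], popn[rows] * exp(eta_new), r)
    ll_old <- nb_loglik(y[rows], popn[rows] * exp(eta[rows]), r)
    lr <- ll_new - ll_old + log_prior_diff
    acc <- is.finite(lr) && log(stats::runif(1)) < lr
    list(acc = acc, lr = lr)
  }
  adapt <- function(s, lr, gamma) {
    p_acc <- min(1, exp(lr)); if (!is.finite(p_acc)) p_acc <- 0
    s * exp(gamma * (p_acc - 0.44))
  }

  for (it in seq_len(settings$n_iter)) {
    gamma <- if (it <= settings$n_burn) min(0.1, 1 / sqrt(it)) else 0

    # alpha
    d <- stats::rnorm(1, 0, s_alpha)
    lpd <- (stats::dnorm(alpha + d, 0, pr$beta_sd, log = TRUE) -
            stats::dnorm(alpha, 0, pr$beta_sd, log = TRUE))
    res <- mh_scalar(seq_len(n), d, lpd)
    if (res$acc) { alpha <- alpha + d; eta <- eta + d }
    if (gamma > 0) s_alpha <- adapt(s_alpha, res$lr, gamma)

    # betas
    for (k in seq_len(n_beta)) {
      rows <- spec$beta_rows[[k]]
      d <- stats::rnorm(1, 0, s_beta[k])
      lpd <- (stats::dnorm(beta[k] + d, 0, pr$beta_sd, log = TRUE) -
              stats::dnorm(beta[k], 0, pr$beta_sd, log = TRUE))
      res <- mh_scalar(rows, d, lpd)
      if (res$acc) { beta[k] <- beta[k] + d; eta[rows] <- eta[rows] + d }
      if (gamma > 0) s_beta[k] <- adapt(s_beta[k], res$lr, gamma)
    }

    # unstructured effects
    if (use_u) {
      for (j in seq_len(n_dep)) {
        rows <- spec$dep_row[[j]]
        d <- stats::rnorm(1, 0, s_u[j])
        lpd <- (stats::dnorm(u[j] + d, 0, sigma_u, log = TRUE) -
                stats::dnorm(u[j], 0, sigma_u, log = TRUE))
        res <- mh_scalar(rows, d, lpd)
        if (res$acc) { u[j] <- u[j] + d; eta[rows] <- eta[rows] + d }
        if (gamma > 0) s_u[j] <- adapt(s_u[j], res$lr, gamma)
      }
      # likelihood-invariant translation along the alpha/u ridge: the
      # intercept and the mean of u are only jointly identified, and
      # single-site updates crawl along that ridge
      d <- stats::rnorm(1, 0, s_shift_u)
      lr <- sum(stats::dnorm(u - d, 0, sigma_u, log = TRUE)) -
        sum(stats::dnorm(u, 0, sigma_u, log = TRUE)) +
        stats::dnorm(alpha + d, 0, pr$beta_sd, log = TRUE) -
        stats::dnorm(alpha, 0, pr$beta_sd, log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        alpha <- alpha + d; u <- u - d
      }
      if (gamma > 0) s_shift_u <- adapt(s_shift_u, lr, gamma)
      ss_u <- sum(u^2)
      sigma_u <- exp(slice_sample(log(sigma_u), function(ls) {
        s <- exp(ls)
        -(n_dep - 1) * ls - ss_u / (2 * s^2) - s^2 / (2 * pr$sigma_u_sd^2)
      }))
    }

    # ridge translations for the factor blocks: shift the intercept and all
    # coefficients of one factor in opposite directions; only the factor's
    # reference rows change likelihood
    for (blk in shift_blocks) {
      d <- stats::rnorm(1, 0, s_shift_b[blk$id])
      rows <- blk$ref_rows
      ll_new <- nb_loglik(y[rows], popn[rows] * exp(eta[rows] + d), r)
      ll_old <- nb_loglik(y[rows], popn[rows] * exp(eta[rows]), r)
      lr <- ll_new - ll_old +
        stats::dnorm(alpha + d, 0, pr$beta_sd, log = TRUE) -
        stats::dnorm(alpha, 0, pr$beta_sd, log = TRUE) +
        sum(stats::dnorm(beta[blk$coefs] - d, 0, pr$beta_sd, log = TRUE)) -
        sum(stats::dnorm(beta[blk$coefs], 0, pr$beta_sd, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        alpha <- alpha + d
        beta[blk$coefs] <- beta[blk$coefs] - d
        eta[rows] <- eta[rows] + d
      }
      if (gamma > 0) s_shift_b[blk$id] <- adapt(s_shift_b[blk$id], lr, gamma)
    }

    # CAR effects (islands stay pinned at zero)
    if (use_v) {
      for (j in seq_len(n_dep)) {
        dg <- spec$degrees[j]
        if (dg == 0) next
        rows <- spec$dep_row[[j]]
        m_nb <- mean(v[spec$neighbors[[j]]])
        d <- stats::rnorm(1, 0, s_v[j])
        lpd <- -dg / (2 * sigma_v^2) *
          ((v[j] + d - m_nb)^2 - (v[j] - m_nb)^2)
        res <- mh_scalar(rows, d, lpd)
        if (res$acc) { v[j] <- v[j] + d; eta[rows] <- eta[rows] + d }
        if (gamma > 0) s_v[j] <- adapt(s_v[j], res$lr, gamma)
      }
      # recentre the connected block to sum zero each sweep (on-the-fly
      # centring as in WinBUGS car.normal; the sampled intercept absorbs
      # the small shift over iterations)
      conn <- spec$degrees > 0
      if (any(conn)) {
        shift <- mean(v[conn])
        v[conn] <- v[conn] - shift
        rows_conn <- dep_of_row %in% which(conn)
        eta[rows_conn] <- eta[rows_conn] - shift
      }
      ss_v <- 0
      for (j in seq_len(n_dep)) {
        nbj <- spec$neighbors[[j]]
        if (length(nbj))
          ss_v <- ss_v + sum((v[j] - v[nbj])^2)
      }
      ss_v <- ss_v / 2  # each edge counted twice
      if (spec$car_rank > 0)
        sigma_v <- exp(slice_sample(log(sigma_v), function(ls) {
          s <- exp(ls)
          -(spec$car_rank - 1) * ls - ss_v / (2 * s^2) -
            s^2 / (2 * pr$sigma_v_sd^2)
        }))
    }

    # dispersion
    if (!fix_r) {
      d <- stats::rnorm(1, 0, s_logr)
      r_new <- exp(log_r + d)
      ll_new <- nb_loglik(y, popn * exp(eta), r_new)
      ll_old <- nb_loglik(y, popn * exp(eta), r)
      lr <- ll_new - ll_old +
        stats::dnorm(log_r + d, 0, pr$logr_sd, log = TRUE) -
        stats::dnorm(log_r, 0, pr$logr_sd, log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        log_r <- log_r + d; r <- r_new
      }
      if (gamma > 0) s_logr <- adapt(s_logr, lr, gamma)
    }

    if (it > settings$n_burn &&
        (it - settings$n_burn) %% settings$thin == 0) {
      keep_i <- keep_i + 1L
      out[keep_i, ] <- c(alpha, beta, u, v, r, sigma_u, sigma_v)
    }
  }
  out[seq_len(keep_i), , drop = FALSE]
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Adaptive random-walk updates for the intercept, fixed effects, department
#' effects and log dispersion; slice updates for the two scale
#' hyperparameters; the CAR field is recentred to sum zero every sweep.
#' Chains start from dispersed initial values and are bit-reproducible given
#' the seed.
#'
#' @param spec `msprev_model` from [build_model()].
#' @param settings `msprev_mcmc_settings`.
#' @return object of class `msprev_fit`: list with `chains` (list of draw
#'   matrices), `spec`, `settings`.
#' @export
run_mcmc <- function(spec, settings = mcmc_settings()) {
  stopifnot(inherits(spec, "msprev_model"),
            inherits(settings, "msprev_mcmc_settings"))
  set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max, settings$n_chains)
  chains <- lapply(seq_len(settings$n_chains), function(ch)
    run_one_chain(spec, settings, chain_seeds[ch], dispersal = ch))
  structure(list(chains = chains, spec = spec, settings = settings),
            class = "msprev_fit")
}

all_draws <- function(fit) do.call(rbind, fit$chains)

#' Split-Rhat and effective sample size
#'
#' Potential scale reduction computed on split half-chains (rank-free
#' classic formulation) and an autocorrelation-based effective sample size
#' (initial positive sequence estimator), per scalar parameter.
#'
#' @param fit `msprev_fit` with at least 2 chains of >= 100 retained draws.
#' @return data.frame `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "msprev_fit"))
  if (length(fit$chains) < 2) stop("at least 2 chains are required")
  if (any(vapply(fit$chains, nrow, integer(1)) < 100))
    stop("need >= 100 retained draws per chain")
  halves <- list()
  for (m in fit$chains) {
    h <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1):(2 * h), , drop = FALSE]))
  }
  params <- colnames(fit$chains[[1]])
  res <- lapply(params, function(p) {
    xs <- lapply(halves, function(m) m[, p])
    nh <- length(xs[[1]]); mh <- length(xs)
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    w <- mean(vars)
    b <- nh * stats::var(means)
    rhat <- if (w <= 1e-300) {
      if (stats::var(means) <= 1e-300) 1 else Inf
    } else sqrt((w * (nh - 1) / nh + b / nh) / w)
    ess <- sum(vapply(fit$chains, function(m) ess_one(m[, p]), numeric(1)))
    data.frame(parameter = p, rhat = rhat, ess = ess,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) <= 1e-300) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  # initial positive sequence: stop at the first non-positive autocorrelation
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' Posterior draws of stratum-level rates
#'
#' Reconstructs `theta_{d,s} = exp(alpha + beta_sex + beta_age + u_d + v_d)`
#' for every retained draw.
#'
#' @param fit `msprev_fit`.
#' @return 3-d array (draw, department, stratum key `sex|age_class`).
#' @export
posterior_stratum_rates <- function(fit) {
  dr <- all_draws(fit)
  spec <- fit$spec
  st <- expand.grid(age_class = spec$age_levels, sex = spec$sex_levels,
                    stringsAsFactors = FALSE)
  keys <- paste(st$sex, st$age_class, sep = "|")
  n_draw <- nrow(dr)
  arr <- array(NA_real_, c(n_draw, length(spec$deps), length(keys)),
               dimnames = list(NULL, spec$deps, keys))
  beta_of <- function(kind, val) {
    nm <- paste0("beta_", kind, ":", val)
    if (nm %in% colnames(dr)) dr[, nm] else numeric(n_draw)
  }
  for (d in spec$deps) {
    base <- dr[, "alpha"] + dr[, paste0("u:", d)] + dr[, paste0("v:", d)]
    for (k in seq_along(keys)) {
      arr[, d, keys[k]] <- exp(base + beta_of("sex", st$sex[k]) +
                                 beta_of("age", st$age_class[k]))
    }
  }
  arr
}

summarize_draw_matrix <- function(m, value_name = "mean") {
  qs <- apply(m, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  out <- data.frame(department_id = colnames(m),
                    mean = colMeans(m), median = qs[2, ],
                    ci_low = qs[1, ], ci_high = qs[3, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# Per-draw department prevalence per 100,000: directly standardized under a
# reference, or the department's own-population weighted (crude) rate.
department_prevalence_draws <- function(fit, reference = NULL) {
  arr <- posterior_stratum_rates(fit)
  deps <- dimnames(arr)[[2]]
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "msprev_reference"))
    rk <- stratum_key(reference)
    miss <- setdiff(rk, dimnames(arr)[[3]])
    if (length(miss))
      stop("model lacks strata required by the reference: ",
           paste(miss, collapse = "; "))
    w <- reference$weight
    keys <- rk
  } else {
    keys <- dimnames(arr)[[3]]
  }
  p <- matrix(NA_real_, dim(arr)[1], length(deps),
              dimnames = list(NULL, deps))
  df <- fit$spec$data
  for (d in deps) {
    if (is.null(reference)) {
      sub <- df[df$department_id == d, , drop = FALSE]
      kk <- paste(sub$sex, sub$age_class, sep = "|")
      wd <- sub$pop / sum(sub$pop)
      m <- matrix(arr[, d, kk], ncol = length(kk))
      p[, d] <- 1e5 * as.vector(m %*% wd)
    } else {
      m <- matrix(arr[, d, keys], ncol = length(keys))
      p[, d] <- 1e5 * as.vector(m %*% w)
    }
  }
  p
}

#' Posterior summaries of department quantities
#'
#' @param fit `msprev_fit`.
#' @param quantity `"theta"` (the department's modeled crude prevalence per
#'   100,000, weighted by its own population structure), `"standardized"`
#'   (directly standardized under `reference`) or `"rr"` (relative risk
#'   against the unweighted department average of standardized prevalences).
#' @param reference `msprev_reference`; defaults to the bundled French 2004
#'   structure for standardized and rr summaries.
#' @return data.frame `department_id`, `mean`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
summarize_fit <- function(fit, quantity = c("theta", "standardized", "rr"),
                          reference = NULL) {
  quantity <- match.arg(quantity)
  if (nrow(all_draws(fit)) < 100)
    stop("need at least 100 retained draws")
  if (quantity == "theta")
    return(summarize_draw_matrix(department_prevalence_draws(fit, NULL)))
  if (is.null(reference))
    reference <- default_reference(fit$spec$strata)
  if (quantity == "standardized")
    return(summarize_draw_matrix(department_prevalence_draws(fit, reference)))
  relative_risks(fit, reference)
}

#' Relative risks against the average department
#'
#' Per retained draw, each department's directly standardized prevalence is
#' divided by the unweighted mean of all departments' standardized
#' prevalences in the same draw; the ratio is summarized with a 95 percent
#' credible interval.
#'
#' @param fit `msprev_fit` over at least 2 departments.
#' @param reference `msprev_reference` for the standardization step.
#' @return data.frame `department_id`, `mean`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
relative_risks <- function(fit, reference = NULL) {
  if (length(fit$spec$deps) < 2)
    stop("relative risks need at least 2 departments")
  if (is.null(reference))
    reference <- default_reference(fit$spec$strata)
  p <- department_prevalence_draws(fit, reference)
  ref_mean <- rowMeans(p)
  if (any(ref_mean <= 0)) stop("zero mean prevalence in a posterior draw")
  summarize_draw_matrix(p / ref_mean)
}
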