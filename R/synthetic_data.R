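#' Default hyperparameters for the synthetic registry
#'
#' The generator emulates a chronic neurological disease of roughly
#' 150 cases per 100,000 inhabitants: a low childhood rate, a prevalence
#' peak in the 40-59 age classes, about twice the rate in women as in men,
#' moderate spatially structured variation between departments (log-scale sd
#' 0.3 across the contiguity graph) and a smaller unstructured component
#' (sd 0.1).
#'
#' @return named list with `alpha` (log baseline rate for the reference
#'   stratum: first sex, first age class), `beta_sex`, `beta_age` (log
#'   effects for non-reference categories), `sigma_v` (spatial sd),
#'   `sigma_u` (unstructured sd).
#' @export
default_truth_hyperparams <- function() {
  list(alpha = log(5e-5),
       beta_sex = c(male = -0.7),
       beta_age = c("10-19" = 1.6, "20-29" = 3.0, "30-39" = 3.8,
                    "40-49" = 4.1, "50-59" = 4.0, "60-69" = 3.6,
                    "70-79" = 3.1, "80+" = 2.6),
       sigma_v = 0.3, sigma_u = 0.1)
}

#' Rectangular lattice adjacency for scalable property tests
#' @param nrows,ncols grid dimensions.
#' @return `msprev_graph` with rook contiguity; node ids `"r<i>c<j>"`.
#' @export
lattice_graph <- function(nrows, ncols) {
  id <- function(i, j) sprintf("r%dc%d", i, j)
  edges <- list()
  for (i in seq_len(nrows)) for (j in seq_len(ncols)) {
    if (j < ncols) edges[[length(edges) + 1]] <- c(id(i, j), id(i, j + 1))
    if (i < nrows) edges[[length(edges) + 1]] <- c(id(i, j), id(i + 1, j))
  }
  nodes <- as.vector(outer(seq_len(nrows), seq_len(ncols), id))
  adjacency_graph(nodes, if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2))
}

# Draw one intrinsic CAR field on the graph: zero-mean Gaussian with
# precision (D - W) / sigma^2, sampled in the span of the non-null
# eigenvectors and recentred to sum zero per connected component.
# Isolated nodes get 0.
icar_draw <- function(graph, sigma) {
  n <- length(graph$nodes)
  v <- stats::setNames(numeric(n), graph$nodes)
  if (sigma == 0 || n == 0) return(v)
  w <- adjacency_matrix(graph)
  q <- diag(rowSums(w)) - w
  eg <- eigen(q, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1) * 1e-9
  if (!any(pos)) return(v)
  z <- stats::rnorm(sum(pos), 0, sigma / sqrt(eg$values[pos]))
  v[] <- as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  comp <- graph_components(graph)
  deg <- graph_degrees(graph)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (all(deg[idx] == 0)) v[idx] <- 0 else v[idx] <- v[idx] - mean(v[idx])
  }
  v
}

#' Simulate the latent true state
#'
#' Draws a spatially structured field `v` (intrinsic pairwise-difference
#' Gaussian on the contiguity graph, recentred to sum zero) and an
#' unstructured field `u`, then builds per-(department, stratum) true
#' prevalences `exp(alpha + beta_sex + beta_age + u + v)`, clipped below 1.
#'
#' @param graph `msprev_graph`.
#' @param config stratum configuration; `beta_age`/`beta_sex` names must
#'   cover its non-reference categories.
#' @param hyper hyperparameter list as [default_truth_hyperparams()].
#' @param seed integer RNG seed; the draw is deterministic given it.
#' @return list of class `msprev_truth`: `alpha`, `beta_sex`, `beta_age`,
#'   `u`, `v` (named by department), `rates` (data.frame department_id, sex,
#'   age_class, rate), `hyper`, `seed`.
#' @export
simulate_truth <- function(graph, config = stratum_config(),
                           hyper = default_truth_hyperparams(), seed = 1) {
  stopifnot(inherits(graph, "msprev_graph"))
  num <- unlist(hyper[c("alpha", "sigma_v", "sigma_u")])
  if (anyNA(num) || any(!is.finite(c(num, hyper$beta_sex, hyper$beta_age))))
    stop("non-finite hyperparameters")
  if (any(c(hyper$sigma_v, hyper$sigma_u) < 0))
    stop("negative hyperparameter sd")
  set.seed(seed)
  v <- icar_draw(graph, hyper$sigma_v)
  u <- stats::setNames(stats::rnorm(length(graph$nodes), 0, hyper$sigma_u),
                       graph$nodes)
  st <- strata_table(config)
  bs <- effect_lookup(hyper$beta_sex, config$sexes, "beta_sex")
  ba <- effect_lookup(hyper$beta_age, config$age_classes, "beta_age")
  grid <- merge(data.frame(department_id = graph$nodes,
                           stringsAsFactors = FALSE), st)
  grid <- grid[order(grid$department_id, match(grid$sex, config$sexes),
                     match(grid$age_class, config$age_classes)), ]
  rownames(grid) <- NULL
  eta <- hyper$alpha + bs[grid$sex] + ba[grid$age_class] +
    u[grid$department_id] + v[grid$department_id]
  grid$rate <- pmin(exp(eta), 1 - 1e-12)
  structure(list(alpha = hyper$alpha, beta_sex = bs, beta_age = ba,
                 u = u, v = v, rates = grid, hyper = hyper, seed = seed),
            class = "msprev_truth")
}

effect_lookup <- function(beta, levels, what) {
  out <- stats::setNames(numeric(length(levels)), levels)
  extra <- setdiff(levels[-1], names(beta))
  if (length(extra))
    stop(sprintf("%s lacks effects for categories: %s", what,
                 paste(extra, collapse = ", ")))
  out[names(beta)[names(beta) %in% levels]] <-
    beta[names(beta) %in% levels]
  out[levels[1]] <- 0  # reference category
  out
}

#' Simulate true case counts
#'
#' Binomial draws: each resident of a (department, stratum) cell is a case
#' independently with the cell's true prevalence.
#'
#' @param truth `msprev_truth`.
#' @param pop `msprev_population` over the same departments and strata.
#' @param seed integer seed.
#' @param clip_warn error if any true rate reached the clipping bound.
#' @return data.frame `department_id`, `sex`, `age_class`, `n_true`.
#' @export
simulate_cases <- function(truth, pop, seed = 1, clip_warn = 0.5) {
  stopifnot(inherits(truth, "msprev_truth"), inherits(pop, "msprev_population"))
  key_t <- paste(truth$rates$department_id, stratum_key(truth$rates))
  key_p <- paste(pop$department_id, stratum_key(pop))
  idx <- match(key_p, key_t)
  if (anyNA(idx)) stop("population rows without a simulated true rate")
  rate <- truth$rates$rate[idx]
  if (any(rate >= clip_warn))
    stop("true rate at or above the plausibility threshold ", clip_warn)
  set.seed(seed)
  data.frame(department_id = pop$department_id, sex = pop$sex,
             age_class = pop$age_class,
             n_true = stats::rbinom(nrow(pop), pop$population, rate),
             stringsAsFactors = FALSE)
}

#' Capture profile for the three ascertainment sources
#'
#' Marginal capture probabilities for insurance (a), neurologist network (b)
#' and hospitalization (c) plus optional log-linear pairwise interactions on
#' the 2x2x2 capture table (positive values make joint capture more likely
#' than independence).
#'
#' @param p_a,p_b,p_c capture probabilities in [0,1].
#' @param theta_ab,theta_bc,theta_ac pairwise log-linear interactions.
#' @return named list of class `msprev_capture_profile`.
#' @export
capture_profile <- function(p_a = 0.5, p_b = 0.5, p_c = 0.6,
                            theta_ab = 0, theta_bc = 0, theta_ac = 0) {
  p <- c(p_a, p_b, p_c)
  if (any(p < 0) || any(p > 1)) stop("capture probabilities must be in [0,1]")
  structure(list(p_a = p_a, p_b = p_b, p_c = p_c, theta_ab = theta_ab,
                 theta_bc = theta_bc, theta_ac = theta_ac),
            class = "msprev_capture_profile")
}

# Joint distribution over the 8 capture cells (x_a, x_b, x_c in {0,1}),
# log-linear: independence margins times exp(pairwise interactions).
capture_cell_probs <- function(profile) {
  cells <- expand.grid(x_a = 0:1, x_b = 0:1, x_c = 0:1)
  bern <- function(p, x) ifelse(x == 1, p, 1 - p)
  w <- bern(profile$p_a, cells$x_a) * bern(profile$p_b, cells$x_b) *
    bern(profile$p_c, cells$x_c) *
    exp(profile$theta_ab * cells$x_a * cells$x_b +
        profile$theta_bc * cells$x_b * cells$x_c +
        profile$theta_ac * cells$x_a * cells$x_c)
  p <- w / sum(w)
  if (abs(sum(p) - 1) > 1e-9) stop("capture cell probabilities do not sum to 1")
  cbind(cells, p = p)
}

venn_cell_names <- c("a_only", "b_only", "c_only", "ab_only", "ac_only",
                     "bc_only", "abc")

#' Simulate the three overlapping capture lists
#'
#' Each true case is independently assigned to one of the eight capture
#' cells; cases captured by no source are dropped (they are invisible to the
#' registry). Exclusive Venn-cell counts and the implied source marginals
#' are returned.
#'
#' @param true_cases data.frame from [simulate_cases()].
#' @param profile `msprev_capture_profile`.
#' @param seed integer seed.
#' @param config stratum configuration for the emitted source-count table.
#' @return list with `venn` (data.frame of the seven exclusive cells plus
#'   `n_true` per row) and `sources` (`msprev_source_counts`).
#' @export
simulate_capture <- function(true_cases, profile = capture_profile(),
                             seed = 1, config = stratum_config()) {
  cp <- capture_cell_probs(profile)
  # order rows into the seven observable cells + the dropped (0,0,0) cell
  lab <- with(cp, ifelse(x_a + x_b + x_c == 0, "none",
              ifelse(x_a == 1 & x_b == 0 & x_c == 0, "a_only",
              ifelse(x_a == 0 & x_b == 1 & x_c == 0, "b_only",
              ifelse(x_a == 0 & x_b == 0 & x_c == 1, "c_only",
              ifelse(x_a == 1 & x_b == 1 & x_c == 0, "ab_only",
              ifelse(x_a == 1 & x_b == 0 & x_c == 1, "ac_only",
              ifelse(x_a == 0 & x_b == 1 & x_c == 1, "bc_only", "abc"))))))))
  probs <- stats::setNames(cp$p, lab)[c("none", venn_cell_names)]
  set.seed(seed)
  n <- nrow(true_cases)
  cell_counts <- matrix(0L, n, 8,
                        dimnames = list(NULL, c("none", venn_cell_names)))
  for (i in seq_len(n))
    cell_counts[i, ] <- stats::rmultinom(1, true_cases$n_true[i], probs)
  venn <- data.frame(true_cases[c("department_id", "sex", "age_class")],
                     cell_counts[, venn_cell_names, drop = FALSE],
                     n_true = true_cases$n_true, stringsAsFactors = FALSE)
  src <- data.frame(
    department_id = venn$department_id, sex = venn$sex,
    age_class = venn$age_class,
    count_insurance = venn$a_only + venn$ab_only + venn$ac_only + venn$abc,
    count_network = venn$b_only + venn$ab_only + venn$bc_only + venn$abc,
    count_hospital = venn$c_only + venn$ac_only + venn$bc_only + venn$abc,
    stringsAsFactors = FALSE)
  list(venn = venn, sources = as_source_counts(src, config))
}

#' Overlap shares implied by exclusive Venn cells
#'
#' The union is the sum of the seven exclusive cells; each share is the
#' inclusive intersection count divided by that union, the same convention
#' [estimate_unique_cases()] inverts (so the estimator applied to the
#' marginals and these shares recovers the union exactly).
#'
#' @param venn one row (or a summed row) of Venn cells: a data.frame or
#'   named vector holding `a_only` ... `abc`.
#' @param label name for the share set.
#' @return [overlap_shares()] object.
#' @export
shares_from_venn <- function(venn, label = "venn") {
  if (is.data.frame(venn)) {
    if (nrow(venn) != 1) venn <- colSums(venn[venn_cell_names])
    else venn <- unlist(venn[venn_cell_names])
  }
  venn <- venn[venn_cell_names]
  union <- sum(venn)
  if (union <= 0) stop("empty union: no captured cases")
  overlap_shares(s_ab = (venn[["ab_only"]] + venn[["abc"]]) / union,
                 s_bc = (venn[["bc_only"]] + venn[["abc"]]) / union,
                 s_ac = (venn[["ac_only"]] + venn[["abc"]]) / union,
                 s_abc = venn[["abc"]] / union, label = label)
}

#' Simulate a stratified population table
#'
#' Department populations are log-normally sized around `mean_pop` and
#' spread over strata with the French 2004 synthetic reference structure.
#'
#' @param graph `msprev_graph` naming the departments.
#' @param config stratum configuration.
#' @param mean_pop expected department population.
#' @param seed integer seed.
#' @return `msprev_population`.
#' @export
simulate_population <- function(graph, config = stratum_config(),
                                mean_pop = 5e5, seed = 1) {
  ref <- default_reference(config)
  set.seed(seed)
  tot <- exp(stats::rnorm(length(graph$nodes), log(mean_pop), 0.4))
  grid <- merge(data.frame(department_id = graph$nodes,
                           stringsAsFactors = FALSE), strata_table(config))
  grid <- grid[order(grid$department_id, match(grid$sex, config$sexes),
                     match(grid$age_class, config$age_classes)), ]
  rownames(grid) <- NULL
  w <- ref$weight[match(stratum_key(grid), stratum_key(ref))]
  grid$population <- round(tot[match(grid$department_id, graph$nodes)] * w)
  as_population(grid, config)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the source-count CSV, population CSV, adjacency edge list,
#' true-state CSV and a flat-text manifest recording the seed and
#' hyperparameters, so the fixture can be regenerated byte-identically.
#'
#' @param truth `msprev_truth`.
#' @param venn Venn-cell data.frame from [simulate_capture()].
#' @param sources `msprev_source_counts`.
#' @param pop `msprev_population`.
#' @param graph `msprev_graph`.
#' @param dir output directory.
#' @return invisibly, named vector of the files written.
#' @export
write_fixture <- function(truth, venn, sources, pop, graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(sources = file.path(dir, "source_counts.csv"),
             population = file.path(dir, "population.csv"),
             adjacency = file.path(dir, "adjacency.txt"),
             truth = file.path(dir, "true_state.csv"),
             venn = file.path(dir, "venn_cells.csv"),
             manifest = file.path(dir, "manifest.txt"))
  utils::write.csv(as.data.frame(sources), files[["sources"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pop), files[["population"]],
                   row.names = FALSE)
  write_adjacency(graph, files[["adjacency"]])
  tr <- truth$rates
  tr$u <- truth$u[tr$department_id]
  tr$v <- truth$v[tr$department_id]
  utils::write.csv(format_full_precision(tr), files[["truth"]],
                   row.names = FALSE)
  utils::write.csv(venn, files[["venn"]], row.names = FALSE)
  hy <- truth$hyper
  writeLines(c(sprintf("seed: %d", truth$seed),
               sprintf("alpha: %.17g", hy$alpha),
               sprintf("sigma_v: %.17g", hy$sigma_v),
               sprintf("sigma_u: %.17g", hy$sigma_u),
               sprintf("beta_sex: %s",
                       paste(sprintf("%s=%.17g", names(hy$beta_sex),
                                     hy$beta_sex), collapse = ",")),
               sprintf("beta_age: %s",
                       paste(sprintf("%s=%.17g", names(hy$beta_age),
                                     hy$beta_age), collapse = ",")),
               paste("files:", paste(basename(files), collapse = " "))),
             files[["manifest"]])
  invisible(files)
}
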