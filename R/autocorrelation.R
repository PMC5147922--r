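#' Internally indirectly standardized expected counts
#'
#' Pools all departments to estimate stratum-specific rates, then applies
#' them to each department's own population structure:
#' `E_d = sum_k pop_{d,k} * (sum_d' O_{d',k} / sum_d' pop_{d',k})`.
#' By construction the expected counts conserve the observed total.
#'
#' @param cases `msprev_unique_cases`.
#' @param pop `msprev_population` paired over identical departments and
#'   strata.
#' @return data.frame `department_id`, `observed`, `expected`.
#' @export
internal_expected_counts <- function(cases, pop) {
  key_c <- paste(cases$department_id, stratum_key(cases))
  key_p <- paste(pop$department_id, stratum_key(pop))
  if (length(key_c) != length(key_p) || anyNA(match(key_c, key_p)))
    stop("cases and population must cover identical (department, stratum) rows")
  o <- cases$unique_cases_real
  p <- pop$population[match(key_c, key_p)]
  sk <- stratum_key(cases)
  o_k <- tapply(o, sk, sum)
  p_k <- tapply(p, sk, sum)
  bad <- p_k == 0 & o_k > 0
  if (any(bad))
    stop("stratum with cases but zero total population: ",
         paste(names(o_k)[bad], collapse = "; "))
  rate_k <- ifelse(p_k > 0, o_k / p_k, 0)
  e <- p * rate_k[sk]
  out <- stats::aggregate(data.frame(observed = o, expected = e),
                          by = list(department_id = cases$department_id),
                          FUN = sum)
  out[order(out$department_id), , drop = FALSE]
}

#' Standardized prevalence ratio
#'
#' `SPR = 100 * observed / expected` under internal indirect
#' standardization. Departments with `expected = 0` and `observed = 0` get
#' `NA` with a flag; `expected = 0` with cases is an error.
#'
#' @param expected data.frame from [internal_expected_counts()] (columns
#'   `department_id`, `observed`, `expected`).
#' @return data.frame with an added `spr` column (and logical `undefined`).
#' @export
spr <- function(expected) {
  need_cols(expected, c("department_id", "observed", "expected"), "SPR input")
  bad <- expected$expected == 0 & expected$observed > 0
  if (any(bad))
    stop("observed cases with zero expected count: ",
         paste(expected$department_id[bad], collapse = ", "))
  out <- expected
  out$undefined <- out$expected == 0
  out$spr <- ifelse(out$undefined, NA_real_,
                    100 * out$observed / out$expected)
  out
}

#' Moran's I
#'
#' Global spatial autocorrelation index
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}}
#' with binary contiguity weights by default (`w_ij = 1` for departments
#' sharing a border) or row-standardized weights.
#'
#' @param values named numeric vector, one value per graph node (names must
#'   match node ids; an unnamed vector in node order is accepted).
#' @param graph `msprev_graph`.
#' @param weights `"binary"` or `"row"` (row-standardized).
#' @return the index (numeric scalar).
#' @export
moran_i <- function(values, graph, weights = c("binary", "row")) {
  weights <- match.arg(weights)
  x <- align_values(values, graph)
  n <- length(x)
  if (n < 3) stop("Moran's I needs at least 3 areas")
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("zero variance: Moran's I undefined")
  w <- adjacency_matrix(graph, row_standardize = (weights == "row"))
  s0 <- sum(w)
  if (s0 == 0) stop("graph has no edges: Moran's I undefined")
  (n / s0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

align_values <- function(values, graph) {
  if (!is.null(names(values))) {
    miss <- setdiff(graph$nodes, names(values))
    if (length(miss))
      stop("values missing for node(s): ", paste(miss, collapse = ", "))
    values <- values[graph$nodes]
  } else if (length(values) != length(graph$nodes)) {
    stop("unnamed values must have one entry per graph node")
  }
  as.numeric(values)
}

#' Moran test of spatial autocorrelation
#'
#' Normal method: Z-deviate against the randomization-assumption null
#' moments (`E[I] = -1/(n-1)`, the standard randomization variance), with
#' two-sided `p = 2 (1 - Phi(|z|))`. Permutation method: the observed |I|
#' is ranked among `n_perm` random relabelings,
#' `p = (1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (1 + n_perm)`;
#' absolute deviations are taken around the null expectation so the
#' two-sided rejection region matches the z-based test.
#'
#' @inheritParams moran_i
#' @param method `"normal"`, `"permutation"` or `"both"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation draw.
#' @return list of class `msprev_moran`: `i_value`, `e_null`, `var_null`,
#'   `z`, `p_normal`, `p_perm` (NA unless permutations ran), `n_perm`,
#'   `weights`.
#' @export
moran_test <- function(values, graph, weights = c("binary", "row"),
                       method = c("normal", "permutation", "both"),
                       n_perm = 999, seed = 1) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  x <- align_values(values, graph)
  n <- length(x)
  i_obs <- moran_i(stats::setNames(x, graph$nodes), graph, weights)
  w <- adjacency_matrix(graph, row_standardize = (weights == "row"))
  s0 <- sum(w)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  z0 <- x - mean(x)
  b2 <- (sum(z0^4) / n) / (sum(z0^2) / n)^2
  e_null <- -1 / (n - 1)
  # randomization-assumption variance (Cliff & Ord)
  var_null <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
               b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_null^2
  if (var_null <= 0) stop("non-positive null variance")
  z <- (i_obs - e_null) / sqrt(var_null)
  p_normal <- 2 * stats::pnorm(-abs(z))
  p_perm <- NA_real_
  if (method %in% c("permutation", "both")) {
    if (n_perm < 99) stop("n_perm must be at least 99")
    set.seed(seed)
    i_perm <- vapply(seq_len(n_perm), function(k)
      moran_i(stats::setNames(sample(x), graph$nodes), graph, weights),
      numeric(1))
    p_perm <- (1 + sum(abs(i_perm - e_null) >=
                         abs(i_obs - e_null) - 1e-15)) / (1 + n_perm)
  }
  structure(list(i_value = i_obs, e_null = e_null, var_null = var_null,
                 z = z, p_normal = p_normal, p_perm = p_perm,
                 n_perm = if (is.na(p_perm)) 0L else as.integer(n_perm),
                 weights = weights),
            class = "msprev_moran")
}

#' @export
print.msprev_moran <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (null mean %.4f, sd %.4f)\n",
              x$i_value, x$e_null, sqrt(x$var_null)))
  cat(sprintf("Z = %.2f, two-sided normal p = %.4g\n", x$z, x$p_normal))
  if (!is.na(x$p_perm))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}
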