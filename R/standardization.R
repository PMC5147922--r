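#' Bundled reference populations
#'
#' Three shipped weight tables for direct age-sex standardization:
#' \describe{
#'   \item{french_2004}{an approximate (synthetic) reconstruction of the
#'     French 2004 census age-sex margins, shipped because the exact census
#'     table is an external input; replace it via
#'     [read_reference_population()] for production use.}
#'   \item{european}{the 1976 European Standard Population (age only, split
#'     evenly between the sexes).}
#'   \item{world}{the WHO World Standard Population 2000-2025 (age only,
#'     split evenly between the sexes).}
#' }
#' Age-only source tables ship in five-year bins and are re-binned to the
#' configured age classes by lower-bound assignment, which conserves total
#' weight exactly.
#'
#' @param name one of `"french_2004"`, `"european"`, `"world"`.
#' @param config stratum configuration defining the target age classes.
#' @return `msprev_reference` (normalized weights).
#' @export
bundled_reference <- function(name = c("french_2004", "european", "world"),
                              config = stratum_config()) {
  if (!is.character(name) || !name[1] %in% c("french_2004", "european",
                                             "world"))
    stop("unknown reference '", name[1],
         "'; available: french_2004, european, world")
  name <- match.arg(name)
  if (name == "french_2004") {
    return(read_reference_population(
      system.file("extdata", "ref_french_2004_synthetic.csv",
                  package = "msprev", mustWork = TRUE),
      config, name = "french_2004"))
  }
  f <- switch(name, european = "ref_esp1976_5yr.csv",
              world = "ref_who2000_5yr.csv")
  src <- utils::read.csv(system.file("extdata", f, package = "msprev",
                                     mustWork = TRUE),
                         stringsAsFactors = FALSE)
  age_w <- rebin_age_weights(src, config$age_classes)
  df <- do.call(rbind, lapply(config$sexes, function(s)
    data.frame(sex = s, age_class = names(age_w),
               weight = age_w / length(config$sexes),
               stringsAsFactors = FALSE)))
  as_reference_population(df, config, name = name)
}

#' Uniform reference population over the configured strata
#'
#' Equal weight on every stratum; useful as a neutral default when the
#' stratification does not match any shipped table.
#'
#' @param config stratum configuration.
#' @return `msprev_reference`.
#' @export
uniform_reference <- function(config = stratum_config()) {
  st <- strata_table(config)
  as_reference_population(data.frame(st, weight = 1), config,
                          name = "uniform")
}

default_reference <- function(config) {
  if (identical(config$age_classes, default_age_classes()) &&
      identical(config$sexes, c("female", "male")))
    bundled_reference("french_2004", config)
  else uniform_reference(config)
}

parse_age_lower <- function(labels) {
  as.numeric(sub("^([0-9]+).*$", "\\1", labels))
}

parse_age_upper <- function(labels) {
  up <- rep(Inf, length(labels))
  m <- grepl("^[0-9]+-[0-9]+$", labels)
  up[m] <- as.numeric(sub("^[0-9]+-([0-9]+)$", "\\1", labels[m]))
  up
}

#' Re-bin an age-only weight table to target age classes
#'
#' Each source bin is assigned to the target class containing its lower
#' bound, so total weight is conserved exactly. Source bins must nest inside
#' the target classes (the shipped five-year tables nest in ten-year
#' classes).
#'
#' @param src data.frame with `age_class`, `weight`.
#' @param target_classes character vector of target labels.
#' @return named numeric vector of summed weights per target class.
#' @export
rebin_age_weights <- function(src, target_classes) {
  lo_t <- parse_age_lower(target_classes)
  up_t <- parse_age_upper(target_classes)
  lo_s <- parse_age_lower(src$age_class)
  idx <- vapply(lo_s, function(l) {
    k <- which(l >= lo_t & l <= up_t)
    if (!length(k)) stop("source age bin outside target classes: ", l)
    k[1]
  }, integer(1))
  out <- stats::setNames(numeric(length(target_classes)), target_classes)
  for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + src$weight[i]
  out
}

#' Direct age-sex standardized prevalence
#'
#' Weighted average of an area's stratum-specific rates under a fixed
#' external reference population, expressed per 100,000:
#' \deqn{P_d = 10^5 \sum_k w_k \theta_{d,k}.}
#' With point rates the result is one number per department; with posterior
#' draws (see [posterior_stratum_rates()]) standardization is applied per
#' draw and summarized with a mean, median and 95 percent credible interval.
#'
#' @param rates either a data.frame (`department_id`, `sex`, `age_class`,
#'   `rate`) of point rates, or a 3-d array of posterior stratum-rate draws
#'   with dimensions (draw, department, stratum key).
#' @param reference `msprev_reference`.
#' @return data.frame: `department_id`, `prevalence` (and `median`,
#'   `ci_low`, `ci_high` for draws).
#' @export
direct_standardized_prevalence <- function(rates, reference) {
  stopifnot(inherits(reference, "msprev_reference"))
  rk <- stratum_key(reference)
  if (is.array(rates) && length(dim(rates)) == 3) {
    miss <- setdiff(rk, dimnames(rates)[[3]])
    if (length(miss))
      stop("draws lack rates for strata: ", paste(miss, collapse = "; "))
    w <- reference$weight
    deps <- dimnames(rates)[[2]]
    p <- vapply(deps, function(d)
      1e5 * as.vector(matrix(rates[, d, rk], ncol = length(rk)) %*% w),
      numeric(dim(rates)[1]))
    summarize_draw_matrix(p, value_name = "prevalence")
  } else {
    miss <- setdiff(rk, stratum_key(rates))
    if (length(miss))
      stop("rates lack strata: ", paste(miss, collapse = "; "))
    deps <- sort(unique(rates$department_id))
    prev <- vapply(deps, function(d) {
      sub <- rates[rates$department_id == d, , drop = FALSE]
      r <- sub$rate[match(rk, stratum_key(sub))]
      if (anyNA(r)) stop("department ", d, " lacks rates for some strata")
      1e5 * sum(reference$weight * r)
    }, numeric(1))
    data.frame(department_id = deps, prevalence = unname(prev),
               stringsAsFactors = FALSE)
  }
}

#' Crude prevalence per 100,000
#'
#' @param cases `msprev_unique_cases` (the real-valued estimates are used).
#' @param pop `msprev_population` over the same rows.
#' @return list with `by_department` (data.frame `department_id`, `cases`,
#'   `population`, `crude`) and `overall` (single-row data.frame).
#' @export
crude_prevalence <- function(cases, pop) {
  key_c <- paste(cases$department_id, stratum_key(cases))
  key_p <- paste(pop$department_id, stratum_key(pop))
  idx <- match(key_c, key_p)
  if (anyNA(idx)) stop("case rows without matching population rows")
  dep <- stats::aggregate(
    data.frame(cases = cases$unique_cases_real,
               population = pop$population[idx]),
    by = list(department_id = cases$department_id), FUN = sum)
  if (any(dep$population <= 0))
    stop("zero total population for department(s): ",
         paste(dep$department_id[dep$population <= 0], collapse = ", "))
  dep$crude <- 1e5 * dep$cases / dep$population
  overall <- data.frame(cases = sum(dep$cases),
                        population = sum(dep$population))
  overall$crude <- 1e5 * overall$cases / overall$population
  list(by_department = dep, overall = overall)
}
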