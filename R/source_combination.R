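#' Estimate unique cases from three source marginals and overlap shares
#'
#' Three ascertainment lists count some people more than once. Writing N for
#' the unique (union) number of cases and expressing each inclusive
#' intersection as a share of N (`s_ab = |A n B| / N`, etc.),
#' inclusion-exclusion gives
#' \deqn{a + b + c = N (1 + s_{ab} + s_{bc} + s_{ac} - s_{abc})}
#' so the unique total is the marginal sum divided by
#' `1 + s_ab + s_bc + s_ac - s_abc`. With all shares zero the sources are
#' disjoint and N is the plain sum; with all shares one the three lists are
#' identical and N equals each marginal.
#'
#' @param a,b,c non-negative marginal counts of the three sources
#'   (vectorized; recycled to a common length).
#' @param shares an [overlap_shares()] set.
#' @return non-negative real estimate(s) of the unique case count.
#' @export
estimate_unique_cases <- function(a, b, c, shares) {
  stopifnot(inherits(shares, "msprev_shares"))
  if (any(a < 0) || any(b < 0) || any(c < 0))
    stop("marginal counts must be non-negative")
  div <- 1 + shares$s_ab + shares$s_bc + shares$s_ac - shares$s_abc
  if (div <= 0) stop("non-positive dedup divisor: invalid share set")
  (a + b + c) / div
}

#' Read a share catalogue
#'
#' A catalogue names one or more overlap-share sets. Optional `sex` and
#' `age_class` columns provide stratum-specific shares under the same label;
#' a row with both blank (or absent columns) is the label's aggregate set.
#'
#' @param path CSV with columns `label`, `s_ab`, `s_bc`, `s_ac`, `s_abc` and
#'   optionally `sex`, `age_class`.
#' @return data.frame of class `msprev_share_catalogue`.
#' @export
read_share_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_share_catalogue(df)
}

#' @rdname read_share_catalogue
#' @param df data.frame in the catalogue layout.
#' @export
as_share_catalogue <- function(df) {
  need_cols(df, c("label", "s_ab", "s_bc", "s_ac", "s_abc"), "share catalogue")
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$age_class)) df$age_class <- NA_character_
  for (i in seq_len(nrow(df)))      # validates every row
    overlap_shares(df$s_ab[i], df$s_bc[i], df$s_ac[i], df$s_abc[i],
                   df$label[i])
  class(df) <- c("msprev_share_catalogue", "data.frame")
  df
}

#' The share sets used in the French MS study
#'
#' Two catalogued sets: the Lorraine-region aggregate shares applied to most
#' departments (insurance-network 0.46, network-hospital 0.23,
#' insurance-hospital 0.20, triple 0.12) and the Haute-Garonne set (0.25,
#' 0.28, 0.42, 0.17). An alternative Lorraine ordering that swaps the two
#' smaller pairwise values ships as `lorraine_2008_alt`, since the two
#' published footnotes disagree on which pair carries 0.23 versus 0.20.
#'
#' @return `msprev_share_catalogue`.
#' @export
study_share_catalogue <- function() {
  read_share_catalogue(system.file("extdata", "share_catalogue.csv",
                                   package = "msprev", mustWork = TRUE))
}

#' Department-to-share-set assignment
#'
#' @param departments character vector of department ids.
#' @param labels share-set label per department (recycled).
#' @return data.frame of class `msprev_share_assignment` with columns
#'   `department_id`, `label`.
#' @export
share_assignment <- function(departments, labels) {
  df <- data.frame(department_id = as.character(departments),
                   label = rep_len(as.character(labels), length(departments)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$department_id))
    stop("duplicate department in share assignment")
  class(df) <- c("msprev_share_assignment", "data.frame")
  df
}

#' Default study assignment: Haute-Garonne gets its own 2005 share set,
#' every other department the Lorraine 2008 aggregate set.
#' @param departments department ids present in the case table.
#' @export
study_share_assignment <- function(departments) {
  share_assignment(departments,
                   ifelse(departments == "31", "haute_garonne_2005",
                          "lorraine_2008"))
}

lookup_shares <- function(catalogue, label, sex = NA, age_class = NA) {
  rows <- catalogue[catalogue$label == label, , drop = FALSE]
  if (!nrow(rows)) stop("share set not in catalogue: ", label)
  hit <- rows[!is.na(rows$sex) & !is.na(rows$age_class) &
                rows$sex %in% sex & rows$age_class %in% age_class, ,
              drop = FALSE]
  if (!nrow(hit)) hit <- rows[is.na(rows$sex) & is.na(rows$age_class), ,
                              drop = FALSE]
  if (!nrow(hit))
    stop(sprintf("no aggregate or matching stratum-specific shares for '%s'",
                 label))
  overlap_shares(hit$s_ab[1], hit$s_bc[1], hit$s_ac[1], hit$s_abc[1], label)
}

#' Combine the three sources into unique case counts
#'
#' Applies [estimate_unique_cases()] row-wise to a stratified source-count
#' table, using stratum-specific shares where the catalogue provides them and
#' the department's aggregate set otherwise. Real-valued estimates are kept
#' for reporting; a half-to-even rounded integer column feeds the count
#' likelihood. A warning (not an error) is raised when an estimate falls
#' below the largest of its three marginals, which inconsistent shares can
#' produce.
#'
#' @param sources `msprev_source_counts` table.
#' @param assignment `msprev_share_assignment` covering every department.
#' @param catalogue `msprev_share_catalogue`.
#' @return data.frame of class `msprev_unique_cases` with columns
#'   `department_id`, `sex`, `age_class`, `unique_cases_real`,
#'   `unique_cases_int`.
#' @export
combine_table <- function(sources, assignment,
                          catalogue = study_share_catalogue()) {
  stopifnot(inherits(sources, "msprev_source_counts"))
  deps <- unique(sources$department_id)
  miss <- setdiff(deps, assignment$department_id)
  if (length(miss))
    stop("departments without an assigned share set: ",
         paste(miss, collapse = ", "))
  lab <- stats::setNames(assignment$label, assignment$department_id)
  n <- nrow(sources)
  real <- numeric(n)
  for (i in seq_len(n)) {
    sh <- lookup_shares(catalogue, lab[[sources$department_id[i]]],
                        sources$sex[i], sources$age_class[i])
    real[i] <- estimate_unique_cases(sources$count_insurance[i],
                                     sources$count_network[i],
                                     sources$count_hospital[i], sh)
  }
  mx <- pmax(sources$count_insurance, sources$count_network,
             sources$count_hospital)
  low <- real < mx - 1e-9
  if (any(low))
    warning(sprintf(paste0("%d row(s) have a unique-case estimate below the",
                           " largest source marginal (inconsistent shares)"),
            sum(low)))
  out <- data.frame(department_id = sources$department_id,
                    sex = sources$sex, age_class = sources$age_class,
                    unique_cases_real = real,
                    unique_cases_int = round_half_even(real),
                    stringsAsFactors = FALSE)
  class(out) <- c("msprev_unique_cases", "data.frame")
  attr(out, "strata") <- attr(sources, "strata")
  out
}

#' Aggregate counts to department or region level
#'
#' Sums every numeric column of a stratified (or department-level) table by
#' department, or by region given a department-to-region map.
#'
#' @param table data.frame with a `department_id` column and numeric count
#'   columns.
#' @param level `"department"` or `"region"`.
#' @param region_map data.frame with columns `department_id`, `region`;
#'   required (and must cover all departments) when `level = "region"`.
#' @return data.frame of per-group sums.
#' @export
aggregate_counts <- function(table, level = c("department", "region"),
                             region_map = NULL) {
  level <- match.arg(level)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (level == "department") {
    key <- table$department_id
  } else {
    if (is.null(region_map))
      stop("region_map is required for regional aggregation")
    miss <- setdiff(unique(table$department_id), region_map$department_id)
    if (length(miss))
      stop("departments missing from region map: ",
           paste(miss, collapse = ", "))
    key <- region_map$region[match(table$department_id,
                                   region_map$department_id)]
  }
  out <- stats::aggregate(table[num], by = list(group = key), FUN = sum)
  names(out)[1] <- if (level == "department") "department_id" else "region"
  out[order(out[[1]]), , drop = FALSE]
}
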