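#' Stratum configuration
#'
#' Defines the demographic strata used throughout the package: the cross
#' product of sexes and ordered age classes. The default age classes are
#' ten-year bins from 0-9 up to an open 80+ class, which re-bin cleanly from
#' the five-year classes of the standard European and world reference tables.
#'
#' @param age_classes character vector of ordered age-class labels.
#' @param sexes character vector of sex labels; the first is the reference
#'   category in the regression model.
#' @return An object of class `msprev_strata` with elements `sexes`,
#'   `age_classes`.
#' @export
stratum_config <- function(age_classes = default_age_classes(),
                           sexes = c("female", "male")) {
  if (length(age_classes) < 1 || anyDuplicated(age_classes))
    stop("age_classes must be a non-empty vector of unique labels")
  if (length(sexes) < 1 || anyDuplicated(sexes))
    stop("sexes must be unique labels")
  structure(list(sexes = as.character(sexes),
                 age_classes = as.character(age_classes)),
            class = "msprev_strata")
}

#' @rdname stratum_config
#' @export
default_age_classes <- function() {
  c("0-9", "10-19", "20-29", "30-39", "40-49",
    "50-59", "60-69", "70-79", "80+")
}

#' Full stratum table (cross-product of sex and age class)
#'
#' @param config a `stratum_config()` object.
#' @return data.frame with columns `sex`, `age_class`, one row per stratum,
#'   age class varying fastest.
#' @export
strata_table <- function(config = stratum_config()) {
  stopifnot(inherits(config, "msprev_strata"))
  out <- expand.grid(age_class = config$age_classes, sex = config$sexes,
                     stringsAsFactors = FALSE)
  data.frame(sex = out$sex, age_class = out$age_class,
             stringsAsFactors = FALSE)
}

stratum_key <- function(df) paste(df$sex, df$age_class, sep = "|")

check_strata <- function(df, config, where) {
  bad <- !(df$age_class %in% config$age_classes)
  if (any(bad))
    stop(sprintf("%s: unknown age_class label(s) at row(s) %s: %s", where,
                 paste(utils::head(which(bad), 5), collapse = ", "),
                 paste(unique(df$age_class[bad]), collapse = ", ")))
  bad <- !(df$sex %in% config$sexes)
  if (any(bad))
    stop(sprintf("%s: unknown sex label(s) at row(s) %s", where,
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  invisible(TRUE)
}

check_nonneg_int <- function(x, col, where) {
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop(sprintf("%s: column '%s' must hold non-negative integers (offending row %d)",
                 where, col, which(is.na(x) | x < 0 | x != floor(x))[1]))
  invisible(TRUE)
}

check_unique_dep_stratum <- function(df, where) {
  key <- paste(df$department_id, stratum_key(df))
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (department, stratum) rows, e.g. %s",
                 where, key[which(duplicated(key))[1]]))
  invisible(TRUE)
}

need_cols <- function(df, cols, where) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Read a three-source case-count table
#'
#' Reads per-(department, sex, age class) marginal case counts from the three
#' ascertainment sources (health insurance, neurologist network,
#' hospitalization discharge records).
#'
#' @param path CSV file with header columns `department_id`, `sex`,
#'   `age_class`, `count_insurance`, `count_network`, `count_hospital`.
#' @param config stratum configuration used to validate labels.
#' @return validated data.frame of class `msprev_source_counts`.
#' @export
read_source_counts <- function(path, config = stratum_config()) {
  df <- suppressWarnings(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(department_id = "character")))
  as_source_counts(df, config)
}

#' @rdname read_source_counts
#' @param df a data.frame holding the same columns as the CSV contract.
#' @export
as_source_counts <- function(df, config = stratum_config()) {
  where <- "source counts"
  need_cols(df, c("department_id", "sex", "age_class", "count_insurance",
                  "count_network", "count_hospital"), where)
  df$department_id <- as.character(df$department_id)
  check_strata(df, config, where)
  for (cl in c("count_insurance", "count_network", "count_hospital"))
    check_nonneg_int(df[[cl]], cl, where)
  check_unique_dep_stratum(df, where)
  class(df) <- c("msprev_source_counts", "data.frame")
  attr(df, "strata") <- config
  df
}

#' Read a population table
#'
#' @param path CSV with columns `department_id`, `sex`, `age_class`,
#'   `population`.
#' @param config stratum configuration.
#' @return validated data.frame of class `msprev_population`.
#' @export
read_population <- function(path, config = stratum_config()) {
  df <- suppressWarnings(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(department_id = "character")))
  as_population(df, config)
}

#' @rdname read_population
#' @param df data.frame with the population-table columns.
#' @export
as_population <- function(df, config = stratum_config()) {
  where <- "population table"
  need_cols(df, c("department_id", "sex", "age_class", "population"), where)
  df$department_id <- as.character(df$department_id)
  check_strata(df, config, where)
  check_nonneg_int(df$population, "population", where)
  check_unique_dep_stratum(df, where)
  class(df) <- c("msprev_population", "data.frame")
  attr(df, "strata") <- config
  df
}

#' Adjacency graph of areas
#'
#' A light undirected-graph container: unique node ids and a symmetric edge
#' set with no self-loops. Isolated nodes are permitted (their spatial random
#' effect is pinned at zero by the model).
#'
#' @param nodes character vector of area ids.
#' @param edges two-column character matrix (or data.frame) of unordered node
#'   pairs.
#' @return object of class `msprev_graph`.
#' @export
adjacency_graph <- function(nodes, edges = matrix(character(0), ncol = 2)) {
  nodes <- unique(as.character(nodes))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && length(edges) > 0)
    stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loop edge not allowed: ",
           edges[which(edges[, 1] == edges[, 2])[1], 1])
    miss <- setdiff(c(edges), nodes)
    if (length(miss)) nodes <- c(nodes, miss)
    # canonical order + dedup so the edge set is symmetric by construction
    a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b))
    edges <- cbind(a[keep], b[keep])
  }
  structure(list(nodes = nodes, edges = edges), class = "msprev_graph")
}

#' Read an adjacency edge list
#'
#' One edge per line as `id_a id_b` (whitespace separated). A line with a
#' single token declares an isolated node. Blank lines and lines starting
#' with `#` are ignored. The graph is symmetric regardless of the direction
#' edges are written in.
#'
#' @param path text file path.
#' @return `msprev_graph`.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  n_tok <- lengths(toks)
  if (any(n_tok > 2))
    stop("adjacency file: more than two tokens on line: ",
         lines[which(n_tok > 2)[1]])
  nodes <- unlist(toks[n_tok == 1])
  ed <- toks[n_tok == 2]
  edges <- if (length(ed)) do.call(rbind, ed) else matrix(character(0), ncol = 2)
  adjacency_graph(c(nodes, c(edges)), edges)
}

#' Write an adjacency graph back to an edge-list file
#' @param graph `msprev_graph`.
#' @param path output file.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "msprev_graph"))
  iso <- setdiff(graph$nodes, c(graph$edges))
  lines <- c(iso, if (nrow(graph$edges))
    paste(graph$edges[, 1], graph$edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor lists and degrees
#' @param graph `msprev_graph`.
#' @return `graph_neighbors`: named list of character vectors;
#'   `graph_degrees`: named integer vector.
#' @export
graph_neighbors <- function(graph) {
  stopifnot(inherits(graph, "msprev_graph"))
  nb <- stats::setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (nm in graph$nodes) nb[[nm]] <- character(0)
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges[k, 1]; b <- graph$edges[k, 2]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  nb
}

#' @rdname graph_neighbors
#' @export
graph_degrees <- function(graph) {
  lengths(graph_neighbors(graph))
}

#' Connected components of the adjacency graph
#' @param graph `msprev_graph`.
#' @return integer vector of component membership named by node.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "msprev_graph"))
  g <- igraph::graph_from_data_frame(
    if (nrow(graph$edges)) as.data.frame(graph$edges) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  memb <- igraph::components(g)$membership
  memb[graph$nodes]
}

#' Binary contiguity weight matrix
#' @param graph `msprev_graph`.
#' @param row_standardize divide each row by its sum (rows of isolated nodes
#'   stay zero).
#' @return numeric matrix with dimnames = node ids.
#' @export
adjacency_matrix <- function(graph, row_standardize = FALSE) {
  n <- length(graph$nodes)
  w <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      w[graph$edges[k, 1], graph$edges[k, 2]] <- 1
      w[graph$edges[k, 2], graph$edges[k, 1]] <- 1
    }
  }
  if (row_standardize) {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }
  w
}

#' Bundled adjacency of the 21 studied French departments
#'
#' Hand-encoded land-border contiguity among the 21 departments of the five
#' studied regions (Lorraine, Bretagne, Auvergne, Rhone, Midi-Pyrenees).
#' Departments in different study regions are connected only where they truly
#' share a border (Cantal touches Aveyron and Lot); Rhone borders no studied
#' department and is an isolated node.
#'
#' @return `msprev_graph` with 21 nodes.
#' @export
bundled_adjacency <- function() {
  read_adjacency(system.file("extdata", "adjacency_fr21.txt",
                             package = "msprev", mustWork = TRUE))
}

#' Overlap-share set
#'
#' Proportions describing how much the three ascertainment sources identify
#' the same people: pairwise inclusive intersections and the triple
#' intersection, each expressed as a fraction of the unique (union) case
#' total. Source a = health insurance, b = neurologist network,
#' c = hospitalization.
#'
#' @param s_ab,s_bc,s_ac,s_abc proportions in [0,1].
#' @param label name of the set.
#' @return object of class `msprev_shares`.
#' @export
overlap_shares <- function(s_ab, s_bc, s_ac, s_abc, label = "shares") {
  v <- c(s_ab = s_ab, s_bc = s_bc, s_ac = s_ac, s_abc = s_abc)
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("overlap shares must be finite proportions in [0,1]")
  if (s_abc > min(s_ab, s_bc, s_ac) + 1e-12)
    stop("triple share s_abc exceeds a pairwise share")
  if (1 + s_ab + s_bc + s_ac - s_abc <= 0)
    stop("invalid share set: non-positive dedup divisor")
  structure(list(s_ab = s_ab, s_bc = s_bc, s_ac = s_ac, s_abc = s_abc,
                 label = label), class = "msprev_shares")
}

#' Read a reference population weight table
#'
#' @param path CSV with columns `sex`, `age_class`, `weight`.
#' @param config stratum configuration; the file must provide one row per
#'   stratum of the configuration.
#' @param name reference name recorded on the object.
#' @return data.frame of class `msprev_reference` with normalized weights
#'   summing to 1; the original total is kept in attribute `raw_total`.
#' @export
read_reference_population <- function(path, config = stratum_config(),
                                      name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_reference_population(df, config, name)
}

#' @rdname read_reference_population
#' @param df data.frame with columns `sex`, `age_class`, `weight`.
#' @export
as_reference_population <- function(df, config = stratum_config(),
                                    name = "reference") {
  where <- sprintf("reference population '%s'", name)
  need_cols(df, c("sex", "age_class", "weight"), where)
  check_strata(df, config, where)
  full <- strata_table(config)
  have <- stratum_key(df)
  miss <- setdiff(stratum_key(full), have)
  if (length(miss))
    stop(sprintf("%s: missing strata: %s", where, paste(miss, collapse = "; ")))
  if (anyDuplicated(have))
    stop(sprintf("%s: duplicated strata", where))
  if (anyNA(df$weight) || any(df$weight < 0))
    stop(sprintf("%s: weights must be non-negative", where))
  tot <- sum(df$weight)
  if (tot <= 0) stop(sprintf("%s: weights sum to zero", where))
  # order rows as the configured stratum table
  df <- df[match(stratum_key(full), have), , drop = FALSE]
  rownames(df) <- NULL
  df$weight <- df$weight / tot
  class(df) <- c("msprev_reference", "data.frame")
  attr(df, "raw_total") <- tot
  attr(df, "name") <- name
  attr(df, "strata") <- config
  df
}

#' Write the results bundle as CSV files
#'
#' Writes one CSV per table in a results bundle. Numeric columns are written
#' at full precision; prevalence and relative-risk tables additionally get a
#' `*_display` column rounded to one decimal, the convention of published
#' prevalence tables.
#'
#' @param results named list of data.frames (e.g. as produced by
#'   [run_pipeline()]).
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(results, dir) {
  stopifnot(is.list(results))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) next
    df <- add_display_columns(df)
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_full_precision(df), f, row.names = FALSE,
                     quote = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

display_cols <- c("prevalence", "ci_low", "ci_high", "mean", "median", "rr",
                  "spr", "crude")

add_display_columns <- function(df) {
  for (cl in intersect(display_cols, names(df)))
    if (is.numeric(df[[cl]]))
      df[[paste0(cl, "_display")]] <- sprintf("%.1f", round(df[[cl]], 1))
  df
}

format_full_precision <- function(df) {
  for (cl in names(df))
    if (is.double(df[[cl]]))
      df[[cl]] <- sprintf("%.17g", df[[cl]])
  df
}

#' Round half to even, returning integer counts
#' @param x numeric vector.
#' @return numeric vector of integers (base `round`, IEC 60559 banker's
#'   rounding).
#' @keywords internal
round_half_even <- function(x) round(x, 0)
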