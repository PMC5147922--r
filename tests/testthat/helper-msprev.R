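# shared test helpers: tiny constructors and independent oracles

make_unique_cases <- function(df, config = stratum_config()) {
  class(df) <- c("msprev_unique_cases", "data.frame")
  attr(df, "strata") <- config
  df
}

one_stratum_config <- function() {
  stratum_config(age_classes = "all", sexes = "all")
}

# one-stratum unique-cases + population pair over given departments
flat_fixture <- function(deps, cases, pops) {
  cfg <- one_stratum_config()
  uc <- make_unique_cases(
    data.frame(department_id = deps, sex = "all", age_class = "all",
               unique_cases_real = cases, unique_cases_int = round(cases),
               stringsAsFactors = FALSE), cfg)
  pop <- as_population(
    data.frame(department_id = deps, sex = "all", age_class = "all",
               population = pops, stringsAsFactors = FALSE), cfg)
  list(uc = uc, pop = pop, cfg = cfg)
}

ring_graph <- function(n, prefix = "d") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  adjacency_graph(ids, cbind(ids, ids[c(2:n, 1)]))
}

# brute-force Moran double sum, independent of the package implementation
moran_brute <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(w)) * num / sum((x - xb)^2)
}

# Spearman rho as Pearson correlation of average ranks, written out by hand
spearman_oracle <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

random_source_table <- function(n_dep = 3, config = stratum_config()) {
  st <- strata_table(config)
  deps <- sprintf("dep%02d", seq_len(n_dep))
  grid <- merge(data.frame(department_id = deps), st)
  grid$count_insurance <- rpois(nrow(grid), 30)
  grid$count_network <- rpois(nrow(grid), 20)
  grid$count_hospital <- rpois(nrow(grid), 25)
  as_source_counts(grid, config)
}

# printed relative-risk columns (main analysis and the high-share
# sensitivity run) for the 21 departments, used to exercise the ranking
# comparison on real published numbers
published_rr_main <- function() {
  data.frame(
    department_id = c("57", "54", "55", "88", "22", "09", "31", "69", "35",
                      "81", "29", "56", "46", "03", "32", "12", "82", "15",
                      "43", "63", "65"),
    mean = c(2.1, 1.7, 1.4, 1.3, 1.2, 1.1, 1.1, 1.1, 1.0, 1.0, 1.0, 1.0,
             0.9, 0.9, 0.9, 0.8, 0.8, 0.8, 0.7, 0.7, 0.5),
    stringsAsFactors = FALSE)
}

published_rr_high_shares <- function() {
  data.frame(
    department_id = c("57", "54", "88", "55", "69", "31", "22", "09", "35",
                      "81", "46", "29", "56", "32", "82", "03", "12", "15",
                      "63", "43", "65"),
    mean = c(2.2, 1.7, 1.3, 1.3, 1.2, 1.1, 1.1, 1.1, 1.0, 1.0, 0.9, 0.9,
             0.9, 0.9, 0.9, 0.8, 0.8, 0.8, 0.7, 0.7, 0.6),
    stringsAsFactors = FALSE)
}
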