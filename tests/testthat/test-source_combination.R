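test_that("unique-case estimator matches closed-form and Venn oracles", {
  # disjoint sources: the estimate is the plain sum
  expect_equal(estimate_unique_cases(100, 50, 25, overlap_shares(0, 0, 0, 0)),
               175)
  # three identical lists: divisor 1 + 3 - 1 = 3 collapses to one list
  expect_equal(estimate_unique_cases(80, 80, 80, overlap_shares(1, 1, 1, 1)),
               80)
  # Venn oracle: cells (40,30,20,10,5,5,10) -> marginals (65,55,40),
  # union 120, divisor 4/3
  sh <- overlap_shares(20 / 120, 15 / 120, 15 / 120, 10 / 120)
  expect_equal(estimate_unique_cases(65, 55, 40, sh), 120, tolerance = 1e-12)

  expect_error(overlap_shares(0.9, 0.9, 0.9, 2), "\\[0,1\\]")
  expect_error(overlap_shares(0.1, 0.1, 0.1, 0.3), "exceeds")
})

test_that("estimator inverts simulated capture exactly (central identity)", {
  cfg <- one_stratum_config()
  set.seed(21)
  for (k in 1:50) {
    tc <- data.frame(department_id = "X", sex = "all", age_class = "all",
                     n_true = sample(200:5000, 1))
    prof <- capture_profile(runif(1, .2, .95), runif(1, .2, .95),
                            runif(1, .2, .95), runif(1, -1, 1),
                            runif(1, -1, 1), runif(1, -1, 1))
    cap <- simulate_capture(tc, prof, seed = 5000 + k, cfg)
    union <- sum(cap$venn[msprev:::venn_cell_names])
    if (union == 0) next
    est <- estimate_unique_cases(cap$sources$count_insurance,
                                 cap$sources$count_network,
                                 cap$sources$count_hospital,
                                 shares_from_venn(cap$venn))
    expect_equal(est, union, tolerance = 1e-9)
  }
})

test_that("estimator is monotone in marginals and antitone in shares", {
  sh <- overlap_shares(0.3, 0.2, 0.25, 0.1)
  base <- estimate_unique_cases(50, 40, 30, sh)
  expect_gt(estimate_unique_cases(51, 40, 30, sh), base)
  expect_gt(estimate_unique_cases(50, 45, 30, sh), base)
  sh_up <- overlap_shares(0.35, 0.2, 0.25, 0.1)
  expect_lt(estimate_unique_cases(50, 40, 30, sh_up), base)
})

test_that("combine_table applies assignments, warns on inconsistency, sums", {
  cfg <- stratum_config(age_classes = c("young", "old"))
  df <- expand.grid(department_id = c("31", "57"), sex = c("female", "male"),
                    age_class = c("young", "old"),
                    stringsAsFactors = FALSE)
  set.seed(4)
  df$count_insurance <- rpois(8, 40)
  df$count_network <- rpois(8, 30)
  df$count_hospital <- rpois(8, 35)
  src <- as_source_counts(df, cfg)

  # the study default: Haute-Garonne has its own set
  asg <- study_share_assignment(unique(src$department_id))
  expect_equal(asg$label[asg$department_id == "31"], "haute_garonne_2005")
  expect_equal(asg$label[asg$department_id == "57"], "lorraine_2008")
  uc <- combine_table(src, asg)
  d31 <- 1 + 0.25 + 0.28 + 0.42 - 0.17
  i31 <- src$department_id == "31"
  expect_equal(uc$unique_cases_real[i31],
               (src$count_insurance[i31] + src$count_network[i31] +
                  src$count_hospital[i31]) / d31, tolerance = 1e-12)

  # all-zero shares: unique equals the row sum of the three sources
  cat0 <- as_share_catalogue(data.frame(label = "none", s_ab = 0, s_bc = 0,
                                        s_ac = 0, s_abc = 0))
  uc0 <- combine_table(src, share_assignment(c("31", "57"), "none"), cat0)
  expect_equal(uc0$unique_cases_real,
               src$count_insurance + src$count_network + src$count_hospital)

  # additivity: stratum-level estimates sum to the department totals
  dep_tot <- aggregate_counts(
    as.data.frame(uc)[c("department_id", "unique_cases_real")], "department")
  for (d in c("31", "57"))
    expect_equal(dep_tot$unique_cases_real[dep_tot$department_id == d],
                 sum(uc$unique_cases_real[uc$department_id == d]),
                 tolerance = 1e-9)

  # N below the largest marginal is flagged, not fatal
  cat_bad <- as_share_catalogue(data.frame(label = "hot", s_ab = 0.9,
                                           s_bc = 0.0, s_ac = 0.9,
                                           s_abc = 0.0))
  lop <- as_source_counts(data.frame(department_id = "31", sex = "female",
                                     age_class = "young",
                                     count_insurance = 100L,
                                     count_network = 0L,
                                     count_hospital = 0L), cfg)
  expect_warning(combine_table(lop, share_assignment("31", "hot"), cat_bad),
                 "below the largest")

  expect_error(combine_table(src, share_assignment("31", "lorraine_2008")),
               "without an assigned")
})

test_that("stratum-specific catalogue rows override the aggregate set", {
  cfg <- stratum_config(age_classes = c("young", "old"), sexes = "all")
  cat <- as_share_catalogue(data.frame(
    label = "mix", sex = c(NA, "all"), age_class = c(NA, "old"),
    s_ab = c(0, 1), s_bc = c(0, 1), s_ac = c(0, 1), s_abc = c(0, 1)))
  src <- as_source_counts(data.frame(
    department_id = "X", sex = "all", age_class = c("young", "old"),
    count_insurance = c(10L, 10L), count_network = c(10L, 10L),
    count_hospital = c(10L, 10L)), cfg)
  uc <- combine_table(src, share_assignment("X", "mix"), cat)
  expect_equal(uc$unique_cases_real[uc$age_class == "young"], 30)  # aggregate
  expect_equal(uc$unique_cases_real[uc$age_class == "old"], 10)    # specific
})

test_that("regional aggregation reproduces printed study totals", {
  t1 <- read.csv(system.file("extdata", "table1_department_counts.csv",
                             package = "msprev"),
                 colClasses = c(department_id = "character"))
  reg <- aggregate_counts(t1, "region",
                          region_map = t1[c("department_id", "region")])
  get <- function(r, col) reg[[col]][reg$region == r]
  expect_identical(get("NE", "count_insurance"), 2833L)
  expect_identical(get("C", "count_network"), 583L)
  expect_identical(get("NE", "unique_observed"), 5961L)
  expect_identical(get("SW", "count_hospital"), 2806L)

  # single-department region equals its own row
  expect_identical(get("SE", "count_insurance"),
                   t1$count_insurance[t1$department_id == "69"])

  expect_error(aggregate_counts(t1, "region",
                                region_map = t1[1:5, c("department_id",
                                                       "region")]),
               "missing from region map")
})
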