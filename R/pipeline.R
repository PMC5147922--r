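#' Assemble a run configuration
#'
#' Inputs may be given as file paths (read with the core readers) or as
#' already-constructed package objects; paths are validated up front so a
#' broken configuration fails before any computation starts.
#'
#' @param source_counts path or `msprev_source_counts`.
#' @param population path or `msprev_population`.
#' @param adjacency path or `msprev_graph`.
#' @param share_catalogue path, `msprev_share_catalogue`, or `NULL` for the
#'   bundled study catalogue.
#' @param share_assignment path, `msprev_share_assignment`, or `"study"`
#'   for the default study assignment (Haute-Garonne set for department 31,
#'   Lorraine aggregate elsewhere), or a single catalogue label applied to
#'   every department.
#' @param config stratum configuration.
#' @param moran_weights `"binary"` or `"row"`.
#' @param moran_n_perm permutations for the Moran test.
#' @param mcmc `msprev_mcmc_settings`.
#' @param references character vector of bundled reference names (the first
#'   is used for relative risks) or a named list of `msprev_reference`
#'   objects.
#' @param output_dir directory for result CSVs, or `NULL` to skip writing.
#' @param seed master seed for the Moran permutations (the MCMC seed lives
#'   in `mcmc`).
#' @return list of class `msprev_config`.
#' @export
run_config <- function(source_counts, population, adjacency,
                       share_catalogue = NULL, share_assignment = "study",
                       config = stratum_config(),
                       moran_weights = "binary", moran_n_perm = 999,
                       mcmc = mcmc_settings(), references = "french_2004",
                       output_dir = NULL, seed = 1) {
  for (p in list(source_counts, population, adjacency, share_catalogue,
                 share_assignment))
    if (is.character(p) && length(p) == 1 && grepl("[./\\\\]", p) &&
        !file.exists(p))
      stop("configured input file does not exist: ", p)
  structure(list(source_counts = source_counts, population = population,
                 adjacency = adjacency, share_catalogue = share_catalogue,
                 share_assignment = share_assignment, config = config,
                 moran_weights = moran_weights,
                 moran_n_perm = moran_n_perm, mcmc = mcmc,
                 references = references, output_dir = output_dir,
                 seed = seed),
            class = "msprev_config")
}

#' Read a flat-text run configuration
#'
#' `key: value` lines (one per key; `#` comments ignored). Recognized keys:
#' `source_counts`, `population`, `adjacency`, `share_catalogue`,
#' `share_assignment`, `age_classes` (comma-separated), `sexes`,
#' `moran_weights`, `moran_n_perm`, `n_chains`, `n_iter`, `n_burn`, `thin`,
#' `references` (comma-separated), `output_dir`, `seed`. Relative paths are
#' resolved against the configuration file's directory.
#'
#' @param path configuration file.
#' @return `msprev_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed configuration line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get <- function(k, default = NULL) if (k %in% keys) vals[keys == k][1] else default
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  cfg <- stratum_config(
    age_classes = if (!is.null(get("age_classes")))
      trimws(strsplit(get("age_classes"), ",")[[1]]) else
        default_age_classes(),
    sexes = if (!is.null(get("sexes")))
      trimws(strsplit(get("sexes"), ",")[[1]]) else c("female", "male"))
  run_config(
    source_counts = resolve(get("source_counts")),
    population = resolve(get("population")),
    adjacency = resolve(get("adjacency")),
    share_catalogue = resolve(get("share_catalogue")),
    share_assignment = {
      sa <- get("share_assignment", "study")
      if (sa != "study" && grepl("[./\\\\]", sa)) resolve(sa) else sa
    },
    config = cfg,
    moran_weights = get("moran_weights", "binary"),
    moran_n_perm = as.integer(get("moran_n_perm", "999")),
    mcmc = mcmc_settings(
      n_chains = as.integer(get("n_chains", "2")),
      n_iter = as.integer(get("n_iter", "20000")),
      n_burn = as.integer(get("n_burn", "10000")),
      thin = as.integer(get("thin", "5")),
      seed = as.integer(get("seed", "1"))),
    references = if (!is.null(get("references")))
      trimws(strsplit(get("references"), ",")[[1]]) else "french_2004",
    output_dir = get("output_dir"),
    seed = as.integer(get("seed", "1")))
}

load_config_inputs <- function(cfg) {
  ld <- function(x, reader, cls) {
    if (inherits(x, cls)) x else reader(x)
  }
  sources <- if (inherits(cfg$source_counts, "msprev_source_counts"))
    cfg$source_counts else read_source_counts(cfg$source_counts, cfg$config)
  pop <- if (inherits(cfg$population, "msprev_population"))
    cfg$population else read_population(cfg$population, cfg$config)
  graph <- ld(cfg$adjacency, read_adjacency, "msprev_graph")
  catalogue <- if (is.null(cfg$share_catalogue)) study_share_catalogue()
    else ld(cfg$share_catalogue, read_share_catalogue,
            "msprev_share_catalogue")
  deps <- unique(sources$department_id)
  assignment <- if (inherits(cfg$share_assignment, "msprev_share_assignment"))
    cfg$share_assignment
  else if (identical(cfg$share_assignment, "study"))
    study_share_assignment(deps)
  else if (is.character(cfg$share_assignment) &&
           cfg$share_assignment %in% catalogue$label)
    share_assignment(deps, cfg$share_assignment)
  else {
    df <- utils::read.csv(cfg$share_assignment, stringsAsFactors = FALSE,
                          colClasses = c(department_id = "character"))
    share_assignment(df$department_id, df$label)
  }
  list(sources = sources, pop = pop, graph = graph, catalogue = catalogue,
       assignment = assignment)
}

resolve_references <- function(refs, config) {
  if (is.list(refs) && all(vapply(refs, inherits, logical(1),
                                  "msprev_reference")))
    return(refs)
  out <- lapply(refs, function(nm)
    if (identical(nm, "uniform")) uniform_reference(config)
    else bundled_reference(nm, config))
  names(out) <- unlist(refs)
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read and validate inputs; combine the three sources
#' into unique case counts; internal indirect standardization, SPR and the
#' Moran test on the SPR values; fit the spatial negative-binomial model;
#' directly standardize to each configured reference; relative risks
#' against the department average; crude prevalence. Convergence problems
#' warn (and are flagged in the manifest) but do not abort.
#'
#' @param cfg `msprev_config`.
#' @return (invisibly when writing) a results bundle: named list with
#'   `unique_cases`, `spr_table`, `moran`, `fit`, `diagnostics`, `theta`,
#'   `standardized` (one table per reference), `rr`, `crude`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "msprev_config"))
  inp <- load_config_inputs(cfg)
  warns <- character(0)

  uc <- withCallingHandlers(
    combine_table(inp$sources, inp$assignment, inp$catalogue),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  exp_counts <- internal_expected_counts(uc, inp$pop)
  spr_tab <- spr(exp_counts)
  ok <- !spr_tab$undefined
  moran <- moran_test(stats::setNames(spr_tab$spr[ok],
                                      spr_tab$department_id[ok]),
                      subgraph(inp$graph, spr_tab$department_id[ok]),
                      weights = cfg$moran_weights, method = "both",
                      n_perm = cfg$moran_n_perm, seed = cfg$seed)

  spec <- withCallingHandlers(
    build_model(uc, inp$pop, inp$graph),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  fit <- run_mcmc(spec, cfg$mcmc)
  diag <- convergence_diagnostics(fit)
  if (any(diag$rhat > 1.1)) {
    msg <- sprintf("%d parameter(s) with split-Rhat > 1.1 (max %.3f)",
                   sum(diag$rhat > 1.1), max(diag$rhat))
    warning(msg)
    warns <- c(warns, msg)
  }

  refs <- resolve_references(cfg$references, cfg$config)
  std <- lapply(refs, function(rf) summarize_fit(fit, "standardized", rf))
  rr <- relative_risks(fit, refs[[1]])
  theta <- summarize_fit(fit, "theta")
  crude <- crude_prevalence(uc, inp$pop)

  manifest <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("mcmc_seed: %d", cfg$mcmc$seed),
    sprintf("mcmc: %d chains x %d iter, burn %d, thin %d",
            cfg$mcmc$n_chains, cfg$mcmc$n_iter, cfg$mcmc$n_burn,
            cfg$mcmc$thin),
    sprintf("references: %s", paste(names(refs), collapse = ", ")),
    sprintf("moran_weights: %s", cfg$moran_weights),
    sprintf("max_rhat: %.4f", max(diag$rhat)),
    sprintf("warnings: %d", length(warns)),
    paste0("warning: ", warns))

  results <- list(unique_cases = uc, spr_table = spr_tab,
                  moran = moran, fit = fit, diagnostics = diag,
                  theta = theta, standardized = std, rr = rr,
                  crude = crude, manifest = manifest)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- list(unique_cases = as.data.frame(uc),
                 spr = spr_tab,
                 moran = data.frame(i = moran$i_value, e_null = moran$e_null,
                                    var_null = moran$var_null, z = moran$z,
                                    p_normal = moran$p_normal,
                                    p_perm = moran$p_perm,
                                    n_perm = moran$n_perm,
                                    weights = moran$weights),
                 theta = theta, rr = rr,
                 crude = crude$by_department,
                 diagnostics = diag)
    for (nm in names(std)) tabs[[paste0("standardized_", nm)]] <- std[[nm]]
    write_results(tabs, cfg$output_dir)
    writeLines(manifest, file.path(cfg$output_dir, "manifest.txt"))
    return(invisible(results))
  }
  results
}

subgraph <- function(graph, nodes) {
  keep <- graph$edges[, 1] %in% nodes & graph$edges[, 2] %in% nodes
  adjacency_graph(nodes, graph$edges[keep, , drop = FALSE])
}

#' Share-set sensitivity analysis
#'
#' Re-runs combine-fit-relative-risk with each named share set applied to
#' every department (the same MCMC seed throughout), and compares each
#' alternative's relative-risk ranking with the main run's.
#'
#' @param cfg `msprev_config` describing the main run.
#' @param share_sets character vector of catalogue labels to use as
#'   alternatives (e.g. `c("haute_garonne_2005")`).
#' @return list of class `msprev_sensitivity`: `main` (the main results),
#'   `runs` (RR tables per share set), `rank_correlations` (data.frame),
#'   `rank_table` (per-department ranks across runs).
#' @export
sensitivity_run <- function(cfg, share_sets) {
  main <- run_pipeline(cfg)
  inp <- load_config_inputs(cfg)
  runs <- list(main = main$rr)
  for (lab in share_sets) {
    alt_cfg <- cfg
    alt_cfg$share_assignment <- share_assignment(
      unique(inp$sources$department_id), lab)
    alt_cfg$output_dir <- NULL
    alt <- run_pipeline(alt_cfg)
    runs[[lab]] <- alt$rr
  }
  labs <- setdiff(names(runs), "main")
  rc <- do.call(rbind, lapply(labs, function(lab) {
    cmp <- compare_rankings(runs$main, runs[[lab]])
    data.frame(share_set = lab, spearman_rho = cmp$rho,
               stringsAsFactors = FALSE)
  }))
  rank_tab <- data.frame(department_id = runs$main$department_id,
                         stringsAsFactors = FALSE)
  for (nm in names(runs)) {
    m <- runs[[nm]]
    rank_tab[[paste0("rank_", nm)]] <-
      rank(-m$mean[match(rank_tab$department_id, m$department_id)],
           ties.method = "average")
  }
  structure(list(main = main, runs = runs, rank_correlations = rc,
                 rank_table = rank_tab), class = "msprev_sensitivity")
}

#' Compare two relative-risk rankings
#'
#' Spearman rank correlation (average ranks for ties) between the `mean`
#' columns of two department tables over an identical department set, plus
#' the aligned per-department rank pairs.
#'
#' @param rr_a,rr_b data.frames with `department_id` and `mean` columns.
#' @return list with `rho` and `table` (department, rank_a, rank_b).
#' @export
compare_rankings <- function(rr_a, rr_b) {
  if (!setequal(rr_a$department_id, rr_b$department_id))
    stop("the two tables cover different department sets")
  b <- rr_b$mean[match(rr_a$department_id, rr_b$department_id)]
  ra <- rank(-rr_a$mean, ties.method = "average")
  rb <- rank(-b, ties.method = "average")
  list(rho = stats::cor(ra, rb, method = "spearman"),
       table = data.frame(department_id = rr_a$department_id,
                          rank_a = ra, rank_b = rb,
                          stringsAsFactors = FALSE))
}
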