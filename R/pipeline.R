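#' Assemble a full run configuration
#'
#' Bundles the task and cohort configurations with the analysis mode, output
#' directory, and master seed. The master seed deterministically spawns
#' per-stage seeds (cohort sampling, parameter linkage, session order, trial
#' simulation) so stages are independently re-runnable.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()].
#' @param mode `"age_as_variable"` (age is a predictor column alongside the
#'   regions) or `"age_residualized"` (age dropped and regressed out of every
#'   variable).
#' @param out_dir Output directory for delimited-text artifacts, or `NULL`
#'   to skip writing.
#' @param seed Master integer seed.
#' @param verbose Emit stage messages.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = task_config(), cohort = cohort_config(),
                       mode = c("age_as_variable", "age_residualized"),
                       out_dir = NULL, seed = 1L, verbose = FALSE) {
  cfg <- list(task = task, cohort = cohort, mode = match.arg(mode),
              out_dir = out_dir, seed = as.integer(seed), verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file may override any field of [task_config()] (under `task:`),
#' [cohort_config()] (under `cohort:`, with `regions:` as a list of
#' `{region, mean, sd, age_slope}` records and `linkage:` as a list of
#' `{param, variable, weight}` records), plus top-level `mode`, `out_dir`,
#' `seed`, and `verbose`. A complete annotated example ships in
#' `system.file("extdata", "example-config.yaml", package = "dopacca")`.
#'
#' @param path Path to a YAML configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  task <- do.call(task_config, raw$task %||% list())
  craw <- raw$cohort %||% list()
  if (!is.null(craw$regions)) {
    craw$regions <- do.call(rbind, lapply(craw$regions, function(r)
      data.frame(region = r$region, mean = r$mean, sd = r$sd,
                 age_slope = r$age_slope, stringsAsFactors = FALSE)))
  }
  links <- craw$linkage
  craw$linkage <- NULL
  for (nm in c("param_base", "param_noise_sd"))
    if (!is.null(craw[[nm]])) craw[[nm]] <- unlist(craw[[nm]])
  cohort <- do.call(cohort_config, craw)
  if (!is.null(links)) {
    W <- matrix(0, length(agent_param_names), nrow(cohort$regions) + 1L,
                dimnames = list(agent_param_names,
                                c("age", cohort$regions$region)))
    for (l in links) W[l$param, l$variable] <- l$weight
    cohort$linkage <- W
    validate_cohort_config(cohort)
  }
  run_config(task = task, cohort = cohort,
             mode = raw$mode %||% "age_as_variable",
             out_dir = raw$out_dir, seed = raw$seed %||% 1L,
             verbose = isTRUE(raw$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + k * 1000003) %% 2147483629 + 1)
}

write_table_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a delimited-text artifact written by the pipeline
#'
#' @param path Path to a file written by [run_pipeline()] (comma-separated
#'   with `#`-prefixed metadata header lines).
#' @return A data frame.
#' @export
read_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the complete simulation and analysis pipeline
#'
#' Executes the stages in order: sample the cohort and link agent parameters,
#' build the shared session, simulate every participant's trials, score the
#' five behavioral metrics, fit the canonical correlation analysis between
#' the predictor set (age plus regional binding potentials, or their
#' age-residualized versions) and the criterion set (the five metrics), and
#' run the univariate follow-up regressions. Participants with any flagged
#' (missing) metric are excluded from the CCA with a warning. With a fixed
#' configuration and seed, outputs are byte-identical across runs.
#'
#' @param cfg A [run_config()] (or a path to a YAML file accepted by
#'   [read_run_config()]).
#'
#' @return A list with `cohort`, `session`, `trials`, `features`, `cca`
#'   (a [dopacca()] fit), `dimension_tests`, `coefficients` (long-format
#'   Coef/r_s/r_s^2 table), `followup`, `excluded_ids`, and `manifest`.
#'   If `cfg$out_dir` is set, each table is also written there as
#'   comma-separated text with `#`-prefixed metadata headers.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 7))
#' res$cca
#' }
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage cohort")
  cohort <- stage("cohort", {
    ch <- sample_cohort(cfg$cohort, seed = derive_seed(cfg$seed, 1L))
    link_agent_params(ch, cfg$cohort, seed = derive_seed(cfg$seed, 2L))
  })
  say("stage session")
  session <- stage("session",
                   build_session(cfg$task, seed = derive_seed(cfg$seed, 3L)))
  say("stage simulate")
  trials <- stage("simulate",
                  simulate_cohort_sessions(session, cohort, cfg$task,
                                           seed = derive_seed(cfg$seed, 4L)))
  say("stage score")
  features <- stage("score", profile_cohort(trials, cfg$task))

  say("stage cca")
  regions <- cfg$cohort$regions$region
  metric_cols <- c("choice_inflexibility", "first_stock_choice",
                   "suboptimal_investment", "absolute_error", "optimism")
  keep <- stats::complete.cases(features[, metric_cols])
  excluded <- features$id[!keep]
  if (length(excluded))
    warning("excluding ", length(excluded),
            " participant(s) with flagged metrics from the CCA",
            call. = FALSE)
  feat <- features[keep, ]
  coh <- cohort[match(feat$id, cohort$id), ]
  Y <- as.matrix(feat[, metric_cols])
  fit <- stage("cca", {
    if (cfg$mode == "age_as_variable") {
      X <- as.matrix(coh[, c("age", regions)])
      dopacca(X, Y)
    } else {
      rr <- residualize_age(as.matrix(coh[, c("age", regions)]), Y)
      dopacca(rr$x, rr$y)
    }
  })
  coefficients <- coefficient_table(fit)

  say("stage followup")
  followup <- stage("followup", followup_suite(features, cohort))

  manifest <- list(seed = cfg$seed, mode = cfg$mode,
                   n_participants = cfg$cohort$n_participants,
                   n_blocks = cfg$task$n_blocks,
                   trials_per_block = cfg$task$trials_per_block,
                   package_version = as.character(utils::packageVersion("dopacca")),
                   excluded_ids = excluded)

  res <- list(cohort = cohort, session = session, trials = trials,
              features = features, cca = fit,
              dimension_tests = fit$dimension_tests,
              coefficients = coefficients, followup = followup,
              excluded_ids = excluded, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- c(seed = cfg$seed, mode = cfg$mode,
              package = paste0("dopacca ", manifest$package_version))
    wr <- function(df, name)
      write_table_with_meta(df, file.path(cfg$out_dir, name), meta)
    wr(trials, "trials.csv")
    wr(cohort, "participants.csv")
    wr(features, "features.csv")
    wr(fit$dimension_tests, "dimension_tests.csv")
    wr(coefficients, "coefficients.csv")
    wr(followup, "followup.csv")
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  res
}

# long-format standardized/structure coefficient table, all functions
coefficient_table <- function(fit) {
  do.call(rbind, lapply(seq_along(fit$cancor), function(j) {
    rbind(
      data.frame(set = "predictor", f = j, variable = fit$x_names,
                 Coef = unname(fit$xcoef[, j]),
                 r_s = unname(fit$xstructure[, j]),
                 stringsAsFactors = FALSE),
      data.frame(set = "criterion", f = j, variable = fit$y_names,
                 Coef = unname(fit$ycoef[, j]),
                 r_s = unname(fit$ystructure[, j]),
                 stringsAsFactors = FALSE)
    )
  })) -> tab
  tab$r_s_sq <- tab$r_s^2
  tab
}

#' Render the dimension-reduction table for given squared correlations
#'
#' Formats the sequential Wilks/Rao-F dimension-reduction table in the
#' conventional layout (Roots, Wilks, F, Df1, Df2, p-value). The default
#' inputs are the five squared canonical correlations and sample size of the
#' reference analysis of the risky-investment study (N = 35, p = q = 5),
#' which yields Df1 = 25, 16, 9, 4, 1 and Df2 = 94.37, 80.07, 65.86, 56.00,
#' 29.00.
#'
#' @param r_squared Squared canonical correlations (descending).
#' @param n Sample size.
#' @param p,q Set sizes.
#' @return Data frame with columns `Roots`, `Wilks`, `F`, `Df1`, `Df2`,
#'   `p.value` (values rounded for display as in the conventional layout).
#' @examples
#' replicate_table1()
#' @export
replicate_table1 <- function(r_squared = c(0.581, 0.351, 0.072, 0.028, 0.005),
                             n = 35, p = 5, q = 5) {
  dt <- wilks_dimension_tests(r_squared, n, p, q)
  data.frame(Roots = dt$roots,
             Wilks = round(dt$wilks, 3),
             F = round(dt$F, 2),
             Df1 = dt$df1,
             Df2 = round(dt$df2, 2),
             p.value = round(dt$p_value, 3),
             stringsAsFactors = FALSE)
}
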