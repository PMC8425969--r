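# Trial-table CSV dialect, run configuration files and the command-line
# surface tying the pipeline together.

TRIAL_COLUMNS <- c("subject_id", "control", "tdcs", "block", "trial", "card",
                   "response", "base_points", "delivered_points", "correct")

#' Write a trial table to CSV
#'
#' One row per trial, in the standard dialect: `subject_id`, `control`
#' (high/low), `tdcs` (sham/stim), `block`, `trial`, `card`, `response`,
#' `base_points`, `delivered_points`, `correct` (0/1).
#'
#' @param trials trial table data.frame.
#' @param path output file.
#' @export
write_trial_table <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0L)
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- trials[, TRIAL_COLUMNS]
  out$correct <- as.integer(out$correct)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Parses the standard CSV dialect into typed records, validating categorical
#' fields against their enumerations and checking the Go-cost identity
#' (`delivered == base - 1` after a Go response, `delivered == base`
#' otherwise). Violations raise an error naming the offending row(s).
#'
#' @param path CSV file in the dialect written by [write_trial_table()].
#' @return data.frame of trial records (`correct` as logical).
#' @export
read_trial_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(x))
  if (length(miss) > 0L)
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0L) { x$correct <- logical(0); return(x) }
  fail <- function(what, rows)
    stop(what, " in row(s): ",
         paste(utils::head(rows, 10L), collapse = ", "),
         if (length(rows) > 10L) " ...", call. = FALSE)
  bad <- which(!x$card %in% CARD_LEVELS)
  if (length(bad)) fail("unknown card label", bad)
  bad <- which(!x$response %in% RESPONSE_LEVELS)
  if (length(bad)) fail("unknown response label", bad)
  bad <- which(!x$control %in% CONTROL_LEVELS)
  if (length(bad)) fail("unknown control label", bad)
  bad <- which(!x$tdcs %in% TDCS_LEVELS)
  if (length(bad)) fail("unknown tdcs label", bad)
  for (col in c("block", "trial", "base_points", "delivered_points")) {
    bad <- which(!is.finite(x[[col]]) | x[[col]] != round(x[[col]]))
    if (length(bad)) fail(paste("non-integer", col), bad)
  }
  bad <- which(!x$base_points %in% c(-10L, 0L, 10L))
  if (length(bad)) fail("base_points outside {-10, 0, +10}", bad)
  expected <- x$base_points - (x$response == "go")
  bad <- which(x$delivered_points != expected)
  if (length(bad)) fail("Go-cost identity violated", bad)
  x$correct <- as.logical(x$correct)
  x
}

#' Read a run configuration file
#'
#' Run configurations are YAML files with sections `cohort` (group sizes,
#' effects preset, subject SDs, schedule geometry), `task` (reward scale),
#' `mcmc` (chains, warmup, draws) and `seeds`. Seeds are never defaulted:
#' a stage whose seed is absent from both the command line and the `seeds`
#' section refuses to run.
#'
#' @param path YAML file.
#' @return a list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

# Build a cohort_config from a run_config's cohort/task sections.
config_to_cohort <- function(cfg, seed) {
  co <- cfg$cohort
  if (is.null(co)) co <- list()
  npg <- if (!is.null(co$n_per_group)) unlist(co$n_per_group) else
    c(high_sham = 26L, high_stim = 26L, low_sham = 24L, low_stim = 27L)
  coefs <- generating_coefficients(if (!is.null(co$effects)) co$effects
                                   else "demo")
  sd <- if (!is.null(co$subject_sd)) unlist(co$subject_sd) else
    c(alpha = 0.5, beta = 0.5, pi = 0.5, b_go = 0.5)
  cohort_config(
    n_per_group = npg, coefficients = coefs, subject_sd = sd,
    n_reps = if (!is.null(co$n_reps)) co$n_reps else 40L,
    contingency = if (!is.null(co$contingency)) co$contingency else 0.7,
    contingency_mode = if (!is.null(co$contingency_mode)) co$contingency_mode
      else "fixed",
    reward_scale = if (!is.null(cfg$task$reward_scale)) cfg$task$reward_scale
      else 0.1,
    seed = seed)
}

config_to_mcmc <- function(cfg, seed) {
  mc <- cfg$mcmc
  if (is.null(mc)) mc <- list()
  mcmc_config(
    n_chains = if (!is.null(mc$n_chains)) mc$n_chains else 2L,
    warmup = if (!is.null(mc$warmup)) mc$warmup else 300L,
    draws = if (!is.null(mc$draws)) mc$draws else 300L,
    rhat_threshold = if (!is.null(mc$rhat_threshold)) mc$rhat_threshold
      else 1.05,
    seed = seed)
}

# Resolve a stage seed: --seed flag wins, then the config's seeds section.
resolve_seed <- function(opts, cfg, stage) {
  if (!is.null(opts$seed)) return(as.integer(opts$seed))
  s <- cfg$seeds[[stage]]
  if (is.null(s))
    stop("missing seed: pass --seed or set seeds$", stage,
         " in the config file", call. = FALSE)
  as.integer(s)
}

#' Command-line interface
#'
#' Subcommands: `simulate --config <yaml> --seed <int> --out <csv>` (generate
#' a synthetic cohort; a `<out>_truth.csv` sidecar stores the ground-truth
#' parameters), `metrics --data <csv> --out <dir>` (per-subject behavioral
#' summary, accuracy table, and - when the four-group design is present -
#' the PPI ANOVA and estimation-plot effect sizes), `fit --data <csv>
#' --config <yaml> --seed <int> --out <dir>` (hierarchical fit; draws and
#' posterior summary as CSV), `summarize --draws <csv>` (print posterior
#' summaries of a draws table) and `recover --config <yaml> --seed <int>
#' --out <dir>` (generate, fit, and score coefficient recovery end to end).
#' Every run logs the package version, the config file hash and the seeds
#' used. Returns (invisibly) a process exit status: 0 on success, 1 on any
#' validation failure.
#'
#' @param args character vector of command-line arguments, e.g.
#'   `c("simulate", "--config", "cfg.yaml", "--seed", "1", "--out", "x.csv")`.
#' @return integer exit status, invisibly.
#' @export
gng_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: pavbias <simulate|metrics|fit|summarize|recover> ...",
           call. = FALSE)
    sub <- args[1]
    opts <- parse_cli_options(args[-1])
    switch(sub,
      simulate = cli_simulate(opts),
      metrics = cli_metrics(opts),
      fit = cli_fit(opts),
      summarize = cli_summarize(opts),
      recover = cli_recover(opts),
      stop("unknown subcommand: ", sub, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i], call. = FALSE)
    key <- substring(args[i], 3L)
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_log <- function(..., config_path = NULL, seeds = NULL) {
  message("pavbias ", as.character(packageVersion("pavbias")), ": ", ...)
  if (!is.null(config_path))
    message("  config: ", config_path, " (md5 ",
            unname(tools::md5sum(config_path)), ")")
  if (!is.null(seeds))
    message("  seed(s): ", paste(names(seeds), unlist(seeds), sep = "=",
                                 collapse = ", "))
}

require_opts <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0L)
    stop("missing required option(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
}

cli_simulate <- function(opts) {
  require_opts(opts, c("config", "out"))
  cfg <- read_run_config(opts$config)
  seed <- resolve_seed(opts, cfg, "simulate")
  cli_log("simulate", config_path = opts$config, seeds = list(simulate = seed))
  cohort <- generate_cohort(config_to_cohort(cfg, seed))
  write_trial_table(cohort$trials, opts$out)
  truth_path <- sub("\\.csv$", "", opts$out)
  write.csv(cohort$truth$params, paste0(truth_path, "_truth.csv"),
            row.names = FALSE)
  message("  wrote ", nrow(cohort$trials), " trials to ", opts$out)
}

cli_metrics <- function(opts) {
  require_opts(opts, c("data", "out"))
  trials <- read_trial_table(opts$data)
  cli_log("metrics on ", opts$data)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  bs <- behavioral_summary(trials)
  write.csv(bs, file.path(opts$out, "subject_summary.csv"), row.names = FALSE)
  write.csv(accuracy_percgo(trials),
            file.path(opts$out, "accuracy_percgo.csv"), row.names = FALSE)
  bs$group <- group_label(bs$control, bs$tdcs)
  groups <- unique(bs$group)
  enough <- length(groups) == 4L &&
    all(table(bs$group[bs$block == 1]) >= 2L) && !anyNA(bs$ppi)
  if (enough) {
    an <- mixed_anova(bs, dv = "ppi", subject = "subject_id",
                      between = "group", within = "block")
    write.csv(an, file.path(opts$out, "ppi_anova.csv"), row.names = FALSE)
    if (is.null(opts$seed))
      stop("missing seed: pass --seed for the bootstrap effect sizes",
           call. = FALSE)
    b1 <- bs[bs$block == 1, ]
    es <- estimation_vs_control(b1$ppi, b1$group, "high_sham",
                                n_boot = 5000L,
                                seed = as.integer(opts$seed))
    write.csv(es, file.path(opts$out, "ppi_effect_sizes.csv"),
              row.names = FALSE)
  } else {
    message("  fewer than four complete groups: wrote per-subject summaries only")
  }
}

cli_fit <- function(opts) {
  require_opts(opts, c("data", "config", "out"))
  cfg <- read_run_config(opts$config)
  seed <- resolve_seed(opts, cfg, "fit")
  cli_log("fit", config_path = opts$config, seeds = list(fit = seed))
  trials <- read_trial_table(opts$data)
  fit <- fit_hierarchical(trials, config_to_mcmc(cfg, seed),
                          reward_scale = if (!is.null(cfg$task$reward_scale))
                            cfg$task$reward_scale else 0.1)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(fit_draws(fit), file.path(opts$out, "draws.csv"),
            row.names = FALSE)
  write.csv(summary(fit), file.path(opts$out, "posterior_summary.csv"),
            row.names = FALSE)
  write.csv(fit$subject_params, file.path(opts$out, "subject_params.csv"),
            row.names = FALSE)
}

cli_summarize <- function(opts) {
  require_opts(opts, "draws")
  path <- opts$draws
  if (dir.exists(path)) path <- file.path(path, "draws.csv")
  df <- read.csv(path, stringsAsFactors = FALSE)
  print(summarize_draws_table(df))
}

cli_recover <- function(opts) {
  require_opts(opts, c("config", "out"))
  cfg <- read_run_config(opts$config)
  seed <- resolve_seed(opts, cfg, "simulate")
  fit_seed <- tryCatch(resolve_seed(opts["none"], cfg, "fit"),
                       error = function(e) seed + 1L)
  cli_log("recover", config_path = opts$config,
          seeds = list(simulate = seed, fit = fit_seed))
  cohort <- generate_cohort(config_to_cohort(cfg, seed))
  fit <- fit_hierarchical(cohort$trials, config_to_mcmc(cfg, fit_seed),
                          reward_scale = cohort$config$reward_scale)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(cohort$trials, file.path(opts$out, "trials.csv"))
  write.csv(fit_draws(fit), file.path(opts$out, "draws.csv"),
            row.names = FALSE)
  rep <- recovery_report(fit, cohort$truth)
  write.csv(rep, file.path(opts$out, "recovery_report.csv"),
            row.names = FALSE)
  message("  coverage: ", sum(rep$covered), "/", nrow(rep),
          " coefficients inside their 95% HDI")
}
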