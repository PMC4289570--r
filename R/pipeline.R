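# Config-driven end-to-end runner: Step-1 refit -> projection -> Step-2
# sampling -> summaries, with table-style CSV artifacts and JSON provenance.

#' Analysis configuration
#'
#' @param population \code{"BRVO"} or \code{"CRVO"}.
#' @param time_point Month of assessment (only month 1 is packaged; other
#'   time points require user-supplied input files).
#' @param direction \code{"trial1"} (base case: compare in the ranibizumab
#'   trial's setting on the +/-10/+/-20 scheme) or \code{"trial2"}
#'   (sensitivity: compare in the dexamethasone trial's setting on the
#'   +/-5/+/-15 scheme; requires user-supplied mean/SD summaries for the
#'   ranibizumab arms, which the packaged fixtures do not carry).
#' @param seed Integer seed used for both the optimiser restarts and the
#'   sampler.
#' @param n_restarts Step-1 restarts.
#' @param draws,burn_in,chains Sampler settings.
#' @param out_dir Output directory for artifacts.
#' @param trial1_files,trial2_files Optional \code{c(csv, json)} paths
#'   overriding the packaged fixtures (see [read_trial_files()]).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(population, time_point = 1L,
                            direction = c("trial1", "trial2"),
                            seed = 1L, n_restarts = 20L,
                            draws = 100000L, burn_in = 50000L, chains = 1L,
                            out_dir = tempfile("mnitc-run-"),
                            trial1_files = NULL, trial2_files = NULL) {
  structure(list(population = match.arg(population, c("BRVO", "CRVO")),
                 time_point = as.integer(time_point),
                 direction = match.arg(direction),
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 draws = as.integer(draws), burn_in = as.integer(burn_in),
                 chains = as.integer(chains), out_dir = out_dir,
                 trial1_files = trial1_files, trial2_files = trial2_files),
            class = "analysis_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

load_or_read <- function(files, population, treatment, time_point) {
  if (!is.null(files)) return(read_trial_files(files[1L], files[2L]))
  load_fixture(population, treatment, time_point)
}

#' Run a full indirect-comparison analysis
#'
#' Executes the two-step pipeline for one configuration: fits the Step-1
#' fine-grained distributions to the trial-2 summaries, projects them onto
#' the common scheme, reconstructs counts, samples the Bayesian
#' indirect-comparison posterior, and writes artifact files: a Step-1
#' fitted-summaries CSV, a posterior-summary CSV, and a provenance JSON
#' capturing every setting and seed.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with elements \code{step1}, \code{data},
#'   \code{draws}, \code{summary} and \code{paths}.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  pop <- config$population
  tp <- config$time_point
  if (tp == 6L && pop == "BRVO")
    log_stage("caveat", paste0(
      "month-6 BRVO comparisons may be biased in favour of the comparator: ",
      "rescue laser treatment was available in that trial after month 3"))
  if (config$direction == "trial1") {
    trial1 <- load_or_read(config$trial1_files, pop, "ranibizumab", tp)
    trial2 <- load_or_read(config$trial2_files, pop, "dexamethasone", tp)
    scheme <- ranibizumab_scheme()
  } else {
    trial1 <- load_or_read(config$trial1_files, pop, "dexamethasone", tp)
    trial2 <- load_or_read(config$trial2_files, pop, "ranibizumab", tp)
    scheme <- geneva_scheme()
    if (is.na(trial2$treatment$mean_change))
      stop("the '", config$direction, "' direction refits trial 2 (",
           trial2$trial_label, ") and therefore needs mean/SD summaries ",
           "for its arms, which are not in the packaged fixtures; supply ",
           "trial2_files = c(csv, json) in the fixture format (see ",
           "?read_trial_files) with mean_treatment/sd_treatment and ",
           "mean_control/sd_control filled in")
  }
  log_stage("step1", "fitting trial-2 (%s) distributions, %d restarts, seed %d",
            trial2$trial_label, config$n_restarts, config$seed)
  targets <- step1_targets(trial2)
  step1 <- fit_step1(targets, seed = config$seed,
                     n_restarts = config$n_restarts)
  log_stage("step1", "total RMSE %.4f (converged: %s)", step1$total_rmse,
            step1$diagnostics$converged)
  if (!step1$diagnostics$converged)
    stop("Step-1 optimisation did not converge; restart objective values: ",
         paste(format(step1$diagnostics$restart_values, digits = 4),
               collapse = ", "))
  data <- build_model_data(trial1, step1, scheme)
  log_stage("step2", "sampling %d draws after %d burn-in (%d chain(s))",
            config$draws, config$burn_in, config$chains)
  draws <- sample_indirect(data, draws = config$draws,
                           burn_in = config$burn_in, seed = config$seed,
                           chains = config$chains)
  log_stage("step2", "max split Rhat %.3f; acceptance %s",
            max(draws$diagnostics$rhat, na.rm = TRUE),
            paste(sprintf("%.2f", draws$metadata$acceptance), collapse = "/"))
  summ <- summarize_posterior(draws)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    step1_csv = file.path(config$out_dir,
                          sprintf("step1_%s_month%d.csv", tolower(pop), tp)),
    step1_json = file.path(config$out_dir,
                           sprintf("step1_%s_month%d.json", tolower(pop), tp)),
    summary_csv = file.path(config$out_dir,
                            sprintf("summary_%s_month%d.csv", tolower(pop), tp)),
    provenance = file.path(config$out_dir, "provenance.json"))
  write_step1_csv(step1, paths$step1_csv)
  jsonlite::write_json(list(
    q_treat = unname(step1$q_treat), q_sham = unname(step1$q_sham),
    ranges = as.data.frame(step1$refinement),
    total_rmse = step1$total_rmse,
    residuals = as.list(step1$residuals)),
    paths$step1_json, auto_unbox = TRUE, digits = NA)
  write_summary_csv(summ, paths$summary_csv)
  jsonlite::write_json(list(
    package = "mnitc",
    version = as.character(utils::packageVersion("mnitc")),
    r_version = R.version.string,
    config = unclass(config),
    trial1 = trial1$trial_label, trial2 = trial2$trial_label,
    step1_total_rmse = step1$total_rmse,
    sampler = draws$metadata,
    max_rhat = max(draws$diagnostics$rhat, na.rm = TRUE)),
    paths$provenance, auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done", "artifacts in %s", config$out_dir)
  invisible(list(step1 = step1, data = data, draws = draws, summary = summ,
                 paths = paths))
}

# Table-style CSV of the Step-1 fitted summaries (fixed formatting so
# repeated runs are byte-identical).
write_step1_csv <- function(step1, path) {
  fit <- step1$fitted_summaries
  tg <- step1$targets
  rows <- data.frame(
    quantity = c(tg$labels, "Mean improvement (letters)", "SD improvement"),
    treatment = sprintf("%.6f", c(unname(fit$treat_probs), fit$treat_mean,
                                  fit$treat_sd)),
    sham = sprintf("%.6f", c(unname(fit$sham_probs), fit$sham_mean,
                             fit$sham_sd)),
    relative_risk = c(sprintf("%.6f", unname(fit$rr)), "", ""))
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

write_summary_csv <- function(summ, path) {
  df <- as.data.frame(summ)
  df[-1] <- lapply(df[-1], function(v) sprintf("%.6f", v))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: \code{fit-step1} (Step 1 only), \code{compare} (full
#' pipeline for one population), \code{run-all} (both populations) and
#' \code{fixtures} (list packaged datasets). Options \code{--seed},
#' \code{--draws}, \code{--burn-in} and \code{--restarts} override the
#' matching settings of a JSON \code{--config} file, if one is given.
#' Exits non-zero if any stage fails to converge.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments, so an \code{Rscript} wrapper can call this
#'   directly).
#' @return Invisibly, the exit code (0 on success).
#' @export
mnitc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mnitc <fit-step1|compare|run-all|fixtures> [options]",
    "  fit-step1  --population BRVO|CRVO [--restarts N] [--seed S] [--out DIR]",
    "  compare    --population BRVO|CRVO [--direction trial1|trial2]",
    "             [--draws N] [--burn-in N] [--restarts N] [--seed S] [--out DIR]",
    "  run-all    [--draws N] [--burn-in N] [--restarts N] [--seed S] [--out DIR]",
    "  fixtures   (list packaged datasets)", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--population", type = "character", default = NULL),
      optparse::make_option("--direction", type = "character", default = "trial1"),
      optparse::make_option("--time-point", dest = "time_point",
                            type = "integer", default = 1L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--draws", type = "integer", default = 100000L),
      optparse::make_option("--burn-in", dest = "burn_in", type = "integer",
                            default = 50000L),
      optparse::make_option("--restarts", type = "integer", default = 20L),
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out", type = "character", default = "mnitc-out"))),
    args = args[-1L])
  from_config <- list()
  if (!is.null(opts$config))
    from_config <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  get_opt <- function(name, default) {
    if (!is.null(from_config[[name]])) from_config[[name]] else
      if (!is.null(opts[[name]])) opts[[name]] else default
  }
  make_config <- function(pop) {
    analysis_config(population = pop,
                    time_point = get_opt("time_point", 1L),
                    direction = get_opt("direction", "trial1"),
                    seed = opts$seed, n_restarts = opts$restarts,
                    draws = opts$draws, burn_in = opts$burn_in,
                    out_dir = file.path(opts$out, tolower(pop)))
  }
  code <- tryCatch({
    switch(cmd,
      "fixtures" = {
        print(list_fixtures())
        0L
      },
      "fit-step1" = {
        if (is.null(opts$population)) stop("--population is required")
        ds <- load_fixture(opts$population, "dexamethasone", opts$time_point)
        fit <- fit_step1(step1_targets(ds), seed = opts$seed,
                         n_restarts = opts$restarts)
        print(fit)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        write_step1_csv(fit, file.path(opts$out,
          sprintf("step1_%s.csv", tolower(opts$population))))
        if (fit$diagnostics$converged) 0L else 1L
      },
      "compare" = {
        if (is.null(opts$population)) stop("--population is required")
        res <- run_analysis(make_config(opts$population))
        print(res$summary)
        0L
      },
      "run-all" = {
        for (pop in c("BRVO", "CRVO")) {
          res <- run_analysis(make_config(pop))
          print(res$summary)
        }
        0L
      },
      { message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
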