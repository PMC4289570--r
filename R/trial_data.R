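#' Per-arm trial summary
#'
#' Holds one arm's published summaries: category proportions on a scheme,
#' arm size, optional extra reported range proportions (e.g. "gain >= 10
#' letters"), and optional mean/SD of letter change.
#'
#' @param arm_label \code{"treatment"} or \code{"control"}.
#' @param n Number of patients in the arm.
#' @param category_probs Proportions per scheme category (gain-first order),
#'   summing to 1 within 0.01 (printed rounding).
#' @param extra_probs Optional data frame with columns \code{label},
#'   \code{lower}, \code{upper}, \code{prob} for additional reported ranges.
#' @param mean_change,sd_change Mean and standard deviation of letter change,
#'   if reported (\code{NA} otherwise).
#' @return An object of class \code{arm_summary}.
#' @export
arm_summary <- function(arm_label, n, category_probs, extra_probs = NULL,
                        mean_change = NA_real_, sd_change = NA_real_) {
  arm_label <- match.arg(arm_label, c("treatment", "control"))
  n <- as.integer(n)
  if (n <= 0L) stop("arm size n must be positive")
  if (any(category_probs < 0 | category_probs > 1))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(category_probs) - 1) > 0.01)
    stop("category proportions must sum to 1 within 0.01 (got ",
         format(sum(category_probs)), ")")
  if (!is.na(sd_change) && sd_change < 0) stop("sd_change must be >= 0")
  structure(list(arm_label = arm_label, n = n,
                 category_probs = as.numeric(category_probs),
                 extra_probs = extra_probs,
                 mean_change = as.numeric(mean_change),
                 sd_change = as.numeric(sd_change)),
            class = "arm_summary")
}

#' A two-arm trial dataset on one category scheme
#'
#' @param trial_label Trial name.
#' @param population \code{"BRVO"} or \code{"CRVO"}.
#' @param time_point Month of assessment.
#' @param treatment,control [arm_summary()] objects on the same scheme.
#' @param scheme The [category_scheme()] the proportions are reported on.
#' @param rr_reported Optional data frame of published treatment-vs-control
#'   relative risks (columns \code{label}, \code{rr}), kept as printed.
#' @return An object of class \code{trial_dataset}.
#' @export
trial_dataset <- function(trial_label, population, time_point,
                          treatment, control, scheme, rr_reported = NULL) {
  population <- match.arg(population, c("BRVO", "CRVO"))
  stopifnot(inherits(treatment, "arm_summary"), inherits(control, "arm_summary"),
            inherits(scheme, "category_scheme"))
  if (length(treatment$category_probs) != nrow(scheme) ||
      length(control$category_probs) != nrow(scheme))
    stop("both arms must report proportions on the dataset's scheme")
  structure(list(trial_label = trial_label, population = population,
                 time_point = as.integer(time_point),
                 treatment = treatment, control = control,
                 scheme = scheme, rr_reported = rr_reported),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %s, %s, month %d (scheme: %s)\n",
              x$trial_label, x$population, x$time_point,
              scheme_name(x$scheme)))
  df <- data.frame(category = x$scheme$label,
                   prob_treatment = x$treatment$category_probs,
                   prob_control = x$control$category_probs)
  print(df, ...)
  cat(sprintf("n_treatment = %d, n_control = %d\n",
              x$treatment$n, x$control$n))
  invisible(x)
}

fixture_dir <- function() system.file("extdata", package = "mnitc")

fixture_stem <- function(population, treatment_name, time_point) {
  sprintf("%s_%s_month%d", tolower(population), tolower(treatment_name),
          as.integer(time_point))
}

#' List packaged trial fixtures
#'
#' @return A data frame with one row per packaged fixture (population,
#'   treatment, time point, trial label).
#' @export
list_fixtures <- function() {
  files <- list.files(fixture_dir(), pattern = "\\.json$")
  out <- do.call(rbind, lapply(files, function(f) {
    meta <- jsonlite::read_json(file.path(fixture_dir(), f))
    data.frame(population = meta$population, treatment = meta$treatment_name,
               time_point = meta$time_point, trial = meta$trial_label)
  }))
  out[order(out$population, out$treatment), , drop = FALSE]
}

#' Load a packaged trial dataset
#'
#' Fixtures ship the per-arm proportions, arm sizes and (where published)
#' means, SDs and relative risks exactly as printed in the source trial
#' reports; integer counts are always re-derived with
#' [counts_from_proportions()], never stored.
#'
#' @param population \code{"BRVO"} or \code{"CRVO"}.
#' @param treatment_name \code{"ranibizumab"} or \code{"dexamethasone"}.
#' @param time_point Month (only month 1 is packaged).
#' @return A [trial_dataset()].
#' @export
load_fixture <- function(population, treatment_name, time_point = 1) {
  stem <- fixture_stem(population, treatment_name, time_point)
  csv <- file.path(fixture_dir(), paste0(stem, ".csv"))
  js <- file.path(fixture_dir(), paste0(stem, ".json"))
  if (!file.exists(csv) || !file.exists(js)) {
    avail <- list_fixtures()
    stop("fixture '", stem, "' is not packaged; available fixtures:\n",
         paste(sprintf("  %s / %s / month %d", avail$population,
                       avail$treatment, avail$time_point), collapse = "\n"))
  }
  read_trial_files(csv, js)
}

#' Read a trial dataset from user-supplied files
#'
#' Expects the packaged fixture format: a CSV with columns
#' \code{category_label, lower, upper, prob_treatment, prob_control} and a
#' JSON sidecar carrying \code{trial_label}, \code{population},
#' \code{treatment_name}, \code{time_point}, \code{scheme_name},
#' \code{n_treatment}, \code{n_control} and optional \code{mean_change},
#' \code{sd_change}, \code{extra_ranges} and \code{rr_reported} entries.
#'
#' @param csv_path,json_path Paths to the two files.
#' @return A [trial_dataset()].
#' @export
read_trial_files <- function(csv_path, json_path) {
  tab <- read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("category_label", "lower", "upper", "prob_treatment", "prob_control")
  if (!all(need %in% names(tab)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  scheme <- category_scheme(meta$scheme_name,
                            data.frame(label = tab$category_label,
                                       lower = tab$lower, upper = tab$upper))
  # re-order probabilities to the scheme's gain-first row order
  ord <- match(scheme$lower, tab$lower)
  extra <- NULL
  if (!is.null(meta$extra_ranges) && length(meta$extra_ranges))
    extra <- as.data.frame(meta$extra_ranges)
  arm <- function(which) {
    ex <- NULL
    if (!is.null(extra))
      ex <- data.frame(label = extra$label, lower = extra$lower,
                       upper = extra$upper,
                       prob = extra[[paste0("prob_", which)]])
    arm_summary(
      if (which == "treatment") "treatment" else "control",
      meta[[paste0("n_", which)]],
      tab[[paste0("prob_", which)]][ord],
      extra_probs = ex,
      mean_change = null_na(meta[[paste0("mean_", which)]]),
      sd_change = null_na(meta[[paste0("sd_", which)]]))
  }
  rr <- NULL
  if (!is.null(meta$rr_reported)) rr <- as.data.frame(meta$rr_reported)
  trial_dataset(meta$trial_label, meta$population, meta$time_point,
                arm("treatment"), arm("control"), scheme, rr_reported = rr)
}

null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Integer counts from published proportions
#'
#' Reconstructs per-category patient counts from printed proportions by
#' largest-remainder (Hamilton) rounding so that the counts sum exactly to
#' the arm size. Ties in the remainders are broken toward the earlier
#' (higher-gain) category.
#'
#' @param probs Proportions (gain-first order), summing to 1 within 0.01.
#' @param n Arm size.
#' @return Integer vector of counts summing to \code{n}.
#' @export
counts_from_proportions <- function(probs, n) {
  if (any(probs < 0)) stop("proportions must be non-negative")
  if (abs(sum(probs) - 1) > 0.01)
    stop("proportions must sum to 1 within 0.01")
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  target <- probs * n
  base <- floor(target + 1e-9)
  rem <- target - base
  k <- n - sum(base)
  counts <- base
  if (k > 0) {
    # order by remainder descending, ties to the earlier (higher-gain) index
    add <- order(-rem, seq_along(rem))[seq_len(k)]
    counts[add] <- counts[add] + 1
  } else if (k < 0) {
    # printed proportions summed above 1: take back from the smallest
    # remainders among positive counts
    drop_order <- order(rem, -seq_along(rem))
    drop_order <- drop_order[counts[drop_order] > 0]
    dropped <- drop_order[seq_len(-k)]
    counts[dropped] <- counts[dropped] - 1
  }
  as.integer(counts)
}

#' Relative risk with a delta-method confidence interval
#'
#' Point estimate \code{(x_t/n_t)/(x_c/n_c)} with the log-scale delta-method
#' interval \code{RR * exp(-+ z * sqrt(1/x_t - 1/n_t + 1/x_c - 1/n_c))}.
#' A zero numerator returns the degenerate \code{(0, 0, 0)} triple, matching
#' the convention used when trial reports print "0.00 (0.00, 0.00)"; a zero
#' denominator with a non-zero numerator is an error (the failure mode that
#' motivates the Bayesian route).
#'
#' @param x_t,n_t Events and size of the treatment arm.
#' @param x_c,n_c Events and size of the control arm.
#' @param conf Confidence level (default 0.95).
#' @return An object of class \code{rr_estimate} with fields \code{point},
#'   \code{lower}, \code{upper}, \code{conf}.
#' @export
relative_risk <- function(x_t, n_t, x_c, n_c, conf = 0.95) {
  stopifnot(n_t > 0, n_c > 0, x_t >= 0, x_c >= 0, x_t <= n_t, x_c <= n_c)
  if (x_c == 0) {
    if (x_t > 0)
      stop("relative risk undefined: zero events in the control arm")
    return(rr_estimate(0, 0, 0, conf))
  }
  if (x_t == 0) return(rr_estimate(0, 0, 0, conf))
  point <- (x_t / n_t) / (x_c / n_c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / x_t - 1 / n_t + 1 / x_c - 1 / n_c)
  rr_estimate(point, point * exp(-z * se), point * exp(z * se), conf)
}

rr_estimate <- function(point, lower, upper, conf = 0.95) {
  structure(list(point = point, lower = lower, upper = upper, conf = conf),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("RR %.*f (%.*f, %.*f) [%g%% CI]\n", digits, x$point,
              digits, x$lower, digits, x$upper, 100 * x$conf))
  invisible(x)
}

#' Frequentist relative risks for every category of a trial dataset
#'
#' Reconstructs counts for both arms and applies [relative_risk()] per
#' category, reproducing a trial report's relative-risk column.
#'
#' @param dataset A [trial_dataset()].
#' @param conf Confidence level.
#' @return A data frame with columns \code{category}, \code{rr},
#'   \code{lower}, \code{upper}.
#' @export
dataset_relative_risks <- function(dataset, conf = 0.95) {
  xt <- counts_from_proportions(dataset$treatment$category_probs,
                                dataset$treatment$n)
  xc <- counts_from_proportions(dataset$control$category_probs,
                                dataset$control$n)
  rows <- lapply(seq_along(xt), function(j) {
    rr <- relative_risk(xt[j], dataset$treatment$n, xc[j], dataset$control$n,
                        conf = conf)
    data.frame(category = dataset$scheme$label[j], rr = rr$point,
               lower = rr$lower, upper = rr$upper)
  })
  do.call(rbind, rows)
}
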