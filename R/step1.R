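# Step 1: refit fine-grained multinomial distributions for a treatment and
# its sham to published summary statistics, by minimising the root of the
# summed squared residuals between model output and the printed summaries
# (category probabilities, an extra reported range, relative risks, means
# and standard deviations), subject to simplex constraints on the two
# 9-range probability vectors.

#' Build Step-1 fitting targets from a trial dataset
#'
#' Collects, for both arms, the 5 scheme probabilities, any extra reported
#' range probability (e.g. gain >= 10 letters), the mean and SD of letter
#' change, and the published treatment-vs-sham relative risks. Relative-risk
#' targets are taken from the dataset's printed values when available and
#' otherwise computed as ratios of the printed proportions.
#'
#' @param dataset A [trial_dataset()] whose arms carry means and SDs.
#' @return An object of class \code{step1_targets}.
#' @export
step1_targets <- function(dataset) {
  tr <- dataset$treatment
  sh <- dataset$control
  if (is.na(tr$mean_change) || is.na(tr$sd_change) ||
      is.na(sh$mean_change) || is.na(sh$sd_change))
    stop("Step 1 requires means and SDs of letter change for both arms")
  extra <- tr$extra_probs
  labels <- c(dataset$scheme$label, if (!is.null(extra)) extra$label)
  rr <- NULL
  if (!is.null(dataset$rr_reported)) {
    idx <- match(labels, dataset$rr_reported$label)
    if (!anyNA(idx)) rr <- dataset$rr_reported$rr[idx]
  }
  if (is.null(rr)) {
    tprob <- c(tr$category_probs, if (!is.null(extra)) extra$prob)
    cprob <- c(sh$category_probs, if (!is.null(sh$extra_probs)) sh$extra_probs$prob)
    rr <- ifelse(cprob == 0, ifelse(tprob == 0, 0, NA_real_), tprob / cprob)
    if (anyNA(rr)) stop("cannot derive a relative-risk target: zero sham ",
                        "proportion with non-zero treatment proportion")
  }
  structure(list(
    scheme = dataset$scheme,
    extra_ranges = if (is.null(extra)) NULL else extra[, c("label", "lower", "upper")],
    labels = labels,
    treat = list(probs = tr$category_probs,
                 extra = if (is.null(extra)) numeric(0) else extra$prob,
                 mean = tr$mean_change, sd = tr$sd_change, n = tr$n),
    sham = list(probs = sh$category_probs,
                extra = if (is.null(sh$extra_probs)) numeric(0) else sh$extra_probs$prob,
                mean = sh$mean_change, sd = sh$sd_change, n = sh$n),
    rr = as.numeric(rr)),
    class = "step1_targets")
}

# Penalty used for a fitted relative risk whose sham probability is exactly
# zero while the treatment probability is not: large enough that the
# optimizer never rests there, finite so the objective stays comparable.
RR_ZERO_PENALTY <- 1e3

# Precomputed linear maps from the 9-range masses to the fitted quantities:
# an aggregation matrix for the target ranges and, for the moments, the
# per-range mean and mean-square of the integer letters it contains (exact
# under the uniform-within-range expansion, so no expansion is needed in
# the optimiser's hot loop).
step1_design <- function(targets, refinement = refinement_scheme()) {
  ranges <- rbind(
    data.frame(lower = targets$scheme$lower, upper = targets$scheme$upper),
    if (!is.null(targets$extra_ranges))
      targets$extra_ranges[, c("lower", "upper")])
  agg <- t(vapply(seq_len(nrow(ranges)), function(i) {
    inside <- refinement$lower >= ranges$lower[i] &
      refinement$upper <= ranges$upper[i]
    crossed <- !inside & refinement$upper >= ranges$lower[i] &
      refinement$lower <= ranges$upper[i]
    if (any(crossed))
      stop("target range [", ranges$lower[i], ",", ranges$upper[i],
           "] is not aligned with the refinement boundaries")
    as.numeric(inside)
  }, numeric(nrow(refinement))))
  mu <- mapply(function(l, u) mean(l:u), refinement$lower, refinement$upper)
  msq <- mapply(function(l, u) mean((l:u)^2), refinement$lower,
                refinement$upper)
  list(agg = agg, mu = mu, msq = msq, refinement = refinement)
}

# Fitted range probabilities, relative risks and moments implied by a pair
# of 9-range vectors on the common refinement.
step1_model_summaries <- function(q_treat, q_sham, targets,
                                  design = step1_design(targets)) {
  pt <- as.numeric(design$agg %*% q_treat)
  ps <- as.numeric(design$agg %*% q_sham)
  rr <- ifelse(ps == 0, ifelse(pt == 0, 0, RR_ZERO_PENALTY), pt / ps)
  mt <- sum(q_treat * design$mu)
  ms <- sum(q_sham * design$mu)
  list(treat_probs = setNames(pt, targets$labels),
       sham_probs = setNames(ps, targets$labels),
       rr = setNames(rr, targets$labels),
       treat_mean = mt, sham_mean = ms,
       treat_sd = sqrt(max(sum(q_treat * design$msq) - mt^2, 0)),
       sham_sd = sqrt(max(sum(q_sham * design$msq) - ms^2, 0)))
}

#' Step-1 residuals and objective
#'
#' \code{step1_residuals()} returns the signed residuals (fitted minus
#' target) over all fitted quantities: the per-arm range probabilities
#' (including any extra reported range), the treatment-vs-sham relative
#' risks, and the per-arm means and SDs -- 22 residuals for the packaged
#' datasets. \code{step1_objective()} is the square root of the (optionally
#' weighted) sum of squared residuals; note the sum, not the mean. Only the
#' mean and SD residuals depend on the uniform-within-range expansion; the
#' probability and relative-risk residuals are functions of the range masses
#' alone.
#'
#' @param q_treat,q_sham Probability vectors on the 9-range common
#'   refinement (gain-first row order).
#' @param targets A [step1_targets()] object.
#' @param weights Optional non-negative weights, recycled over the residual
#'   vector (default all 1).
#' @return \code{step1_residuals()}: a named numeric vector;
#'   \code{step1_objective()}: a scalar.
#' @export
step1_residuals <- function(q_treat, q_sham, targets,
                            design = step1_design(targets)) {
  fit <- step1_model_summaries(q_treat, q_sham, targets, design)
  res <- c(fit$treat_probs - c(targets$treat$probs, targets$treat$extra),
           fit$sham_probs - c(targets$sham$probs, targets$sham$extra),
           fit$rr - targets$rr,
           fit$treat_mean - targets$treat$mean,
           fit$sham_mean - targets$sham$mean,
           fit$treat_sd - targets$treat$sd,
           fit$sham_sd - targets$sham$sd)
  k <- length(targets$labels)
  names(res) <- c(paste0("prob_treat.", targets$labels),
                  paste0("prob_sham.", targets$labels),
                  paste0("rr.", targets$labels),
                  "mean_treat", "mean_sham", "sd_treat", "sd_sham")
  res
}

#' @rdname step1_residuals
#' @export
step1_objective <- function(q_treat, q_sham, targets, weights = NULL,
                            design = step1_design(targets)) {
  res <- step1_residuals(q_treat, q_sham, targets, design)
  w <- if (is.null(weights)) rep(1, length(res)) else rep_len(weights, length(res))
  sqrt(sum(w * res^2))
}

# Additive log-ratio transform with the centre range (row 5, [-4,+4]) as
# reference: 8 free parameters per arm, strictly positive simplex image.
ALR_REF <- 5L

alr_inverse <- function(theta) {
  z <- exp(c(theta[seq_len(ALR_REF - 1L)], 0, theta[ALR_REF:length(theta)]) -
             max(theta, 0))
  z / sum(z)
}

alr_forward <- function(q) {
  lq <- log(pmax(q, 1e-12)) - log(pmax(q[ALR_REF], 1e-12))
  lq[-ALR_REF]
}

# Start informed by the targets: ranges determined by the printed
# probabilities are set directly, undetermined within-category splits are
# even. Zeros are floored at a small epsilon for the log transform.
informed_start <- function(arm, targets, refinement) {
  q <- rep(1 / nrow(refinement), nrow(refinement))
  # distribute each target category's mass evenly over its refinement rows
  for (j in seq_len(nrow(targets$scheme))) {
    rows <- which(refinement$lower >= targets$scheme$lower[j] &
                    refinement$upper <= targets$scheme$upper[j])
    q[rows] <- arm$probs[j] / length(rows)
  }
  # use the extra range (if any) to pin the split it straddles
  if (!is.null(targets$extra_ranges) && length(arm$extra)) {
    for (i in seq_len(nrow(targets$extra_ranges))) {
      lo <- targets$extra_ranges$lower[i]
      hi <- targets$extra_ranges$upper[i]
      inside <- which(refinement$lower >= lo & refinement$upper <= hi)
      # rows of the straddled parent category not inside the extra range
      parent <- which(vapply(seq_len(nrow(targets$scheme)), function(j) {
        rows <- which(refinement$lower >= targets$scheme$lower[j] &
                        refinement$upper <= targets$scheme$upper[j])
        any(rows %in% inside) && !all(rows %in% inside)
      }, logical(1)))
      if (length(parent) == 1L) {
        rows <- which(refinement$lower >= targets$scheme$lower[parent] &
                        refinement$upper <= targets$scheme$upper[parent])
        split_in <- intersect(rows, inside)
        split_out <- setdiff(rows, inside)
        covered <- sum(q[setdiff(inside, rows)])
        m_in <- max(arm$extra[i] - covered, 0)
        m_out <- max(arm$probs[parent] - m_in, 0)
        q[split_in] <- m_in / length(split_in)
        q[split_out] <- m_out / length(split_out)
      }
    }
  }
  q <- pmax(q, 1e-6)
  q / sum(q)
}

#' Fit Step-1 distributions to published targets
#'
#' Jointly fits the treatment and sham 9-range probability vectors by
#' multi-start constrained minimisation of [step1_objective()]. The simplex
#' constraints are enforced exactly through an additive log-ratio
#' parameterisation; restarts draw starting points from a flat Dirichlet,
#' with one additional start informed by the targets themselves. Each
#' restart runs a quasi-Newton (BFGS) minimisation followed by a
#' Nelder-Mead polish; the best optimum over restarts is returned, with its
#' fitted summaries recomputed from the optimal range masses.
#'
#' @param targets A [step1_targets()] object.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of random restarts (default 20).
#' @param weights Optional residual weights passed to [step1_objective()].
#' @param maxit Iteration cap per optimiser call.
#' @return An object of class \code{step1_result} with elements
#'   \code{q_treat}, \code{q_sham}, \code{treatment_dist}, \code{sham_dist},
#'   \code{fitted_summaries}, \code{residuals}, \code{total_rmse} and
#'   \code{diagnostics}.
#' @export
fit_step1 <- function(targets, seed = 1L, n_restarts = 20L, weights = NULL,
                      maxit = 1000L) {
  stopifnot(inherits(targets, "step1_targets"))
  refinement <- refinement_scheme()
  k <- nrow(refinement)
  design <- step1_design(targets, refinement)
  target_vec <- c(targets$treat$probs, targets$treat$extra,
                  targets$sham$probs, targets$sham$extra, targets$rr,
                  targets$treat$mean, targets$sham$mean,
                  targets$treat$sd, targets$sham$sd)
  n_res <- length(target_vec)
  w <- if (is.null(weights)) rep(1, n_res) else rep_len(weights, n_res)
  # minimise the smooth weighted sum of squares; its root (the reported
  # objective) has the same minimiser but a gradient singularity at zero
  fn <- function(theta) {
    qt <- alr_inverse(theta[seq_len(k - 1L)])
    qs <- alr_inverse(theta[k:(2L * (k - 1L))])
    pt <- as.numeric(design$agg %*% qt)
    ps <- as.numeric(design$agg %*% qs)
    rr <- ifelse(ps == 0, ifelse(pt == 0, 0, RR_ZERO_PENALTY), pt / ps)
    mt <- sum(qt * design$mu)
    ms <- sum(qs * design$mu)
    fitted <- c(pt, ps, rr, mt, ms,
                sqrt(max(sum(qt * design$msq) - mt^2, 0)),
                sqrt(max(sum(qs * design$msq) - ms^2, 0)))
    sum(w * (fitted - target_vec)^2)
  }
  set.seed(seed)
  starts <- list(c(alr_forward(informed_start(targets$treat, targets, refinement)),
                   alr_forward(informed_start(targets$sham, targets, refinement))))
  for (r in seq_len(n_restarts)) {
    g <- matrix(rgamma(2L * k, 1), nrow = 2L)
    starts[[r + 1L]] <- c(alr_forward(g[1L, ] / sum(g[1L, ])),
                          alr_forward(g[2L, ] / sum(g[2L, ])))
  }
  best <- NULL
  values <- numeric(length(starts))
  deltas <- numeric(length(starts))
  iters <- 0L
  for (s in seq_along(starts)) {
    # alternate quasi-Newton and simplex polish until successive objective
    # values stabilise (well inside the 1e-4 stopping rule)
    par <- starts[[s]]
    val <- sqrt(fn(par))
    delta <- Inf
    ok <- TRUE
    for (cycle in 1:3) {
      o1 <- tryCatch(
        optim(par, fn, method = "BFGS",
              control = list(maxit = min(maxit, 300L), reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(o1)) { ok <- FALSE; break }
      o2 <- optim(o1$par, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-12))
      o <- if (o2$value < o1$value) o2 else o1
      iters <- iters + o1$counts[["function"]] + o2$counts[["function"]]
      delta <- val - sqrt(o$value)
      par <- o$par
      val <- sqrt(o$value)
      if (delta < 1e-8) break
    }
    if (!ok) { values[s] <- NA_real_; deltas[s] <- NA_real_; next }
    values[s] <- val
    deltas[s] <- delta
    if (is.null(best) || val < best$value)
      best <- list(par = par, value = val, delta = delta)
  }
  if (is.null(best))
    stop("Step-1 optimisation failed on all restarts; objective values: ",
         paste(format(values), collapse = ", "))
  # high-precision polish on the winning restart only (values on the
  # reported root scale, optimisation on the smooth sum-of-squares scale)
  for (cycle in 1:3) {
    p1 <- optim(best$par, fn, method = "BFGS",
                control = list(maxit = 1000L, reltol = 1e-15))
    p2 <- optim(p1$par, fn, method = "Nelder-Mead",
                control = list(maxit = 3000L, reltol = 1e-15))
    p <- if (p2$value < p1$value) p2 else p1
    iters <- iters + p1$counts[["function"]] + p2$counts[["function"]]
    delta <- best$value - sqrt(p$value)
    if (sqrt(p$value) < best$value)
      best <- list(par = p$par, value = sqrt(p$value), delta = max(delta, 0))
    if (delta < 1e-10) break
  }
  q_treat <- alr_inverse(best$par[seq_len(k - 1L)])
  q_sham <- alr_inverse(best$par[k:(2L * (k - 1L))])
  fitted <- step1_model_summaries(q_treat, q_sham, targets)
  res <- step1_residuals(q_treat, q_sham, targets)
  # convergence in the sense of the stopping rule: the best restart's final
  # polish cycle improved the objective by less than 1e-4
  converged <- is.finite(best$delta) && best$delta < 1e-4
  structure(list(
    q_treat = setNames(q_treat, refinement$label),
    q_sham = setNames(q_sham, refinement$label),
    treatment_dist = expand_uniform(q_treat, refinement),
    sham_dist = expand_uniform(q_sham, refinement),
    fitted_summaries = fitted,
    residuals = res,
    total_rmse = best$value,
    targets = targets,
    refinement = refinement,
    diagnostics = list(restart_values = values, final_deltas = deltas,
                       iterations = iters, converged = converged,
                       n_restarts = length(starts), seed = seed)),
    class = "step1_result")
}

#' @export
print.step1_result <- function(x, ...) {
  cat("Step-1 refit on the 9-range common refinement\n")
  cat(sprintf("  total RMSE (root of summed squares): %.4f  [converged: %s]\n",
              x$total_rmse, x$diagnostics$converged))
  tab <- data.frame(range = names(x$q_treat),
                    q_treatment = round(unname(x$q_treat), 4),
                    q_sham = round(unname(x$q_sham), 4))
  print(tab, row.names = FALSE, ...)
  cat(sprintf("  fitted mean (treat/sham): %.3f / %.3f; fitted SD: %.3f / %.3f\n",
              x$fitted_summaries$treat_mean, x$fitted_summaries$sham_mean,
              x$fitted_summaries$treat_sd, x$fitted_summaries$sham_sd))
  invisible(x)
}

#' Project a Step-1 result onto a category scheme
#'
#' Aggregates the fitted treatment and sham range masses onto any scheme
#' refined by the 9-range common refinement (e.g. the +/-10, +/-20 scheme
#' used by the comparator trial), for use in the Step-2 model.
#'
#' @param result A [fit_step1()] result.
#' @param scheme Target [category_scheme()].
#' @return A list with numeric vectors \code{treatment} and \code{sham},
#'   one probability per category of \code{scheme}.
#' @export
project_step1 <- function(result, scheme) {
  stopifnot(inherits(result, "step1_result"))
  list(treatment = project_q(unname(result$q_treat), result$refinement, scheme),
       sham = project_q(unname(result$q_sham), result$refinement, scheme))
}

#' Back-calculate a standard deviation from a confidence interval on a mean
#'
#' For a level-\code{conf} interval \code{(lower, upper)} on a mean of
#' \code{n} observations, returns \code{sqrt(n) * (upper - lower) / (2 z)}.
#' The packaged datasets ship the published SD values directly; this helper
#' documents how such values are derived from reported interval limits.
#'
#' @param lower,upper Interval limits (letters).
#' @param n Number of observations behind the mean.
#' @param conf Confidence level (default 0.95).
#' @return Estimated standard deviation (letters).
#' @export
estimate_sd_from_ci <- function(lower, upper, n, conf = 0.95) {
  stopifnot(upper >= lower, n > 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  sqrt(n) * (upper - lower) / (2 * z)
}
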