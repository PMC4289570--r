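# Step 2: Bayesian indirect comparison of two treatments on a common
# 5-category scheme via their shared sham comparators. Trial 1 contributes
# observed counts; trial 2 contributes counts reconstructed from the Step-1
# refit. The linking assumption is that the treatment-vs-sham relative
# risks of trial 2's treatment carry over to trial 1's population:
#   p_T2_j  proportional to  (p_ind_j / p_C1_j) * p_C2_j,
# with Dirichlet(1,...,1) priors on p_C1, p_T1, p_C2 and the indirect
# probabilities p_ind.

#' Assemble count data for the Bayesian indirect-comparison model
#'
#' Trial-1 counts are reconstructed from the trial's printed proportions and
#' arm sizes; trial-2 counts are the trial-2 arm sizes multiplied by the
#' Step-1 fitted probabilities projected onto the common scheme, both via
#' [counts_from_proportions()].
#'
#' @param trial1 A [trial_dataset()] reported on \code{scheme}.
#' @param step1 A [fit_step1()] result for trial 2's arms.
#' @param scheme The common [category_scheme()] for the comparison.
#' @return An object of class \code{indirect_model_data} with integer count
#'   vectors \code{x_C1}, \code{x_T1}, \code{x_C2}, \code{x_T2} and arm
#'   sizes \code{n_C1}, \code{n_T1}, \code{n_C2}, \code{n_T2}.
#' @export
build_model_data <- function(trial1, step1, scheme) {
  stopifnot(inherits(trial1, "trial_dataset"), inherits(step1, "step1_result"))
  if (!isTRUE(all.equal(trial1$scheme$lower, scheme$lower)))
    stop("trial 1 is not reported on the requested scheme")
  proj <- project_step1(step1, scheme)
  x_T1 <- counts_from_proportions(trial1$treatment$category_probs,
                                  trial1$treatment$n)
  x_C1 <- counts_from_proportions(trial1$control$category_probs,
                                  trial1$control$n)
  n_T2 <- step1$targets$treat$n
  n_C2 <- step1$targets$sham$n
  x_T2 <- counts_from_proportions(unname(proj$treatment), n_T2)
  x_C2 <- counts_from_proportions(unname(proj$sham), n_C2)
  indirect_model_data(x_C1, x_T1, x_C2, x_T2, labels = scheme$label)
}

#' @rdname build_model_data
#' @param x_C1,x_T1,x_C2,x_T2 Integer count vectors on a common scheme
#'   (gain-first order); trial 1 control/treatment, trial 2 control/treatment.
#' @param labels Optional category labels.
#' @export
indirect_model_data <- function(x_C1, x_T1, x_C2, x_T2, labels = NULL) {
  k <- length(x_C1)
  stopifnot(length(x_T1) == k, length(x_C2) == k, length(x_T2) == k)
  check <- function(x, nm) {
    if (any(x < 0)) stop(nm, " contains negative counts")
    as.integer(x)
  }
  if (is.null(labels)) labels <- paste0("category_", seq_len(k))
  structure(list(x_C1 = check(x_C1, "x_C1"), x_T1 = check(x_T1, "x_T1"),
                 x_C2 = check(x_C2, "x_C2"), x_T2 = check(x_T2, "x_T2"),
                 n_C1 = sum(x_C1), n_T1 = sum(x_T1),
                 n_C2 = sum(x_C2), n_T2 = sum(x_T2),
                 labels = labels),
            class = "indirect_model_data")
}

#' @export
print.indirect_model_data <- function(x, ...) {
  cat("<indirect_model_data>", length(x$labels), "categories\n")
  print(data.frame(category = x$labels, x_T1 = x$x_T1, x_C1 = x$x_C1,
                   x_T2 = x$x_T2, x_C2 = x$x_C2), row.names = FALSE)
  invisible(x)
}

# Deterministic trial-2 treatment probabilities implied by the linking:
# rows of p_ind, p_C1, p_C2 -> rows of p_T2 (rescaled to sum to 1).
linked_p_T2 <- function(p_ind, p_C1, p_C2) {
  u <- p_ind * p_C2 / p_C1
  u / sum(u)
}

#' Log posterior density of the indirect-comparison model
#'
#' Sum of the four multinomial log-likelihoods (including their
#' combinatorial constants) under flat Dirichlet priors, which are constant
#' on the simplex. Any non-positive probability yields \code{-Inf} rather
#' than an error.
#'
#' @param params A list with probability vectors \code{p_C1}, \code{p_T1},
#'   \code{p_C2}, \code{p_ind} on the open simplex.
#' @param data An [indirect_model_data()] object.
#' @return A scalar log density (up to the additive prior constant).
#' @export
log_posterior <- function(params, data) {
  ps <- params[c("p_C1", "p_T1", "p_C2", "p_ind")]
  if (any(vapply(ps, function(p) any(p <= 0), logical(1)))) return(-Inf)
  mult_ll <- function(x, p) {
    p <- p / sum(p)
    lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x * log(p))
  }
  p_T2 <- linked_p_T2(params$p_ind, params$p_C1, params$p_C2)
  mult_ll(data$x_C1, params$p_C1) + mult_ll(data$x_T1, params$p_T1) +
    mult_ll(data$x_C2, params$p_C2) + mult_ll(data$x_T2, p_T2)
}

#' Draw from the posterior of the indirect-comparison model
#'
#' Samples \code{p_C1}, \code{p_T1}, \code{p_C2} and the indirect
#' probabilities \code{p_ind} by Markov chain Monte Carlo: the trial-1
#' treatment block is conjugate (exact Dirichlet Gibbs draws), while the
#' three coupled simplexes are updated by adaptive random-walk Metropolis on
#' additive-log-ratio coordinates (adaptation runs during burn-in only, so
#' the retained chain is a valid time-homogeneous MCMC sample). The linked
#' \code{p_T2} is recomputed deterministically from the stored draws.
#'
#' @param data An [indirect_model_data()] object.
#' @param draws Number of post-burn-in draws to keep (default 100000).
#' @param burn_in Number of discarded adaptation draws (default 50000).
#' @param seed Integer seed (R RNG; drives both Gibbs and Metropolis moves).
#' @param chains Number of chains (draws are split evenly across them;
#'   default 1, matching the single long run of the original analysis).
#' @return An object of class \code{indirect_draws}: a list with element
#'   \code{draws} (matrices \code{p_C1}, \code{p_T1}, \code{p_C2},
#'   \code{p_ind}, \code{p_T2}, one row per retained draw), sampler
#'   \code{metadata} and convergence \code{diagnostics} (split-chain Rhat
#'   per stored probability; a warning is attached, not raised, when any
#'   Rhat exceeds 1.05).
#' @export
sample_indirect <- function(data, draws = 100000L, burn_in = 50000L,
                            seed = 1L, chains = 1L) {
  stopifnot(inherits(data, "indirect_model_data"), draws >= 2L, chains >= 1L)
  k <- length(data$x_C1)
  set.seed(seed)
  init_C1 <- (data$x_C1 + 1) / sum(data$x_C1 + 1)
  init_C2 <- (data$x_C2 + 1) / sum(data$x_C2 + 1)
  w <- (data$x_T2 + 1) / sum(data$x_T2 + 1) * init_C1 / init_C2
  init_ind <- w / sum(w)
  per_chain <- ceiling(draws / chains)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    jit <- function(p) { q <- p * exp(runif(k, -0.05, 0.05) * (ch > 1)); q / sum(q) }
    res[[ch]] <- mnitc_sample_cpp(data$x_C1, data$x_T1, data$x_C2, data$x_T2,
                                  as.integer(per_chain), as.integer(burn_in),
                                  jit(init_C1), jit(init_C2), jit(init_ind),
                                  0.3, TRUE)
  }
  bind <- function(name) {
    m <- do.call(rbind, lapply(res, `[[`, name))[seq_len(per_chain * chains), ,
                                                 drop = FALSE]
    colnames(m) <- data$labels
    m
  }
  out <- list(p_C1 = bind("p_C1"), p_T1 = bind("p_T1"),
              p_C2 = bind("p_C2"), p_ind = bind("p_ind"))
  u <- out$p_ind * out$p_C2 / out$p_C1
  out$p_T2 <- u / rowSums(u)
  rhat <- vapply(out[c("p_C1", "p_T1", "p_C2", "p_ind")], function(m) {
    apply(m, 2, split_rhat, chains = chains)
  }, numeric(k))
  warn <- NULL
  if (any(rhat > 1.05, na.rm = TRUE))
    warn <- sprintf("max split-chain Rhat %.3f exceeds 1.05", max(rhat))
  structure(list(
    draws = out,
    metadata = list(draws = per_chain * chains, burn_in = burn_in,
                    seed = seed, chains = chains,
                    acceptance = rowMeans(vapply(res, `[[`, numeric(3),
                                                 "acceptance")),
                    warning = warn),
    diagnostics = list(rhat = rhat)),
    class = "indirect_draws")
}

# Split-chain potential scale reduction factor on a single stored vector.
split_rhat <- function(x, chains = 1L) {
  n <- length(x)
  m <- 2L * chains
  len <- floor(n / m)
  if (len < 2L) return(NA_real_)
  xs <- matrix(x[seq_len(len * m)], nrow = len)
  bm <- colMeans(xs)
  wv <- mean(apply(xs, 2, var))
  bv <- len * var(bm)
  if (wv == 0) return(1)
  sqrt(((len - 1) / len * wv + bv / len) / wv)
}

#' @export
print.indirect_draws <- function(x, ...) {
  cat(sprintf("<indirect_draws> %d draws (%d chain(s), burn-in %d)\n",
              x$metadata$draws, x$metadata$chains, x$metadata$burn_in))
  cat(sprintf("  Metropolis acceptance (C1/C2/ind): %s\n",
              paste(sprintf("%.2f", x$metadata$acceptance), collapse = " / ")))
  cat(sprintf("  max split Rhat: %.3f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  if (!is.null(x$metadata$warning)) cat("  warning:", x$metadata$warning, "\n")
  invisible(x)
}

#' Summarise posterior draws of the indirect comparison
#'
#' Per category: posterior means and percentile credible intervals for the
#' trial-1 treatment probabilities (\code{p_T1}) and the indirect
#' probabilities (\code{p_ind}); the relative risk as the ratio of posterior
#' means, with a delta-method interval on the log scale using the posterior
#' variances of the two blocks (treated as independent), and, as a secondary
#' interval, the percentiles of the per-draw ratio.
#'
#' @param x An [sample_indirect()] result.
#' @param conf Credible level (default 0.95).
#' @return A data frame of class \code{posterior_summary}.
#' @export
summarize_posterior <- function(x, conf = 0.95) {
  stopifnot(inherits(x, "indirect_draws"))
  a <- (1 - conf) / 2
  z <- stats::qnorm(1 - a)
  t1 <- x$draws$p_T1
  ind <- x$draws$p_ind
  m_t1 <- colMeans(t1)
  m_ind <- colMeans(ind)
  v_t1 <- apply(t1, 2, var)
  v_ind <- apply(ind, 2, var)
  rr <- m_ind / m_t1
  se_log <- sqrt(v_ind / m_ind^2 + v_t1 / m_t1^2)
  ratio <- ind / t1
  out <- data.frame(
    category = colnames(t1),
    mean_treat1 = m_t1,
    lower_treat1 = apply(t1, 2, quantile, probs = a),
    upper_treat1 = apply(t1, 2, quantile, probs = 1 - a),
    mean_indirect = m_ind,
    lower_indirect = apply(ind, 2, quantile, probs = a),
    upper_indirect = apply(ind, 2, quantile, probs = 1 - a),
    rr = rr,
    rr_lower = rr * exp(-z * se_log),
    rr_upper = rr * exp(z * se_log),
    rr_q_lower = apply(ratio, 2, quantile, probs = a),
    rr_q_upper = apply(ratio, 2, quantile, probs = 1 - a),
    row.names = NULL)
  structure(out, conf = conf, metadata = x$metadata,
            class = c("posterior_summary", "data.frame"))
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%g%% intervals, %d draws)\n",
              100 * attr(x, "conf"), attr(x, "metadata")$draws))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Bucher adjusted indirect comparison (provided for contrast)
#'
#' Classical indirect comparison of treatment B against treatment A through
#' a common comparator, one outcome at a time: the point estimate is
#' \code{rr_B / rr_A} and the variance of the log relative risk is the sum
#' of the two component log-scale variances (back-calculated from the
#' component intervals). Fails by construction on zero-count categories and
#' can yield indirect probabilities above 1 when multiplied into comparator
#' probabilities -- the motivation for the joint Bayesian model.
#'
#' @param rr_AvsS,rr_BvsS [relative_risk()] estimates of each treatment
#'   against the shared comparator.
#' @return An \code{rr_estimate} for B versus A.
#' @export
bucher_indirect <- function(rr_AvsS, rr_BvsS) {
  stopifnot(inherits(rr_AvsS, "rr_estimate"), inherits(rr_BvsS, "rr_estimate"))
  if (rr_AvsS$point == 0 || rr_BvsS$point == 0 ||
      rr_AvsS$lower <= 0 || rr_BvsS$lower <= 0)
    stop("Bucher indirect comparison fails on zero estimates ",
         "(division by zero); use the Bayesian model")
  conf <- rr_AvsS$conf
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(((log(rr_AvsS$upper) - log(rr_AvsS$lower)) / (2 * z))^2 +
               ((log(rr_BvsS$upper) - log(rr_BvsS$lower)) / (2 * z))^2)
  point <- rr_BvsS$point / rr_AvsS$point
  rr_estimate(point, point * exp(-z * se), point * exp(z * se), conf)
}
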