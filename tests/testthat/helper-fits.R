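# Shared fixtures for the suite: Step-1 fits are moderately expensive, so
# they are computed once per population/settings and cached across files.
.fit_cache <- new.env(parent = emptyenv())

cached_step1 <- function(population, n_restarts = 8L, seed = 42L) {
  key <- paste(population, n_restarts, seed, sep = "/")
  if (is.null(.fit_cache[[key]])) {
    ds <- load_fixture(population, "dexamethasone", 1)
    .fit_cache[[key]] <- fit_step1(step1_targets(ds), seed = seed,
                                   n_restarts = n_restarts)
  }
  .fit_cache[[key]]
}

random_simplex <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}

# Synthetic Step-1 targets generated from a known pair of 9-range vectors
# (relative risks derived as exact ratios, moments via the uniform
# expansion), for parameter-recovery and zero-objective tests.
synthetic_targets <- function(q_treat, q_sham) {
  ref <- refinement_scheme()
  gs <- geneva_scheme()
  mk_arm <- function(q, label) {
    p5 <- unname(project_q(q, ref, gs))
    extra <- sum(q[ref$lower >= 10])
    d <- expand_uniform(q, ref)
    arm_summary(label, 100L, p5,
                extra_probs = data.frame(label = "Gain >=10 letters",
                                         lower = 10L, upper = 30L,
                                         prob = extra),
                mean_change = distribution_mean(d),
                sd_change = distribution_sd(d))
  }
  tr <- mk_arm(q_treat, "treatment")
  sh <- mk_arm(q_sham, "control")
  rr <- data.frame(
    label = c(gs$label, "Gain >=10 letters"),
    rr = c(tr$category_probs, tr$extra_probs$prob) /
      c(sh$category_probs, sh$extra_probs$prob))
  step1_targets(trial_dataset("synthetic", "BRVO", 1L, tr, sh, gs,
                              rr_reported = rr))
}
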