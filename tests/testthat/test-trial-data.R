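test_that("packaged fixtures carry the published summaries", {
  brvo_r <- load_fixture("BRVO", "ranibizumab", 1)
  expect_equal(brvo_r$treatment$n, 131L)
  expect_equal(brvo_r$treatment$category_probs[1], 0.191)
  expect_equal(brvo_r$control$n, 132L)

  crvo_d <- load_fixture("CRVO", "dexamethasone", 1)
  expect_equal(crvo_d$treatment$n, 136L)
  expect_equal(crvo_d$treatment$category_probs[1], 0.213)
  expect_equal(crvo_d$treatment$sd_change, 10.721)

  brvo_d <- load_fixture("BRVO", "dexamethasone", 1)
  expect_equal(brvo_d$control$n, 279L)
  expect_equal(brvo_d$control$mean_change, 3.8)
  expect_equal(brvo_d$treatment$extra_probs$prob, 0.426)

  expect_equal(nrow(list_fixtures()), 4L)
  expect_error(load_fixture("BRVO", "aflibercept", 1), "not packaged")
  expect_error(load_fixture("BRVO", "ranibizumab", 6), "not packaged")
})

test_that("largest-remainder counts match hand-derived examples", {
  expect_equal(counts_from_proportions(c(0.191, 0.313, 0.489, 0.008, 0.000), 131),
               c(25L, 41L, 64L, 1L, 0L))
  expect_equal(counts_from_proportions(c(1, 0, 0, 0, 0), 10),
               c(10L, 0L, 0L, 0L, 0L))
  expect_equal(counts_from_proportions(rep(0.2, 5), 5), rep(1L, 5))
  expect_error(counts_from_proportions(c(-0.1, 1.1), 10), "non-negative")
  expect_error(counts_from_proportions(c(0.5, 0.4), 10), "sum to 1")
})

test_that("count reconstruction sums to n and is idempotent", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:9, 1)
    p <- round(random_simplex(k), 3)
    if (abs(sum(p) - 1) > 0.01) next
    n <- sample(5:400, 1)
    x <- counts_from_proportions(p, n)
    expect_equal(sum(x), n)
    expect_true(all(x >= 0))
    expect_equal(counts_from_proportions(x / n, n), x)
  }
})

test_that("relative risk reproduces the published delta-method intervals", {
  rr <- relative_risk(25, 131, 5, 132)
  expect_equal(round(rr$point, 2), 5.04)
  expect_equal(round(rr$lower, 2), 1.99)
  expect_equal(round(rr$upper, 2), 12.76)

  expect_equal(relative_risk(10, 100, 10, 100)$point, 1)

  zero <- relative_risk(0, 131, 2, 132)
  expect_equal(c(zero$point, zero$lower, zero$upper), c(0, 0, 0))
  expect_error(relative_risk(3, 131, 0, 132), "zero events")

  tab1 <- dataset_relative_risks(load_fixture("BRVO", "ranibizumab", 1))
  expect_equal(round(tab1$rr, 2), c(5.04, 1.59, 0.69, 0.17, 0.00))
  expect_equal(round(tab1$lower, 2), c(1.99, 1.04, 0.56, 0.02, 0.00))
  expect_equal(round(tab1$upper, 2), c(12.76, 2.44, 0.85, 1.38, 0.00))
})

test_that("relative risk point equals the proportion ratio on a small sweep", {
  for (n_t in c(5L, 12L, 20L)) for (n_c in c(7L, 20L)) {
    for (x_t in 1:n_t) for (x_c in 1:n_c) {
      rr <- relative_risk(x_t, n_t, x_c, n_c)
      expect_equal(rr$point, (x_t / n_t) / (x_c / n_c))
      expect_true(rr$lower <= rr$point && rr$point <= rr$upper)
    }
  }
})

test_that("interval width shrinks as either arm grows, proportions fixed", {
  widths_t <- vapply(c(10, 20, 40, 80), function(n) {
    rr <- relative_risk(0.3 * n, n, 6, 20)
    rr$upper - rr$lower
  }, numeric(1))
  widths_c <- vapply(c(10, 20, 40, 80), function(n) {
    rr <- relative_risk(6, 20, 0.3 * n, n)
    rr$upper - rr$lower
  }, numeric(1))
  expect_true(all(diff(widths_t) < 0))
  expect_true(all(diff(widths_c) < 0))
})

test_that("arm_summary validates its invariants", {
  expect_error(arm_summary("treatment", 0, c(0.5, 0.5)), "positive")
  expect_error(arm_summary("treatment", 10, c(0.8, 0.3)), "sum to 1")
  expect_error(arm_summary("treatment", 10, c(1.2, -0.2)), "\\[0, 1\\]")
  expect_error(arm_summary("treatment", 10, c(0.5, 0.5), sd_change = -1), ">= 0")
})
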