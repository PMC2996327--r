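test_that("ld_pmf follows the Luria-Delbruck recursion and its closed forms", {
  p <- ld_pmf(0, 5)
  expect_equal(as.numeric(p), c(1, 0, 0, 0, 0, 0))

  p1 <- ld_pmf(1, 1)
  expect_equal(p1[1], exp(-1))
  expect_equal(p1[2], exp(-1) / 2)

  # mass bounded and p0 exact across m
  for (m in c(0.1, 1, 5, 10)) {
    p <- ld_pmf(m, 200)
    expect_equal(p[1], exp(-m))
    expect_true(all(p >= 0))
    expect_lte(sum(p), 1 + 1e-12)
    expect_gte(attr(p, "truncation_mass"), 0)
  }

  # monotone approach of the partial mass to 1 as r_max grows (the tail is
  # heavy, ~ m / r_max, so convergence is slow)
  mass <- vapply(c(10, 50, 200, 800), function(r) sum(ld_pmf(5, r)), numeric(1))
  expect_true(all(diff(mass) >= 0))
  expect_gt(mass[4], 1 - 2 * 5 / 800)

  expect_error(ld_pmf(-1, 5), class = "ofmscreen_domain_error")
})

test_that("ld_pmf matches the empirical count distribution of simulate_assay", {
  m <- 2
  a <- simulate_assay(m / 1e4, 1e4, 1e5, seed = 71)
  r_max <- 200L
  emp <- tabulate(pmin(a$loss_count, r_max) + 1L, nbins = r_max + 1L) / nrow(a)
  p <- ld_pmf(m, r_max)
  theo <- as.numeric(p)
  theo[r_max + 1L] <- theo[r_max + 1L] + attr(p, "truncation_mass")
  tv <- 0.5 * sum(abs(emp - theo))
  expect_lt(tv, 0.01)
})

test_that("simulate_assay has Poisson event counts and respects bounds", {
  a <- simulate_assay(0, 1e4, 50, seed = 1)
  expect_true(all(a$loss_count == 0))

  a2 <- simulate_assay(2e-4, 1e4, 1e5, seed = 5)
  expect_lt(abs(mean(a2$loss_count == 0) - exp(-2)), 0.01)
  expect_true(all(a2$loss_count <= 1e4))

  expect_identical(
    simulate_assay(1e-3, 1e4, 20, seed = 3),
    simulate_assay(1e-3, 1e4, 20, seed = 3)
  )
  expect_error(simulate_assay(1.5, 1e4, 10), class = "ofmscreen_domain_error")

  # binomial thinning when only part of the culture is scored
  a3 <- simulate_assay(2e-3, 1e4, 200, seed = 9, cells_sampled = 1000)
  expect_true(all(a3$loss_count <= 1000))
})

test_that("P0 estimator applies its closed form and error contract", {
  zeros <- tibble::tibble(loss_count = rep(0L, 10), culture_size = 1e4)
  expect_equal(estimate_p0(zeros)$m_hat, 0)

  half <- tibble::tibble(loss_count = c(rep(0L, 5), rep(2L, 5)), culture_size = 1e4)
  expect_equal(estimate_p0(half)$m_hat, -log(0.5), tolerance = 1e-12)
  expect_equal(estimate_p0(half)$rate_per_division, -log(0.5) / 1e4)

  none <- tibble::tibble(loss_count = rep(3L, 10), culture_size = 1e4)
  expect_error(estimate_p0(none), class = "ofmscreen_estimator_undefined")
})

test_that("Lea-Coulson median estimator solves the median equation", {
  # root values verified by substitution into r/m - log(m) = 1.24
  a5 <- tibble::tibble(loss_count = rep(5L, 9), culture_size = 1e4)
  m5 <- estimate_lc_median(a5)$m_hat
  expect_equal(5 / m5 - log(m5), 1.24, tolerance = 1e-7)
  expect_equal(m5, 2.37, tolerance = 0.005)

  a100 <- tibble::tibble(loss_count = rep(100L, 9), culture_size = 1e4)
  m100 <- estimate_lc_median(a100)$m_hat
  expect_equal(100 / m100 - log(m100), 1.24, tolerance = 1e-7)
  expect_equal(m100, 22.9, tolerance = 0.005)

  zeromed <- tibble::tibble(loss_count = c(0L, 0L, 7L), culture_size = 1e4)
  expect_error(estimate_lc_median(zeromed), class = "ofmscreen_estimator_undefined")

  # strictly increasing in the median count
  mhat <- vapply(1:50, function(r) {
    estimate_lc_median(tibble::tibble(loss_count = rep(r, 5), culture_size = 1e4))$m_hat
  }, numeric(1))
  expect_true(all(diff(mhat) > 0))
})

test_that("MSS maximum-likelihood estimator recovers m and handles boundaries", {
  allzero <- tibble::tibble(loss_count = rep(0L, 20), culture_size = 1e4)
  expect_warning(est <- estimate_mss_mle(allzero), "boundary")
  expect_equal(est$m_hat, 0)

  # parameter recovery at m = 5
  hits <- sum(vapply(1:20, function(s) {
    a <- simulate_assay(5e-4, 1e4, 200, seed = s)
    abs(estimate_mss_mle(a)$m_hat - 5) / 5 <= 0.15
  }, logical(1)))
  expect_gte(hits, 16)

  # grid-search oracle: 50 copies of a single culture with r = 3
  a <- tibble::tibble(loss_count = rep(3L, 50), culture_size = 1e4)
  mle <- estimate_mss_mle(a)$m_hat
  grid <- seq(0.5, 5, by = 1e-3)
  ll <- vapply(grid, function(m) ofmscreen:::ld_loglik(m, rep(3L, 50), 1024L), numeric(1))
  expect_lt(abs(mle - grid[which.max(ll)]), 2e-3)

  # the optimum beats both bracket ends
  a2 <- simulate_assay(2e-4, 1e4, 100, seed = 4)
  m2 <- estimate_mss_mle(a2)$m_hat
  counts <- pmin(a2$loss_count, 1024L)
  llopt <- ofmscreen:::ld_loglik(m2, counts, 1024L)
  expect_gte(llopt, ofmscreen:::ld_loglik(m2 / 5, counts, 1024L))
  expect_gte(llopt, ofmscreen:::ld_loglik(m2 * 5, counts, 1024L))
})

test_that("the three estimators agree on simulated assays", {
  for (m in c(1, 2, 5)) {
    diffs <- vapply(1:20, function(s) {
      a <- simulate_assay(m / 1e4, 1e4, 500, seed = 100 + s)
      ms <- c(
        tryCatch(estimate_p0(a)$m_hat, error = function(e) NA_real_),
        tryCatch(estimate_lc_median(a)$m_hat, error = function(e) NA_real_),
        estimate_mss_mle(a)$m_hat
      )
      max(abs(outer(ms, ms, "-")) / mean(ms, na.rm = TRUE), na.rm = TRUE)
    }, numeric(1))
    expect_lt(median(diffs), 0.25)
  }
})

test_that("rate_from_m converts events per culture to per-division rates", {
  expect_equal(rate_from_m(2, 1e3), 2e-3)
  expect_equal(rate_from_m(0, 1e4), 0)
  # headline wild-type scale: m = 21 in a 1e4-cell culture is 2.1e-3/division
  expect_equal(rate_from_m(21, 1e4), 2.1e-3)
})

test_that("round trip simulate -> estimate recovers the rate", {
  ok <- vapply(1:20, function(s) {
    mu <- 5e-4
    a <- simulate_assay(mu, 1e4, 200, seed = 300 + s)
    est <- estimate_loss_rate(a, "lc_median")
    abs(est$rate_per_division - mu) / mu <= 0.2
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("bootstrap_ci is deterministic, degenerate-safe, and covers", {
  flat <- tibble::tibble(loss_count = rep(7L, 30), culture_size = 1e4)
  b <- bootstrap_ci(flat, "lc_median", n_boot = 200, seed = 1)
  expect_equal(b$ci_low, b$ci_high)

  a <- simulate_assay(5e-4, 1e4, 100, seed = 2)
  b1 <- bootstrap_ci(a, "lc_median", n_boot = 150, seed = 7)
  b2 <- bootstrap_ci(a, "lc_median", n_boot = 150, seed = 7)
  expect_identical(tidy(b1), tidy(b2))
  expect_true(b1$ci_low < b1$rate_per_division, b1$rate_per_division < b1$ci_high)

  # an assay on which the estimator is undefined fails up front
  nozero <- tibble::tibble(loss_count = rep(50L, 30), culture_size = 1e4)
  expect_error(
    bootstrap_ci(nozero, "p0", n_boot = 100, seed = 3),
    class = "ofmscreen_estimator_undefined"
  )
})

test_that("bootstrap percentile interval covers the true rate", {
  cover <- vapply(1:100, function(s) {
    a <- simulate_assay(5e-4, 1e4, 100, seed = 2000 + s)
    b <- bootstrap_ci(a, "lc_median", n_boot = 500, level = 0.95, seed = s)
    b$ci_low <= 5e-4 && 5e-4 <= b$ci_high
  }, logical(1))
  expect_gte(sum(cover), 90)
})
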