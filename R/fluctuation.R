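#' Luria-Delbruck probability mass function
#'
#' Probability of observing `r` loss-derived cells in a culture when loss
#' events occur at an expected `m` per culture and each loss clone grows at
#' the same rate as the rest of the population (the classical
#' Luria-Delbruck / Lea-Coulson model). Computed by the standard recursion
#' \deqn{p_0 = e^{-m}, \qquad p_r = \frac{m}{r}\sum_{i=0}^{r-1}
#'   \frac{p_i}{r-i+1}.}
#'
#' @param m Expected number of loss events per culture (non-negative).
#' @param r_max Largest count to evaluate.
#' @return Numeric vector of probabilities for counts `0:r_max`, with
#'   attribute `truncation_mass` giving `1 - sum(p)`, the probability mass
#'   beyond `r_max`.
#' @examples
#' p <- ld_pmf(1, 5)
#' p[1] # exp(-1)
#' @export
ld_pmf <- function(m, r_max) {
  stopifnot(length(m) == 1, length(r_max) == 1, r_max >= 0)
  if (!is.finite(m) || m < 0) {
    rlang::abort("`m` must be a finite non-negative number.",
      class = "ofmscreen_domain_error"
    )
  }
  r_max <- as.integer(r_max)
  p <- numeric(r_max + 1L)
  p[1L] <- exp(-m)
  if (r_max >= 1L && m > 0) {
    for (r in seq_len(r_max)) {
      # weights 1/(r - i + 1) for i = 0..r-1, i.e. 1/(r+1), ..., 1/2
      p[r + 1L] <- m / r * sum(p[seq_len(r)] / ((r + 1L):2L))
    }
  }
  structure(p, truncation_mass = max(0, 1 - sum(p)))
}

validate_assay <- function(assay) {
  stopifnot(is.data.frame(assay))
  if (!all(c("loss_count", "culture_size") %in% names(assay))) {
    rlang::abort("An assay needs `loss_count` and `culture_size` columns.")
  }
  if (nrow(assay) < 1L) {
    rlang::abort("An assay needs at least one culture.")
  }
  r <- assay$loss_count
  n <- unique(assay$culture_size)
  if (length(n) != 1L) {
    rlang::abort("All cultures in one assay must share `culture_size`.")
  }
  if (any(r < 0) || any(r != floor(r))) {
    rlang::abort("`loss_count` must be non-negative integers.")
  }
  s <- n
  if ("cells_sampled" %in% names(assay) && !all(is.na(assay$cells_sampled))) {
    s <- unique(assay$cells_sampled)
    if (length(s) != 1L || is.na(s) || s <= 0 || s > n) {
      rlang::abort("`cells_sampled` must be a single value in (0, culture_size].")
    }
  }
  if (any(r > s)) {
    rlang::abort("`loss_count` cannot exceed the number of cells scored.")
  }
  list(counts = as.numeric(r), culture_size = as.numeric(n), cells_sampled = as.numeric(s))
}

new_loss_rate_est <- function(m_hat, culture_size, method, n_cultures,
                              ci_low = NA_real_, ci_high = NA_real_,
                              conf_level = NA_real_) {
  structure(
    list(
      m_hat = m_hat,
      rate_per_division = rate_from_m(m_hat, culture_size),
      culture_size = culture_size,
      method = method,
      n_cultures = n_cultures,
      ci_low = ci_low,
      ci_high = ci_high,
      conf_level = conf_level
    ),
    class = "loss_rate_est"
  )
}

#' @export
print.loss_rate_est <- function(x, ...) {
  cat(
    sprintf(
      "<loss_rate_est> method=%s  m_hat=%.4g  rate/division=%.4g  (n=%d cultures)\n",
      x$method, x$m_hat, x$rate_per_division, x$n_cultures
    )
  )
  if (!is.na(x$ci_low)) {
    cat(sprintf(
      "  %.0f%% CI on rate: [%.4g, %.4g]\n",
      100 * x$conf_level, x$ci_low, x$ci_high
    ))
  }
  invisible(x)
}

#' Convert expected events per culture to a per-division loss rate
#'
#' A colony grown from a single cell to `culture_size` cells has undergone
#' `culture_size - 1` divisions; the package takes the number of divisions as
#' `culture_size` itself, a negligible difference for the culture sizes used
#' in fluctuation assays (>= 10^3 cells).
#'
#' @param m_hat Expected loss events per culture.
#' @param culture_size Final cells per culture (>= 2).
#' @return Loss probability per cell division.
#' @export
rate_from_m <- function(m_hat, culture_size) {
  stopifnot(all(m_hat >= 0), all(culture_size >= 2))
  m_hat / culture_size
}

# Rescale an estimate made from a sampled subset of the culture back to the
# whole culture: under binomial thinning of the final population the observed
# process has m_obs = m * (cells_sampled / culture_size).
sampling_scale <- function(v) v$culture_size / v$cells_sampled

#' P0 estimator of the expected loss events per culture
#'
#' `m_hat = -log(P0)` where `P0` is the fraction of cultures with zero
#' loss-derived cells; valid because event counts per culture are Poisson.
#'
#' @param assay Data frame with `loss_count` and `culture_size` columns (and
#'   optionally `cells_sampled`), one row per culture.
#' @return A `loss_rate_est` object; see [tidy.loss_rate_est()].
#' @export
estimate_p0 <- function(assay) {
  v <- validate_assay(assay)
  frac0 <- mean(v$counts == 0)
  if (frac0 == 0) {
    rlang::abort(
      "No culture has a zero count; the P0 estimator is undefined. Use estimate_lc_median() or estimate_mss_mle().",
      class = "ofmscreen_estimator_undefined"
    )
  }
  m_hat <- -log(frac0) * sampling_scale(v)
  new_loss_rate_est(m_hat, v$culture_size, "p0", length(v$counts))
}

# Solve median_count / m - log(m) = 1.24 for m > 0. The left side is strictly
# decreasing in m, so the root is unique; bracketing is done in log space.
lc_median_root <- function(median_count, constant = 1.24, tol = 1e-10) {
  stopifnot(median_count > 0)
  f <- function(logm) {
    m <- exp(logm)
    median_count / m - logm - constant
  }
  stats::uniroot(f, lower = log(1e-6), upper = log(1e6), tol = tol)$root |> exp()
}

#' Lea-Coulson median estimator
#'
#' Solves the Lea-Coulson median equation
#' \eqn{\tilde r / m - \ln m = 1.24} for `m`, where \eqn{\tilde r} is the
#' median per-culture count (lower median for even culture numbers).
#'
#' @inheritParams estimate_p0
#' @return A `loss_rate_est` object.
#' @export
estimate_lc_median <- function(assay) {
  v <- validate_assay(assay)
  med <- lower_median(v$counts)
  if (med == 0) {
    rlang::abort(
      "The median count is 0; the Lea-Coulson median estimator is undefined. Use estimate_p0().",
      class = "ofmscreen_estimator_undefined"
    )
  }
  m_hat <- lc_median_root(med) * sampling_scale(v)
  new_loss_rate_est(m_hat, v$culture_size, "lc_median", length(v$counts))
}

# Log-likelihood of m for observed counts under ld_pmf, right-censoring
# counts >= cap (standard jackpot handling: the exact size of a jackpot
# carries almost no information about m and would need an O(r^2) recursion).
ld_loglik <- function(m, counts, cap) {
  p <- ld_pmf(m, cap - 1L)
  tail_mass <- max(attr(p, "truncation_mass"), 1e-300)
  p <- pmax(p, 1e-300)
  cens <- counts >= cap
  sum(log(p[counts[!cens] + 1L])) + sum(cens) * log(tail_mass)
}

#' Maximum-likelihood estimator under the Luria-Delbruck distribution
#'
#' Maximises the likelihood of the per-culture counts under [ld_pmf()]
#' (the Ma-Sandri-Sarkar approach), bracketing the optimum a factor of 10
#' either side of the Lea-Coulson median (or P0) starting value. Counts of
#' `cap` or more are treated as right-censored.
#'
#' @inheritParams estimate_p0
#' @param cap Counts at or above this value enter the likelihood through the
#'   upper-tail mass only.
#' @return A `loss_rate_est` object.
#' @export
estimate_mss_mle <- function(assay, cap = 1024L) {
  v <- validate_assay(assay)
  counts <- as.integer(pmin(v$counts, cap))
  if (all(counts == 0)) {
    rlang::warn("All counts are zero; the MLE sits on the boundary m = 0.")
    return(new_loss_rate_est(0, v$culture_size, "mss_mle", length(counts)))
  }
  med <- lower_median(counts)
  m0 <- if (med > 0) lc_median_root(med) else -log(mean(counts == 0))
  m0 <- max(m0, 1e-4)
  opt <- stats::optimize(
    function(logm) ld_loglik(exp(logm), counts, cap),
    interval = log(c(m0 / 10, m0 * 10)),
    maximum = TRUE,
    tol = 1e-8
  )
  m_hat <- exp(opt$maximum) * sampling_scale(v)
  new_loss_rate_est(m_hat, v$culture_size, "mss_mle", length(v$counts))
}

#' Estimate a per-division loss rate from a fluctuation assay
#'
#' Front end dispatching to the three estimators. `method = "auto"` uses the
#' Lea-Coulson median estimator when the median count is positive and falls
#' back to P0 otherwise (the usual regime for very stable constructs).
#'
#' @inheritParams estimate_p0
#' @param method One of `"lc_median"`, `"p0"`, `"mss_mle"`, `"auto"`.
#' @param ... Passed on to the chosen estimator.
#' @return A `loss_rate_est` object.
#' @export
estimate_loss_rate <- function(assay,
                               method = c("lc_median", "p0", "mss_mle", "auto"),
                               ...) {
  method <- match.arg(method)
  if (method == "auto") {
    v <- validate_assay(assay)
    method <- if (lower_median(v$counts) > 0) "lc_median" else "p0"
  }
  switch(method,
    lc_median = estimate_lc_median(assay),
    p0 = estimate_p0(assay),
    mss_mle = estimate_mss_mle(assay, ...)
  )
}

#' Bootstrap percentile confidence interval for a loss-rate estimate
#'
#' Resamples cultures with replacement, re-estimates, and reports the
#' percentile interval. Resamples on which the estimator is undefined (for
#' example, no zero-count culture for P0) are dropped; more than 50% of them
#' failing is an error.
#'
#' @inheritParams estimate_loss_rate
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return The input estimate (`loss_rate_est`) with `ci_low`, `ci_high`
#'   (per-division rate scale) and `conf_level` filled in.
#' @export
bootstrap_ci <- function(assay, method = "lc_median", n_boot = 1000L,
                         level = 0.95, seed = NULL, ...) {
  stopifnot(n_boot >= 100, level > 0, level < 1)
  est <- estimate_loss_rate(assay, method = method, ...)
  rates <- with_seed(seed, {
    purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(assay), replace = TRUE)
      tryCatch(
        estimate_loss_rate(assay[idx, , drop = FALSE], method = method, ...)$rate_per_division,
        ofmscreen_estimator_undefined = function(e) NA_real_
      )
    })
  })
  if (mean(is.na(rates)) > 0.5) {
    rlang::abort(
      "The estimator was undefined on more than half of the bootstrap resamples.",
      class = "ofmscreen_estimator_undefined"
    )
  }
  qs <- stats::quantile(rates, c((1 - level) / 2, 1 - (1 - level) / 2),
    na.rm = TRUE, names = FALSE
  )
  est$ci_low <- qs[1]
  est$ci_high <- qs[2]
  est$conf_level <- level
  est
}

#' Simulate a fluctuation assay under the Luria-Delbruck loss process
#'
#' For each culture the number of loss events is Poisson with mean
#' `rate * culture_size`; each event strikes a lineage while the population
#' grows, at a point uniform over the divisions (equivalently uniform over
#' population size), and its clone expands to the final population alongside
#' everyone else, so a clone born when the culture had `j` cells ends with
#' roughly `culture_size / j` cells. Loss lineages grow at `relative_fitness`
#' times the rate of fragment-bearing lineages (default 1, the assumption
#' under which the Lea-Coulson machinery applies).
#'
#' @param rate Per-division loss probability in `[0, 1]`.
#' @param culture_size Final cells per culture (>= 2).
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed; counts are deterministic given the seed.
#' @param cells_sampled If only a sample of each culture is scored, the
#'   number of cells scored; counts are binomially thinned accordingly.
#' @param relative_fitness Growth rate of loss lineages relative to
#'   fragment-bearing lineages.
#' @param label Optional strain/construct label stored in a `strain` column.
#' @return A tibble with one row per culture: `culture_id`, `loss_count`,
#'   `culture_size` (plus `cells_sampled` and `strain` when supplied), with
#'   the true rate and seed stored as attributes.
#' @export
simulate_assay <- function(rate, culture_size, n_cultures, seed = NULL,
                           cells_sampled = NULL, relative_fitness = 1,
                           label = NULL) {
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    rlang::abort("`rate` must be a probability in [0, 1].",
      class = "ofmscreen_domain_error"
    )
  }
  stopifnot(culture_size >= 2, n_cultures >= 1, relative_fitness > 0)
  n_final <- culture_size
  m <- rate * n_final
  counts <- with_seed(seed, {
    k <- stats::rpois(n_cultures, m)
    total <- sum(k)
    out <- numeric(n_cultures)
    if (total > 0) {
      # population size at which each event occurs, uniform over divisions
      j <- ceiling(stats::runif(total) * n_final)
      clone <- pmax(1, floor((n_final / j)^relative_fitness))
      grp <- rep.int(seq_len(n_cultures), k)
      sums <- rowsum(clone, grp)
      out[as.integer(rownames(sums))] <- sums[, 1L]
    }
    out <- pmin(out, n_final)
    if (!is.null(cells_sampled)) {
      stopifnot(cells_sampled >= 1, cells_sampled <= n_final)
      # scoring a sample of the culture: hypergeometric draw of loss-derived
      # cells among the cells_sampled cells actually plated
      out <- stats::rhyper(n_cultures, m = out, n = n_final - out, k = cells_sampled)
    }
    out
  })
  res <- tibble::tibble(
    culture_id = seq_len(n_cultures),
    loss_count = as.integer(counts),
    culture_size = as.integer(culture_size)
  )
  if (!is.null(cells_sampled)) {
    res$cells_sampled <- as.integer(cells_sampled)
  }
  if (!is.null(label)) {
    res <- tibble::add_column(res, strain = label, .before = 1)
  }
  attr(res, "true_rate") <- rate
  attr(res, "seed") <- seed
  res
}
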