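#' Simulate visible red sectors in colonies losing a marked chromosome
#'
#' Grows each colony as a synchronous binary division tree from a single
#' fragment-bearing founder. At every division of a fragment-bearing cell,
#' with probability `loss_rate` exactly one daughter loses the ADE2-marked
#' fragment; that event founds one visible red sector. Loss events inside
#' already-red lineages create no new sector (nested losses merge under
#' visual scoring), and red lineages keep growing at the same rate, so the
#' number of fragment-bearing cells follows
#' `W(g+1) = 2 W(g) - Binomial(W(g), loss_rate)`. Only events within the
#' first `generations` divisions found a sector large enough to see: a
#' sector founded later is too small a fraction of the colony to score by
#' eye, which is why the horizon is bounded.
#'
#' The expected visible sector count is
#' \eqn{\sum_{g=0}^{G-1} \mu (2-\mu)^g}.
#'
#' @param loss_rate Per-division loss probability in `[0, 1]`.
#' @param generations Visibility horizon `G` (1-24). The default of 9 is
#'   the horizon at which the three calibration anchor rates (2.1e-3, 1e-2,
#'   1e-1 per division) land in the three semi-quantitative classes.
#' @param n_colonies Number of colonies to simulate.
#' @param seed Optional integer seed.
#' @return Integer vector of visible sector counts, one per colony.
#' @examples
#' median(simulate_sectors(2.1e-3, n_colonies = 200, seed = 1))
#' @export
simulate_sectors <- function(loss_rate, generations = 9L, n_colonies = 1L,
                             seed = NULL) {
  if (!is.finite(loss_rate) || loss_rate < 0 || loss_rate > 1) {
    rlang::abort("`loss_rate` must be a probability in [0, 1].",
      class = "ofmscreen_domain_error"
    )
  }
  stopifnot(generations >= 1, generations <= 24, n_colonies >= 1)
  with_seed(seed, {
    white <- rep.int(1, n_colonies)
    sectors <- integer(n_colonies)
    for (g in seq_len(generations)) {
      losses <- stats::rbinom(n_colonies, size = white, prob = loss_rate)
      sectors <- sectors + losses
      white <- 2 * white - losses
    }
    sectors
  })
}

#' Classify a colony-sectoring level into the screen's semi-quantitative bins
#'
#' Median visible sectors per colony map to the three classes used when
#' scoring chromoductants on limiting adenine: 0-3 sectors is the level seen
#' with a per-division loss rate around 2e-3 (`wildtype_like`), 5-10 sectors
#' corresponds to rates around 1e-2 (`elevated`), and 10 or more to rates
#' around 1e-1 (`high`). A median of 4, which the verbal scale leaves
#' unassigned, is classified `elevated`.
#'
#' @param median_count Median visible sectors per colony (>= 0). Vectorised.
#' @return Character vector: `"wildtype_like"`, `"elevated"` or `"high"`.
#' @export
classify_sectors <- function(median_count) {
  stopifnot(all(median_count >= 0))
  dplyr::case_when(
    median_count >= 10 ~ "high",
    median_count >= 4 ~ "elevated",
    TRUE ~ "wildtype_like"
  )
}

sector_classes <- c("wildtype_like", "elevated", "high")

#' Screen verdict from duplicate chromoductant sectoring classes
#'
#' Applies the secondary-screen decision rules to the sectoring classes of
#' two independent chromoductants per construct:
#'
#' * `non_Ofm` — both 0ORID-DR chromoductants sector highly (the construct
#'   with a full origin complement is also destabilised, as for a general
#'   chromosome-transmission defect);
#' * `not_a_hit` — both 5ORID-DR chromoductants look wild-type;
#' * `Ofm` — both 5ORID-DR chromoductants are elevated or high while both
#'   0ORID-DR chromoductants look wild-type;
#' * `possible_probable` — everything else, notably discordant duplicates.
#'
#' @param class5_rep1,class5_rep2 Sectoring classes of the two 5ORID-DR
#'   chromoductants.
#' @param class0_rep1,class0_rep2 Sectoring classes of the two 0ORID-DR
#'   chromoductants.
#' @return One of `"Ofm"`, `"possible_probable"`, `"non_Ofm"`,
#'   `"not_a_hit"`.
#' @export
screen_call <- function(class5_rep1, class5_rep2, class0_rep1, class0_rep2) {
  cls <- c(class5_rep1, class5_rep2, class0_rep1, class0_rep2)
  if (!all(cls %in% sector_classes)) {
    rlang::abort(sprintf(
      "Sector classes must be one of: %s.",
      paste(sector_classes, collapse = ", ")
    ))
  }
  c5 <- cls[1:2]
  c0 <- cls[3:4]
  if (all(c0 == "high")) {
    "non_Ofm"
  } else if (all(c5 == "wildtype_like")) {
    "not_a_hit"
  } else if (all(c5 %in% c("elevated", "high")) && all(c0 == "wildtype_like")) {
    "Ofm"
  } else {
    "possible_probable"
  }
}

#' Sectoring calibration curve over a grid of loss rates
#'
#' Simulates colonies at each loss rate (the same seed is reused across
#' rates, giving common random numbers) and reports the median sector count
#' and its class. This is the package's in-silico version of calibrating the
#' visual sectoring scale against fluctuation-measured loss rates.
#'
#' @param mu_grid Loss rates in `[0, 1]`.
#' @param generations Visibility horizon.
#' @param n_colonies Colonies per rate.
#' @param seed Optional integer seed.
#' @return A tibble of class `ofm_calibration`: `mu`, `median_sectors`,
#'   `class`.
#' @examples
#' calibration_curve(c(2.1e-3, 1e-2, 1e-1), seed = 1)
#' @export
calibration_curve <- function(mu_grid, generations = 9L, n_colonies = 500L,
                              seed = NULL) {
  stopifnot(all(mu_grid >= 0), all(mu_grid <= 1))
  med <- purrr::map_dbl(
    mu_grid,
    function(mu) {
      lower_median(simulate_sectors(mu, generations, n_colonies, seed = seed))
    }
  )
  out <- tibble::tibble(
    mu = mu_grid,
    median_sectors = med,
    class = classify_sectors(med)
  )
  class(out) <- c("ofm_calibration", class(out))
  attr(out, "generations") <- generations
  attr(out, "n_colonies") <- n_colonies
  attr(out, "seed") <- seed
  out
}

# Exact distribution of visible sector counts at small G by dynamic
# programming over (white-cell count, sectors so far). Used as an
# enumeration oracle in tests; exported for completeness of the colony
# model's analysis tools.

#' Exact sector-count distribution for small visibility horizons
#'
#' Enumerates the colony division tree exactly: the state after each
#' generation is the number of fragment-bearing cells, and loss events per
#' generation are binomial. Feasible for `generations` up to ~8.
#'
#' @inheritParams simulate_sectors
#' @param max_sectors Largest sector count to tabulate.
#' @return A tibble `sectors`, `prob` summing to 1.
#' @export
sector_distribution_exact <- function(loss_rate, generations = 3L,
                                      max_sectors = 64L) {
  stopifnot(generations >= 1, generations <= 8)
  # dist: named list keyed by white count, each a prob vector over sectors
  white_max <- 2^generations
  # matrix P[w+1, s+1] = P(white = w, sectors = s)
  P <- matrix(0, nrow = white_max + 1, ncol = max_sectors + 1)
  P[2, 1] <- 1 # start: 1 white cell, 0 sectors
  for (g in seq_len(generations)) {
    Q <- matrix(0, nrow = white_max + 1, ncol = max_sectors + 1)
    for (w in which(rowSums(P) > 0) - 1L) {
      probs_l <- stats::dbinom(0:w, w, loss_rate)
      for (s in which(P[w + 1, ] > 0) - 1L) {
        mass <- P[w + 1, s + 1]
        for (l in 0:w) {
          if (probs_l[l + 1] == 0) next
          s2 <- min(s + l, max_sectors)
          Q[2 * w - l + 1, s2 + 1] <- Q[2 * w - l + 1, s2 + 1] + mass * probs_l[l + 1]
        }
      }
    }
    P <- Q
  }
  tibble::tibble(sectors = 0:max_sectors, prob = colSums(P))
}
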