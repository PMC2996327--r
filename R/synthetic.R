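# Virtual strain panels and end-to-end screen simulation.

panel_archetypes <- c("wildtype_like", "ofm_like", "general_instability", "intermediate")

# Anchor per-division loss rates of the reference (wild-type) strain:
# 2.1e-3 for the origin-depleted 5ORID-DR fragment and 3e-5 for the
# origin-replete 0ORID-DR fragment, the tabulated reference values.
wt_anchor_rates <- c("5ORID-DR" = 2.1e-3, "0ORID-DR" = 3e-5)

#' Generate a panel of virtual strains with known loss rates
#'
#' Each strain carries true per-division loss rates for the 5ORID-DR and
#' 0ORID-DR constructs, drawn according to its archetype:
#'
#' * `wildtype_like` — the anchor rates themselves;
#' * `ofm_like` — the 5ORID-DR rate multiplied log-uniformly by 5-50 while
#'   the 0ORID-DR rate is multiplied by only 1-4 (a gap-replication defect);
#' * `general_instability` — both rates share one log-uniform multiplier of
#'   300-3000 (capped at 0.5 per division), emulating a chromosome
#'   transmission defect strong enough that the origin-replete construct
#'   sectors visibly;
#' * `intermediate` — both rates share a log-uniform 30-300 multiplier.
#'
#' @param n_strains Panel size.
#' @param archetype_mix Named proportions over the archetypes (summing
#'   to 1). Counts are allocated deterministically by largest remainder.
#' @param seed Optional integer seed; the panel is reproducible given it.
#' @return A tibble: `strain`, `archetype`, `rate5`, `rate0` (per-division
#'   probabilities).
#' @examples
#' make_panel(10, c(wildtype_like = 0.8, ofm_like = 0.2), seed = 1)
#' @export
make_panel <- function(n_strains,
                       archetype_mix = c(
                         wildtype_like = 0.8, ofm_like = 0.1,
                         general_instability = 0.1
                       ),
                       seed = NULL) {
  stopifnot(n_strains >= 1)
  if (is.null(names(archetype_mix)) ||
    !all(names(archetype_mix) %in% panel_archetypes) ||
    any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-8) {
    rlang::abort("`archetype_mix` must be named proportions over the archetypes summing to 1.")
  }
  counts <- diff(c(0, floor(cumsum(archetype_mix) * n_strains + 1e-9)))
  archetype <- rep(names(archetype_mix), counts)
  with_seed(seed, {
    draws <- purrr::map(archetype, function(a) {
      switch(a,
        wildtype_like = c(1, 1),
        ofm_like = c(
          exp(stats::runif(1, log(5), log(50))),
          stats::runif(1, 1, 4)
        ),
        general_instability = rep(exp(stats::runif(1, log(300), log(3000))), 2),
        intermediate = rep(exp(stats::runif(1, log(30), log(300))), 2)
      )
    })
    tibble::tibble(
      strain = sprintf("virt%03d_%s", seq_along(archetype), archetype),
      archetype = archetype,
      rate5 = pmin(0.5, wt_anchor_rates[["5ORID-DR"]] * purrr::map_dbl(draws, 1)),
      rate0 = pmin(0.5, wt_anchor_rates[["0ORID-DR"]] * purrr::map_dbl(draws, 2))
    )
  })
}

#' Run the full virtual sectoring-and-fluctuation screen on a panel
#'
#' Mirrors the two-stage screen: for every strain, duplicate chromoductants
#' carrying each construct are streaked and their colony sectoring classes
#' scored ([simulate_sectors()], [classify_sectors()], [screen_call()]);
#' strains called `Ofm` or `possible_probable` then go through fluctuation
#' assays for both constructs ([simulate_assay()]) and rate estimation
#' ([estimate_loss_rate()] with automatic estimator choice), and an Ofm
#' index is computed from the estimated rates against estimated wild-type
#' baseline rates. The origin-replete construct is assayed with larger
#' cultures because its loss rate is two orders of magnitude lower.
#'
#' @param panel A tibble from [make_panel()].
#' @param generations,n_colonies Sectoring-stage parameters.
#' @param n_cultures,culture_size_5,culture_size_0 Fluctuation-stage
#'   parameters (culture sizes for the 5ORID-DR and 0ORID-DR assays).
#' @param seed Integer master seed; every stochastic stage receives an
#'   explicit sub-seed derived from it, so the whole screen is reproducible.
#' @param ofm_threshold,non_ofm_threshold Index classification thresholds
#'   (see [score_ofm()]).
#' @return A list of class `virtual_screen`: `per_strain` (truth, sector
#'   classes, verdict, estimated rates, true and estimated Ofm index),
#'   `confusion` (verdict x archetype counts), `baseline` (estimated
#'   baseline rates), `seed`.
#' @export
run_virtual_screen <- function(panel,
                               generations = 9L, n_colonies = 500L,
                               n_cultures = 50L,
                               culture_size_5 = 1e4, culture_size_0 = 1e5,
                               seed = NULL,
                               ofm_threshold = 20, non_ofm_threshold = 10) {
  stopifnot(is.data.frame(panel), all(c("strain", "archetype", "rate5", "rate0") %in% names(panel)))
  n <- nrow(panel)
  seeds <- derive_seeds(seed, 4L * n + 4L)

  est_rate_e5 <- function(rate, culture_size, s) {
    assay <- simulate_assay(rate, culture_size, n_cultures, seed = s)
    estimate_loss_rate(assay, method = "auto")$rate_per_division * 1e5
  }

  # estimated baseline (wild-type anchor strain run through the same assay)
  base5_e5 <- est_rate_e5(wt_anchor_rates[["5ORID-DR"]], culture_size_5, seeds[4L * n + 1L])
  base0_e5 <- est_rate_e5(wt_anchor_rates[["0ORID-DR"]], culture_size_0, seeds[4L * n + 2L])

  per_strain <- purrr::map_dfr(seq_len(n), function(i) {
    s4 <- seeds[(4L * (i - 1L) + 1L):(4L * i)]
    med <- function(mu, s) {
      lower_median(simulate_sectors(mu, generations, n_colonies, seed = s))
    }
    m5 <- c(med(panel$rate5[i], s4[1]), med(panel$rate5[i], s4[2]))
    m0 <- c(med(panel$rate0[i], s4[3]), med(panel$rate0[i], s4[4]))
    cls5 <- classify_sectors(m5)
    cls0 <- classify_sectors(m0)
    tibble::tibble(
      strain = panel$strain[i],
      archetype = panel$archetype[i],
      rate5_true = panel$rate5[i],
      rate0_true = panel$rate0[i],
      class5_rep1 = cls5[1], class5_rep2 = cls5[2],
      class0_rep1 = cls0[1], class0_rep2 = cls0[2],
      verdict = screen_call(cls5[1], cls5[2], cls0[1], cls0[2])
    )
  })

  called <- per_strain$verdict %in% c("Ofm", "possible_probable")
  assay_seeds <- derive_seeds(seeds[4L * n + 3L], 2L * n)
  est <- purrr::map_dfr(seq_len(n), function(i) {
    if (!called[i]) {
      return(tibble::tibble(rate5_est_e5 = NA_real_, rate0_est_e5 = NA_real_))
    }
    tibble::tibble(
      rate5_est_e5 = est_rate_e5(panel$rate5[i], culture_size_5, assay_seeds[2L * i - 1L]),
      rate0_est_e5 = est_rate_e5(panel$rate0[i], culture_size_0, assay_seeds[2L * i])
    )
  })
  per_strain <- dplyr::bind_cols(per_strain, est)
  per_strain$index_true <- ofm_index(
    per_strain$rate5_true * 1e5, wt_anchor_rates[["5ORID-DR"]] * 1e5,
    per_strain$rate0_true * 1e5, wt_anchor_rates[["0ORID-DR"]] * 1e5
  )
  per_strain$index_est <- ifelse(
    called,
    ofm_index(per_strain$rate5_est_e5, base5_e5, per_strain$rate0_est_e5, base0_e5),
    NA_real_
  )

  confusion <- per_strain |>
    dplyr::count(.data$archetype, .data$verdict, name = "n") |>
    tidyr::complete(
      archetype = unique(per_strain$archetype),
      verdict = c("Ofm", "possible_probable", "non_Ofm", "not_a_hit"),
      fill = list(n = 0L)
    )

  structure(
    list(
      per_strain = per_strain,
      confusion = confusion,
      baseline = c("5ORID-DR" = base5_e5, "0ORID-DR" = base0_e5),
      seed = seed
    ),
    class = "virtual_screen"
  )
}

#' @export
print.virtual_screen <- function(x, ...) {
  tab <- tidyr::pivot_wider(x$confusion,
    names_from = "verdict", values_from = "n"
  )
  cat(sprintf(
    "<virtual_screen> %d strains (seed %s)\n",
    nrow(x$per_strain), format(x$seed)
  ))
  print(tab)
  invisible(x)
}
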