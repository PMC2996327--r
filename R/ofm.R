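#' Ofm index from four loss rates
#'
#' The Ofm (originless fragment maintenance) index contrasts how strongly a
#' mutation destabilises the origin-depleted 5ORID-DR chromosome III
#' derivative versus the origin-replete 0ORID-DR derivative:
#' \deqn{\mathrm{Ofm} = \frac{\mu_5^{mut} - \mu_5^{base}}
#'                           {\mu_0^{mut} - \mu_0^{base}},}
#' the ratio of additional loss events per \eqn{10^5} divisions sustained by
#' each derivative relative to a baseline strain. A mutation that
#' destabilises both derivatives equally (a kinetochore defect, say) scores
#' near 1; a defect specific to replicating the long inter-origin gap scores
#' high. The index is scale-invariant, so rates may be supplied in any common
#' unit (the conventional display unit is \eqn{10^{-5}} per division).
#'
#' @param mut5,base5 Loss rates of the 5ORID-DR derivative in the mutant and
#'   baseline strains.
#' @param mut0,base0 Loss rates of the 0ORID-DR derivative in the mutant and
#'   baseline strains.
#' @return The index, or `NA` when the denominator is not positive (the
#'   baseline strain scored against itself yields 0/0, conventionally
#'   reported as "not defined"). A negative numerator over a positive
#'   denominator is returned as the negative value it is. Vectorised.
#' @examples
#' ofm_index(500, 100, 401, 1) # 1: equal destabilisation
#' ofm_index(1000, 100, 11, 1) # 90: gap-specific defect
#' @export
ofm_index <- function(mut5, base5, mut0, base0) {
  args <- vctrs_recycle(mut5, base5, mut0, base0)
  if (any(unlist(args) < 0, na.rm = TRUE)) {
    rlang::abort("Loss rates must be non-negative.",
      class = "ofmscreen_domain_error"
    )
  }
  num <- args[[1]] - args[[2]]
  den <- args[[3]] - args[[4]]
  ifelse(den > 0, num / den, NA_real_)
}

# minimal common-length recycling for scalar-or-vector numeric args
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' First-order (delta-method) standard deviation of the Ofm index
#'
#' Propagates independent rate standard deviations through the ratio of
#' differences. With numerator `N = mut5 - base5` and denominator
#' `D = mut0 - base0`, \eqn{\mathrm{SD} \approx \sqrt{\sigma_N^2/D^2 +
#' N^2\sigma_D^2/D^4}}. The linearisation is only trustworthy when the
#' denominator's coefficient of variation is small (roughly < 20%); for
#' noisier denominators the true sampling distribution of the index is
#' heavy-tailed and this value understates the spread.
#'
#' @inheritParams ofm_index
#' @param sd5,sdb5,sd0,sdb0 Standard deviations of the four rates, same
#'   units.
#' @return Approximate standard deviation of the index.
#' @export
ofm_index_sd <- function(mut5, sd5, base5, sdb5, mut0, sd0, base0, sdb0) {
  idx <- ofm_index(mut5, base5, mut0, base0)
  if (any(is.na(idx))) {
    rlang::abort("The Ofm index is undefined here; no SD can be propagated.")
  }
  stopifnot(all(c(sd5, sdb5, sd0, sdb0) >= 0))
  num <- mut5 - base5
  den <- mut0 - base0
  var_num <- sd5^2 + sdb5^2
  var_den <- sd0^2 + sdb0^2
  sqrt(var_num / den^2 + num^2 * var_den / den^4)
}

#' Score strains for the Ofm phenotype against a baseline strain
#'
#' Takes a long loss-rate table (one row per strain x construct), computes
#' each strain's Ofm index against the chosen baseline strain — which
#' supplies both baseline rates — and classifies:
#'
#' * `Ofm` — index defined, at least `ofm_threshold`, and the mutant's
#'   5ORID-DR rate at least `destab_fold` times the baseline's (a guard
#'   against large indices arising without real destabilisation);
#' * `non-Ofm` — index defined and below `non_ofm_threshold`;
#' * `indeterminate` — everything else, including undefined indices.
#'
#' @param rates Data frame with columns `strain`, `construct`, `rate_e5` and
#'   optionally `sd_e5`; rates in units of 1e-5 per division as
#'   conventionally tabulated. Greek-letter construct spellings are accepted.
#' @param baseline Strain name supplying both baseline rates.
#' @param ofm_threshold,non_ofm_threshold,destab_fold Classification
#'   thresholds (defaults 20, 10 and 2).
#' @return A tibble with one row per non-baseline strain: `strain`,
#'   `baseline`, `index`, `index_sd`, `rounded_index` (half away from zero),
#'   `call`.
#' @examples
#' score_ofm(table2_rates(), baseline = "Wild Type")
#' @export
score_ofm <- function(rates, baseline = "Wild Type", ofm_threshold = 20,
                      non_ofm_threshold = 10, destab_fold = 2) {
  stopifnot(is.data.frame(rates))
  rates <- dplyr::mutate(rates, construct = canonical_construct(.data$construct))
  if (!"sd_e5" %in% names(rates)) {
    rates$sd_e5 <- NA_real_
  }
  get_rate <- function(strain, construct) {
    row <- dplyr::filter(rates, .data$strain == !!strain, .data$construct == !!construct)
    if (nrow(row) == 0 || is.na(row$rate_e5[1])) {
      rlang::abort(sprintf(
        "Strain '%s' has no rate for construct '%s'.", strain, construct
      ))
    }
    list(rate = row$rate_e5[1], sd = row$sd_e5[1])
  }
  base5 <- get_rate(baseline, "5ORID-DR")
  base0 <- get_rate(baseline, "0ORID-DR")
  strains <- setdiff(unique(rates$strain), baseline)
  purrr::map_dfr(strains, function(s) {
    mut5 <- get_rate(s, "5ORID-DR")
    mut0 <- get_rate(s, "0ORID-DR")
    idx <- ofm_index(mut5$rate, base5$rate, mut0$rate, base0$rate)
    idx_sd <- if (!is.na(idx) && !anyNA(c(mut5$sd, base5$sd, mut0$sd, base0$sd))) {
      ofm_index_sd(
        mut5$rate, mut5$sd, base5$rate, base5$sd,
        mut0$rate, mut0$sd, base0$rate, base0$sd
      )
    } else {
      NA_real_
    }
    call <- if (is.na(idx)) {
      "indeterminate"
    } else if (idx >= ofm_threshold && mut5$rate >= destab_fold * base5$rate) {
      "Ofm"
    } else if (idx < non_ofm_threshold) {
      "non-Ofm"
    } else {
      "indeterminate"
    }
    tibble::tibble(
      strain = s,
      baseline = baseline,
      index = idx,
      index_sd = idx_sd,
      rounded_index = if (is.na(idx)) NA_real_ else round_half_away(idx),
      call = call
    )
  })
}
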