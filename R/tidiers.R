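# broom-style tidiers for the package's fitted/simulated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a loss-rate estimate
#'
#' @param x A `loss_rate_est`.
#' @param ... Unused.
#' @return One-row tibble: `method`, `m_hat`, `rate_per_division`,
#'   `rate_e5`, `ci_low_e5`, `ci_high_e5`, `n_cultures`.
#' @method tidy loss_rate_est
#' @export
tidy.loss_rate_est <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    m_hat = x$m_hat,
    rate_per_division = x$rate_per_division,
    rate_e5 = x$rate_per_division * 1e5,
    ci_low_e5 = x$ci_low * 1e5,
    ci_high_e5 = x$ci_high * 1e5,
    n_cultures = x$n_cultures
  )
}

#' @rdname tidy.loss_rate_est
#' @method glance loss_rate_est
#' @export
glance.loss_rate_est <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_cultures = x$n_cultures,
    culture_size = x$culture_size,
    conf_level = x$conf_level
  )
}

#' Tidy a replication simulation
#'
#' `tidy()` returns per-origin firing fractions; `glance()` the whole-cell
#' summary.
#'
#' @param x A `replication_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy replication_sim
#' @export
tidy.replication_sim <- function(x, ...) {
  dplyr::mutate(x$firing, construct = x$construct, regime = x$regime)
}

#' @rdname tidy.replication_sim
#' @method glance replication_sim
#' @export
glance.replication_sim <- function(x, ...) {
  tibble::tibble(
    construct = x$construct,
    regime = x$regime,
    incomplete_fraction = x$incomplete_fraction,
    se = x$se,
    mean_unreplicated_kb = x$mean_unreplicated_kb,
    n = x$n
  )
}

#' Tidy a virtual screen
#'
#' `tidy()` returns the per-strain results table; `glance()` summary
#' counts and recovery statistics.
#'
#' @param x A `virtual_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy virtual_screen
#' @export
tidy.virtual_screen <- function(x, ...) {
  x$per_strain
}

#' @rdname tidy.virtual_screen
#' @method glance virtual_screen
#' @export
glance.virtual_screen <- function(x, ...) {
  ps <- x$per_strain
  ofm_truth <- ps$archetype == "ofm_like"
  tibble::tibble(
    n_strains = nrow(ps),
    n_called_ofm = sum(ps$verdict == "Ofm"),
    sensitivity_ofm = if (any(ofm_truth)) {
      mean(ps$verdict[ofm_truth] == "Ofm")
    } else {
      NA_real_
    },
    false_ofm_general = sum(ps$verdict == "Ofm" & ps$archetype == "general_instability")
  )
}
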