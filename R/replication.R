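#' Distance a replication fork travels in a given time
#'
#' @param speed_kb_min Fork speed in kb per minute (> 0).
#' @param time_min Elapsed time in minutes (>= 0).
#' @return Distance in kb. Vectorised.
#' @examples
#' fork_reach(2.3, 55) # ~126 kb: one fork over a full S phase
#' fork_reach(2.3, 27.5) # ~63 kb: an origin firing mid S phase
#' @export
fork_reach <- function(speed_kb_min, time_min) {
  stopifnot(all(speed_kb_min > 0), all(time_min >= 0))
  speed_kb_min * time_min
}

#' Build an origin map for a chromosome construct
#'
#' @param origins Data frame with columns `origin`, `position_kb`,
#'   `competence` (probability the origin is licensed in a given cell
#'   cycle), `t_mean_min`, `t_sd_min` (firing-time distribution, minutes
#'   into S phase; the draw is truncated at 0) and logical `dormant`
#'   (normally passively replicated; late `t_mean_min`).
#' @param length_kb Construct length in kb.
#' @param name Construct name.
#' @return A tibble of class `origin_map`, sorted by position, with
#'   attributes `length_kb` and `construct`.
#' @export
origin_map <- function(origins, length_kb, name = "custom") {
  stopifnot(is.data.frame(origins), length_kb > 0)
  need <- c("origin", "position_kb", "competence", "t_mean_min", "t_sd_min", "dormant")
  if (!all(need %in% names(origins))) {
    rlang::abort(paste0(
      "An origin map needs columns: ", paste(need, collapse = ", "), "."
    ))
  }
  if (any(origins$position_kb < 0 | origins$position_kb > length_kb)) {
    rlang::abort("Origin positions must lie within [0, length_kb].")
  }
  stopifnot(
    all(origins$competence >= 0 & origins$competence <= 1),
    all(origins$t_sd_min >= 0),
    !anyDuplicated(origins$position_kb)
  )
  out <- tibble::as_tibble(origins)[order(origins$position_kb), need]
  class(out) <- c("origin_map", class(out))
  attr(out, "length_kb") <- length_kb
  attr(out, "construct") <- name
  out
}

# Efficiency classes used by the packaged maps: efficient origins are active
# in >= 90% of cell cycles, inefficient ones in 15-25%, and dormant origins
# are licensed but programmed to fire late, so they are normally replicated
# passively by an incoming fork first.
.origin_row <- function(origin, position_kb, class) {
  switch(class,
    efficient = tibble::tibble(
      origin = origin, position_kb = position_kb, competence = 0.9,
      t_mean_min = 10, t_sd_min = 4, dormant = FALSE
    ),
    inefficient = tibble::tibble(
      origin = origin, position_kb = position_kb, competence = 0.2,
      t_mean_min = 25, t_sd_min = 5, dormant = FALSE
    ),
    dormant = tibble::tibble(
      origin = origin, position_kb = position_kb, competence = 0.9,
      t_mean_min = 50, t_sd_min = 5, dormant = TRUE
    )
  )
}

#' Packaged chromosome III derivative origin maps
#'
#' Stylised maps of the four constructs used throughout the package. The
#' coordinates are a documented simplification of chromosome III geometry
#' (they preserve the published relative layout — the ~100-kb origin-deleted
#' gap, ARS313 about 20 kb and ARS315 about 50 kb distal to the ARS310
#' deletion, HML-associated dormant origins near the left telomere — not
#' base-pair positions), so the simulator's claims are orderings and ratios
#' between constructs and regimes, never absolute loss rates.
#'
#' * `"0ORID-DR"` (200 kb): full origin complement left of the right
#'   fragmentation point — five efficient origins, the inefficient
#'   centromere-proximal ARS308, three dormant HML-associated origins.
#' * `"5ORID-DR"` (200 kb): the five efficient origins deleted; only the
#'   dormant origins (and inefficient ARS308) remain.
#' * `"5ORID"` (315 kb): full-length chromosome with the same five
#'   deletions but retaining everything distal to the ARS310 deletion
#'   (ARS313, ARS315 and the right-arm origins) plus the dormant left-end
#'   origins.
#' * `"DL-6ORID"` (290 kb): derived from 5ORID by deleting ARS308 and
#'   fragmenting away the left end, removing the dormant origins; the
#'   origin-free gap can only be replicated by leftward forks.
#'
#' Greek-letter spellings (e.g. `"5ORIΔ-ΔR"`) are accepted.
#'
#' @param name Construct name.
#' @return An `origin_map`.
#' @examples
#' builtin_construct("5ORID-DR")
#' @export
builtin_construct <- function(name) {
  name <- canonical_construct(name)
  dormant_left <- dplyr::bind_rows(
    .origin_row("ARS301", 2, "dormant"),
    .origin_row("ARS302/303/320", 8, "dormant"),
    .origin_row("ARS304", 22, "dormant")
  )
  efficient_left <- dplyr::bind_rows(
    .origin_row("ARS305", 40, "efficient"),
    .origin_row("ARS306", 70, "efficient"),
    .origin_row("ARS307", 95, "efficient"),
    .origin_row("ARS309", 120, "efficient"),
    .origin_row("ARS310", 140, "efficient")
  )
  ars308 <- .origin_row("ARS308", 112, "inefficient")
  right_arm <- dplyr::bind_rows(
    .origin_row("ARS313", 122, "inefficient"),
    .origin_row("ARS315", 152, "efficient"),
    .origin_row("ARS316", 182, "efficient"),
    .origin_row("ARS317", 212, "efficient"),
    .origin_row("ARS318", 242, "efficient"),
    .origin_row("ARS319", 272, "efficient"),
    # subtelomeric X/Y'-element origins: licensed but normally dormant
    .origin_row("telR-X-ARS", 306, "dormant"),
    .origin_row("telR-Y-ARS", 313, "dormant")
  )
  switch(name,
    "0ORID-DR" = origin_map(
      dplyr::bind_rows(dormant_left, efficient_left, ars308),
      length_kb = 200, name = "0ORID-DR"
    ),
    "5ORID-DR" = origin_map(
      dplyr::bind_rows(dormant_left, ars308),
      length_kb = 200, name = "5ORID-DR"
    ),
    "5ORID" = origin_map(
      dplyr::bind_rows(dormant_left, ars308, right_arm),
      length_kb = 315, name = "5ORID"
    ),
    "DL-6ORID" = origin_map(
      dplyr::mutate(right_arm, position_kb = .data$position_kb - 25),
      length_kb = 290, name = "DL-6ORID"
    ),
    rlang::abort(sprintf(
      "Unknown construct '%s'. Known: 0ORID-DR, 5ORID-DR, 5ORID, DL-6ORID.",
      name
    ))
  )
}

#' Define a replication regime
#'
#' A regime bundles the kinetic and fork-stability parameters of a genotype:
#' fork speed, the length of S phase, the time available before mitosis
#' (checkpoint-dependent delay included), the per-kb probability that a fork
#' arrests permanently (a crippled fork that is never restored), and whether
#' dormant origins are licensed at all.
#'
#' @param name Regime label.
#' @param fork_speed_kb_min Fork speed (default 2.3 kb/min, the median rate
#'   in budding yeast).
#' @param s_phase_min Length of S phase (default 55 min).
#' @param available_min Time from the start of S phase until mitosis strips
#'   unreplicated chromatids (>= `s_phase_min`; default equal to it).
#' @param fork_fail_per_kb Probability per kb travelled that a fork arrests
#'   permanently; the distance to arrest is drawn so that a fork survives
#'   `d` kb with probability `(1 - f)^d` (constant hazard).
#' @param fork_lifetime_kb Characteristic fork-aging distance: forks
#'   accumulate wear with distance travelled and arrest permanently with a
#'   rising hazard, surviving `d` kb with probability
#'   `exp(-(d / fork_lifetime_kb)^fork_lifetime_shape)`. `Inf` (the
#'   default) disables aging. Aging arrest is how a genotype that cannot
#'   restore crippled replisomes is modelled; the constant-hazard
#'   `fork_fail_per_kb` and aging act independently (whichever arrest comes
#'   first).
#' @param fork_lifetime_shape Weibull shape of the aging hazard (> 1 means
#'   old forks fail much more often than young ones; default 3).
#' @param dormant_enabled If `FALSE`, dormant origins are removed before
#'   simulating (as if unlicensed).
#' @return A list of class `replication_regime`.
#' @export
replication_regime <- function(name = "custom",
                               fork_speed_kb_min = 2.3,
                               s_phase_min = 55,
                               available_min = s_phase_min,
                               fork_fail_per_kb = 0,
                               fork_lifetime_kb = Inf,
                               fork_lifetime_shape = 3,
                               dormant_enabled = TRUE) {
  stopifnot(
    fork_speed_kb_min > 0, s_phase_min > 0, available_min >= s_phase_min,
    fork_fail_per_kb >= 0, fork_fail_per_kb <= 1,
    fork_lifetime_kb > 0, fork_lifetime_shape > 0
  )
  structure(
    list(
      name = name,
      fork_speed_kb_min = fork_speed_kb_min,
      s_phase_min = s_phase_min,
      available_min = available_min,
      fork_fail_per_kb = fork_fail_per_kb,
      fork_lifetime_kb = fork_lifetime_kb,
      fork_lifetime_shape = fork_lifetime_shape,
      dormant_enabled = dormant_enabled
    ),
    class = "replication_regime"
  )
}

#' Packaged replication regimes
#'
#' Model genotypes as parameter bundles. These are calibrated model
#' defaults, not measured quantities; the vignette derives them.
#'
#' * `wild_type`: 2.3 kb/min forks, no permanent arrest (crippled forks are
#'   always restored by the intact DNA damage response), generous time
#'   before mitosis (145 min) reflecting a functional checkpoint delay.
#' * `rad9_like`: normal fork speed, but aged (crippled) forks are never
#'   restored, so forks arrest with a hazard that rises with distance
#'   travelled. The aging scale is set so that a single fork fails 10% of
#'   the time while traversing the 127-kb origin-free region of the
#'   DL-6ORID fragment (the calibration anchor for this genotype: about
#'   10% of such cells lose that fragment). Mec1-dependent delay of
#'   mitosis retained (115 min).
#' * `mec1_like` / `mrc1_like`: forks progress at half speed and arrest
#'   rarely (2e-4 per kb), but the cell cannot delay mitosis at all
#'   (65 min), so slow forks often run out of time in long gaps.
#'
#' @param name One of `"wild_type"`, `"rad9_like"`, `"mec1_like"`,
#'   `"mrc1_like"`.
#' @return A `replication_regime`.
#' @export
builtin_regime <- function(name) {
  switch(name,
    wild_type = replication_regime(
      "wild_type",
      fork_speed_kb_min = 2.3, available_min = 145, fork_fail_per_kb = 0
    ),
    rad9_like = replication_regime(
      "rad9_like",
      fork_speed_kb_min = 2.3, available_min = 115,
      # survive(127 kb) = 0.9 under the cubic aging hazard
      fork_lifetime_kb = 127 / (-log(0.9))^(1 / 3)
    ),
    mec1_like = replication_regime(
      "mec1_like",
      fork_speed_kb_min = 1.15, available_min = 65, fork_fail_per_kb = 2e-4
    ),
    mrc1_like = replication_regime(
      "mrc1_like",
      fork_speed_kb_min = 1.15, available_min = 65, fork_fail_per_kb = 2e-4
    ),
    rlang::abort(sprintf(
      "Unknown regime '%s'. Known: wild_type, rad9_like, mec1_like, mrc1_like.",
      name
    ))
  )
}

# Simulate one cell. Origins are licensed independently with their
# competences, draw truncated-normal firing times, and fire only if their
# locus is still unreplicated then (passive replication silences them).
# Forks move at constant speed and arrest permanently after an
# exponential(-log(1-f)) distance. Because every stretch of DNA is
# replicated by exactly one fork front, coverage between two adjacent fired
# origins is the sum of the two facing forks' reaches: a front that dies is
# only rescued if the opposing fork (or an origin firing beyond the dead
# front, which these sorted adjacency rules capture) covers the remainder.
# Returns unreplicated kb at `t_end` and the indices of origins that fired.
simulate_cell <- function(x, tau, arr_l, arr_r, comp, len, v, t_end) {
  act <- which(comp & tau <= t_end)
  if (length(act) == 0L) {
    return(list(unrep = len, fired = integer(0)))
  }
  # decide firing in time order; passive replication check uses the nearest
  # fired origin on each side (trailing forks are blocked behind it)
  ord <- act[order(tau[act])]
  fired <- integer(0)
  for (k in ord) {
    covered <- FALSE
    if (length(fired) > 0L) {
      left <- fired[x[fired] < x[k]]
      if (length(left) > 0L) {
        j <- left[which.max(x[left])]
        reach <- min(v * (tau[k] - tau[j]), arr_r[j])
        covered <- reach >= (x[k] - x[j])
      }
      if (!covered) {
        right <- fired[x[fired] > x[k]]
        if (length(right) > 0L) {
          j <- right[which.min(x[right])]
          reach <- min(v * (tau[k] - tau[j]), arr_l[j])
          covered <- reach >= (x[j] - x[k])
        }
      }
    }
    if (!covered) {
      fired <- c(fired, k)
    }
  }
  fired <- fired[order(x[fired])]
  xf <- x[fired]
  tf <- tau[fired]
  cl <- pmin(v * (t_end - tf), arr_l[fired])
  cr <- pmin(v * (t_end - tf), arr_r[fired])
  nf <- length(fired)
  unrep <- max(0, xf[1L] - cl[1L]) + max(0, len - xf[nf] - cr[nf])
  if (nf > 1L) {
    gaps <- xf[-1L] - xf[-nf]
    unrep <- unrep + sum(pmax(0, gaps - cr[-nf] - cl[-1L]))
  }
  list(unrep = unrep, fired = fired)
}

#' Monte-Carlo simulation of construct replication
#'
#' Simulates `n` cells replicating a chromosome construct under a regime
#' and scores each cell incomplete if any position is unreplicated when
#' mitosis arrives (`available_min` after the start of S phase); incomplete
#' replication is equated with loss of the construct at the following
#' division. Origin firing fractions record actual initiation (not passive
#' replication) per origin.
#'
#' @param construct An `origin_map` (or a construct name understood by
#'   [builtin_construct()]).
#' @param regime A `replication_regime` (or a name understood by
#'   [builtin_regime()]).
#' @param n Number of simulated cells.
#' @param seed Optional integer seed; results are deterministic given it.
#' @return A list of class `replication_sim`: `incomplete_fraction`, `se`
#'   (binomial Monte-Carlo standard error), `mean_unreplicated_kb`,
#'   `firing` (tibble of per-origin firing fractions), `n`, `seed`,
#'   `construct`, `regime`.
#' @examples
#' simulate_replication("0ORID-DR", "wild_type", n = 200, seed = 1)
#' @export
simulate_replication <- function(construct, regime, n = 1000L, seed = NULL) {
  if (is.character(construct)) construct <- builtin_construct(construct)
  if (is.character(regime)) regime <- builtin_regime(regime)
  stopifnot(inherits(construct, "origin_map"), inherits(regime, "replication_regime"), n >= 1)
  len <- attr(construct, "length_kb")
  orig <- construct
  if (!regime$dormant_enabled) {
    orig <- orig[!orig$dormant, ]
  }
  k <- nrow(orig)
  x <- orig$position_kb
  v <- regime$fork_speed_kb_min
  t_end <- regime$available_min
  f <- regime$fork_fail_per_kb
  lambda <- if (f > 0) -log1p(-f) else 0
  lifetime <- regime$fork_lifetime_kb
  shape <- regime$fork_lifetime_shape
  draw_arrest <- function(nn) {
    d <- if (lambda > 0) stats::rexp(nn, lambda) else rep.int(Inf, nn)
    if (is.finite(lifetime)) {
      d <- pmin(d, stats::rweibull(nn, shape = shape, scale = lifetime))
    }
    d
  }

  res <- with_seed(seed, {
    incomplete <- logical(n)
    unrep_kb <- numeric(n)
    fired_n <- integer(max(k, 1L))
    if (k == 0L) {
      incomplete[] <- TRUE
      unrep_kb[] <- len
    } else {
      comp_m <- matrix(stats::runif(n * k) < rep(orig$competence, each = n), n, k)
      tau_m <- matrix(
        rtnorm_pos(n * k, rep(orig$t_mean_min, each = n), rep(orig$t_sd_min, each = n)),
        n, k
      )
      if (lambda > 0 || is.finite(lifetime)) {
        arrl_m <- matrix(draw_arrest(n * k), n, k)
        arrr_m <- matrix(draw_arrest(n * k), n, k)
      } else {
        arrl_m <- arrr_m <- matrix(Inf, n, k)
      }
      for (i in seq_len(n)) {
        cell <- simulate_cell(
          x, tau_m[i, ], arrl_m[i, ], arrr_m[i, ], comp_m[i, ], len, v, t_end
        )
        unrep_kb[i] <- cell$unrep
        incomplete[i] <- cell$unrep > 1e-9
        fired_n[cell$fired] <- fired_n[cell$fired] + 1L
      }
    }
    list(incomplete = incomplete, unrep_kb = unrep_kb, fired_n = fired_n)
  })

  q <- mean(res$incomplete)
  firing <- if (k > 0) {
    tibble::tibble(origin = orig$origin, firing_fraction = res$fired_n[seq_len(k)] / n)
  } else {
    tibble::tibble(origin = character(0), firing_fraction = numeric(0))
  }
  structure(
    list(
      incomplete_fraction = q,
      se = sqrt(q * (1 - q) / n),
      mean_unreplicated_kb = mean(res$unrep_kb),
      firing = firing,
      n = as.integer(n),
      seed = seed,
      construct = attr(construct, "construct"),
      regime = regime$name
    ),
    class = "replication_sim"
  )
}

#' @export
print.replication_sim <- function(x, ...) {
  cat(sprintf(
    "<replication_sim> %s under %s: incomplete %.4g +/- %.2g (n=%d)\n",
    x$construct, x$regime, x$incomplete_fraction, x$se, x$n
  ))
  invisible(x)
}

#' Contrast construct stability across two regimes
#'
#' Simulates both constructs under both regimes and reports, per regime, the
#' ratio of incomplete-replication fractions `construct_a / construct_b`
#' with a delta-method standard error, plus the ratio of those ratios across
#' regimes. Used to ask ordering questions such as whether removing dormant
#' origins costs more in a fork-arrest regime than in a slow-fork regime.
#'
#' @param construct_a,construct_b Constructs (`origin_map` or name).
#' @param regime_1,regime_2 Regimes (`replication_regime` or name).
#' @param n Cells per simulation.
#' @param seed Optional integer master seed.
#' @return A tibble with one row per regime (`regime`, `inc_a`, `se_a`,
#'   `inc_b`, `se_b`, `ratio`, `ratio_se`; ratios are `NA` when the
#'   denominator fraction is 0) and attribute `ratio_of_ratios`
#'   (regime 1 over regime 2).
#' @export
regime_contrast <- function(construct_a, construct_b, regime_1, regime_2,
                            n = 10000L, seed = NULL) {
  seeds <- derive_seeds(seed, 4L)
  if (is.null(seed)) seeds <- rep(list(NULL), 4L)
  sims <- list(
    simulate_replication(construct_a, regime_1, n, seeds[[1]]),
    simulate_replication(construct_b, regime_1, n, seeds[[2]]),
    simulate_replication(construct_a, regime_2, n, seeds[[3]]),
    simulate_replication(construct_b, regime_2, n, seeds[[4]])
  )
  row <- function(sa, sb) {
    ratio <- if (sb$incomplete_fraction > 0) {
      sa$incomplete_fraction / sb$incomplete_fraction
    } else {
      NA_real_
    }
    ratio_se <- if (!is.na(ratio) && sa$incomplete_fraction > 0) {
      ratio * sqrt(
        (sa$se / sa$incomplete_fraction)^2 + (sb$se / sb$incomplete_fraction)^2
      )
    } else {
      NA_real_
    }
    tibble::tibble(
      regime = sa$regime,
      construct_a = sa$construct, inc_a = sa$incomplete_fraction, se_a = sa$se,
      construct_b = sb$construct, inc_b = sb$incomplete_fraction, se_b = sb$se,
      ratio = ratio, ratio_se = ratio_se
    )
  }
  out <- dplyr::bind_rows(row(sims[[1]], sims[[2]]), row(sims[[3]], sims[[4]]))
  rr <- if (!anyNA(out$ratio) && out$ratio[2] > 0) out$ratio[1] / out$ratio[2] else NA_real_
  attr(out, "ratio_of_ratios") <- rr
  out
}
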