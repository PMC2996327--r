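single_origin_map <- function(position, length_kb, competence = 1,
                              t_mean = 0, t_sd = 0) {
  origin_map(
    tibble::tibble(
      origin = "ori", position_kb = position, competence = competence,
      t_mean_min = t_mean, t_sd_min = t_sd, dormant = FALSE
    ),
    length_kb = length_kb
  )
}

test_that("fork_reach reproduces the arithmetic of fork travel", {
  expect_equal(fork_reach(2.3, 55), 126.5) # full S phase, ~120 kb
  expect_equal(fork_reach(2.3, 27.5), 63.25) # mid-S firing, ~60 kb
  expect_equal(fork_reach(2.3, 0), 0)
})

test_that("packaged construct maps have the documented origin content", {
  m0 <- builtin_construct("0ORID-DR")
  expect_equal(sum(m0$competence == 0.9 & !m0$dormant), 5)
  expect_equal(sum(m0$dormant), 3)

  m5 <- builtin_construct("5ORIΔ-ΔR") # Greek spelling accepted
  expect_false(any(m5$competence == 0.9 & !m5$dormant))
  expect_true(all(c("ARS301", "ARS304", "ARS308") %in% m5$origin))

  dl <- builtin_construct("DL-6ORID")
  expect_false(any(dl$dormant & dl$position_kb < 100)) # no dormants left of the gap
  expect_false("ARS308" %in% dl$origin)
  expect_true(all(c("ARS313", "ARS315") %in% dl$origin))

  full <- builtin_construct("5ORID")
  expect_true(any(full$dormant & full$position_kb < 30))
  expect_true(all(c("ARS313", "ARS315") %in% full$origin))
  # ARS313 about 20 kb and ARS315 about 50 kb distal to the gap end
  gap_end <- 102
  expect_equal(full$position_kb[full$origin == "ARS313"] - gap_end, 20)
  expect_equal(full$position_kb[full$origin == "ARS315"] - gap_end, 50)

  expect_error(builtin_construct("7ORID"), "Unknown construct")
  expect_error(builtin_regime("tel1_like"), "Unknown regime")
  expect_error(
    origin_map(
      tibble::tibble(
        origin = "x", position_kb = 500, competence = 1,
        t_mean_min = 10, t_sd_min = 1, dormant = FALSE
      ),
      length_kb = 100
    ),
    "within"
  )
})

test_that("a chromosome with no firing origin is never replicated", {
  empty <- origin_map(
    tibble::tibble(
      origin = character(0), position_kb = numeric(0), competence = numeric(0),
      t_mean_min = numeric(0), t_sd_min = numeric(0), dormant = logical(0)
    ),
    length_kb = 100
  )
  s <- simulate_replication(empty, replication_regime(), n = 50, seed = 1)
  expect_equal(s$incomplete_fraction, 1)
  expect_equal(s$mean_unreplicated_kb, 100)
})

test_that("a single reliable centred origin with time to spare always finishes", {
  m <- single_origin_map(30, 60)
  reg <- replication_regime(available_min = 60) # needs 30/2.3 ~ 13 min
  s <- simulate_replication(m, reg, n = 200, seed = 2)
  expect_equal(s$incomplete_fraction, 0)
  expect_equal(s$firing$firing_fraction, 1)
})

test_that("with no failure and unlimited time, incompleteness is the no-firing probability", {
  p <- c(0.5, 0.7, 0.3)
  m <- origin_map(
    tibble::tibble(
      origin = c("a", "b", "c"), position_kb = c(30, 60, 90), competence = p,
      t_mean_min = 10, t_sd_min = 4, dormant = FALSE
    ),
    length_kb = 120
  )
  reg <- replication_regime(available_min = 1e6)
  s <- simulate_replication(m, reg, n = 20000, seed = 3)
  theory <- prod(1 - p)
  se <- sqrt(theory * (1 - theory) / 20000)
  expect_lt(abs(s$incomplete_fraction - theory), 3 * se)
})

test_that("single-fork failure follows the geometric closed form", {
  d <- 80
  f <- 0.005
  m <- single_origin_map(0, d)
  reg <- replication_regime(available_min = 1e6, fork_fail_per_kb = f)
  s <- simulate_replication(m, reg, n = 20000, seed = 4)
  theory <- 1 - (1 - f)^d
  se <- sqrt(theory * (1 - theory) / 20000)
  expect_lt(abs(s$incomplete_fraction - theory), 3 * se)
})

test_that("adding an origin never makes replication less complete", {
  base <- builtin_construct("5ORID-DR")
  plus <- origin_map(
    dplyr::bind_rows(
      base,
      tibble::tibble(
        origin = "ARS305", position_kb = 40, competence = 0.9,
        t_mean_min = 10, t_sd_min = 4, dormant = FALSE
      )
    ),
    length_kb = attr(base, "length_kb"), name = "5ORID-DR+ARS305"
  )
  for (regname in c("rad9_like", "mec1_like")) {
    a <- simulate_replication(base, regname, n = 10000, seed = 11)
    b <- simulate_replication(plus, regname, n = 10000, seed = 11)
    expect_lte(
      b$incomplete_fraction,
      a$incomplete_fraction + 2 * sqrt(a$se^2 + b$se^2) + 1e-9
    )
  }
})

test_that("replication simulation is deterministic given a seed", {
  a <- simulate_replication("5ORID", "rad9_like", n = 400, seed = 9)
  b <- simulate_replication("5ORID", "rad9_like", n = 400, seed = 9)
  expect_identical(glance(a), glance(b))
  expect_identical(tidy(a), tidy(b))
})

test_that("dormant origins are passively replicated when efficient origins are present", {
  s <- simulate_replication("0ORID-DR", "wild_type", n = 20000, seed = 13)
  dormant_firing <- dplyr::filter(tidy(s), grepl("ARS30[1-4]|302", .data$origin))
  expect_lt(max(dormant_firing$firing_fraction), 0.02)
})

test_that("dormant-origin rescue stabilises the full-length gapped chromosome", {
  # removing the dormant origins (DL-6ORID) costs >= 10-fold in a regime
  # where aged forks are not restored
  full <- simulate_replication("5ORID", "rad9_like", n = 20000, seed = 21)
  dl <- simulate_replication("DL-6ORID", "rad9_like", n = 20000, seed = 22)
  expect_gte(dl$incomplete_fraction, 10 * full$incomplete_fraction)
})

test_that("regime_contrast reports unit ratios for identical setups", {
  m <- single_origin_map(0, 120)
  regf <- replication_regime("custom", available_min = 1e6, fork_fail_per_kb = 0.002)
  rc <- regime_contrast(m, m, regf, regf, n = 10000, seed = 31)
  expect_true(all(abs(rc$ratio - 1) < 3 * rc$ratio_se))
  expect_lt(abs(attr(rc, "ratio_of_ratios") - 1), 0.2)

  # zero denominator yields an undefined ratio, not infinity
  safe <- single_origin_map(60, 120)
  reg0 <- replication_regime(available_min = 1e6)
  rc0 <- regime_contrast(safe, safe, reg0, reg0, n = 200, seed = 32)
  expect_true(all(is.na(rc0$ratio)))
})
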