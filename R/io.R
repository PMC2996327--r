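# Reading and writing the package's tab-delimited interchange formats.
# Rates travel in files in the conventional display unit of 1e-5 losses per
# division; per-division probabilities are used internally. "ND", "N.D." and
# "Not defined" (case-sensitive) are the recognised missing-value tokens.

missing_tokens <- c("ND", "N.D.", "Not defined")

parse_rate_col <- function(x, path, col) {
  x_chr <- as.character(x)
  miss <- is.na(x_chr) | x_chr %in% missing_tokens
  val <- suppressWarnings(as.numeric(x_chr))
  bad <- !miss & is.na(val)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Non-numeric value '%s' in column '%s' of %s (line %d).",
      x_chr[bad][1], col, path, which(bad)[1] + 1L
    ))
  }
  if (any(val[!miss] < 0)) {
    rlang::abort(sprintf("Negative rate in column '%s' of %s.", col, path))
  }
  replace(val, miss, NA_real_)
}

#' Read a loss-rate table
#'
#' Expects a UTF-8 tab-delimited file with header columns `strain`,
#' `construct`, `rate_e5` and optionally `sd_e5`; rates in units of 1e-5
#' per division. Missing-value tokens (`ND`, `N.D.`, `Not defined`) mark a
#' construct as unmeasured for that strain and the row is dropped. Construct
#' names are canonicalised to their ASCII spelling.
#'
#' @param path File path.
#' @return A tibble: `strain`, `construct`, `rate_e5`, `sd_e5`.
#' @export
read_loss_rates <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0) {
    rlang::abort(sprintf("No rate rows found in %s.", path))
  }
  need <- c("strain", "construct", "rate_e5")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf(
      "%s must have columns %s.", path, paste(need, collapse = ", ")
    ))
  }
  if (!"sd_e5" %in% names(df)) {
    df$sd_e5 <- NA_character_
  }
  out <- tibble::tibble(
    strain = df$strain,
    construct = canonical_construct(df$construct),
    rate_e5 = parse_rate_col(df$rate_e5, path, "rate_e5"),
    sd_e5 = parse_rate_col(df$sd_e5, path, "sd_e5")
  )
  dplyr::filter(out, !is.na(.data$rate_e5))
}

#' Write a loss-rate table
#'
#' @param x Tibble as returned by [read_loss_rates()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_loss_rates <- function(x, path) {
  stopifnot(all(c("strain", "construct", "rate_e5") %in% names(x)))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Packaged transcription of the checkpoint-mutant loss-rate table
#'
#' Loss rates (x 1e-5 per division, with standard deviations) of the four
#' chromosome III derivatives in the wild-type strain and ten checkpoint
#' mutants, as tabulated in the source study of origin-depleted chromosome
#' maintenance. Feed it to [score_ofm()] to recompute every published Ofm
#' index.
#'
#' @return A tibble: `strain`, `construct`, `rate_e5`, `sd_e5`.
#' @examples
#' table2_rates() |> score_ofm(baseline = "Wild Type")
#' @export
table2_rates <- function() {
  read_loss_rates(system.file("extdata", "table2.tsv",
    package = "ofmscreen",
    mustWork = TRUE
  ))
}

#' Read a fluctuation-assay table
#'
#' Tab-delimited with header `strain`, `construct`, `culture_id`,
#' `loss_count`, `culture_size` and optional `cells_sampled`; one row per
#' culture.
#'
#' @param path File path.
#' @return A tibble with one row per culture.
#' @export
read_assays <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      strain = readr::col_character(),
      construct = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("strain", "construct", "culture_id", "loss_count", "culture_size")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf(
      "%s must have columns %s.", path, paste(need, collapse = ", ")
    ))
  }
  df$construct <- canonical_construct(df$construct)
  df
}

#' Write a fluctuation-assay table
#'
#' @param x Assay tibble (see [read_assays()] for the columns).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assays <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read an origin map from a tab-delimited file
#'
#' Columns `origin`, `position_kb`, `competence`, `t_mean_min`, `t_sd_min`,
#' `dormant` (logical).
#'
#' @param path File path.
#' @param length_kb Construct length in kb.
#' @param name Construct name.
#' @return An `origin_map`.
#' @export
read_origin_map <- function(path, length_kb, name = "custom") {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      origin = readr::col_character(),
      dormant = readr::col_logical(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  origin_map(df, length_kb = length_kb, name = name)
}
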