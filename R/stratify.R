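# Difference-based agreement reports for two checkers: the five-stratum
# breakdown, the severity-level distribution within full agreement, and the
# six-way summary that folds everything short of full agreement into a
# single disagreement slice.

#' Exact percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero to the
#' requested number of decimals — the convention used by the printed
#' agreement figures this package reproduces.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param decimals Number of decimal places (default 1).
#' @return Numeric vector of percentages in [0, 100].
#' @examples
#' percentage(6056, 7658)       # 79.1
#' percentage(8, 6056, 2)       # 0.13
#' @export
percentage <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    rlang::abort("`denominator` must be positive.", class = "ddic_domain_error")
  }
  if (any(numerator < 0 | numerator > denominator)) {
    rlang::abort("`numerator` must lie in [0, denominator].",
                 class = "ddic_domain_error")
  }
  if (any(decimals < 0)) {
    rlang::abort("`decimals` must be >= 0.", class = "ddic_domain_error")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Stratify two-checker agreement by strength-code difference
#'
#' Assigns every rated pair to one of five strata by the absolute
#' difference of the two checkers' harmonized codes (0 agreement ...
#' 4 strong disagreement), and breaks the full-agreement stratum down by
#' the common severity level.
#'
#' @param ratings Long ratings table (`drug_u`, `drug_v`, `rater`, `code`)
#'   with exactly two raters, both rating every pair.
#' @param decimals Decimals for reported percentages (default 1).
#' @return An object of class `agreement_report`: a list with
#'   `total_pairs`, `strata` (tibble stratum/count/pct, percentages of all
#'   pairs), `by_level` (tibble level/label/count/pct, percentages of the
#'   agreement count), `denominators`, and `decimals`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
stratify <- function(ratings, decimals = 1) {
  wide <- ratings_to_wide(ratings)
  raters <- attr(wide, "raters")
  total <- nrow(wide)
  strata <- wide |>
    dplyr::count(.data$stratum, name = "count") |>
    tidyr::complete(stratum = classify_stratum(0:4), fill = list(count = 0L)) |>
    dplyr::arrange(.data$stratum)
  strata$pct <- percentage(strata$count, total, decimals)
  agree <- wide[wide$difference == 0L, , drop = FALSE]
  n_agree <- nrow(agree)
  by_level <- tibble::tibble(level = 0:4) |>
    dplyr::left_join(
      dplyr::count(agree, level = .data[[raters[1]]], name = "count"),
      by = "level"
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  label = severity_label(.data$level)) |>
    dplyr::select("level", "label", "count")
  by_level$pct <- if (n_agree > 0) {
    percentage(by_level$count, n_agree, decimals)
  } else {
    rep(NA_real_, nrow(by_level))
  }
  structure(
    list(
      total_pairs = total,
      strata = strata,
      by_level = by_level,
      denominators = list(strata = total, by_level = n_agree),
      decimals = decimals,
      raters = raters
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report: %d pairs, raters %s\n",
              x$total_pairs, paste(x$raters, collapse = " vs ")))
  print(x$strata)
  cat(sprintf("Within agreement (%d pairs):\n", x$denominators$by_level))
  print(x$by_level)
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param panel `"strata"` (default) or `"levels"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.agreement_report <- function(x, panel = c("strata", "levels"), ...) {
  panel <- match.arg(panel)
  if (panel == "strata") x$strata else x$by_level
}

#' One-row summary of an agreement report
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row tibble with the total, agreement count and percentage.
#' @export
glance.agreement_report <- function(x, ...) {
  agree <- x$strata$count[x$strata$stratum == "agreement"]
  tibble::tibble(
    total_pairs = x$total_pairs,
    n_agreement = agree,
    pct_agreement = x$strata$pct[x$strata$stratum == "agreement"],
    n_raters = 2L
  )
}

#' Six-way agreement summary
#'
#' The coarse partition used for per-subcategory pie summaries: pairs on
#' which both checkers agree are split by the common severity level
#' (contraindicated, major, moderate, minor, not found); every pair with
#' any difference in codes collapses into a single *disagreement* slice.
#'
#' @param ratings Long two-rater ratings table.
#' @param decimals Decimals for percentages (default 2).
#' @return A tibble with columns `category`, `count`, `pct` (percent of all
#'   pairs) and attribute `total_pairs`.
#' @export
sixway_summary <- function(ratings, decimals = 2) {
  wide <- ratings_to_wide(ratings)
  raters <- attr(wide, "raters")
  total <- nrow(wide)
  common <- ifelse(wide$difference == 0L, wide[[raters[1]]], NA_integer_)
  cats <- c("agreement_contraindicated", "agreement_major",
            "agreement_moderate", "agreement_minor",
            "agreement_not_found", "disagreement")
  category <- ifelse(is.na(common), "disagreement",
                     cats[match(4L - common, 0:4)])
  out <- tibble::tibble(category = factor(category, levels = cats)) |>
    dplyr::count(.data$category, name = "count", .drop = FALSE) |>
    dplyr::mutate(category = as.character(.data$category),
                  pct = percentage(.data$count, total, decimals))
  attr(out, "total_pairs") <- total
  out
}
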