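# Deterministic worked-example fixtures. Each fixture exists both as a
# constructor (below) and as checked-in catalog/ratings files under
# inst/extdata/, so the text parsers and the computations are exercised
# against the same bytes. All fixture data is synthetic: drug identifiers
# are placeholders, not real active substances.

new_fixture <- function(name, catalog, ratings, expected) {
  structure(list(name = name, catalog = catalog, ratings = ratings,
                 expected = expected),
            class = "ddi_fixture")
}

#' @export
print.ddi_fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s': %d drugs, %d rating rows\n",
              x$name, nrow(x$catalog), nrow(x$ratings)))
  cat("Expected:\n")
  utils::str(x$expected, give.attr = FALSE)
  invisible(x)
}

#' Worked-example fixture: the beta-blocker x peripheral-vasodilator cell
#'
#' A 13 x 4 subcategory product (52 pairs) in which the two checkers agree
#' on "not found" for exactly half the pairs and split 0-versus-2 on the
#' other half. This is the single-off-level reconstruction consistent with
#' a 50/50 agreement split, and it yields Fleiss' kappa of -1/3 for the
#' cell: observed agreement 0.5 against chance agreement 0.625. Any single
#' fixed non-zero level for the disagreeing rater gives the same kappa;
#' mixing non-zero levels does not.
#'
#' @return A `ddi_fixture` with elements `catalog`, `ratings`, and
#'   `expected` (kappa, band, stratum counts, six-way percentages).
#' @export
fixture_c07_c04 <- function() {
  catalog <- as_drug_catalog(tibble::tibble(
    drug_id = c(sprintf("C07_%03d", 1:13), sprintf("C04_%03d", 1:4)),
    name = c(sprintf("synthetic beta blocker %d", 1:13),
             sprintf("synthetic peripheral vasodilator %d", 1:4)),
    category = "C",
    primary_subcategory = c(rep("C07", 13), rep("C04", 4)),
    atc_codes = c(rep("C07", 13), rep("C04", 4))
  ))
  pairs <- tidyr::crossing(drug_u = sprintf("C07_%03d", 1:13),
                           drug_v = sprintf("C04_%03d", 1:4))
  # first 26 pairs in enumeration order agree on 0; the rest split 0 vs 2
  code_b <- rep(c(0L, 2L), each = 26)
  ratings <- dplyr::bind_rows(
    tibble::tibble(pairs, rater = "edic_a", code = 0L),
    tibble::tibble(pairs, rater = "edic_b", code = code_b)
  ) |> canonicalize_pairs()
  new_fixture(
    "c07_c04", catalog, ratings,
    expected = list(
      kappa = -1 / 3, p_bar = 0.5, p_bar_e = 0.625, band = "poor",
      n_pairs = 52L,
      strata = c(agreement = 26L, mild_disagreement = 26L),
      sixway_pct = c(agreement_not_found = 50, disagreement = 50)
    )
  )
}

#' Worked-example fixture: perfect agreement, degenerate and not
#'
#' A small two-subcategory product on which the checkers always agree.
#' The `"mixed"` variant mixes severity levels, so chance agreement stays
#' below 1 and kappa = 1 arises non-degenerately; the `"all_zero"` variant
#' has every rating at level 0, the indeterminate 0/0 case reported as
#' kappa = 1 with the degenerate flag set.
#'
#' @param variant `"mixed"` (default) or `"all_zero"`.
#' @return A `ddi_fixture`.
#' @export
fixture_perfect_agreement <- function(variant = c("mixed", "all_zero")) {
  variant <- match.arg(variant)
  catalog <- as_drug_catalog(tibble::tibble(
    drug_id = c("C02_001", "C02_002", "C04_001", "C04_002"),
    name = sprintf("synthetic drug %d", 1:4),
    category = "C",
    primary_subcategory = c("C02", "C02", "C04", "C04"),
    atc_codes = c("C02", "C02", "C04", "C04")
  ))
  pairs <- tidyr::crossing(drug_u = c("C02_001", "C02_002"),
                           drug_v = c("C04_001", "C04_002"))
  code <- if (variant == "mixed") c(0L, 2L, 3L, 0L) else rep(0L, 4)
  ratings <- dplyr::bind_rows(
    tibble::tibble(pairs, rater = "edic_a", code = code),
    tibble::tibble(pairs, rater = "edic_b", code = code)
  ) |> canonicalize_pairs()
  new_fixture(
    paste0("perfect_agreement_", variant), catalog, ratings,
    expected = list(kappa = 1, band = "perfect",
                    degenerate = (variant == "all_zero"), n_pairs = 4L)
  )
}
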