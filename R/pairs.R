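# Drug catalog structure and pair-set enumeration under the ATC Level-2
# category scheme: a cardiovascular category C partitioned into
# subcategories (C01, C02, ...) and an "other" category O partitioned into
# its own subcategories (A02, A10, ..., including split codes like N05-1).

#' Validate a drug catalog
#'
#' A catalog is a tibble with one row per drug: `drug_id`, `name`,
#' `category` ("C" or "O"), `primary_subcategory` (ATC Level-2 code used
#' for pair enumeration; each drug counts in exactly one subcategory), and
#' `atc_codes` (semicolon-separated full ATC code list, metadata only).
#'
#' @param catalog Data frame with the columns above (`name` and
#'   `atc_codes` optional).
#' @return A validated tibble with class `ddi_catalog`.
#' @export
as_drug_catalog <- function(catalog) {
  req <- c("drug_id", "category", "primary_subcategory")
  if (!is.data.frame(catalog) || !all(req %in% names(catalog))) {
    rlang::abort(
      sprintf("`catalog` must have columns %s.", paste(req, collapse = ", ")),
      class = "ddic_malformed_error"
    )
  }
  catalog <- tibble::as_tibble(catalog)
  catalog$drug_id <- as.character(catalog$drug_id)
  if (!"name" %in% names(catalog)) catalog$name <- catalog$drug_id
  if (!"atc_codes" %in% names(catalog)) catalog$atc_codes <- catalog$primary_subcategory
  dup <- catalog$drug_id[duplicated(catalog$drug_id)]
  if (length(dup)) {
    rlang::abort(sprintf("Duplicate drug_id: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "ddic_malformed_error")
  }
  bad_cat <- which(!catalog$category %in% c("C", "O"))
  if (length(bad_cat)) {
    rlang::abort(
      sprintf("Invalid category '%s' for drug %s (must be C or O).",
              catalog$category[bad_cat[1]], catalog$drug_id[bad_cat[1]]),
      class = "ddic_malformed_error"
    )
  }
  is_c_sub <- grepl("^C[0-9]", catalog$primary_subcategory)
  mism <- which((catalog$category == "C") != is_c_sub)
  if (length(mism)) {
    rlang::abort(
      sprintf("Drug %s: category %s inconsistent with subcategory %s.",
              catalog$drug_id[mism[1]], catalog$category[mism[1]],
              catalog$primary_subcategory[mism[1]]),
      class = "ddic_malformed_error"
    )
  }
  class(catalog) <- c("ddi_catalog", class(catalog))
  catalog
}

#' Subcategory sizes of a catalog
#'
#' @param catalog A drug catalog.
#' @param category Restrict to `"C"`, `"O"`, or both (default).
#' @return A tibble `category`, `subcategory`, `n_drugs`.
#' @export
subcategory_sizes <- function(catalog, category = c("C", "O")) {
  catalog <- as_drug_catalog(catalog)
  catalog |>
    dplyr::filter(.data$category %in% !!category) |>
    dplyr::count(.data$category, subcategory = .data$primary_subcategory,
                 name = "n_drugs") |>
    dplyr::arrange(.data$category, .data$subcategory)
}

category_drugs <- function(catalog, category) {
  catalog$drug_id[catalog$category == category]
}

subcategory_drugs <- function(catalog, subcategory) {
  catalog$drug_id[catalog$primary_subcategory == subcategory]
}

#' Enumerate all unordered pairs within a category
#'
#' All |C|(|C|-1)/2 unordered drug pairs of one category, endpoints in
#' canonical (sorted) order.
#'
#' @param catalog A drug catalog.
#' @param category Category code, default `"C"`.
#' @return Tibble `drug_u`, `drug_v`, `subcat_u`, `subcat_v`.
#' @export
enumerate_within_pairs <- function(catalog, category = "C") {
  catalog <- as_drug_catalog(catalog)
  drugs <- category_drugs(catalog, category)
  pairs <- all_unordered_pairs(drugs)
  attach_subcats(pairs, catalog)
}

#' Enumerate within-category pairs across distinct subcategories
#'
#' The unordered pairs of one category whose endpoints carry different
#' primary subcategories — the universe that excludes therapeutic
#' duplication (two drugs from the same pharmacotherapeutic subgroup).
#' Count = sum over x < y of |Cx| |Cy|.
#'
#' @inheritParams enumerate_within_pairs
#' @return Tibble `drug_u`, `drug_v`, `subcat_u`, `subcat_v`.
#' @export
enumerate_cross_subcategory_pairs <- function(catalog, category = "C") {
  pairs <- enumerate_within_pairs(catalog, category)
  pairs[pairs$subcat_u != pairs$subcat_v, , drop = FALSE]
}

#' Enumerate the product of two categories
#'
#' All (u in X, v in Y) pairs across two disjoint categories;
#' count = |X| * |Y|.
#'
#' @param catalog A drug catalog.
#' @param category_x,category_y The two category codes (default `"C"`,
#'   `"O"`).
#' @return Tibble `drug_u`, `drug_v`, `subcat_u`, `subcat_v` with `drug_u`
#'   from `category_x`.
#' @export
enumerate_category_product <- function(catalog, category_x = "C", category_y = "O") {
  catalog <- as_drug_catalog(catalog)
  x <- category_drugs(catalog, category_x)
  y <- category_drugs(catalog, category_y)
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("Both categories must be non-empty.", class = "ddic_domain_error")
  }
  pairs <- tidyr::crossing(drug_u = x, drug_v = y)
  attach_subcats(pairs, catalog)
}

attach_subcats <- function(pairs, catalog) {
  sub <- stats::setNames(catalog$primary_subcategory, catalog$drug_id)
  pairs$subcat_u <- unname(sub[pairs$drug_u])
  pairs$subcat_v <- unname(sub[pairs$drug_v])
  pairs
}
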