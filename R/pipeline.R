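# End-to-end assembly: per-subcategory-pair kappa matrices, band tables
# sorted by agreement, and the full report bundle.

#' Kappa matrix over ATC Level-2 subcategory pairs
#'
#' Computes one [kappa_between_sets()] result per pair of subcategories:
#' all 28 unordered pairs of the 8 cardiovascular subcategories
#' (`mode = "within_C"`), or the 8 x 11 rectangle of cardiovascular by
#' other subcategories (`mode = "C_cross_O"`). Ratings are filtered to
#' each cell's drug sets; unrated pairs within a cell are imputed as
#' mutual level 0 unless `impute = FALSE`.
#'
#' @param catalog A drug catalog.
#' @param ratings Long harmonized ratings table.
#' @param mode `"within_C"` or `"C_cross_O"`.
#' @param impute Impute unrated pairs as mutual level 0?
#' @return An object of class `kappa_matrix`: a list with `cells` (tibble
#'   `subcat_x`, `subcat_y`, `n_pairs`, `n_rated`, `n_imputed`, `kappa`,
#'   `band`, `degenerate`), `mode`, and the subcategory axes. Supports
#'   `tidy()`, `as.matrix()` and `autoplot()`.
#' @export
build_kappa_matrix <- function(catalog, ratings,
                               mode = c("within_C", "C_cross_O"),
                               impute = TRUE) {
  mode <- match.arg(mode)
  catalog <- as_drug_catalog(catalog)
  ratings <- validate_ratings(ratings)
  unknown <- setdiff(unique(c(ratings$drug_u, ratings$drug_v)), catalog$drug_id)
  if (length(unknown)) {
    rlang::abort(
      sprintf("Ratings reference drug id(s) absent from the catalog: %s",
              paste(utils::head(unknown, 5), collapse = ", ")),
      class = "ddic_domain_error"
    )
  }
  sizes <- subcategory_sizes(catalog)
  subs_c <- sizes$subcategory[sizes$category == "C"]
  if (mode == "within_C") {
    grid <- t(utils::combn(subs_c, 2))
    axes <- list(x = subs_c, y = subs_c)
  } else {
    subs_o <- sizes$subcategory[sizes$category == "O"]
    grid <- as.matrix(tidyr::crossing(x = subs_c, y = subs_o))
    axes <- list(x = subs_c, y = sizes$subcategory[sizes$category == "O"])
  }
  sub_of <- stats::setNames(catalog$primary_subcategory, catalog$drug_id)
  su <- unname(sub_of[ratings$drug_u])
  sv <- unname(sub_of[ratings$drug_v])
  cells <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sx <- grid[i, 1]; sy <- grid[i, 2]
    dx <- subcategory_drugs(catalog, sx)
    dy <- subcategory_drugs(catalog, sy)
    if (length(dx) == 0 || length(dy) == 0) {
      return(tibble::tibble(subcat_x = sx, subcat_y = sy,
                            n_pairs = length(dx) * length(dy),
                            n_rated = 0L, n_imputed = 0L,
                            kappa = NA_real_, band = NA_character_,
                            degenerate = NA))
    }
    keep <- (su == sx & sv == sy) | (su == sy & sv == sx)
    cell_ratings <- ratings[keep, , drop = FALSE]
    if (nrow(cell_ratings) == 0 && !impute) {
      return(tibble::tibble(subcat_x = sx, subcat_y = sy,
                            n_pairs = length(dx) * length(dy),
                            n_rated = 0L, n_imputed = 0L,
                            kappa = NA_real_, band = NA_character_,
                            degenerate = NA))
    }
    if (nrow(cell_ratings) == 0) {
      # whole cell imputed: both raters answer "not found" everywhere
      raters <- sort(unique(ratings$rater))
      cell_ratings <- tidyr::crossing(
        tidyr::crossing(drug_u = dx, drug_v = dy), rater = raters
      )
      cell_ratings$code <- 0L
      cell_ratings <- canonicalize_pairs(cell_ratings)
      fk <- kappa_between_sets(cell_ratings, dx, dy, impute = FALSE)
      fk$n_imputed <- fk$n_universe
      n_rated <- 0L
    } else {
      fk <- kappa_between_sets(cell_ratings, dx, dy, impute = impute)
      n_rated <- fk$n_universe - fk$n_imputed
    }
    tibble::tibble(subcat_x = sx, subcat_y = sy,
                   n_pairs = fk$n_universe, n_rated = n_rated,
                   n_imputed = fk$n_imputed, kappa = fk$kappa,
                   band = fk$band, degenerate = fk$degenerate)
  })
  structure(list(cells = cells, mode = mode, axes = axes),
            class = "kappa_matrix")
}

#' @export
print.kappa_matrix <- function(x, ...) {
  cat(sprintf("Kappa matrix (%s): %d cells\n", x$mode, nrow(x$cells)))
  print(x$cells)
  invisible(x)
}

#' Tidy a kappa matrix
#' @param x A `kappa_matrix`.
#' @param ... Unused.
#' @return The long cell tibble.
#' @export
tidy.kappa_matrix <- function(x, ...) x$cells

#' Dense matrix of kappa values
#'
#' @param x A `kappa_matrix`.
#' @param ... Unused.
#' @return A numeric matrix, rows `subcat_x` by columns `subcat_y`; the
#'   within-category form is symmetric with `NA` on the diagonal.
#' @export
as.matrix.kappa_matrix <- function(x, ...) {
  m <- matrix(NA_real_, length(x$axes$x), length(x$axes$y),
              dimnames = list(x$axes$x, x$axes$y))
  for (i in seq_len(nrow(x$cells))) {
    m[x$cells$subcat_x[i], x$cells$subcat_y[i]] <- x$cells$kappa[i]
    if (x$mode == "within_C") {
      m[x$cells$subcat_y[i], x$cells$subcat_x[i]] <- x$cells$kappa[i]
    }
  }
  m
}

#' Band table for a kappa matrix
#'
#' The cells of a kappa matrix sorted by descending kappa and annotated
#' with their Landis-Koch band — the layout of published per-subcategory
#' agreement tables.
#'
#' @param x A `kappa_matrix`.
#' @return A tibble sorted by decreasing `kappa` with a `pair` label
#'   column.
#' @export
kappa_band_table <- function(x) {
  stopifnot(inherits(x, "kappa_matrix"))
  x$cells |>
    dplyr::filter(!is.na(.data$kappa)) |>
    dplyr::arrange(dplyr::desc(.data$kappa), .data$subcat_x, .data$subcat_y) |>
    dplyr::mutate(pair = paste(.data$subcat_x, .data$subcat_y, sep = "-")) |>
    dplyr::select("pair", "subcat_x", "subcat_y", "n_pairs",
                  "kappa", "band", "degenerate")
}

#' Run the full concordance analysis
#'
#' Orchestrates the whole pipeline on a harmonized dataset: overall Fleiss'
#' kappa for the within-category universes (all pairs, and restricted to
#' cross-subcategory pairs) and for the category-product universe (full
#' product, and restricted to rated pairs), the stratified agreement
#' reports, per-subcategory-pair six-way summaries, and both kappa
#' matrices with band tables.
#'
#' @param catalog A drug catalog (tibble or path to a catalog TSV).
#' @param ratings Harmonized long ratings table (tibble or path to a
#'   ratings CSV, read with [read_ratings()]).
#' @param dialects Named character vector rater -> dialect, forwarded to
#'   [read_ratings()] when `ratings` is a path.
#' @param modes Which analyses to run: subset of `c("within_C",
#'   "C_cross_O")`.
#' @param decimals Percentage decimals for the stratified reports.
#' @param impute Impute unrated pairs as mutual level 0?
#' @return An object of class `ddi_bundle`: a list with `manifest`,
#'   `overall` (tibble of the overall kappa analyses), `reports`,
#'   `sixway`, `matrices`, and `band_tables`.
#' @export
run_pipeline <- function(catalog, ratings, dialects = NULL,
                         modes = c("within_C", "C_cross_O"),
                         decimals = 1, impute = TRUE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.character(catalog) && length(catalog) == 1) {
    catalog <- read_catalog(catalog)
  }
  catalog <- as_drug_catalog(catalog)
  if (is.character(ratings) && length(ratings) == 1) {
    ratings <- read_ratings(ratings, dialects = dialects)
  }
  ratings <- validate_ratings(ratings)
  unknown <- setdiff(unique(c(ratings$drug_u, ratings$drug_v)), catalog$drug_id)
  if (length(unknown)) {
    rlang::abort(
      sprintf("Ratings reference drug id(s) absent from the catalog: %s",
              paste(utils::head(unknown, 5), collapse = ", ")),
      class = "ddic_domain_error"
    )
  }
  sub_of <- stats::setNames(catalog$primary_subcategory, catalog$drug_id)
  cat_of <- stats::setNames(catalog$category, catalog$drug_id)
  overall <- list()
  reports <- list()
  sixway <- list()
  matrices <- list()
  band_tables <- list()

  if ("within_C" %in% modes) {
    c_drugs <- category_drugs(catalog, "C")
    rr <- ratings[cat_of[ratings$drug_u] == "C" & cat_of[ratings$drug_v] == "C", ]
    fk_all <- kappa_within_category(rr, c_drugs, impute = impute)
    cross <- enumerate_cross_subcategory_pairs(catalog, "C")
    cross_keys <- pair_key(cross$drug_u, cross$drug_v)
    rr_cross <- rr[pair_key(rr$drug_u, rr$drug_v) %in% cross_keys, ]
    comp <- complete_universe(rr_cross, cross[, c("drug_u", "drug_v")],
                              n_raters = 2, impute = impute)
    fk_cross <- fleiss_kappa(ratings_to_counts(comp$ratings))
    fk_cross$n_imputed <- comp$n_imputed
    fk_cross$n_universe <- comp$n_universe
    overall$within_C_all_pairs <- fk_all
    overall$within_C_cross_subcategory <- fk_cross
    reports$within_C <- stratify(comp$ratings, decimals = decimals)
    matrices$within_C <- build_kappa_matrix(catalog, rr, mode = "within_C",
                                            impute = impute)
    band_tables$within_C <- kappa_band_table(matrices$within_C)
    sixway$within_C <- sixway_by_cell(comp$ratings, sub_of)
  }

  if ("C_cross_O" %in% modes) {
    spans <- cat_of[ratings$drug_u] != cat_of[ratings$drug_v]
    rr <- ratings[spans, , drop = FALSE]
    c_drugs <- category_drugs(catalog, "C")
    o_drugs <- category_drugs(catalog, "O")
    fk_full <- kappa_between_sets(rr, c_drugs, o_drugs, impute = impute)
    fk_rated <- kappa_between_sets(rr, c_drugs, o_drugs, impute = FALSE)
    overall$C_cross_O_full_product <- fk_full
    overall$C_cross_O_rated_only <- fk_rated
    comp <- complete_universe(
      rr, canonicalize_pairs(enumerate_category_product(catalog, "C", "O")),
      n_raters = 2, impute = impute
    )
    reports$C_cross_O <- stratify(comp$ratings, decimals = decimals)
    matrices$C_cross_O <- build_kappa_matrix(catalog, rr, mode = "C_cross_O",
                                             impute = impute)
    band_tables$C_cross_O <- kappa_band_table(matrices$C_cross_O)
    sixway$C_cross_O <- sixway_by_cell(comp$ratings, sub_of)
  }

  overall_tbl <- purrr::imap_dfr(overall, function(fk, nm) {
    dplyr::bind_cols(tibble::tibble(analysis = nm), glance(fk),
                     tibble::tibble(n_imputed = fk$n_imputed %||% 0L))
  })
  manifest <- list(
    n_drugs = nrow(catalog),
    subcategory_sizes = subcategory_sizes(catalog),
    n_ratings_rows = nrow(ratings),
    raters = sort(unique(ratings$rater)),
    modes = modes, decimals = decimals, impute = impute
  )
  structure(
    list(manifest = manifest, overall = overall_tbl, reports = reports,
         sixway = sixway, matrices = matrices, band_tables = band_tables),
    class = "ddi_bundle"
  )
}

# Six-way summary per subcategory pair, as one long tibble.
sixway_by_cell <- function(ratings, sub_of) {
  su <- unname(sub_of[ratings$drug_u])
  sv <- unname(sub_of[ratings$drug_v])
  cell <- paste(pmin(su, sv), pmax(su, sv), sep = "-")
  split(seq_len(nrow(ratings)), cell) |>
    purrr::imap_dfr(function(idx, nm) {
      s <- sixway_summary(ratings[idx, , drop = FALSE])
      dplyr::bind_cols(tibble::tibble(cell = nm), s)
    })
}

#' @export
print.ddi_bundle <- function(x, ...) {
  cat("DDI concordance bundle\n")
  cat(sprintf("  drugs: %d, ratings rows: %d, raters: %s\n",
              x$manifest$n_drugs, x$manifest$n_ratings_rows,
              paste(x$manifest$raters, collapse = ", ")))
  cat("Overall analyses:\n")
  print(x$overall)
  invisible(x)
}
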