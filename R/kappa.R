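# Fleiss' kappa on a ratings-count matrix, plus the category-restricted
# instantiations used for the ATC subcategory analysis.
#
# For N rated pairs, n raters and l severity levels, with n_ij the number of
# raters assigning pair i to level j:
#   P_i   = (sum_j n_ij^2 - n) / (n (n - 1))
#   P-bar = mean_i P_i
#   p_j   = column sum / (n N),  P-bar_e = sum_j p_j^2
#   kappa = (P-bar - P-bar_e) / (1 - P-bar_e)
# All sums are accumulated on exact integers; each reported quantity is a
# single final division, so results are bit-reproducible across platforms.

#' Build a ratings-count matrix from a long ratings table
#'
#' Converts a long two-plus-rater ratings table (one row per pair x rater)
#' into the N x l count matrix consumed by [fleiss_kappa()]: cell (i, j)
#' holds the number of raters assigning pair i to severity level j.
#'
#' @param ratings Data frame with columns `drug_u`, `drug_v`, `rater`, and
#'   `code` (harmonized severity code 0..4).
#' @param levels Integer vector of severity levels (columns), default 0:4.
#' @return An integer matrix with one row per unordered pair, column names
#'   `"0"`.."4"`, row names the canonical pair keys, and attribute
#'   `n_raters`.
#' @export
ratings_to_counts <- function(ratings, levels = 0:4) {
  ratings <- validate_ratings(ratings)
  key <- pair_key(ratings$drug_u, ratings$drug_v)
  dup <- duplicated(paste(key, ratings$rater, sep = "\r"))
  if (any(dup)) {
    rlang::abort(
      sprintf("Duplicate rating for pair %s by rater %s.",
              key[which(dup)[1]], ratings$rater[which(dup)[1]]),
      class = "ddic_malformed_error"
    )
  }
  tab <- table(factor(key, levels = unique(key)),
               factor(ratings$code, levels = levels))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), as.character(levels)))
  n <- length(unique(ratings$rater))
  bad <- which(rowSums(m) != n)
  if (length(bad)) {
    rlang::abort(
      sprintf("Pair %s has %d rating(s); expected one per rater (%d).",
              rownames(m)[bad[1]], rowSums(m)[bad[1]], n),
      class = "ddic_malformed_error"
    )
  }
  attr(m, "n_raters") <- n
  m
}

validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || nrow(counts) == 0 || ncol(counts) < 2) {
    rlang::abort("`counts` must be a non-empty matrix with at least 2 level columns.",
                 class = "ddic_domain_error")
  }
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L)) {
    rlang::abort("`counts` cells must be non-negative integers.",
                 class = "ddic_domain_error")
  }
  rs <- rowSums(counts)
  n <- attr(counts, "n_raters") %||% rs[1]
  bad <- which(rs != n)
  if (length(bad)) {
    rlang::abort(
      sprintf("Row %s sums to %d, expected the rater count %d.",
              rownames(counts)[bad[1]] %||% as.character(bad[1]), rs[bad[1]], n),
      class = "ddic_malformed_error"
    )
  }
  if (n < 2) {
    rlang::abort("At least 2 raters per pair are required.",
                 class = "ddic_domain_error")
  }
  attr(counts, "n_raters") <- as.integer(n)
  counts
}

#' Fleiss' kappa for a ratings-count matrix
#'
#' Computes the chance-corrected multi-rater agreement statistic. When all
#' ratings fall in a single level, chance agreement is 1 and the ratio is
#' indeterminate; observed agreement is then also perfect, so the result is
#' reported as kappa = 1 with `degenerate = TRUE` so trivial unanimity can
#' be distinguished downstream.
#'
#' @param counts Integer matrix (or data frame) with one row per rated pair
#'   and one column per severity level; see [ratings_to_counts()]. A long
#'   ratings table (columns `drug_u`, `drug_v`, `rater`, `code`) is also
#'   accepted and converted.
#' @return An object of class `fleiss_kappa`: a list with elements `kappa`,
#'   `p_bar`, `p_bar_e`, `level_proportions`, `pair_agreements`, `n_pairs`,
#'   `n_raters`, `band`, and `degenerate`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' m <- rbind(c(2, 0, 0, 0, 0), c(0, 2, 0, 0, 0))
#' fleiss_kappa(m)
#' @export
fleiss_kappa <- function(counts) {
  if (is.data.frame(counts) && all(c("drug_u", "drug_v", "rater", "code") %in% names(counts))) {
    counts <- ratings_to_counts(counts)
  }
  m <- validate_counts(counts)
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)) - 1L)
  n <- attr(m, "n_raters")
  N <- nrow(m)
  storage.mode(m) <- "double"     # exact for the integer magnitudes involved
  S_i <- rowSums(m^2)             # integer-valued
  P_i <- (S_i - n) / (n * (n - 1))
  p_bar <- (sum(S_i) - N * n) / (N * n * (n - 1))
  col_sums <- colSums(m)
  p_j <- col_sums / (n * N)
  p_bar_e <- sum(col_sums^2) / (n * N)^2
  degenerate <- any(col_sums == n * N)
  kappa <- if (degenerate) 1 else (p_bar - p_bar_e) / (1 - p_bar_e)
  structure(
    list(
      kappa = kappa,
      p_bar = p_bar,
      p_bar_e = p_bar_e,
      level_proportions = stats::setNames(p_j, colnames(m)),
      pair_agreements = stats::setNames(P_i, rownames(m)),
      n_pairs = N,
      n_raters = n,
      band = classify_band(kappa),
      degenerate = degenerate
    ),
    class = "fleiss_kappa"
  )
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa: %.4f (%s%s)\n", x$kappa, x$band,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  N = %d pairs, %d raters, %d levels\n",
              x$n_pairs, x$n_raters, length(x$level_proportions)))
  cat(sprintf("  observed agreement P-bar = %.4f, chance P-bar_e = %.4f\n",
              x$p_bar, x$p_bar_e))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-level proportions of a Fleiss' kappa fit
#'
#' @param x A `fleiss_kappa` object.
#' @param ... Unused.
#' @return A tibble with one row per severity level: `level`, `proportion`.
#' @export
tidy.fleiss_kappa <- function(x, ...) {
  tibble::tibble(
    level = as.integer(names(x$level_proportions)),
    proportion = unname(x$level_proportions)
  )
}

#' One-row summary of a Fleiss' kappa fit
#'
#' @param x A `fleiss_kappa` object.
#' @param ... Unused.
#' @return A one-row tibble: `kappa`, `p_bar`, `p_bar_e`, `n_pairs`,
#'   `n_raters`, `band`, `degenerate`.
#' @export
glance.fleiss_kappa <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, p_bar = x$p_bar, p_bar_e = x$p_bar_e,
    n_pairs = x$n_pairs, n_raters = x$n_raters,
    band = x$band, degenerate = x$degenerate
  )
}

# Complete a rated pair universe: rows of `universe` (tibble drug_u, drug_v,
# canonical order) not present in `ratings` are imputed as mutual level 0 --
# both checkers answering "no interaction found".
complete_universe <- function(ratings, universe, n_raters, impute = TRUE) {
  ukey <- pair_key(universe$drug_u, universe$drug_v)
  if (anyDuplicated(ukey)) {
    rlang::abort("Pair universe contains duplicate unordered pairs.",
                 class = "ddic_malformed_error")
  }
  rkey <- pair_key(ratings$drug_u, ratings$drug_v)
  outside <- setdiff(unique(rkey), ukey)
  if (length(outside)) {
    rlang::abort(
      sprintf("Rated pair(s) outside the enumerated universe: %s",
              paste(utils::head(outside, 5), collapse = "; ")),
      class = "ddic_domain_error"
    )
  }
  missing_keys <- setdiff(ukey, rkey)
  n_imputed <- length(missing_keys)
  if (n_imputed > 0 && impute) {
    mu <- universe[match(missing_keys, ukey), , drop = FALSE]
    fill <- tidyr::crossing(mu[, c("drug_u", "drug_v")],
                            rater = sort(unique(ratings$rater)))
    fill$code <- 0L
    ratings <- dplyr::bind_rows(ratings[, c("drug_u", "drug_v", "rater", "code")],
                                fill[, c("drug_u", "drug_v", "rater", "code")])
  }
  list(ratings = ratings, n_imputed = if (impute) n_imputed else 0L,
       n_universe = length(ukey))
}

#' Fleiss' kappa over all pairs within one drug category
#'
#' Restricts the generic statistic to the unordered-pair universe of a drug
#' set: one matrix row per pair {u, v} with u != v, both in `drugs`. Pairs
#' of the universe absent from `ratings` are, by default, imputed as rated
#' level 0 ("no interaction found") by every rater, matching how checkers
#' answer queries for unlisted combinations.
#'
#' @param ratings Long ratings table (`drug_u`, `drug_v`, `rater`, `code`)
#'   with every endpoint in `drugs`.
#' @param drugs Character vector of drug identifiers defining the category.
#' @param impute Impute unrated pairs as mutual level 0? If `FALSE`, only
#'   rated pairs enter the matrix.
#' @return A `fleiss_kappa` object with extra elements `n_imputed` and
#'   `n_universe`.
#' @export
kappa_within_category <- function(ratings, drugs, impute = TRUE) {
  ratings <- validate_ratings(ratings)
  drugs <- unique(as.character(drugs))
  if (length(drugs) < 2) {
    rlang::abort("`drugs` must contain at least 2 identifiers.",
                 class = "ddic_domain_error")
  }
  out_ep <- setdiff(unique(c(ratings$drug_u, ratings$drug_v)), drugs)
  if (length(out_ep)) {
    rlang::abort(
      sprintf("Rating endpoint(s) outside the category: %s",
              paste(utils::head(out_ep, 5), collapse = ", ")),
      class = "ddic_domain_error"
    )
  }
  universe <- all_unordered_pairs(drugs)
  res <- complete_universe(ratings, universe, impute = impute,
                           n_raters = length(unique(ratings$rater)))
  fk <- fleiss_kappa(ratings_to_counts(res$ratings))
  fk$n_imputed <- res$n_imputed
  fk$n_universe <- res$n_universe
  fk
}

#' Fleiss' kappa over the product of two disjoint drug sets
#'
#' Restricts the generic statistic to the rectangular pair universe
#' (u in `set_x`, v in `set_y`): |X| x |Y| matrix rows. This single
#' operation serves the category-level C x O analysis and every
#' subcategory-pair cell (Cx x Cy and Cx x Oy). Unrated pairs are imputed
#' as mutual level 0 unless `impute = FALSE`.
#'
#' @param ratings Long ratings table; each rated pair must have one
#'   endpoint in `set_x` and the other in `set_y`.
#' @param set_x,set_y Disjoint character vectors of drug identifiers.
#' @param impute Impute unrated pairs as mutual level 0?
#' @return A `fleiss_kappa` object with extra elements `n_imputed` and
#'   `n_universe`.
#' @export
kappa_between_sets <- function(ratings, set_x, set_y, impute = TRUE) {
  ratings <- validate_ratings(ratings)
  set_x <- unique(as.character(set_x))
  set_y <- unique(as.character(set_y))
  if (length(set_x) == 0 || length(set_y) == 0) {
    rlang::abort("Both drug sets must be non-empty.", class = "ddic_domain_error")
  }
  if (length(intersect(set_x, set_y))) {
    rlang::abort(
      sprintf("Drug sets must be disjoint; shared: %s",
              paste(utils::head(intersect(set_x, set_y), 5), collapse = ", ")),
      class = "ddic_domain_error"
    )
  }
  in_x_u <- ratings$drug_u %in% set_x
  in_y_u <- ratings$drug_u %in% set_y
  in_x_v <- ratings$drug_v %in% set_x
  in_y_v <- ratings$drug_v %in% set_y
  ok <- (in_x_u & in_y_v) | (in_y_u & in_x_v)
  if (any(!ok)) {
    i <- which(!ok)[1]
    rlang::abort(
      sprintf("Rated pair (%s, %s) does not span the two sets.",
              ratings$drug_u[i], ratings$drug_v[i]),
      class = "ddic_domain_error"
    )
  }
  universe <- tidyr::crossing(drug_u = set_x, drug_v = set_y)
  res <- complete_universe(ratings, universe, impute = impute,
                           n_raters = length(unique(ratings$rater)))
  fk <- fleiss_kappa(ratings_to_counts(res$ratings))
  fk$n_imputed <- res$n_imputed
  fk$n_universe <- res$n_universe
  fk
}

#' Landis-Koch agreement band for a kappa value
#'
#' Classifies kappa into the conventional verbal bands after rounding
#' half-up to two decimals: negative values are *poor*, then *slight*
#' [0.00, 0.20], *fair* (0.20, 0.40], *moderate*
#' (0.40, 0.60], *substantial* (0.60, 0.80], *almost perfect* (0.80, 1.00),
#' and *perfect* reserved for kappa exactly 1 before rounding. Rounding
#' first matches how published agreement tables band values such as 0.203
#' (slight) versus 0.212 (fair).
#'
#' @param kappa Numeric vector in [-1, 1].
#' @return Character vector of band labels.
#' @examples
#' classify_band(c(-0.333, 0.203, 0.212, 0.655, 1))
#' @export
classify_band <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) == 0) {
    rlang::abort("`kappa` must be numeric.", class = "ddic_domain_error")
  }
  eps <- 1e-9
  if (any(is.na(kappa) | kappa < -1 - eps | kappa > 1 + eps)) {
    rlang::abort("`kappa` must lie in [-1, 1].", class = "ddic_domain_error")
  }
  r <- round_half_up(kappa, 2)
  ri <- as.integer(round(r * 100))
  dplyr::case_when(
    abs(kappa - 1) <= eps ~ "perfect",
    ri < 0L    ~ "poor",
    ri <= 20L  ~ "slight",
    ri <= 40L  ~ "fair",
    ri <= 60L  ~ "moderate",
    ri <= 80L  ~ "substantial",
    .default = "almost_perfect"
  )
}

#' Agreement band labels in increasing order
#' @return Character vector of the seven band labels.
#' @export
band_levels <- function() {
  c("poor", "slight", "fair", "moderate", "substantial",
    "almost_perfect", "perfect")
}

# Round half away from zero (the convention behind every printed percentage
# and banded kappa reproduced here); base round() is banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
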