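# Shared helpers for long ratings tables.
#
# The package's working representation of rated pairs is a long tibble with
# one row per (unordered pair, rater): columns drug_u, drug_v, rater, code.
# Pairs are unordered; the canonical key sorts the two identifiers.

pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "||")
}

#' Canonicalize an unordered ratings table
#'
#' Reorders each pair's endpoints so `drug_u <= drug_v`, making pair lookup
#' order-insensitive (checker queries are symmetric in the two drugs).
#'
#' @param ratings Data frame with columns `drug_u`, `drug_v`.
#' @return The same data frame with endpoints canonically ordered.
#' @export
canonicalize_pairs <- function(ratings) {
  u <- pmin(ratings$drug_u, ratings$drug_v)
  v <- pmax(ratings$drug_u, ratings$drug_v)
  ratings$drug_u <- u
  ratings$drug_v <- v
  ratings
}

validate_ratings <- function(ratings) {
  req <- c("drug_u", "drug_v", "rater", "code")
  if (!is.data.frame(ratings) || !all(req %in% names(ratings))) {
    rlang::abort(
      sprintf("`ratings` must be a data frame with columns %s.",
              paste(req, collapse = ", ")),
      class = "ddic_malformed_error"
    )
  }
  if (nrow(ratings) == 0) {
    rlang::abort("`ratings` is empty.", class = "ddic_domain_error")
  }
  ratings <- tibble::as_tibble(ratings)
  ratings$drug_u <- as.character(ratings$drug_u)
  ratings$drug_v <- as.character(ratings$drug_v)
  ratings$rater <- as.character(ratings$rater)
  self <- which(ratings$drug_u == ratings$drug_v)
  if (length(self)) {
    rlang::abort(
      sprintf("Self-pair (%s with itself) at row %d.",
              ratings$drug_u[self[1]], self[1]),
      class = "ddic_malformed_error"
    )
  }
  ratings$code <- validate_severity(ratings$code, "code")
  canonicalize_pairs(ratings)
}

all_unordered_pairs <- function(drugs) {
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) < 2) {
    return(tibble::tibble(drug_u = character(), drug_v = character()))
  }
  idx <- utils::combn(length(drugs), 2)
  tibble::tibble(drug_u = drugs[idx[1, ]], drug_v = drugs[idx[2, ]])
}

# Wide view for the two-rater analyses: one row per pair with the two codes
# in rater order, plus the absolute difference and stratum.
ratings_to_wide <- function(ratings) {
  ratings <- validate_ratings(ratings)
  raters <- sort(unique(ratings$rater))
  if (length(raters) != 2) {
    rlang::abort(
      sprintf("Exactly 2 raters are required for difference-based strata; found %d (%s).",
              length(raters), paste(utils::head(raters, 5), collapse = ", ")),
      class = "ddic_malformed_error"
    )
  }
  dup <- duplicated(paste(pair_key(ratings$drug_u, ratings$drug_v),
                          ratings$rater, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1]
    rlang::abort(
      sprintf("Duplicate rating for pair (%s, %s) by rater %s.",
              ratings$drug_u[i], ratings$drug_v[i], ratings$rater[i]),
      class = "ddic_malformed_error"
    )
  }
  wide <- tidyr::pivot_wider(
    ratings[, c("drug_u", "drug_v", "rater", "code")],
    names_from = "rater", values_from = "code"
  )
  miss <- which(is.na(wide[[raters[1]]]) | is.na(wide[[raters[2]]]))
  if (length(miss)) {
    rlang::abort(
      sprintf("Pair (%s, %s) is not rated by both raters.",
              wide$drug_u[miss[1]], wide$drug_v[miss[1]]),
      class = "ddic_malformed_error"
    )
  }
  wide$difference <- strength_difference(wide[[raters[1]]], wide[[raters[2]]])
  wide$stratum <- classify_stratum(wide$difference)
  attr(wide, "raters") <- raters
  wide
}
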