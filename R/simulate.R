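# Seeded two-rater severity simulator.
#
# The generator emulates the empirical shape of a two-checker severity
# dataset: the first rater draws each pair's code from a marginal heavily
# concentrated on level 0 ("no interaction found"); with probability `a`
# the second rater copies the first (agreement), otherwise it moves by a
# nonzero offset drawn from a disagreement kernel, resampled until the
# result stays on the 0-4 scale. Resampling (rather than clamping to the
# boundary) keeps the realized offset distribution symmetric for interior
# codes instead of piling mass onto codes 0 and 4.

#' Specification of a synthetic two-rater severity dataset
#'
#' Defaults reproduce the study shape the package's analyses assume: the
#' printed ATC Level-2 subcategory sizes (8 cardiovascular subcategories
#' totalling 137 drugs, 11 other subcategories totalling 189), a severity
#' marginal dominated by "not found", and an agreement probability of 0.8.
#'
#' @param c_sizes Named integer vector of cardiovascular subcategory sizes.
#' @param o_sizes Named integer vector of other-category subcategory sizes.
#' @param marginal Probabilities of severity levels 0..4 for rater 1 (sums
#'   to 1).
#' @param agreement Probability `a` that rater 2 copies rater 1.
#' @param kernel Named numeric vector of disagreement-offset weights; names
#'   are signed integer offsets, offset 0 must carry no mass.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `generator_spec`.
#' @export
generator_spec <- function(c_sizes = c(C01 = 46, C02 = 11, C03 = 15, C04 = 4,
                                       C07 = 13, C08 = 11, C09 = 19, C10 = 18),
                           o_sizes = c(A02 = 11, A10 = 23, A12 = 2, B01 = 36,
                                       G04 = 7, M01 = 19, M04 = 6,
                                       `N05-1` = 29, `N05-2` = 20,
                                       `N06-1` = 31, `N06-2` = 5),
                           marginal = c(0.95, 0.005, 0.03, 0.01, 0.005),
                           agreement = 0.8,
                           kernel = c(`-2` = 0.15, `-1` = 0.05,
                                      `1` = 0.1, `2` = 0.7),
                           seed = 1L) {
  if (length(marginal) != 5 || any(marginal < 0) ||
      abs(sum(marginal) - 1) > 1e-9) {
    rlang::abort("`marginal` must be 5 non-negative probabilities summing to 1.",
                 class = "ddic_validation_error")
  }
  if (!is.numeric(agreement) || agreement < 0 || agreement > 1) {
    rlang::abort("`agreement` must lie in [0, 1].",
                 class = "ddic_validation_error")
  }
  offs <- suppressWarnings(as.integer(names(kernel)))
  if (any(is.na(offs)) || any(kernel < 0) || sum(kernel) <= 0 ||
      any(offs == 0L & kernel > 0) || any(abs(offs) > 4L)) {
    rlang::abort(paste("`kernel` must assign non-negative weight to nonzero",
                       "integer offsets in -4..4, with positive total mass."),
                 class = "ddic_validation_error")
  }
  if (is.null(names(c_sizes)) || is.null(names(o_sizes)) ||
      any(c(c_sizes, o_sizes) < 1)) {
    rlang::abort("Subcategory sizes must be named and positive.",
                 class = "ddic_validation_error")
  }
  structure(
    list(c_sizes = c_sizes, o_sizes = o_sizes,
         marginal = marginal / sum(marginal), agreement = agreement,
         kernel = kernel / sum(kernel), seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Synthetic catalog for a generator specification
#'
#' @param spec A [generator_spec()].
#' @return A drug catalog tibble with synthetic drug ids of the form
#'   `"<subcategory>_<index>"`.
#' @export
synthetic_catalog <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  one <- function(sizes, category) {
    purrr::imap_dfr(as.list(sizes), function(k, sub) {
      tibble::tibble(
        drug_id = sprintf("%s_%03d", sub, seq_len(k)),
        name = sprintf("synthetic %s drug %d", sub, seq_len(k)),
        category = category,
        primary_subcategory = sub,
        atc_codes = sub
      )
    })
  }
  as_drug_catalog(dplyr::bind_rows(one(spec$c_sizes, "C"),
                                   one(spec$o_sizes, "O")))
}

#' Generate a synthetic two-rater ratings dataset
#'
#' Builds the catalog implied by the spec, enumerates the requested pair
#' universes, and rates every pair with two synthetic raters (`edic_a`,
#' `edic_b`) under the spec's marginal/agreement/kernel model. Identical
#' seeds give byte-identical tables.
#'
#' @param spec A [generator_spec()].
#' @param universe Which pair sets to rate: subset of `c("within_C",
#'   "C_cross_O")` (default both).
#' @return A list with elements `catalog` (tibble) and `ratings` (long
#'   tibble `drug_u`, `drug_v`, `rater`, `code`).
#' @export
generate_ratings <- function(spec, universe = c("within_C", "C_cross_O")) {
  stopifnot(inherits(spec, "generator_spec"))
  universe <- match.arg(universe, several.ok = TRUE)
  catalog <- synthetic_catalog(spec)
  pairs <- dplyr::bind_rows(
    if ("within_C" %in% universe) {
      enumerate_within_pairs(catalog, "C")[, c("drug_u", "drug_v")]
    },
    if ("C_cross_O" %in% universe) {
      canonicalize_pairs(
        enumerate_category_product(catalog, "C", "O")
      )[, c("drug_u", "drug_v")]
    }
  )
  codes <- with_seed(spec$seed, draw_pair_codes(nrow(pairs), spec))
  ratings <- dplyr::bind_rows(
    tibble::tibble(pairs, rater = "edic_a", code = codes$r1),
    tibble::tibble(pairs, rater = "edic_b", code = codes$r2)
  ) |>
    dplyr::arrange(.data$drug_u, .data$drug_v, .data$rater)
  list(catalog = catalog, ratings = ratings)
}

# Vectorized two-rater draw for N pairs under the generator model.
draw_pair_codes <- function(n_pairs, spec) {
  r1 <- sample(0:4, n_pairs, replace = TRUE, prob = spec$marginal)
  r2 <- r1
  copy <- stats::runif(n_pairs) < spec$agreement
  idx <- which(!copy)
  offs <- as.integer(names(spec$kernel))[spec$kernel > 0]
  feasible <- vapply(0:4, function(c) any(c + offs >= 0L & c + offs <= 4L),
                     logical(1))
  stuck <- unique(r1[idx])[!feasible[unique(r1[idx]) + 1L]]
  if (length(stuck)) {
    rlang::abort(
      sprintf("Disagreement kernel offers no valid offset from code(s) %s.",
              paste(stuck, collapse = ", ")),
      class = "ddic_validation_error"
    )
  }
  offs <- as.integer(names(spec$kernel))
  while (length(idx)) {
    draw <- sample(offs, length(idx), replace = TRUE, prob = spec$kernel)
    cand <- r1[idx] + draw
    ok <- cand >= 0L & cand <= 4L
    r2[idx[ok]] <- cand[ok]
    idx <- idx[!ok]
  }
  list(r1 = as.integer(r1), r2 = as.integer(r2))
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
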