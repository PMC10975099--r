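# Plain-text readers and writers: catalog TSV (drug names may contain
# commas), ratings CSV, counts-matrix CSV, and the JSON/CSV report bundle.

#' Read a drug catalog TSV
#'
#' Expected header: `drug_id`, `name`, `category`, `primary_subcategory`,
#' `atc_codes` (semicolon-separated ATC codes in one field).
#'
#' @param path Path to a tab-separated catalog file.
#' @return A validated drug catalog tibble.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Catalog file not found: %s", path),
                 class = "ddic_io_error")
  }
  cat_raw <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) {
      rlang::abort(sprintf("Cannot parse catalog %s: %s", path, conditionMessage(e)),
                   class = "ddic_io_error")
    }
  )
  if (nrow(cat_raw) == 0) {
    rlang::abort(sprintf("Catalog %s is empty.", path), class = "ddic_io_error")
  }
  withCallingHandlers(
    as_drug_catalog(cat_raw),
    error = function(e) {
      rlang::abort(sprintf("Catalog %s: %s", path, conditionMessage(e)),
                   class = "ddic_io_error", parent = e)
    }
  )
}

#' Write a drug catalog TSV
#' @param catalog A drug catalog.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- as_drug_catalog(catalog)
  readr::write_tsv(catalog[, c("drug_id", "name", "category",
                               "primary_subcategory", "atc_codes")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a ratings CSV
#'
#' Expected header: `drug_u`, `drug_v`, `rater`, then either
#' `severity_label` (with optional `recommendation`), harmonized through
#' the per-rater dialect assignment, or a pre-harmonized `severity_code`
#' column accepted verbatim after a range check.
#'
#' @param path Path to a comma-separated ratings file.
#' @param dialects Named character vector mapping rater id -> registered
#'   dialect (required when `severity_label` is present).
#' @return A canonicalized long ratings tibble (`drug_u`, `drug_v`,
#'   `rater`, `code`).
#' @export
read_ratings <- function(path, dialects = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Ratings file not found: %s", path),
                 class = "ddic_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("drug_u", "drug_v", "rater")
  if (!all(req %in% names(raw))) {
    rlang::abort(
      sprintf("Ratings %s: missing column(s) %s.", path,
              paste(setdiff(req, names(raw)), collapse = ", ")),
      class = "ddic_io_error"
    )
  }
  self <- which(raw$drug_u == raw$drug_v)
  if (length(self)) {
    rlang::abort(
      sprintf("Ratings %s, line %d: self-pair (%s with itself).",
              path, self[1] + 1L, raw$drug_u[self[1]]),
      class = "ddic_io_error"
    )
  }
  if ("severity_code" %in% names(raw)) {
    code <- suppressWarnings(as.integer(raw$severity_code))
    bad <- which(is.na(code) | code < 0L | code > 4L)
    if (length(bad)) {
      rlang::abort(
        sprintf("Ratings %s, line %d: invalid severity_code '%s'.",
                path, bad[1] + 1L, raw$severity_code[bad[1]]),
        class = "ddic_io_error"
      )
    }
  } else if ("severity_label" %in% names(raw)) {
    unknown_rater <- setdiff(unique(raw$rater), names(dialects))
    if (is.null(dialects) || length(unknown_rater)) {
      rlang::abort(
        sprintf("Ratings %s: no dialect assigned for rater(s) %s.",
                path, paste(unknown_rater %||% unique(raw$rater), collapse = ", ")),
        class = "ddic_config_error"
      )
    }
    rec <- if ("recommendation" %in% names(raw)) raw$recommendation else NULL
    code <- integer(nrow(raw))
    for (r in unique(raw$rater)) {
      i <- which(raw$rater == r)
      code[i] <- tryCatch(
        harmonize_severity(raw$severity_label[i],
                           if (is.null(rec)) NULL else rec[i],
                           dialect = dialects[[r]]),
        error = function(e) {
          rlang::abort(sprintf("Ratings %s (rater %s): %s",
                               path, r, conditionMessage(e)),
                       class = "ddic_io_error", parent = e)
        }
      )
    }
  } else {
    rlang::abort(
      sprintf("Ratings %s: need either a severity_label or severity_code column.",
              path),
      class = "ddic_io_error"
    )
  }
  validate_ratings(tibble::tibble(
    drug_u = raw$drug_u, drug_v = raw$drug_v, rater = raw$rater, code = code
  ))
}

#' Write a ratings CSV (pre-harmonized codes)
#' @param ratings Long ratings tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  out <- ratings[, c("drug_u", "drug_v", "rater", "code")]
  names(out)[4] <- "severity_code"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a counts matrix CSV
#'
#' One row per rated pair: `pair_id`, then one column per severity level
#' (`n0`..`n4`).
#'
#' @param counts Matrix from [ratings_to_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- tibble::tibble(pair_id = rownames(counts) %||%
                         as.character(seq_len(nrow(counts))))
  cnt <- tibble::as_tibble(as.data.frame(counts))
  names(cnt) <- paste0("n", colnames(counts))
  readr::write_csv(dplyr::bind_cols(df, cnt), path, progress = FALSE)
  invisible(path)
}

#' Read a counts matrix CSV
#' @param path Path written by [write_counts()].
#' @return An integer counts matrix with `n_raters` attribute.
#' @export
read_counts <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    pair_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$pair_id
  colnames(m) <- sub("^n", "", colnames(m))
  validate_counts(m)
}

# Convert a bundle to plain lists for stable JSON serialization.
bundle_to_list <- function(bundle) {
  df2l <- function(d) lapply(as.data.frame(d), function(col) {
    if (is.factor(col)) as.character(col) else col
  })
  list(
    manifest = list(
      n_drugs = bundle$manifest$n_drugs,
      subcategory_sizes = df2l(bundle$manifest$subcategory_sizes),
      n_ratings_rows = bundle$manifest$n_ratings_rows,
      raters = bundle$manifest$raters,
      modes = bundle$manifest$modes,
      decimals = bundle$manifest$decimals,
      impute = bundle$manifest$impute
    ),
    overall = df2l(bundle$overall),
    reports = lapply(bundle$reports, function(r) list(
      total_pairs = r$total_pairs,
      strata = df2l(r$strata),
      by_level = df2l(r$by_level),
      denominators = r$denominators
    )),
    sixway = lapply(bundle$sixway, df2l),
    band_tables = lapply(bundle$band_tables, df2l),
    matrices = lapply(bundle$matrices, function(m) list(
      mode = m$mode, cells = df2l(m$cells)
    ))
  )
}

#' Write a report bundle to a directory
#'
#' Emits `bundle.json` (every analysis in one stable-key-order document),
#' a dense kappa-matrix CSV and a band-table CSV per analysis mode, and —
#' last, so its presence marks a complete write — `manifest.json` with the
#' run settings and an md5 content hash per emitted file.
#'
#' @param bundle A `ddi_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "ddi_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    rlang::abort(sprintf("Output directory not writable: %s", out_dir),
                 class = "ddic_io_error")
  }
  written <- character()
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    written <<- c(written, p)
  }
  emit_csv <- function(d, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(d, rownames = "subcat_x"), p,
                     progress = FALSE)
    written <<- c(written, p)
  }
  emit_json(bundle_to_list(bundle), "bundle.json")
  for (mode in names(bundle$matrices)) {
    emit_csv(as.data.frame(as.matrix(bundle$matrices[[mode]])),
             sprintf("kappa_matrix_%s.csv", mode))
    p <- file.path(out_dir, sprintf("band_table_%s.csv", mode))
    readr::write_csv(bundle$band_tables[[mode]], p, progress = FALSE)
    written <- c(written, p)
  }
  manifest <- list(
    settings = bundle_to_list(bundle)$manifest,
    files = lapply(stats::setNames(written, basename(written)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a bundle directory
#'
#' @param out_dir Directory written by [write_bundle()].
#' @return The parsed `bundle.json` as a nested list.
#' @export
read_bundle <- function(out_dir) {
  p <- file.path(out_dir, "bundle.json")
  if (!file.exists(file.path(out_dir, "manifest.json"))) {
    rlang::abort(sprintf("No manifest.json in %s: incomplete bundle.", out_dir),
                 class = "ddic_io_error")
  }
  jsonlite::read_json(p, simplifyVector = TRUE)
}
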