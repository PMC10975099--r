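# Severity dialects and the unified 0-4 interaction-strength scale.
#
# Each electronic drug-interaction checker (EDIC) reports DDI severity in its
# own vocabulary. Both vocabularies collapse onto a five-level interaction
# strength code: 0 not found/unknown, 1 minor, 2 moderate, 3 major/serious,
# 4 contraindicated ("don't use together").

#' Harmonized severity levels
#'
#' The unified interaction-strength scale used throughout the package:
#' integer codes 0 to 4 with the canonical level names.
#'
#' @return A named integer vector mapping level name to code.
#' @examples
#' severity_levels()
#' @export
severity_levels <- function() {
  c(not_found = 0L, minor = 1L, moderate = 2L, major = 3L, contraindicated = 4L)
}

#' Human-readable label for a severity code
#'
#' @param code Integer vector of severity codes in 0..4.
#' @return A factor with levels not_found < minor < moderate < major <
#'   contraindicated.
#' @export
severity_label <- function(code) {
  code <- validate_severity(code)
  lv <- severity_levels()
  factor(names(lv)[code + 1L], levels = names(lv), ordered = TRUE)
}

validate_severity <- function(code, arg = "code") {
  if (length(code) == 0) {
    rlang::abort(sprintf("`%s` must be non-empty.", arg), class = "ddic_domain_error")
  }
  if (is.double(code)) {
    if (any(!is.na(code) & code != trunc(code))) {
      rlang::abort(sprintf("`%s` must contain integer severity codes.", arg),
                   class = "ddic_domain_error")
    }
    code <- as.integer(code)
  }
  if (!is.integer(code)) {
    rlang::abort(sprintf("`%s` must be an integer vector.", arg),
                 class = "ddic_domain_error")
  }
  bad <- which(is.na(code) | code < 0L | code > 4L)
  if (length(bad)) {
    rlang::abort(
      sprintf("`%s` contains invalid severity codes (must be 0..4): %s",
              arg, paste(utils::head(code[bad], 5), collapse = ", ")),
      class = "ddic_domain_error"
    )
  }
  code
}

# Registry of label dialects, one per checker. Populated with the two
# built-in checker vocabularies at load time; users can register more.
.dialects <- new.env(parent = emptyenv())

#' Normalize a severity label for dialect lookup
#'
#' Lower-cases, trims, collapses internal whitespace, and straightens
#' typographic apostrophes, so that e.g. "Don't Use Together" and
#' "don't use together" compare equal.
#'
#' @param x Character vector of labels.
#' @return Normalized character vector (NA stays NA).
#' @export
normalize_label <- function(x) {
  x <- as.character(x)
  x <- gsub("’", "'", x)
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

new_dialect <- function(name, entries) {
  # entries: named list keyed by normalized label; each value either an
  # integer code, or list(default = code, recommendations = named codes)
  structure(list(name = name, entries = entries), class = "ddic_dialect")
}

#' Register a severity-label dialect
#'
#' A dialect maps a checker's label vocabulary onto the 0-4 interaction
#' strength codes. An entry is either a single code, or a list with a
#' `default` code and a `recommendations` map keyed by recommendation text,
#' for checkers whose top label splits by professional recommendation.
#'
#' @param name Dialect identifier (e.g. `"webmd"`).
#' @param entries Named list: label -> code, or label -> list(default,
#'   recommendations). Labels and recommendation keys are normalized with
#'   [normalize_label()].
#' @param overwrite Replace an existing dialect of the same name?
#' @return The dialect name, invisibly.
#' @export
register_dialect <- function(name, entries, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!overwrite && exists(name, envir = .dialects, inherits = FALSE)) {
    rlang::abort(sprintf("Dialect '%s' is already registered.", name),
                 class = "ddic_config_error")
  }
  if (is.null(names(entries)) || any(names(entries) == "")) {
    rlang::abort("All dialect entries must be named by label.",
                 class = "ddic_config_error")
  }
  norm <- list()
  for (lab in names(entries)) {
    e <- entries[[lab]]
    if (is.list(e)) {
      def <- validate_severity(as.integer(e$default), "default")
      recs <- e$recommendations %||% list()
      rn <- normalize_label(names(recs))
      recs <- stats::setNames(
        lapply(recs, function(v) validate_severity(as.integer(v), "recommendation code")),
        rn
      )
      norm[[normalize_label(lab)]] <- list(default = def, recommendations = recs)
    } else {
      norm[[normalize_label(lab)]] <- validate_severity(as.integer(e), "code")
    }
  }
  assign(name, new_dialect(name, norm), envir = .dialects)
  invisible(name)
}

#' List registered dialects
#' @return Character vector of dialect names.
#' @export
list_dialects <- function() {
  sort(ls(envir = .dialects))
}

get_dialect <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !exists(name, envir = .dialects, inherits = FALSE)) {
    rlang::abort(
      sprintf("Dialect '%s' is not registered (known: %s).",
              as.character(name)[1] %||% "<missing>",
              paste(list_dialects(), collapse = ", ")),
      class = "ddic_config_error"
    )
  }
  get(name, envir = .dialects, inherits = FALSE)
}

#' Load dialect definitions from a YAML config file
#'
#' The file maps dialect name -> label -> code, where a code is either an
#' integer or a map with `default` and `recommendations` keys.
#'
#' @param path Path to a YAML file.
#' @param overwrite Replace dialects already registered under the same name?
#' @return Character vector of registered dialect names, invisibly.
#' @export
read_dialects <- function(path, overwrite = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Dialect config file not found: %s", path),
                 class = "ddic_io_error")
  }
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) register_dialect(nm, cfg[[nm]], overwrite = overwrite)
  invisible(names(cfg))
}

# Built-in vocabularies of the two checkers compared in the package's
# worked examples. WebMD's scale is positional; Drugs.com folds both level-3
# and level-4 interactions under "Major" and distinguishes them by the
# professional recommendation, of which only "Contraindicated" marks the
# do-not-combine level.
register_builtin_dialects <- function() {
  register_dialect("webmd", list(
    "0 Interactions Found" = 0L,
    "Unknown"              = 0L,
    "Minor"                = 1L,
    "Monitor closely"      = 2L,
    "Serious"              = 3L,
    "Don't use together"   = 4L
  ), overwrite = TRUE)
  register_dialect("drugscom", list(
    "Unknown"                = 0L,
    "No interactions found"  = 0L,
    "Minor"                  = 1L,
    "Moderate"               = 2L,
    "Major" = list(
      default = 3L,
      recommendations = list("Contraindicated" = 4L)
    )
  ), overwrite = TRUE)
}

#' Harmonize a checker severity label to the 0-4 scale
#'
#' Translates one checker's severity vocabulary into the unified
#' interaction-strength code. A missing or empty label means the checker
#' found no interaction and harmonizes to 0. For dialects whose entries
#' carry recommendation overrides (the Drugs.com "Major" level), the
#' recommendation text selects the final code; any unlisted or absent
#' recommendation falls back to the entry default.
#'
#' @param label Character vector of severity labels.
#' @param recommendation Optional character vector of recommendation texts
#'   (recycled to the length of `label`).
#' @param dialect Registered dialect identifier.
#' @return Integer vector of severity codes in 0..4.
#' @examples
#' harmonize_severity("Monitor closely", dialect = "webmd")
#' harmonize_severity("Major", "Contraindicated", dialect = "drugscom")
#' @export
harmonize_severity <- function(label, recommendation = NULL, dialect) {
  d <- get_dialect(dialect)
  n <- length(label)
  if (is.null(recommendation)) recommendation <- NA_character_
  recommendation <- rep_len(as.character(recommendation), n)
  lab <- normalize_label(label)
  rec <- normalize_label(recommendation)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (is.na(lab[i]) || lab[i] == "") {
      out[i] <- 0L
      next
    }
    entry <- d$entries[[lab[i]]]
    if (is.null(entry)) {
      rlang::abort(
        sprintf("Unknown severity label '%s' for dialect '%s'.",
                label[i], dialect),
        class = "ddic_unknown_label_error"
      )
    }
    if (is.list(entry)) {
      code <- entry$default
      if (!is.na(rec[i]) && rec[i] != "" &&
          !is.null(entry$recommendations[[rec[i]]])) {
        code <- entry$recommendations[[rec[i]]]
      }
      out[i] <- code
    } else {
      out[i] <- entry
    }
  }
  out
}

#' Absolute difference of two interaction-strength codes
#'
#' The per-pair disagreement measure for two checkers: the absolute
#' difference of the harmonized codes, in 0..4. Symmetric in its arguments.
#'
#' @param a,b Integer vectors of severity codes (recycled).
#' @return Integer vector of absolute differences.
#' @examples
#' strength_difference(3, 2)
#' @export
strength_difference <- function(a, b) {
  a <- validate_severity(a, "a")
  b <- validate_severity(b, "b")
  abs(a - b)
}

#' The five agreement strata
#'
#' Pairs are partitioned by the absolute strength-code difference between
#' the two checkers: 0 agreement, 1 mild agreement, 2 mild disagreement,
#' 3 disagreement, 4 strong disagreement.
#'
#' @return A tibble with columns `stratum` and `difference`.
#' @export
agreement_strata <- function() {
  tibble::tibble(
    stratum = stratum_levels(),
    difference = 0:4
  )
}

stratum_levels <- function() {
  c("agreement", "mild_agreement", "mild_disagreement",
    "disagreement", "strong_disagreement")
}

#' Classify a strength-code difference into an agreement stratum
#'
#' @param difference Integer vector of absolute code differences in 0..4.
#' @return An ordered factor over the five strata.
#' @examples
#' classify_stratum(0:4)
#' @export
classify_stratum <- function(difference) {
  if (is.double(difference) && all(difference == trunc(difference), na.rm = TRUE)) {
    difference <- as.integer(difference)
  }
  if (!is.integer(difference) || length(difference) == 0 ||
      any(is.na(difference) | difference < 0L | difference > 4L)) {
    rlang::abort("`difference` must contain integers in 0..4.",
                 class = "ddic_domain_error")
  }
  factor(stratum_levels()[difference + 1L],
         levels = stratum_levels(), ordered = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
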