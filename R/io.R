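provenance_header <- function(seed = NULL, extra = NULL) {
  bits <- c(sprintf("corrmediate %s",
                    as.character(utils::packageVersion("corrmediate"))),
            if (!is.null(seed)) sprintf("seed=%s", format(seed)),
            extra)
  paste("#", paste(bits, collapse = "; "))
}

#' Read a participant-level cohort CSV
#'
#' Comma-separated, UTF-8, header row mandatory, `.` decimal separator;
#' lines starting with `#` (provenance headers) are skipped. Columns named
#' in `required` must be present and numeric; unknown columns are preserved
#' but ignored by the analyses. Rows with missing values in required
#' columns are flagged (attribute `incomplete_rows`) and counted in a
#' message; they are dropped later, at fit time.
#'
#' @param path Path to the CSV file.
#' @param required Column names that must be present (default: the
#'   canonical analysis columns -- five temperaments, three mediators, two
#'   outcomes, age and BMI).
#' @return A `data.frame` with attribute `incomplete_rows` (integer row
#'   indices with missingness among required columns).
#' @export
read_cohort_csv <- function(path, required = analysis_columns()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in required) {
    x <- tab[[nm]]
    if (!is.numeric(x)) {
      blank <- !nzchar(trimws(as.character(x))) | is.na(x)
      conv <- suppressWarnings(as.numeric(as.character(x)))
      bad <- which(is.na(conv) & !blank)
      if (length(bad)) {
        stop(sprintf("unparseable numeric value in column '%s', row %d: '%s'",
                     nm, bad[1L], as.character(x)[bad[1L]]))
      }
      tab[[nm]] <- conv
    }
    if (is.integer(tab[[nm]])) tab[[nm]] <- as.numeric(tab[[nm]])
  }
  incomplete <- which(!stats::complete.cases(tab[, required, drop = FALSE]))
  if (length(incomplete)) {
    message(sprintf("%d of %d row(s) have missing analysis values",
                    length(incomplete), nrow(tab)))
  }
  attr(tab, "incomplete_rows") <- incomplete
  tab
}

#' Write a cohort table to CSV with a provenance header
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @param seed Seed recorded in the provenance comment line.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' Write battery results to CSV
#'
#' Formatted per [format_results_table()], preceded by a provenance
#' comment line.
#'
#' @param results A [run_battery()] table.
#' @param path Output path.
#' @param decimals Decimal places for estimates and CI bounds.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path, decimals = 2) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(attr(results, "seed")), con)
  utils::write.csv(format_results_table(results, decimals = decimals), con,
                   row.names = FALSE)
  invisible(path)
}

#' Serialise effect estimates to JSON
#'
#' A results-table-shaped JSON object (effect, estimate, ci_lo, ci_hi, p,
#' p_floor) plus metadata (J, seed, method, contrast, n_used).
#'
#' @param est An `effect_estimates` object or a [mediate_multi()] fit.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
effects_json <- function(est, path = NULL) {
  if (inherits(est, "mediate_multi")) est <- est$effects
  stopifnot(inherits(est, "effect_estimates"))
  payload <- list(
    effects = est$estimates,
    J = est$J, seed = est$seed, method = est$method,
    contrast = est$contrast, n_used = est$n_used,
    conf_level = est$conf_level,
    package = sprintf("corrmediate %s",
                      as.character(utils::packageVersion("corrmediate")))
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a run configuration from YAML or JSON
#'
#' Field names mirror the arguments of [cohort_config()], [mediate_multi()]
#' and [run_battery()]; the command-line interface merges these with flag
#' values (flag > config file > built-in default).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # keep keys like `n` (a YAML 1.1 boolean literal) as plain strings
    yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) x, "bool#no" = function(x) x))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json")
  }
}
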