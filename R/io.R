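# Cohort CSV reading and writing.
#
# Schema: columns age (years), smoker (0/1), sbp (mmHg), totalc (mmol/L),
# hdlc (mmol/L), diabetes (0/1), bmi (kg/m^2). Column names are matched
# case-insensitively and normalized to lower case on read. Missing cells are
# empty or the literal NA. Lines starting with '#' are comments.

#' Read a cohort CSV
#'
#' @param path path to a CSV file with the standard cohort columns (any
#'   order, case-insensitive names, `#` comment lines allowed).
#' @return Data frame with the normalized columns in canonical order.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  names(raw) <- tolower(names(raw))
  expected <- cohort_cols()
  unknown <- setdiff(names(raw), expected)
  missing <- setdiff(expected, names(raw))
  if (length(unknown) || length(missing))
    stop("cohort schema mismatch: ",
         if (length(unknown)) paste0("unknown column(s) ",
                                     paste(unknown, collapse = ", "), "; "),
         if (length(missing)) paste0("missing column(s) ",
                                     paste(missing, collapse = ", "), "; "),
         "expected exactly: ", paste(expected, collapse = ", "))
  out <- raw[expected]
  for (v in expected) {
    suppressWarnings(num <- as.numeric(out[[v]]))
    bad <- which(!is.na(out[[v]]) & is.na(num))
    if (length(bad))
      stop("non-numeric value in column '", v, "' at row ", bad[1])
    out[[v]] <- num
  }
  for (v in c("smoker", "diabetes")) {
    bad <- which(!is.na(out[[v]]) & !out[[v]] %in% c(0, 1))
    if (length(bad))
      stop("column '", v, "' must be 0 or 1; offending row ", bad[1])
  }
  for (v in c("age", "sbp", "totalc", "hdlc", "bmi")) {
    bad <- which(!is.na(out[[v]]) & out[[v]] <= 0)
    if (length(bad))
      stop("column '", v, "' must be strictly positive; offending row ", bad[1])
  }
  out
}

#' Write a cohort CSV
#'
#' @param cohort cohort table.
#' @param path output path.
#' @param comment optional character vector of header comment lines, written
#'   prefixed with `#` (used by the CLI to log seed, config hash and package
#'   version).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in comment) cat("# ", line, "\n", sep = "", file = con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}
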