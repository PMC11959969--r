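#' Validate a binary cohort table
#'
#' A binary cohort is a data frame with one row per individual and 0/1
#' columns for the disease-group indicators plus, optionally, the binary
#' covariates `sex` (1 = male) and `age_band` (1 = the older band, by
#' default 76+), and an integer `age_years` column. All columns except
#' `age_years` must be strictly 0/1; `sex` and `age_band`, when present,
#' are treated as ordinary binary network nodes.
#'
#' @param x a data frame.
#' @return `x` with class `binary_cohort` and attributes `variables` (all
#'   binary node columns) and `diseases` (the node columns that are neither
#'   `sex` nor `age_band`).
#' @export
as_binary_cohort <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) < 1L) stop_morbnet("cohort must have at least one row")
  vars <- setdiff(names(x), "age_years")
  for (v in vars) {
    col <- x[[v]]
    if (!is.numeric(col)) {
      suppressWarnings(col <- as.numeric(as.character(col)))
    }
    bad <- which(is.na(col) | !(col %in% c(0, 1)))
    if (length(bad)) {
      stop_morbnet("column '", v, "' is not 0/1 coded (first bad row: ",
                   bad[1L], ")")
    }
    x[[v]] <- as.integer(col)
  }
  if ("age_years" %in% names(x) && !is.numeric(x$age_years)) {
    stop_morbnet("'age_years' must be numeric")
  }
  attr(x, "variables") <- vars
  attr(x, "diseases") <- setdiff(vars, c("sex", "age_band"))
  class(x) <- c("binary_cohort", "data.frame")
  x
}

cohort_variables <- function(cohort) {
  attr(cohort, "variables") %||% setdiff(names(cohort), "age_years")
}

cohort_diseases <- function(cohort) {
  attr(cohort, "diseases") %||%
    setdiff(cohort_variables(cohort), c("sex", "age_band"))
}

#' Read a cohort from delimited text
#'
#' Reads a comma-separated cohort file (header row of variable names, one
#' row per individual, 0/1 cells for the binary indicators, optional
#' integer `age_years`). When `age_years` is present but `age_band` is
#' absent, the age band is derived as `age_years >= age_split`
#' (the 65–75 / 76+ dichotomy by default). Invalid cells raise errors
#' naming the offending row and column.
#'
#' @param path file path.
#' @param age_split age (years) at which the older band starts; default 76.
#' @return A [as_binary_cohort()] object.
#' @export
read_cohort <- function(path, age_split = 76) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("age_years" %in% names(df) && !("age_band" %in% names(df))) {
    df$age_band <- as.integer(df$age_years >= age_split)
  }
  as_binary_cohort(df)
}

#' Write a cohort as delimited text
#'
#' Comma-separated, UTF-8, header row, unquoted numeric cells; the inverse
#' of [read_cohort()].
#'
#' @param cohort a binary cohort.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
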