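#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr %>% mutate select filter arrange left_join bind_rows group_by summarise ungroup
NULL

VARIABLE_CATEGORIES <- c(
  "climate", "physiochemical", "primary_production",
  "population_estimate", "stock_productivity"
)

#' Describe the variables of an ecosystem table
#'
#' Builds the per-variable metadata used throughout the pipeline: the broad
#' ecological category of each series, whether it is one of the regional
#' sea-surface-temperature (SST) indices, and whether it is a response
#' variable that the models are scored on (biological components; climate and
#' physiochemical drivers are inputs, never scored).
#'
#' @param name Character vector of unique variable names.
#' @param category Category per variable; one of `"climate"`,
#'   `"physiochemical"`, `"primary_production"`, `"population_estimate"`,
#'   `"stock_productivity"`.
#' @param sst_region Logical; `TRUE` for regional SST series. Implies
#'   `category == "climate"`.
#' @param predicted Logical; `TRUE` for variables whose one-step-ahead
#'   predictions are evaluated. Must be `FALSE` for climate and
#'   physiochemical variables.
#' @return A tibble with columns `name`, `category`, `sst_region`,
#'   `predicted`.
#' @export
#' @examples
#' variable_descriptors(
#'   name = c("AMO", "SST_TX", "NPP"),
#'   category = c("climate", "climate", "primary_production"),
#'   sst_region = c(FALSE, TRUE, FALSE),
#'   predicted = c(FALSE, FALSE, TRUE)
#' )
variable_descriptors <- function(name, category,
                                 sst_region = FALSE,
                                 predicted = !category %in% c("climate", "physiochemical")) {
  d <- tibble(
    name = as.character(name),
    category = as.character(category),
    sst_region = rep_len(as.logical(sst_region), length(name)),
    predicted = rep_len(as.logical(predicted), length(name))
  )
  if (anyDuplicated(d$name)) {
    abort(paste0("duplicate variable name: ", d$name[duplicated(d$name)][1]))
  }
  bad <- setdiff(unique(d$category), VARIABLE_CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
  }
  if (any(d$sst_region & d$category != "climate")) {
    abort("sst_region variables must have category 'climate'")
  }
  if (any(d$predicted & d$category %in% c("climate", "physiochemical"))) {
    abort("climate and physiochemical variables cannot be predicted targets")
  }
  d
}

validate_ecosystem_table <- function(data, arg = "data", min_years = 3L) {
  if (!is.data.frame(data)) abort(paste0(arg, " must be a data frame"))
  if (!"year" %in% names(data)) abort(paste0(arg, " must have a 'year' column"))
  yrs <- data$year
  if (anyNA(yrs) || !is.numeric(yrs)) abort("'year' must be numeric with no gaps in recording")
  if (length(yrs) < min_years) abort(paste0("need at least ", min_years, " years of data"))
  if (any(diff(yrs) <= 0)) abort("non-monotone years")
  vars <- setdiff(names(data), "year")
  if (!length(vars)) abort("no variable columns")
  if (anyDuplicated(vars)) abort(paste0("duplicate variable name: ", vars[duplicated(vars)][1]))
  for (v in vars) {
    if (!is.numeric(data[[v]])) abort(paste0("column '", v, "' is not numeric"))
  }
  invisible(data)
}

table_variables <- function(data) setdiff(names(data), "year")

#' Read an annual ecosystem time-series table
#'
#' Reads a years-by-variables table from CSV (or, when the `readxl` package
#' is available, from a single-sheet XLSX file laid out the same way). The
#' first column must hold strictly increasing years; remaining columns are
#' numeric series. Blank cells are kept as missing values, never imputed.
#'
#' @param path Path to a `.csv` or `.xlsx` file whose first column is the
#'   year and whose header row names the variables.
#' @param descriptors Optional descriptor tibble from
#'   [variable_descriptors()]. When supplied, the file must contain exactly
#'   the described variables (any order); unknown columns are an error.
#' @return A tibble with a `year` column followed by the variable columns.
#' @export
read_ecosystem_table <- function(path, descriptors = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading .xlsx requires the 'readxl' package")
    }
    raw <- readxl::read_excel(path)
  } else {
    raw <- readr::read_csv(path,
      show_col_types = FALSE, progress = FALSE,
      name_repair = "minimal"
    )
  }
  names(raw)[1] <- "year"
  if (anyDuplicated(names(raw))) {
    abort(paste0("duplicate variable name: ", names(raw)[duplicated(names(raw))][1]))
  }
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(parsed) & col != "")
      if (length(bad)) {
        abort(paste0(
          "non-numeric cell in column '", names(raw)[j],
          "', row ", bad[1], ": '", col[bad[1]], "'"
        ))
      }
      raw[[j]] <- parsed
    }
  }
  data <- as_tibble(raw)
  validate_ecosystem_table(data, arg = path)
  if (!is.null(descriptors)) {
    vars <- table_variables(data)
    unknown <- setdiff(vars, descriptors$name)
    if (length(unknown)) {
      abort(paste0("unknown columns not in schema: ", paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(descriptors$name, vars)
    if (length(missing)) {
      abort(paste0("columns described but absent: ", paste(missing, collapse = ", ")))
    }
    data <- data[, c("year", descriptors$name)]
  }
  data
}

#' Standardize each series to mean 0, standard deviation 1
#'
#' Centers and scales every variable column by its own sample moments
#' (denominator n - 1), computed over non-missing entries only. The original
#' moments are attached as the `"standardization"` attribute so that model
#' outputs and temperature perturbations can be mapped back to physical
#' units; retrieve them with [standardization_params()].
#'
#' @param data Ecosystem table (tibble with a `year` column).
#' @return The standardized table, carrying a `"standardization"` attribute:
#'   a tibble with columns `variable`, `mean`, `sd` in original units.
#' @seealso [inverse_standardize()]
#' @export
standardize_table <- function(data) {
  validate_ecosystem_table(data)
  vars <- table_variables(data)
  params <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    n_obs <- sum(!is.na(x))
    if (n_obs < 2) abort(paste0("column '", v, "' has fewer than 2 observed values"))
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) abort(paste0("cannot standardize constant column '", v, "'"))
    tibble(variable = v, mean = m, sd = s)
  })
  out <- data
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    out[[v]] <- (data[[v]] - params$mean[i]) / params$sd[i]
  }
  attr(out, "standardization") <- params
  out
}

#' Retrieve standardization parameters
#'
#' @param data A table returned by [standardize_table()].
#' @return Tibble with columns `variable`, `mean`, `sd`.
#' @export
standardization_params <- function(data) {
  p <- attr(data, "standardization")
  if (is.null(p)) abort("table carries no standardization parameters; use standardize_table()")
  p
}

#' Map a standardized table back to original units
#'
#' @param data Ecosystem table on the standardized scale.
#' @param params Tibble with columns `variable`, `mean`, `sd`, as produced by
#'   [standardize_table()]; must cover every variable column of `data`.
#' @return Table in original units (a plain tibble; the attribute is dropped).
#' @export
inverse_standardize <- function(data, params = standardization_params(data)) {
  validate_ecosystem_table(data)
  vars <- table_variables(data)
  missing <- setdiff(vars, params$variable)
  if (length(missing)) {
    abort(paste0("no standardization params for: ", paste(missing, collapse = ", ")))
  }
  out <- data
  for (v in vars) {
    i <- match(v, params$variable)
    out[[v]] <- data[[v]] * params$sd[i] + params$mean[i]
  }
  attr(out, "standardization") <- NULL
  out
}
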