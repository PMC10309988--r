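# Shared data model: one row per farm, one column per survey variable, one
# column per annual expense (E1..E18) and revenue (R1..R3) code in USD.
#
# E5 (veterinary services) is stored as two independent quantities:
# `e5_real` (what the farm actually paid) and `e5_opportunity` (the value of
# state-subsidised services at the average private-visit price). Scenario A
# uses e5_real, scenario B uses e5_opportunity; there is no plain `e5` column.

#' Column schema for farm survey tables
#'
#' Returns the documented column schema used by [read_farm_table()] and
#' [write_farm_table()]: one row per column with its type, whether it is
#' mandatory, and the allowed levels for enumerated variables. Monetary
#' columns are annual amounts in USD for one fiscal year; missing optional
#' amounts are filled with 0 on read (with a warning).
#'
#' @return A tibble with columns `column`, `type` (`"character"`, `"numeric"`,
#'   `"integer"`, `"logical"`, `"enum"`), `mandatory` (logical), and `levels`
#'   (list column; `NULL` unless `type == "enum"`).
#' @export
#' @examples
#' farm_schema()
farm_schema <- function() {
  enum <- function(...) list(c(...))
  man <- tibble::tribble(
    ~column, ~type, ~mandatory, ~levels,
    "farm_id", "character", TRUE, list(NULL),
    "zone", "enum", TRUE, enum("area1_quijos", "area2_pichincha"),
    "technology", "enum", TRUE, enum("non", "semi", "technified"),
    "herd_size_adults", "integer", TRUE, list(NULL),
    "cows_in_production", "integer", TRUE, list(NULL),
    "milking_type", "enum", TRUE, enum("manual", "mechanical"),
    "farm_area_ha", "numeric", TRUE, list(NULL),
    "external_paddocks", "logical", TRUE, list(NULL),
    "manual_tick_removal", "logical", TRUE, list(NULL),
    "veterinary_control", "logical", TRUE, list(NULL),
    "education", "enum", TRUE, enum("primary", "high_school", "university"),
    "owner_hours_per_day", "numeric", TRUE, list(NULL),
    "milk_price", "numeric", TRUE, list(NULL),
    "daily_litres_dry", "numeric", TRUE, list(NULL),
    "daily_litres_rainy", "numeric", TRUE, list(NULL),
    "milk_destination", "enum", TRUE, enum("local", "cheese", "regional"),
    "permanent_paid_labor", "logical", TRUE, list(NULL),
    "crops_for_sale", "logical", TRUE, list(NULL),
    "concentrate_supplementation", "logical", TRUE, list(NULL),
    "grass_cut", "logical", TRUE, list(NULL),
    "insemination_by_professional", "logical", FALSE, list(NULL),
    "high_infestation", "logical", TRUE, list(NULL),
    "treatment_interval_days", "numeric", FALSE, list(NULL)
  )
  amounts <- c(
    paste0("e", 1:4), "e5_real", "e5_opportunity", paste0("e", 6:18),
    paste0("r", 1:3),
    "acaricide_drug_cost", "treatment_labor_cost", "hemo_repellent_drug_cost"
  )
  assay <- as.vector(t(outer(
    unname(ACARICIDE_PREFIX),
    c("_rep1_mortality", "_rep2_mortality", "_control_mortality"),
    paste0
  )))
  dplyr::bind_rows(
    man,
    tibble::tibble(column = amounts, type = "numeric", mandatory = FALSE,
                   levels = list(NULL)),
    tibble::tibble(column = assay, type = "numeric", mandatory = FALSE,
                   levels = list(NULL))
  )
}

expense_columns <- function() {
  c(paste0("e", 1:4), "e5_real", "e5_opportunity", paste0("e", 6:18))
}

revenue_columns <- function() paste0("r", 1:3)

#' Read a farm survey table
#'
#' Reads a table of farm records (one row per farm) from CSV or JSON,
#' checks the mandatory columns of [farm_schema()], coerces column types,
#' fills missing optional amounts with 0 (warning once per column), and
#' preserves unknown columns untouched. Row order is preserved.
#'
#' @param source Path to a CSV or JSON file.
#' @param format `"csv"` (RFC-4180, UTF-8, header row) or `"json"` (array of
#'   objects). Guessed from the file extension by default.
#' @return A tibble of farm records.
#' @export
read_farm_table <- function(source,
                            format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(source)) {
    abort(paste0("farm table not found: ", source), class = "acarecon_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- switch(format,
    csv = readr::read_csv(source, show_col_types = FALSE, progress = FALSE),
    json = tibble::as_tibble(jsonlite::fromJSON(source))
  )
  as_farm_table(raw)
}

#' Coerce a data frame to the farm-record schema
#'
#' @param x A data frame with the columns of [farm_schema()] (unknown columns
#'   are kept as metadata).
#' @return A tibble with schema columns coerced to their declared types.
#' @export
as_farm_table <- function(x) {
  x <- tibble::as_tibble(x)
  schema <- farm_schema()
  missing_mandatory <- setdiff(schema$column[schema$mandatory], names(x))
  if (length(missing_mandatory) > 0) {
    abort(
      paste0("farm table is missing mandatory column(s): ",
             paste(missing_mandatory, collapse = ", ")),
      class = "acarecon_schema_error"
    )
  }
  optional <- setdiff(schema$column[!schema$mandatory], names(x))
  for (col in optional) {
    type <- schema$type[schema$column == col]
    warn(paste0("optional column '", col, "' absent; filled with ",
                if (type == "logical") "FALSE" else "0"))
    x[[col]] <- if (type == "logical") FALSE else 0
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    x[[col]] <- switch(schema$type[i],
      character = as.character(x[[col]]),
      enum = as.character(x[[col]]),
      numeric = as.numeric(x[[col]]),
      integer = {
        v <- as.numeric(x[[col]])
        if (all(is.finite(v) & v == round(v))) as.integer(round(v)) else v
      },
      logical = coerce_logical(x[[col]], col)
    )
  }
  x
}

coerce_logical <- function(v, col) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  lv <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[lv %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[lv %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (anyNA(out) && !anyNA(v)) {
    abort(paste0("column '", col, "' cannot be read as logical"),
          class = "acarecon_schema_error")
  }
  out
}

#' Write a farm table to CSV or JSON
#'
#' @param farms A farm-record tibble (see [farm_schema()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_farm_table <- function(farms, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  switch(format,
    csv = readr::write_csv(farms, path, progress = FALSE),
    json = jsonlite::write_json(farms, path, digits = NA, auto_unbox = FALSE)
  )
  invisible(path)
}

#' Validate one farm record
#'
#' Checks a single farm record against the type invariants of the schema:
#' non-negative finite amounts, non-negative integer counts, enumerations
#' restricted to their listed levels, assay percentages within 0-100, and the
#' herd-consistency rule (cows in production should not exceed the adult herd
#' plus a young-stock allowance, reported at warning severity only).
#' Validation is total: it never raises on bad field values, it returns them.
#'
#' @param rec A one-row data frame or named list holding one farm record.
#' @param young_stock_allowance Extra head allowed above `herd_size_adults`
#'   when checking `cows_in_production` (heifers close to calving are often
#'   reported as in production). Default 0.
#' @return A tibble of violations with columns `field`, `rule`, `severity`
#'   (`"error"` or `"warning"`) and `message`; zero rows when the record is
#'   valid.
#' @export
validate_farm_record <- function(rec, young_stock_allowance = 0) {
  rec <- as.list(rec)
  schema <- farm_schema()
  v <- list()
  add <- function(field, rule, severity, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      field = field, rule = rule, severity = severity, message = message
    )
  }
  num1 <- function(x) suppressWarnings(as.numeric(x)[1])

  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (is.null(rec[[col]]) || length(rec[[col]]) == 0) {
      if (schema$mandatory[i]) {
        add(col, "presence", "error", paste0("mandatory field '", col, "' is missing"))
      }
      next
    }
    val <- rec[[col]]
    type <- schema$type[i]
    if (type %in% c("numeric", "integer")) {
      x <- num1(val)
      if (is.na(x) || !is.finite(x)) {
        add(col, "finite", "error", paste0("'", col, "' is not a finite number"))
        next
      }
      if (x < 0) {
        add(col, "non-negativity", "error",
            paste0("'", col, "' is negative (", format(x), ")"))
      }
      if (type == "integer" && x != round(x)) {
        add(col, "integrality", "error",
            paste0("'", col, "' is not a whole number (", format(x), ")"))
      }
      if (grepl("_mortality$", col) && (x < 0 || x > 100)) {
        add(col, "percentage-range", "error",
            paste0("'", col, "' outside [0, 100]"))
      }
    } else if (type == "enum") {
      levels <- unlist(schema$levels[[i]])
      if (!as.character(val)[1] %in% levels) {
        add(col, "enum-level", "error",
            paste0("'", col, "' has unknown level '", as.character(val)[1],
                   "' (allowed: ", paste(levels, collapse = ", "), ")"))
      }
    } else if (type == "logical") {
      if (!is.logical(val) || is.na(val[1])) {
        lv <- tryCatch(coerce_logical(val, col), error = function(e) NA)
        if (is.na(lv[1])) {
          add(col, "logical", "error", paste0("'", col, "' is not TRUE/FALSE"))
        }
      }
    }
  }

  herd <- num1(rec$herd_size_adults)
  cows <- num1(rec$cows_in_production)
  if (!is.na(herd) && !is.na(cows) && is.finite(herd) && is.finite(cows) &&
      cows > herd + young_stock_allowance) {
    add("cows_in_production", "herd-consistency", "warning",
        paste0("cows_in_production (", cows, ") exceeds herd_size_adults (",
               herd, ") plus young-stock allowance"))
  }
  if (length(v) == 0) {
    return(tibble::tibble(field = character(), rule = character(),
                          severity = character(), message = character()))
  }
  dplyr::bind_rows(v)
}

#' Validate every record of a farm table
#'
#' @param farms A farm-record tibble.
#' @inheritParams validate_farm_record
#' @return A tibble of violations with a leading `farm_id` column (zero rows
#'   when the whole table is valid).
#' @export
validate_farm_table <- function(farms, young_stock_allowance = 0) {
  out <- purrr::map(seq_len(nrow(farms)), function(i) {
    vi <- validate_farm_record(farms[i, ], young_stock_allowance)
    if (nrow(vi) == 0) return(NULL)
    id <- if ("farm_id" %in% names(farms)) as.character(farms$farm_id[i]) else NA_character_
    tibble::add_column(vi, farm_id = id, .before = 1)
  })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    return(tibble::tibble(farm_id = character(), field = character(),
                          rule = character(), severity = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}
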