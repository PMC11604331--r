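#' @importFrom rlang %||% .data
#' @importFrom stats median quantile rbinom rlnorm runif setNames
NULL

# Column schema for branded-food snapshots. All quantities are per 100 g
# (per 100 mL for beverages); salt in g (sodium sources must be converted
# at ingest, salt = sodium * 2.5). Missing values are empty cells, never 0.
snapshot_cols <- c(
  ean = "character", name = "character", ingredients = "character",
  food_group = "character", year = "integer",
  energy_kj = "numeric", sugars_g = "numeric", sfa_g = "numeric",
  salt_g = "numeric", protein_g = "numeric", fibre_g = "numeric",
  fvl_pct = "numeric", total_fat_g = "numeric",
  is_water = "logical", is_processed = "logical"
)

#' Validate a table of branded-food records
#'
#' Checks the snapshot schema and the record-level invariants: nutrient
#' quantities non-negative where present, `fvl_pct` within 0--100,
#' `sugars_g` at most 100, `sfa_g` not exceeding `total_fat_g` when both are
#' present, and (when a taxonomy is supplied) every `food_group` resolving to
#' a scoring category. Violations are reported with row indices.
#'
#' @param records A data frame following the snapshot schema.
#' @param taxonomy Optional `food_taxonomy` used to check group keys.
#' @param years Optional integer vector of admissible snapshot years.
#' @return The validated records as a tibble (invisibly usable in pipes).
#' @export
validate_records <- function(records, taxonomy = NULL, years = NULL) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(names(snapshot_cols), names(records))
  if (length(missing_cols) > 0) {
    stop("snapshot is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- records[, names(snapshot_cols)]
  records$year <- as.integer(records$year)
  for (col in names(snapshot_cols)[snapshot_cols == "numeric"]) {
    records[[col]] <- as.numeric(records[[col]])
  }

  fail <- function(rows, what) {
    if (length(rows) > 0) {
      stop("invalid record(s) at row(s) ",
        paste(utils::head(rows, 10), collapse = ", "),
        if (length(rows) > 10) " ..." else "", ": ", what,
        call. = FALSE
      )
    }
  }
  fail(which(is.na(records$ean) | records$ean == ""), "empty ean")
  fail(which(is.na(records$food_group) | records$food_group == ""),
    "empty food_group")
  fail(which(is.na(records$year)), "missing year")
  if (!is.null(years)) {
    fail(which(!records$year %in% as.integer(years)),
      paste0("year outside configured snapshot years (",
        paste(years, collapse = ", "), ")"))
  }
  for (col in c(
    "energy_kj", "sugars_g", "sfa_g", "salt_g", "protein_g",
    "fibre_g", "fvl_pct", "total_fat_g"
  )) {
    fail(which(!is.na(records[[col]]) & records[[col]] < 0),
      paste0("negative ", col))
  }
  fail(which(!is.na(records$sugars_g) & records$sugars_g > 100),
    "sugars_g above 100 g per 100 g")
  fail(which(!is.na(records$fvl_pct) & records$fvl_pct > 100),
    "fvl_pct above 100")
  both <- !is.na(records$sfa_g) & !is.na(records$total_fat_g)
  fail(which(both & records$sfa_g > records$total_fat_g + 1e-9),
    "sfa_g exceeds total_fat_g")
  fail(which(is.na(records$is_water) | is.na(records$is_processed)),
    "is_water/is_processed must be TRUE or FALSE")
  if (!is.null(taxonomy)) {
    resolve_category(unique(records$food_group), taxonomy)
  }
  records
}

#' Read a branded-food snapshot from CSV
#'
#' The file must carry the documented header (see [validate_records()]).
#' Missing values are encoded as empty cells; `0` is a legal nutrient value
#' and is never treated as missing. A file may hold one snapshot year
#' (supply `year` if it has no `year` column) or several years in one table.
#' If the source declares sodium instead of salt (`sodium_g` column and no
#' `salt_g`), it is converted as salt = sodium × 2.5 and a message is
#' emitted.
#'
#' @param path CSV file path.
#' @param taxonomy Optional `food_taxonomy` for group-key validation.
#' @param year Optional snapshot year, required when the file has no `year`
#'   column.
#' @param years Optional admissible snapshot years (passed to
#'   [validate_records()]).
#' @return Tibble of validated records.
#' @export
read_snapshot <- function(path, taxonomy = NULL, year = NULL, years = NULL) {
  if (!file.exists(path)) stop("snapshot file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!"year" %in% names(raw)) {
    if (is.null(year)) {
      stop("snapshot file has no 'year' column; supply year =", call. = FALSE)
    }
    raw$year <- as.character(year)
  }
  if ("sodium_g" %in% names(raw) && !"salt_g" %in% names(raw)) {
    raw$salt_g <- as.character(suppressWarnings(as.numeric(raw$sodium_g)) * 2.5)
    message("converted sodium_g to salt_g (salt = sodium x 2.5) for ", path)
  }
  missing_cols <- setdiff(names(snapshot_cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("snapshot header is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }

  parse_num <- function(x, col) {
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("malformed numeric value in column '", col, "' at row(s) ",
        paste(utils::head(bad, 10), collapse = ", "),
        call. = FALSE
      )
    }
    out
  }
  parse_lgl <- function(x, col) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(is.na(out) & x != "")
    if (length(bad) > 0) {
      stop("malformed logical value in column '", col, "' at row(s) ",
        paste(utils::head(bad, 10), collapse = ", "),
        call. = FALSE
      )
    }
    out
  }

  rec <- tibble::tibble(
    ean = raw$ean,
    name = raw$name,
    ingredients = raw$ingredients,
    food_group = raw$food_group,
    year = as.integer(parse_num(raw$year, "year")),
    energy_kj = parse_num(raw$energy_kj, "energy_kj"),
    sugars_g = parse_num(raw$sugars_g, "sugars_g"),
    sfa_g = parse_num(raw$sfa_g, "sfa_g"),
    salt_g = parse_num(raw$salt_g, "salt_g"),
    protein_g = parse_num(raw$protein_g, "protein_g"),
    fibre_g = parse_num(raw$fibre_g, "fibre_g"),
    fvl_pct = parse_num(raw$fvl_pct, "fvl_pct"),
    total_fat_g = parse_num(raw$total_fat_g, "total_fat_g"),
    is_water = parse_lgl(raw$is_water, "is_water"),
    is_processed = parse_lgl(raw$is_processed, "is_processed")
  )
  validate_records(rec, taxonomy = taxonomy, years = years)
}

#' Write a branded-food snapshot to CSV
#'
#' Deterministic column order; missing values are written as empty cells.
#' `write_snapshot()` then [read_snapshot()] is the identity on valid record
#' tables.
#'
#' @param records Validated records tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(records, path) {
  records <- validate_records(records)
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}
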