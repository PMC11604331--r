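#' Keep only processed foods
#'
#' Branded-food snapshots may contain unprocessed items; the analysis covers
#' processed foods only. The flag is taken from the data, not inferred.
#'
#' @param records Records tibble.
#' @return Records with `is_processed` TRUE.
#' @export
filter_processed <- function(records) {
  dplyr::filter(records, .data$is_processed)
}

#' Exclude records missing mandatory algorithm components
#'
#' A record is excluded iff any of the five mandatory components (energy,
#' salt, SFA, sugars, protein) is missing. Fibre and FVL missingness never
#' excludes: fibre declaration is not mandatory on labels and is imputed
#' later; FVL is estimated per food group.
#'
#' @param records Records tibble.
#' @return List with `records` (retained) and `report`: tibble of exclusion
#'   counts per food group and year.
#' @export
filter_missing_mandatory <- function(records) {
  mandatory <- c("energy_kj", "salt_g", "sfa_g", "sugars_g", "protein_g")
  miss <- Reduce(`|`, lapply(mandatory, function(col) is.na(records[[col]])))
  report <- records[miss, ] |>
    dplyr::count(.data$food_group, .data$year, name = "n_excluded")
  list(records = records[!miss, ], report = report)
}

#' Impute missing fibre by group-year mean
#'
#' Fibre declaration is optional on food labels, so fibre is often missing.
#' Missing values are replaced by the arithmetic mean of the observed fibre
#' contents within the same food group and year; observed values are left
#' untouched. A group-year whose fibre is entirely missing is an error (the
#' mean is undefined there).
#'
#' @param records Records tibble.
#' @return List with `records` (fibre complete) and `report`: tibble with
#'   per group-year counts of imputed values and the mean used.
#' @export
impute_fibre <- function(records) {
  grouped <- dplyr::group_by(records, .data$food_group, .data$year)
  report <- dplyr::summarise(grouped,
    n_missing = sum(is.na(.data$fibre_g)),
    n_observed = sum(!is.na(.data$fibre_g)),
    mean_fibre = mean(.data$fibre_g, na.rm = TRUE),
    .groups = "drop"
  )
  bad <- report[report$n_missing > 0 & report$n_observed == 0, ]
  if (nrow(bad) > 0) {
    stop(
      "cannot impute fibre: all values missing in group-year(s) ",
      paste(sprintf("%s/%d", bad$food_group, bad$year), collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::mutate(grouped,
    fibre_g = ifelse(is.na(.data$fibre_g),
      mean(.data$fibre_g, na.rm = TRUE), .data$fibre_g
    )
  ) |> dplyr::ungroup()
  report <- report[, c("food_group", "year", "n_missing", "mean_fibre")]
  names(report)[names(report) == "n_missing"] <- "n_imputed"
  list(records = out, report = report)
}

#' Assign per-group FVL estimates to records without a declared value
#'
#' Fruits/vegetables/legumes content is typically not available in branded
#' food databases; the taxonomy carries per-group estimates that are filled
#' in where `fvl_pct` is missing. Declared values are kept.
#'
#' @param records Records tibble.
#' @param taxonomy A `food_taxonomy` with `fvl_estimate` per group.
#' @return Records with `fvl_pct` complete.
#' @export
assign_fvl <- function(records, taxonomy = default_taxonomy()) {
  idx <- match(records$food_group, taxonomy$groups$food_group)
  if (anyNA(idx)) {
    stop("unknown food_group key(s): ",
      paste(unique(records$food_group[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  est <- taxonomy$groups$fvl_estimate[idx]
  need <- is.na(records$fvl_pct)
  no_est <- need & is.na(est)
  if (any(no_est)) {
    stop("no FVL estimate for group(s): ",
      paste(unique(records$food_group[no_est]), collapse = ", "),
      call. = FALSE
    )
  }
  records$fvl_pct[need] <- est[need]
  records
}

#' Exclude group-years smaller than a minimum size
#'
#' Group-level summaries are unreliable for very small groups; group-years
#' with fewer than `min_size` records are dropped entirely.
#'
#' @param records Records tibble.
#' @param min_size Minimum group-year size (default 10).
#' @return List with `records` (retained) and `report`: tibble of dropped
#'   group-years with their sizes.
#' @export
filter_small_groups <- function(records, min_size = 10) {
  sizes <- dplyr::count(records, .data$food_group, .data$year, name = "n")
  small <- sizes[sizes$n < min_size, ]
  keep <- !paste(records$food_group, records$year) %in%
    paste(small$food_group, small$year)
  names(small)[names(small) == "n"] <- "n_excluded"
  list(records = records[keep, ], report = small)
}

#' Run the full data-preparation pipeline
#'
#' Applies, in this fixed order: processed-food filter, mandatory-component
#' exclusion, fibre imputation, FVL assignment, small-group exclusion. The
#' order matters: imputation means are computed over records that survive
#' the mandatory-component filter, per food group and year.
#'
#' @param records Records tibble (one or several snapshot years).
#' @param taxonomy A `food_taxonomy`.
#' @param min_group_size Minimum group-year size (default 10).
#' @return List of class `preprocess_result`: `records` (analysis-ready),
#'   and `report` with `n_input`, `n_retained`, per-stage exclusion tables
#'   and the fibre-imputation table.
#' @export
preprocess_snapshot <- function(records, taxonomy = default_taxonomy(),
                                min_group_size = 10) {
  n_input <- nrow(records)
  step0 <- filter_processed(records)
  n_nonprocessed <- n_input - nrow(step0)
  step1 <- filter_missing_mandatory(step0)
  step2 <- impute_fibre(step1$records)
  step3 <- assign_fvl(step2$records, taxonomy)
  step4 <- filter_small_groups(step3, min_size = min_group_size)
  res <- list(
    records = step4$records,
    report = list(
      n_input = n_input,
      n_nonprocessed = n_nonprocessed,
      missing_mandatory = step1$report,
      fibre_imputation = step2$report,
      small_groups = step4$report,
      n_retained = nrow(step4$records)
    )
  )
  class(res) <- "preprocess_result"
  res
}

#' @export
print.preprocess_result <- function(x, ...) {
  r <- x$report
  cat("<preprocess_result>\n")
  cat("  input records:            ", r$n_input, "\n")
  cat("  non-processed excluded:   ", r$n_nonprocessed, "\n")
  cat("  missing-mandatory excluded:", sum(r$missing_mandatory$n_excluded), "\n")
  cat("  fibre values imputed:      ", sum(r$fibre_imputation$n_imputed), "\n")
  cat("  small group-years dropped: ", nrow(r$small_groups),
    " (", sum(r$small_groups$n_excluded), " records)\n",
    sep = ""
  )
  cat("  retained:                  ", r$n_retained, "\n")
  invisible(x)
}
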