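nutrient_cols <- c(
  "energy_kj", "sugars_g", "sfa_g", "salt_g", "protein_g", "fibre_g"
)

#' Summarise a scored snapshot at food-group level
#'
#' Produces the per-group building blocks of a market-snapshot report:
#' median and interquartile range (25th--75th percentile) of energy and each
#' nutrient; the distribution of class letters in percent; the integer-bin
#' histogram of the final sum of points; and the mean final sum. Medians use
#' the midpoint convention for even group sizes; percentiles use linear
#' interpolation (`stats::quantile()` type 7).
#'
#' @param scored Output of [score_records()] (may contain several years).
#' @param year Optional single year to restrict to.
#' @return Object of class `snapshot_summary`: list of tibbles `nutrients`,
#'   `class_distribution`, `histogram`, `final_sum` (n and mean per
#'   group-year).
#' @export
summarize_snapshot <- function(scored, year = NULL) {
  if (!is.null(year)) {
    scored <- dplyr::filter(scored, .data$year == !!year)
  }
  if (nrow(scored) == 0) stop("no records in requested year", call. = FALSE)
  by_gy <- dplyr::group_by(scored, .data$food_group, .data$year)

  nutrients <- scored |>
    tidyr::pivot_longer(dplyr::all_of(nutrient_cols),
      names_to = "nutrient", values_to = "value"
    ) |>
    dplyr::group_by(.data$food_group, .data$year, .data$nutrient) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      p25 = unname(stats::quantile(.data$value, 0.25, type = 7)),
      p75 = unname(stats::quantile(.data$value, 0.75, type = 7)),
      .groups = "drop"
    )

  class_distribution <- by_gy |>
    dplyr::count(nutri_class = factor(.data$nutri_class, levels = LETTERS[1:5]),
      .drop = FALSE, name = "count"
    ) |>
    dplyr::group_by(.data$food_group, .data$year) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(nutri_class = as.character(.data$nutri_class))

  histogram <- by_gy |>
    dplyr::count(.data$final_sum, name = "count") |>
    dplyr::ungroup()

  final_sum <- by_gy |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_final_sum = mean(.data$final_sum),
      .groups = "drop"
    )

  structure(
    list(
      nutrients = nutrients, class_distribution = class_distribution,
      histogram = histogram, final_sum = final_sum
    ),
    class = "snapshot_summary"
  )
}

#' @export
print.snapshot_summary <- function(x, ...) {
  cat("<snapshot_summary> ", nrow(x$final_sum), " group-year(s), ",
    sum(x$final_sum$n), " records\n",
    sep = ""
  )
  print(x$final_sum, n = Inf)
  invisible(x)
}

#' Percentage-point change in class distributions between two snapshots
#'
#' For each food group present in both summaries, the change per class is
#' the later percentage minus the earlier one, in percentage points. Within
#' a group the changes sum to zero (both distributions sum to 100).
#'
#' @param summary1,summary2 `snapshot_summary` objects for the earlier and
#'   later snapshot (each must cover a single year).
#' @return Tibble with `food_group`, `nutri_class`, `pct_year1`,
#'   `pct_year2`, `pp_change`.
#' @export
pp_change <- function(summary1, summary2) {
  d1 <- summary1$class_distribution
  d2 <- summary2$class_distribution
  if (length(unique(d1$year)) != 1 || length(unique(d2$year)) != 1) {
    stop("each summary must cover exactly one year", call. = FALSE)
  }
  dplyr::inner_join(
    dplyr::select(d1, "food_group", "nutri_class", pct_year1 = "pct"),
    dplyr::select(d2, "food_group", "nutri_class", pct_year2 = "pct"),
    by = c("food_group", "nutri_class")
  ) |>
    dplyr::mutate(pp_change = .data$pct_year2 - .data$pct_year1)
}

#' Overall change in a class distribution, per food group
#'
#' Aggregates the per-class percentage-point changes into one number per
#' group. The default `"total_variation"` metric is half the sum of absolute
#' changes — the share of the group's products (in percentage points) that
#' moved between classes. The `"abs_sum"` variant is the raw sum of absolute
#' changes.
#'
#' @param pp Output of [pp_change()].
#' @param metric `"total_variation"` (default) or `"abs_sum"`.
#' @return Tibble with `food_group` and `overall_change`.
#' @export
overall_change <- function(pp, metric = c("total_variation", "abs_sum")) {
  metric <- match.arg(metric)
  div <- if (metric == "total_variation") 2 else 1
  pp |>
    dplyr::group_by(.data$food_group) |>
    dplyr::summarise(
      overall_change = sum(abs(.data$pp_change)) / div,
      .groups = "drop"
    )
}

#' Top-k food groups by overall class-distribution change
#'
#' @param pp Output of [pp_change()].
#' @param k Number of groups to select (default 5).
#' @param metric Passed to [overall_change()].
#' @return Tibble of the `k` groups with the largest overall change, in
#'   descending order; ties are broken by food-group key order.
#' @export
top_changed_groups <- function(pp, k = 5,
                               metric = c("total_variation", "abs_sum")) {
  oc <- overall_change(pp, metric)
  oc <- oc[order(-oc$overall_change, oc$food_group), ]
  utils::head(oc, k)
}

#' EAN-matched sensitivity analysis
#'
#' Restricts the comparison to identical products available in both
#' snapshots (same EAN in both years) and reports, per food group, the share
#' of matched products whose class letter differs between the years. A sum
#' change that stays within one class counts as "no change". Duplicated EANs
#' within a year are an error.
#'
#' @param scored1,scored2 Scored record tibbles ([score_records()]) for the
#'   two years.
#' @return List with `n_matched`, `by_group` (per-group matched counts and
#'   percent changed), `class_distribution` (matched products' class
#'   distributions per year), and `matched` (the product-level pairs).
#' @export
matched_ean_sensitivity <- function(scored1, scored2) {
  for (s in list(scored1, scored2)) {
    dup <- unique(s$ean[duplicated(s$ean)])
    if (length(dup) > 0) {
      stop("duplicated EAN(s) within a year: ",
        paste(utils::head(dup, 10), collapse = ", "),
        call. = FALSE
      )
    }
  }
  matched <- dplyr::inner_join(
    dplyr::select(scored1, "ean", "food_group",
      class_year1 = "nutri_class", sum_year1 = "final_sum"
    ),
    dplyr::select(scored2, "ean",
      class_year2 = "nutri_class", sum_year2 = "final_sum"
    ),
    by = "ean"
  ) |>
    dplyr::mutate(changed = .data$class_year1 != .data$class_year2)

  by_group <- matched |>
    dplyr::group_by(.data$food_group) |>
    dplyr::summarise(
      n_matched = dplyr::n(),
      n_changed = sum(.data$changed),
      pct_changed = 100 * mean(.data$changed),
      .groups = "drop"
    )

  class_distribution <- dplyr::bind_rows(
    matched |>
      dplyr::count(.data$food_group,
        nutri_class = .data$class_year1, name = "count"
      ) |>
      dplyr::mutate(which_year = "year1"),
    matched |>
      dplyr::count(.data$food_group,
        nutri_class = .data$class_year2, name = "count"
      ) |>
      dplyr::mutate(which_year = "year2")
  ) |>
    dplyr::group_by(.data$food_group, .data$which_year) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup()

  list(
    n_matched = nrow(matched), by_group = by_group,
    class_distribution = class_distribution, matched = matched
  )
}

#' Median nutrient content within each class letter
#'
#' For in-depth analysis of the groups whose distribution changed most: the
#' median content of a nutrient, per class letter and year, within one food
#' group. Classes with no products are absent from the output (not reported
#' as zero).
#'
#' @param scored Scored records (one or several years).
#' @param nutrient One of the snapshot nutrient columns, e.g. `"sugars_g"`.
#' @param group Food-group key.
#' @return Tibble with `food_group`, `year`, `nutri_class`, `n`, `median`.
#' @export
median_by_class <- function(scored, nutrient, group) {
  stopifnot(nutrient %in% nutrient_cols)
  scored |>
    dplyr::filter(.data$food_group == !!group) |>
    dplyr::group_by(.data$food_group, .data$year, .data$nutri_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data[[nutrient]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(nutrient = !!nutrient, .after = "year")
}

#' Histogram of the final sum of points for one group-year
#'
#' @param scored Scored records.
#' @param group Food-group key.
#' @param year Snapshot year.
#' @return Tibble with `final_sum` (integer) and `count`; counts sum to the
#'   group-year's n.
#' @export
score_histogram <- function(scored, group, year) {
  sub <- dplyr::filter(scored, .data$food_group == !!group,
    .data$year == !!year)
  if (nrow(sub) == 0) {
    stop("no records for group ", group, " in year ", year, call. = FALSE)
  }
  dplyr::count(sub, .data$final_sum, name = "count")
}
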