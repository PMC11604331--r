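#' Run the full two-snapshot comparison pipeline
#'
#' End-to-end driver: data preparation of both snapshots, per-product
#' scoring, group-level summaries, percentage-point change analysis, top-k
#' selection, EAN-matched sensitivity analysis, per-class medians of the
#' nutrients of interest for the top-k groups, and final-sum histograms.
#' Optionally writes all tabular outputs as CSV (and histogram plots as PNG)
#' to an output directory; the run log records the scheme hash, boundary
#' convention and metric so a report is fully reproducible.
#'
#' @param snapshot1,snapshot2 Records tibbles or CSV paths for the earlier
#'   and later snapshot.
#' @param scheme A `nutriscore_scheme`.
#' @param taxonomy A `food_taxonomy`.
#' @param top_k Number of most-changed groups for the in-depth analysis.
#' @param metric Overall-change metric, see [overall_change()].
#' @param focus_nutrients Nutrients for the per-class medians of the top-k
#'   groups (default sugars and SFA).
#' @param min_group_size Minimum group-year size retained.
#' @param output_dir Directory for CSV/PNG artifacts, or `NULL` to skip
#'   writing.
#' @param write_plots Also write histogram PNGs (requires a PNG device).
#' @return Object of class `nutriscore_report`: list with `preprocess1`,
#'   `preprocess2`, `scored1`, `scored2`, `summary1`, `summary2`,
#'   `pp_change`, `overall_change`, `top_groups`, `sensitivity`,
#'   `median_by_class`, `histograms`, `log`.
#' @export
run_pipeline <- function(snapshot1, snapshot2,
                         scheme = default_scheme(),
                         taxonomy = default_taxonomy(),
                         top_k = 5,
                         metric = c("total_variation", "abs_sum"),
                         focus_nutrients = c("sugars_g", "sfa_g"),
                         min_group_size = 10,
                         output_dir = NULL, write_plots = FALSE) {
  metric <- match.arg(metric)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  load_snap <- function(x, which) {
    stage(paste0("read_", which), {
      if (is.character(x)) read_snapshot(x, taxonomy) else validate_records(x, taxonomy)
    })
  }
  rec1 <- load_snap(snapshot1, "snapshot1")
  rec2 <- load_snap(snapshot2, "snapshot2")

  prep1 <- stage("preprocess_snapshot1",
    preprocess_snapshot(rec1, taxonomy, min_group_size))
  prep2 <- stage("preprocess_snapshot2",
    preprocess_snapshot(rec2, taxonomy, min_group_size))
  scored1 <- stage("score_snapshot1", score_records(prep1$records, scheme, taxonomy))
  scored2 <- stage("score_snapshot2", score_records(prep2$records, scheme, taxonomy))
  sum1 <- stage("summarize_snapshot1", summarize_snapshot(scored1))
  sum2 <- stage("summarize_snapshot2", summarize_snapshot(scored2))
  pp <- stage("pp_change", pp_change(sum1, sum2))
  oc <- stage("overall_change", overall_change(pp, metric))
  top <- stage("top_changed_groups", top_changed_groups(pp, top_k, metric))
  sens <- stage("matched_ean_sensitivity",
    matched_ean_sensitivity(scored1, scored2))

  scored_all <- dplyr::bind_rows(scored1, scored2)
  mbc <- stage("median_by_class", dplyr::bind_rows(lapply(
    top$food_group,
    function(grp) {
      dplyr::bind_rows(lapply(
        focus_nutrients,
        function(nu) median_by_class(scored_all, nu, grp)
      ))
    }
  )))
  hist_tbl <- stage("score_histogram", dplyr::bind_rows(lapply(
    top$food_group,
    function(grp) {
      dplyr::bind_rows(lapply(
        unique(scored_all$year[scored_all$food_group == grp]),
        function(yr) {
          dplyr::mutate(score_histogram(scored_all, grp, yr),
            food_group = grp, year = yr, .before = 1
          )
        }
      ))
    }
  )))

  report <- structure(
    list(
      preprocess1 = prep1, preprocess2 = prep2,
      scored1 = scored1, scored2 = scored2,
      summary1 = sum1, summary2 = sum2,
      pp_change = pp, overall_change = oc, top_groups = top,
      sensitivity = sens, median_by_class = mbc, histograms = hist_tbl,
      log = list(
        scheme_name = scheme$name,
        scheme_hash = rlang::hash(unclass(scheme)),
        boundary_convention = scheme$boundary_convention,
        metric = metric, top_k = top_k,
        min_group_size = min_group_size,
        n_input = c(nrow(rec1), nrow(rec2)),
        n_retained = c(prep1$report$n_retained, prep2$report$n_retained)
      )
    ),
    class = "nutriscore_report"
  )
  if (!is.null(output_dir)) {
    write_report(report, output_dir, write_plots = write_plots)
  }
  report
}

#' Write a pipeline report bundle to disk
#'
#' Every table a figure is built from is also written as CSV, so downstream
#' checks never need to read pixels.
#'
#' @param report A `nutriscore_report`.
#' @param output_dir Output directory (created if absent).
#' @param write_plots Also render histogram PNGs.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir, write_plots = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(output_dir, name), na = "", progress = FALSE)
  }
  w(dplyr::bind_rows(report$summary1$nutrients, report$summary2$nutrients),
    "table1_nutrient_medians.csv")
  tab2 <- dplyr::bind_rows(
    report$summary1$class_distribution,
    report$summary2$class_distribution
  )
  w(tab2, "table2_class_distribution.csv")
  w(report$pp_change, "table2_pp_change.csv")
  w(report$overall_change, "overall_change.csv")
  w(report$top_groups, "top_groups.csv")
  w(report$median_by_class, "table3_median_by_class.csv")
  w(report$histograms, "final_sum_histograms.csv")
  w(report$sensitivity$by_group, "sensitivity_by_group.csv")
  w(report$scored1, "scores_year1.csv")
  w(report$scored2, "scores_year2.csv")
  w(tibble::tibble(
    key = names(unlist(report$log)),
    value = as.character(unlist(report$log))
  ), "run_log.csv")
  if (write_plots) {
    for (grp in report$top_groups$food_group) {
      p <- plot_score_histogram(report$histograms, grp)
      ggplot2::ggsave(
        file.path(output_dir, paste0("histogram_", grp, ".png")),
        p, width = 7, height = 4, dpi = 150
      )
    }
  }
  invisible(output_dir)
}

#' Plot the final-sum frequency distribution for one food group
#'
#' Integer-binned histogram of the final sum of points, one panel per
#' snapshot year, bars coloured by class letter when class information is
#' available.
#'
#' @param histograms Histogram tibble (`food_group`, `year`, `final_sum`,
#'   `count`), e.g. the `histograms` element of a report, or scored records
#'   (in which case the histogram is tallied here).
#' @param group Food-group key.
#' @param scheme Scheme used to colour bars by the class of each integer sum
#'   (solid categories only); `NULL` for uncoloured bars.
#' @param taxonomy Taxonomy used to resolve the group's category.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(histograms, group,
                                 scheme = default_scheme(),
                                 taxonomy = default_taxonomy()) {
  if ("nutri_class" %in% names(histograms) &&
    !"count" %in% names(histograms)) {
    histograms <- dplyr::count(histograms, .data$food_group, .data$year,
      .data$final_sum,
      name = "count"
    )
  }
  dat <- dplyr::filter(histograms, .data$food_group == !!group)
  if (nrow(dat) == 0) stop("unknown or empty group: ", group, call. = FALSE)
  if (!is.null(scheme)) {
    category <- resolve_category(group, taxonomy)
    dat$nutri_class <- classify_sum(dat$final_sum, category, scheme)
  } else {
    dat$nutri_class <- "unclassified"
  }
  class_fill <- c(
    A = "#038141", B = "#85BB2F", C = "#FECB02",
    D = "#EE8100", E = "#E63E11", unclassified = "grey50"
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$final_sum, y = .data$count, fill = .data$nutri_class
  )) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = class_fill, name = "Nutri-Score") +
    ggplot2::facet_wrap(~year, ncol = 1) +
    ggplot2::labs(
      x = "Final sum of points", y = "Number of products",
      title = paste("Final sum of points:", group)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.nutriscore_report <- function(x, ...) {
  cat("<nutriscore_report>\n")
  cat("  scheme: ", x$log$scheme_name, " (", x$log$boundary_convention,
    " boundaries)\n",
    sep = ""
  )
  cat("  records retained: ", paste(x$log$n_retained, collapse = " / "), "\n")
  cat("  top changed groups (", x$log$metric, "):\n", sep = "")
  print(x$top_groups, n = Inf)
  invisible(x)
}
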