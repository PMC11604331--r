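#' Food-group taxonomy
#'
#' A taxonomy maps food-group keys to display names, to one of the three
#' Nutri-Score scoring categories (`general_solid`, `beverage`,
#' `fats_oils_nuts_seeds`), and to a default fruits/vegetables/legumes (FVL)
#' estimate in percent, used for products without a declared FVL content.
#'
#' @param path Path to a taxonomy YAML file (see
#'   `system.file("extdata", "taxonomy.yaml", package = "nutriscoreR")` for
#'   the format).
#' @return An object of class `food_taxonomy`: a list with
#'   * `groups`: tibble with columns `food_group`, `display`, `category`,
#'     `fvl_estimate`;
#'   * `cheese_groups`: character vector of group keys treated as cheeses.
#' @export
read_taxonomy <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) {
    stop("taxonomy file has no 'groups' entry: ", path, call. = FALSE)
  }
  groups <- dplyr::bind_rows(lapply(raw$groups, function(g) {
    tibble::tibble(
      food_group = g$key,
      display = g$display %||% g$key,
      category = g$category,
      fvl_estimate = as.numeric(g$fvl_estimate %||% NA_real_)
    )
  }))
  tax <- structure(
    list(
      groups = groups,
      cheese_groups = as.character(raw$cheese_groups %||% character())
    ),
    class = "food_taxonomy"
  )
  validate_taxonomy(tax)
}

#' @rdname read_taxonomy
#' @export
default_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "taxonomy.yaml",
    package = "nutriscoreR", mustWork = TRUE
  ))
}

scoring_categories <- c("general_solid", "beverage", "fats_oils_nuts_seeds")

validate_taxonomy <- function(tax) {
  g <- tax$groups
  if (anyDuplicated(g$food_group)) {
    stop("duplicated food_group keys in taxonomy: ",
      paste(unique(g$food_group[duplicated(g$food_group)]), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(g$category), scoring_categories)
  if (length(bad) > 0) {
    stop("unknown scoring categories in taxonomy: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  missing_cheese <- setdiff(tax$cheese_groups, g$food_group)
  if (length(missing_cheese) > 0) {
    stop("cheese_groups not present in taxonomy: ",
      paste(missing_cheese, collapse = ", "),
      call. = FALSE
    )
  }
  tax
}

#' Resolve food groups to scoring categories
#'
#' Every record's food group must resolve to exactly one scoring category;
#' unknown keys are an error (they indicate a taxonomy/data mismatch, not a
#' condition to silently drop).
#'
#' @param food_group Character vector of food-group keys.
#' @param taxonomy A `food_taxonomy`.
#' @return Character vector of scoring categories, same length as
#'   `food_group`.
#' @export
resolve_category <- function(food_group, taxonomy = default_taxonomy()) {
  idx <- match(food_group, taxonomy$groups$food_group)
  if (anyNA(idx)) {
    stop(
      "unknown food_group key(s): ",
      paste(unique(food_group[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  taxonomy$groups$category[idx]
}

#' Write a taxonomy back to YAML
#'
#' @param taxonomy A `food_taxonomy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  out <- list(
    groups = lapply(seq_len(nrow(taxonomy$groups)), function(i) {
      g <- taxonomy$groups[i, ]
      list(
        key = g$food_group, display = g$display,
        category = g$category, fvl_estimate = g$fvl_estimate
      )
    }),
    cheese_groups = as.list(taxonomy$cheese_groups)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.food_taxonomy <- function(x, ...) {
  cat("<food_taxonomy> ", nrow(x$groups), " groups (",
    paste(table(x$groups$category), names(table(x$groups$category)),
      collapse = ", "
    ), ")\n",
    sep = ""
  )
  print(x$groups, n = Inf)
  invisible(x)
}
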