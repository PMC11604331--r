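#' Nutri-Score scoring schemes
#'
#' A scoring scheme bundles, for each scoring category (`general_solid`,
#' `beverage`, `fats_oils_nuts_seeds`): the component point grids, the sparse
#' fruits/vegetables/legumes (FVL) mapping, the protein-counting rule, the
#' special-rule parameters (red-meat protein cap, beverage sweetener points),
#' and the final-sum class bounds. It also carries the keyword lists used to
#' flag red meat and non-nutritive sweeteners, and the boundary convention
#' (`"inclusive"`: a value equal to a cutoff earns the point; `"strict"`: the
#' value must exceed the cutoff).
#'
#' The shipped default transcribes the updated algorithm (solid foods 2022,
#' beverages 2023). Its boundary convention is `"inclusive"`, the convention
#' under which reducing sugars from 17 to 13.5 g/100 g on the general-solid
#' grid removes two points.
#'
#' @param path Path to a scheme YAML file.
#' @return An object of class `nutriscore_scheme` (a validated nested list).
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  scheme <- structure(raw, class = "nutriscore_scheme")
  validate_scheme(scheme)
}

#' @rdname read_scheme
#' @export
default_scheme <- function() {
  read_scheme(system.file("extdata", "nutriscore_scheme.yaml",
    package = "nutriscoreR", mustWork = TRUE
  ))
}

validate_scheme <- function(scheme) {
  stopifnot(is.list(scheme$categories))
  if (!scheme$boundary_convention %in% c("strict", "inclusive")) {
    stop("boundary_convention must be 'strict' or 'inclusive'", call. = FALSE)
  }
  for (cat in names(scheme$categories)) {
    spec <- scheme$categories[[cat]]
    for (comp in names(spec$grids)) {
      g <- spec$grids[[comp]]
      cut <- as.numeric(g$cutoffs)
      if (any(diff(cut) <= 0)) {
        stop("cutoffs not strictly ascending for ", cat, "/", comp,
          call. = FALSE
        )
      }
      if (g$max_points > length(cut)) {
        stop("max_points exceeds attainable points for ", cat, "/", comp,
          call. = FALSE
        )
      }
    }
    fvl <- spec$fvl
    if (length(fvl$points) != length(fvl$cutoffs) + 1 ||
      any(diff(as.numeric(fvl$points)) < 0)) {
      stop("invalid FVL mapping for ", cat, call. = FALSE)
    }
    bounds <- class_bounds_table(spec$class_bounds)
    if (any(bounds$lower > bounds$upper)) {
      stop("empty class interval in ", cat, call. = FALSE)
    }
    gaps <- bounds$lower[-1] - bounds$upper[-nrow(bounds)]
    if (any(gaps != 1)) {
      stop("class bounds for ", cat,
        " are not contiguous/non-overlapping over integer sums",
        call. = FALSE
      )
    }
    if (is.finite(bounds$lower[1]) || is.finite(bounds$upper[nrow(bounds)])) {
      stop("class bounds for ", cat, " do not cover all attainable sums",
        call. = FALSE
      )
    }
  }
  scheme
}

class_bounds_table <- function(class_bounds) {
  tibble::tibble(
    class = names(class_bounds),
    lower = vapply(class_bounds, function(b) as.numeric(b[[1]]), numeric(1)),
    upper = vapply(class_bounds, function(b) as.numeric(b[[2]]), numeric(1))
  )
}

#' Points for one component value on a point grid
#'
#' The points are the number of grid cutoffs reached by the value: under the
#' `"strict"` convention a cutoff is reached when the value exceeds it, under
#' `"inclusive"` when the value equals or exceeds it. Points are capped at
#' the grid's `max_points`. FVL grids use their sparse mapping (a point value
#' per band) instead of counting.
#'
#' @param value Numeric vector of component quantities (must be
#'   non-negative).
#' @param grid A grid entry from a scheme: `list(cutoffs=, max_points=)`, or
#'   an FVL mapping `list(cutoffs=, points=)`.
#' @param convention `"strict"` or `"inclusive"`.
#' @return Integer vector of points.
#' @export
component_points <- function(value, grid, convention = "inclusive") {
  if (anyNA(value)) stop("missing component value", call. = FALSE)
  if (any(value < 0)) stop("negative component value", call. = FALSE)
  cutoffs <- as.numeric(grid$cutoffs)
  # strict: count cutoffs < value; inclusive: count cutoffs <= value
  n_reached <- findInterval(value, cutoffs, left.open = (convention == "strict"))
  if (!is.null(grid$points)) {
    pts <- as.numeric(grid$points)[n_reached + 1L]
  } else {
    pts <- pmin(n_reached, as.integer(grid$max_points))
  }
  as.integer(pts)
}

#' Map a final sum of points to a Nutri-Score class
#'
#' Classification is a step function over integer final sums, per-category:
#' higher sums never yield a better letter. For beverages the numeric bounds
#' start at B; class A is assigned only through the water rule in
#' [score_records()].
#'
#' @param final_sum Integer vector of final sums.
#' @param category Scoring category (single string).
#' @param scheme A `nutriscore_scheme`.
#' @return Character vector of class letters.
#' @export
classify_sum <- function(final_sum, category, scheme = default_scheme()) {
  if (any(final_sum != round(final_sum))) {
    stop("final_sum must be integer-valued", call. = FALSE)
  }
  spec <- scheme$categories[[category]]
  if (is.null(spec)) stop("unknown scoring category: ", category, call. = FALSE)
  bounds <- class_bounds_table(spec$class_bounds)
  idx <- findInterval(final_sum, c(bounds$lower[1], bounds$upper + 0.5))
  if (any(idx < 1 | idx > nrow(bounds))) {
    stop("final_sum outside attainable range for ", category, call. = FALSE)
  }
  bounds$class[idx]
}

#' @export
print.nutriscore_scheme <- function(x, ...) {
  cat("<nutriscore_scheme> ", x$name %||% "(unnamed)",
    " | boundary convention: ", x$boundary_convention, "\n",
    sep = ""
  )
  for (cat_name in names(x$categories)) {
    spec <- x$categories[[cat_name]]
    b <- class_bounds_table(spec$class_bounds)
    cat("  ", cat_name, ": grids {",
      paste(names(spec$grids), collapse = ", "), "}; classes ",
      paste(sprintf("%s[%s,%s]", b$class, b$lower, b$upper), collapse = " "),
      "\n",
      sep = ""
    )
  }
  invisible(x)
}
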