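fold_text <- function(x) {
  x[is.na(x)] <- ""
  x <- tolower(x)
  # fold diacritics so e.g. "knackebrod" matches labels with umlauts;
  # glibc transliteration renders accents as quote marks, which we drop
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  gsub("['\"`^~]", "", x)
}

match_keywords <- function(name, ingredients, keywords) {
  if (length(keywords) == 0) {
    return(rep(FALSE, max(length(name), length(ingredients))))
  }
  text <- paste(fold_text(name), fold_text(ingredients))
  keywords <- fold_text(as.character(keywords))
  hit <- rep(FALSE, length(text))
  for (kw in keywords) {
    hit <- hit | grepl(kw, text, fixed = TRUE)
  }
  hit
}

#' Flag red meat and non-nutritive sweeteners from label text
#'
#' Case-insensitive, diacritic-folded substring match of the configured
#' keyword list against product name and ingredient text, mirroring how
#' red-meat products (for the protein cap) and sweetened beverages (for the
#' sweetener points) are identified from label data.
#'
#' @param name,ingredients Character vectors (may be empty strings or `NA`).
#' @param keywords Character vector of terms; defaults to the shipped
#'   scheme's lists.
#' @return Logical vector.
#' @export
detect_red_meat <- function(name, ingredients,
                            keywords = default_scheme()$keywords$red_meat) {
  match_keywords(name, ingredients, keywords)
}

#' @rdname detect_red_meat
#' @export
detect_sweeteners <- function(name, ingredients,
                              keywords = default_scheme()$keywords$sweeteners) {
  match_keywords(name, ingredients, keywords)
}

# Per-category component point table for a records tibble. Returns a tibble
# of integer point columns. Mandatory components must be present upstream.
component_point_table <- function(records, spec, category, convention) {
  mandatory <- c("energy_kj", "sugars_g", "sfa_g", "salt_g", "protein_g")
  for (col in mandatory) {
    if (anyNA(records[[col]])) {
      stop(
        "missing mandatory component '", col, "' for ", category,
        " record(s); exclude them with filter_missing_mandatory() first",
        call. = FALSE
      )
    }
  }
  if (anyNA(records$fibre_g)) {
    stop("missing fibre_g; impute with impute_fibre() first", call. = FALSE)
  }
  if (anyNA(records$fvl_pct)) {
    stop("missing fvl_pct; assign with assign_fvl() first", call. = FALSE)
  }
  if (category == "fats_oils_nuts_seeds") {
    if (anyNA(records$total_fat_g)) {
      stop("total_fat_g required for fats/oils/nuts/seeds records",
        call. = FALSE
      )
    }
    ratio <- ifelse(records$total_fat_g > 0,
      100 * records$sfa_g / records$total_fat_g, 0
    )
    sfa_pts <- component_points(ratio, spec$grids$sfa_fat_ratio, convention)
  } else {
    sfa_pts <- component_points(records$sfa_g, spec$grids$sfa, convention)
  }
  tibble::tibble(
    energy_points = component_points(records$energy_kj, spec$grids$energy, convention),
    sugars_points = component_points(records$sugars_g, spec$grids$sugars, convention),
    sfa_points = sfa_pts,
    salt_points = component_points(records$salt_g, spec$grids$salt, convention),
    protein_points = component_points(records$protein_g, spec$grids$protein, convention),
    fibre_points = component_points(records$fibre_g, spec$grids$fibre, convention),
    fvl_points = component_points(records$fvl_pct, spec$fvl, convention)
  )
}

#' Negative (unfavourable) points for records of one scoring category
#'
#' Sums the points for energy, sugars, saturated fat (the SFA/total-fat
#' ratio for fats, oils, nuts and seeds) and salt. Beverages flagged as
#' containing non-nutritive sweeteners additionally receive the scheme's
#' sweetener points.
#'
#' @param records Records tibble (preprocessed: mandatory components
#'   present).
#' @param scheme A `nutriscore_scheme`.
#' @param category Scoring category of these records (single string).
#' @param has_sweetener Logical vector (beverages only; default all FALSE).
#' @return Integer vector of negative sums.
#' @export
negative_points <- function(records, scheme = default_scheme(),
                            category = "general_solid",
                            has_sweetener = FALSE) {
  spec <- scheme$categories[[category]]
  if (is.null(spec)) stop("unknown scoring category: ", category, call. = FALSE)
  pts <- component_point_table(records, spec, category,
    scheme$boundary_convention)
  n <- pts$energy_points + pts$sugars_points + pts$sfa_points + pts$salt_points
  if (category == "beverage") {
    n <- n + ifelse(rep_len(has_sweetener, nrow(records)),
      as.integer(spec$sweetener_points), 0L
    )
  }
  as.integer(n)
}

#' Positive (favourable) points and the protein-counting decision
#'
#' Sums fibre, FVL and — when counted — protein points. Protein points are
#' dropped when the negative sum reaches the category's threshold (11 for
#' general solids, 7 for fats/oils/nuts/seeds, never for beverages), with
#' cheeses exempt under the solid-food algorithm. Red-meat products have
#' protein points capped at the scheme's cap.
#'
#' @param records Preprocessed records tibble.
#' @param negative_sum Integer vector from [negative_points()].
#' @param scheme A `nutriscore_scheme`.
#' @param category Scoring category (single string).
#' @param is_red_meat,is_cheese Logical vectors (recycled).
#' @return Tibble with `positive_sum` (applied positive points) and
#'   `protein_counted`.
#' @export
positive_points <- function(records, negative_sum,
                            scheme = default_scheme(),
                            category = "general_solid",
                            is_red_meat = FALSE, is_cheese = FALSE) {
  spec <- scheme$categories[[category]]
  if (is.null(spec)) stop("unknown scoring category: ", category, call. = FALSE)
  pts <- component_point_table(records, spec, category,
    scheme$boundary_convention)
  n <- nrow(records)
  is_red_meat <- rep_len(is_red_meat, n)
  is_cheese <- rep_len(is_cheese, n)
  protein_pts <- pts$protein_points
  cap <- spec$red_meat_protein_cap
  if (!is.null(cap)) {
    protein_pts <- ifelse(is_red_meat, pmin(protein_pts, as.integer(cap)),
      protein_pts
    )
  }
  threshold <- as.numeric(spec$protein_rule$negative_threshold %||% Inf)
  counted <- negative_sum < threshold
  if (isTRUE(spec$protein_rule$cheese_exempt)) {
    counted <- counted | is_cheese
  }
  tibble::tibble(
    positive_sum = as.integer(pts$fibre_points + pts$fvl_points +
      ifelse(counted, protein_pts, 0L)),
    protein_counted = counted
  )
}

#' Score branded-food records with the Nutri-Score algorithm
#'
#' Computes, for every record: the per-component points, the negative and
#' applied positive sums, the final sum of points (negative minus applied
#' positive) and the class letter. The scoring category comes from the
#' taxonomy; red meat and sweeteners are flagged from the label text via the
#' scheme's keyword lists (overridable); cheeses are identified by food
#' group. Water-flagged beverages receive class A regardless of their sum;
#' all other beverages classify B--E.
#'
#' Records must be preprocessed: mandatory components present, fibre imputed
#' and FVL assigned (see [preprocess_snapshot()]).
#'
#' @param records Preprocessed records tibble.
#' @param scheme A `nutriscore_scheme`.
#' @param taxonomy A `food_taxonomy`.
#' @param is_red_meat,has_sweetener Optional logical overrides for the
#'   keyword-based flags.
#' @return The input tibble with score columns appended: `category`,
#'   `is_red_meat`, `is_cheese`, `has_sweetener`, the seven
#'   `*_points` columns, `negative_sum`, `positive_sum`, `protein_counted`,
#'   `final_sum`, `nutri_class`.
#' @export
score_records <- function(records, scheme = default_scheme(),
                          taxonomy = default_taxonomy(),
                          is_red_meat = NULL, has_sweetener = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    stop("no records to score", call. = FALSE)
  }
  category <- resolve_category(records$food_group, taxonomy)
  if (is.null(is_red_meat)) {
    is_red_meat <- detect_red_meat(records$name, records$ingredients,
      scheme$keywords$red_meat)
  }
  if (is.null(has_sweetener)) {
    has_sweetener <- detect_sweeteners(records$name, records$ingredients,
      scheme$keywords$sweeteners)
  }
  is_cheese <- records$food_group %in% taxonomy$cheese_groups

  out <- vector("list", length(unique(category)))
  idx_all <- split(seq_len(nrow(records)), category)
  for (k in seq_along(idx_all)) {
    cat_k <- names(idx_all)[k]
    idx <- idx_all[[k]]
    rec_k <- records[idx, ]
    spec <- scheme$categories[[cat_k]]
    pts <- component_point_table(rec_k, spec, cat_k,
      scheme$boundary_convention)
    nsum <- negative_points(rec_k, scheme, cat_k, has_sweetener[idx])
    pos <- positive_points(rec_k, nsum, scheme, cat_k,
      is_red_meat[idx], is_cheese[idx])
    final_sum <- nsum - pos$positive_sum
    cls <- classify_sum(final_sum, cat_k, scheme)
    if (cat_k == "beverage") {
      cls[rec_k$is_water] <- "A"
    }
    out[[k]] <- dplyr::bind_cols(
      tibble::tibble(
        .row = idx, category = cat_k,
        is_red_meat = is_red_meat[idx], is_cheese = is_cheese[idx],
        has_sweetener = has_sweetener[idx]
      ),
      pts,
      tibble::tibble(
        negative_sum = nsum,
        positive_sum = pos$positive_sum,
        protein_counted = pos$protein_counted,
        final_sum = as.integer(final_sum),
        nutri_class = cls
      )
    )
  }
  scores <- dplyr::bind_rows(out)
  scores <- scores[order(scores$.row), ]
  scores$.row <- NULL
  dplyr::bind_cols(records, scores)
}

#' Score a single record
#'
#' Convenience wrapper around [score_records()] for one product; returns the
#' score fields as a list.
#'
#' @inheritParams score_records
#' @param record A one-row records tibble (or a list coercible to one).
#' @return A list with the score fields of the single record.
#' @export
score_record <- function(record, scheme = default_scheme(),
                         taxonomy = default_taxonomy()) {
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  scored <- score_records(record, scheme, taxonomy)
  as.list(scored[, setdiff(names(scored), names(record))])
}
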