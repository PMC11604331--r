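# Build valid record tibbles with sensible defaults; any field can be
# overridden (scalar or length-n vector).
make_records <- function(n = 1, ...) {
  rec <- tibble::tibble(
    ean = sprintf("ean%05d", seq_len(n)),
    name = paste("product", seq_len(n)),
    ingredients = "",
    food_group = "breakfast_cereals",
    year = 2018L,
    energy_kj = 1000,
    sugars_g = 10,
    sfa_g = 2,
    salt_g = 0.5,
    protein_g = 5,
    fibre_g = 3,
    fvl_pct = 0,
    total_fat_g = NA_real_,
    is_water = FALSE,
    is_processed = TRUE
  )
  overrides <- list(...)
  for (col in names(overrides)) {
    rec[[col]] <- rep_len(overrides[[col]], n)
  }
  rec
}

# Random but valid compositions for property-style suites.
random_records <- function(n, food_group = "breakfast_cereals",
                           year = 2018L) {
  make_records(
    n,
    food_group = food_group, year = year,
    energy_kj = runif(n, 0, 3800),
    sugars_g = runif(n, 0, 80),
    sfa_g = runif(n, 0, 25),
    salt_g = runif(n, 0, 5),
    protein_g = runif(n, 0, 30),
    fibre_g = runif(n, 0, 12),
    fvl_pct = runif(n, 0, 100)
  )
}

# Independent brute-force oracle for grid points: count cutoffs reached,
# capped. Deliberately loop-based and separate from the engine.
oracle_points <- function(value, cutoffs, max_points, convention) {
  vapply(value, function(v) {
    reached <- if (convention == "strict") sum(v > cutoffs) else sum(v >= cutoffs)
    min(reached, max_points)
  }, numeric(1))
}

# Sort-based oracle for the median (midpoint convention) and linearly
# interpolated percentiles.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] * (1 - (h - lo)) + s[lo + 2] * (h - lo)
}
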