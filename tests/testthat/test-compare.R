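scheme <- default_scheme()
tax <- default_taxonomy()

scored_fixture <- function(n = 60, seed = 81) {
  set.seed(seed)
  rec <- dplyr::bind_rows(
    random_records(n, "breakfast_cereals"),
    random_records(n, "sweets_sweet_goods")
  )
  rec$ean <- sprintf("ean%05d", seq_len(nrow(rec)))
  score_records(rec, scheme, tax)
}

test_that("group summaries match sort-based oracles on toy groups", {
  set.seed(91)
  for (n in 1:5) {
    rec <- random_records(n)
    s <- summarize_snapshot(score_records(rec, scheme, tax))
    sug <- s$nutrients[s$nutrients$nutrient == "sugars_g", ]
    expect_equal(sug$median, oracle_median(rec$sugars_g), info = n)
    expect_equal(sug$p25, oracle_percentile(rec$sugars_g, 0.25), info = n)
    expect_equal(sug$p75, oracle_percentile(rec$sugars_g, 0.75), info = n)
  }
  # larger random groups, all nutrients
  scored <- scored_fixture(80)
  s <- summarize_snapshot(scored)
  for (i in seq_len(nrow(s$nutrients))) {
    row <- s$nutrients[i, ]
    x <- scored[[row$nutrient]][scored$food_group == row$food_group]
    expect_equal(row$median, oracle_median(x))
    expect_equal(row$p25, oracle_percentile(x, 0.25))
    expect_equal(row$p75, oracle_percentile(x, 0.75))
  }
})

test_that("identical records collapse to zero-width IQR and one class at 100%", {
  rec <- make_records(12)
  s <- summarize_snapshot(score_records(rec, scheme, tax))
  expect_true(all(s$nutrients$p25 == s$nutrients$p75))
  cd <- s$class_distribution
  expect_equal(sort(cd$pct, decreasing = TRUE)[1], 100)
  expect_equal(sum(cd$pct), 100)
})

test_that("class percentages sum to 100 and histogram counts sum to n", {
  s <- summarize_snapshot(scored_fixture())
  sums <- tapply(
    s$class_distribution$pct,
    paste(s$class_distribution$food_group, s$class_distribution$year), sum
  )
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-12)
  hist_n <- tapply(s$histogram$count,
    paste(s$histogram$food_group, s$histogram$year), sum)
  expect_equal(
    as.numeric(hist_n[paste(s$final_sum$food_group, s$final_sum$year)]),
    s$final_sum$n
  )
})

test_that("percentage-point changes are arithmetic on the two distributions", {
  # forced example: (50,50,0,0,0) -> (40,50,10,0,0)
  mk <- function(pcts, year) {
    structure(list(class_distribution = tibble::tibble(
      food_group = "g", year = year, nutri_class = LETTERS[1:5],
      count = pcts, pct = pcts
    )), class = "snapshot_summary")
  }
  pp <- pp_change(mk(c(50, 50, 0, 0, 0), 2018), mk(c(40, 50, 10, 0, 0), 2020))
  expect_equal(pp$pp_change, c(-10, 0, 10, 0, 0))
  expect_equal(overall_change(pp)$overall_change, 10)
  expect_equal(overall_change(pp, "abs_sum")$overall_change, 20)

  # identical distributions: all zero
  pp0 <- pp_change(mk(c(50, 50, 0, 0, 0), 2018), mk(c(50, 50, 0, 0, 0), 2020))
  expect_equal(pp0$pp_change, rep(0, 5))
  expect_equal(overall_change(pp0)$overall_change, 0)
})

test_that("pp changes are antisymmetric and sum to zero per group", {
  s1 <- summarize_snapshot(scored_fixture(seed = 111))
  scored2 <- scored_fixture(seed = 112)
  scored2$year <- 2020L
  s2 <- summarize_snapshot(scored2)
  pp12 <- pp_change(s1, s2)
  pp21 <- pp_change(s2, s1)
  expect_equal(pp12$pp_change, -pp21$pp_change)
  sums <- tapply(pp12$pp_change, pp12$food_group, sum)
  expect_equal(as.numeric(sums), rep(0, length(sums)), tolerance = 1e-12)
})

test_that("top-k selection recovers groups with injected shifts and breaks ties by key order", {
  pp <- tibble::tibble(
    food_group = rep(c("a_group", "b_group", "c_group", "d_group"), each = 5),
    nutri_class = rep(LETTERS[1:5], 4),
    pp_change = c(
      c(-20, 0, 20, 0, 0), # a: overall 20
      c(-5, 5, 0, 0, 0), # b: overall 5
      c(-5, 0, 5, 0, 0), # c: overall 5 (tie with b)
      c(0, 0, 0, 0, 0) # d: 0
    )
  )
  top <- top_changed_groups(pp, k = 3)
  expect_equal(top$food_group, c("a_group", "b_group", "c_group"))
  expect_equal(top$overall_change, c(20, 5, 5))
})

test_that("EAN-matched sensitivity counts exactly the class-changed shared products", {
  # disjoint EAN sets: nothing matched
  s1 <- scored_fixture(seed = 121)
  s2 <- scored_fixture(seed = 122)
  s2$ean <- paste0("other", seq_len(nrow(s2)))
  sens <- matched_ean_sensitivity(s1, s2)
  expect_equal(sens$n_matched, 0)
  expect_equal(nrow(sens$by_group), 0)

  # identical snapshots: matched but nothing changed
  sens_id <- matched_ean_sensitivity(s1, s1)
  expect_equal(sens_id$n_matched, nrow(s1))
  expect_equal(sens_id$by_group$pct_changed, rep(0, nrow(sens_id$by_group)))

  # constructed reformulation: exactly the shifted products change class
  rec1 <- make_records(20,
    sugars_g = 10, energy_kj = 335, sfa_g = 0, salt_g = 0,
    protein_g = 0, fibre_g = 0
  )
  rec2 <- rec1
  rec2$year <- 2020L
  rec2$sugars_g[1:6] <- 60 # pushes sugars points far up
  sens_c <- matched_ean_sensitivity(
    score_records(rec1, scheme, tax), score_records(rec2, scheme, tax)
  )
  expect_equal(sens_c$by_group$n_changed, 6)
  expect_equal(sens_c$by_group$pct_changed, 100 * 6 / 20)

  # order invariance and products in only one year are ignored
  extra <- score_records(make_records(5, ean = paste0("solo", 1:5)), scheme, tax)
  shuffled <- dplyr::bind_rows(extra, score_records(rec2, scheme, tax))
  shuffled <- shuffled[rev(seq_len(nrow(shuffled))), ]
  sens_s <- matched_ean_sensitivity(score_records(rec1, scheme, tax), shuffled)
  expect_equal(sens_s$by_group$n_changed, sens_c$by_group$n_changed)
  expect_equal(sens_s$n_matched, 20)

  # duplicated EANs are rejected
  dup <- dplyr::bind_rows(s1, s1[1, ])
  expect_error(matched_ean_sensitivity(dup, s1), "duplicated EAN")
})

test_that("per-class medians report only populated classes and ascend on a monotone construction", {
  # sugar content drives both the class and the median: medians must ascend
  rec <- make_records(40,
    sugars_g = seq(1, 60, length.out = 40),
    energy_kj = seq(300, 2500, length.out = 40),
    sfa_g = 0, salt_g = 0, protein_g = 0, fibre_g = 0
  )
  scored <- score_records(rec, scheme, tax)
  mbc <- median_by_class(scored, "sugars_g", "breakfast_cereals")
  mbc <- mbc[order(mbc$nutri_class), ]
  expect_true(all(diff(mbc$median) > 0))
  expect_equal(sum(mbc$n), 40)
  # a class with one record reports that record's value; empty classes are
  # absent rather than zero
  one <- score_records(make_records(1, sugars_g = 0, energy_kj = 0,
    sfa_g = 0, salt_g = 0, protein_g = 0, fibre_g = 0), scheme, tax)
  m1 <- median_by_class(one, "sugars_g", "breakfast_cereals")
  expect_equal(nrow(m1), 1)
  expect_equal(m1$median, 0)
  expect_equal(m1$nutri_class, "A")
})

test_that("final-sum histograms equal a brute-force tally", {
  scored <- scored_fixture(seed = 131)
  h <- score_histogram(scored, "breakfast_cereals", 2018)
  tall <- table(scored$final_sum[scored$food_group == "breakfast_cereals"])
  expect_equal(h$count, as.integer(tall[as.character(h$final_sum)]))
  expect_equal(sum(h$count), sum(scored$food_group == "breakfast_cereals"))
  single <- score_records(make_records(1), scheme, tax)
  h1 <- score_histogram(single, "breakfast_cereals", 2018)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 1L)
  expect_error(score_histogram(scored, "pizzas", 2018), "no records")
})
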