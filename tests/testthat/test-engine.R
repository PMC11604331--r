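scheme <- default_scheme()
tax <- default_taxonomy()

test_that("keyword flags match a membership oracle over the configured lists", {
  expect_true(detect_sweeteners("cola zero", "water, aspartame, e950"))
  expect_true(detect_sweeteners("frisdrank", "zoetstof: sucralose"))
  expect_false(detect_sweeteners("milk", "milk, sugar"))
  expect_true(detect_red_meat("smoked sausage", "varkensvlees, zout"))
  expect_true(detect_red_meat("Rundvlees snack", ""))
  expect_false(detect_red_meat("chicken soup", "chicken, water"))
  # empty text and empty keyword lists are never matches
  expect_false(detect_red_meat("", ""))
  expect_false(detect_sweeteners("anything", "aspartame", keywords = character()))
  # diacritics are folded before matching
  expect_true(detect_sweeteners("limonade", "aspártaëm" , keywords = "aspartaem"))
})

test_that("negative points equal the sum of independently computed component points", {
  set.seed(21)
  rec <- random_records(50)
  n <- negative_points(rec, scheme, "general_solid")
  spec <- scheme$categories$general_solid
  conv <- scheme$boundary_convention
  manual <- oracle_points(rec$energy_kj, spec$grids$energy$cutoffs, 10, conv) +
    oracle_points(rec$sugars_g, spec$grids$sugars$cutoffs, 15, conv) +
    oracle_points(rec$sfa_g, spec$grids$sfa$cutoffs, 10, conv) +
    oracle_points(rec$salt_g, spec$grids$salt$cutoffs, 20, conv)
  expect_equal(n, as.integer(manual))

  zero <- make_records(1,
    energy_kj = 0, sugars_g = 0, sfa_g = 0, salt_g = 0
  )
  expect_equal(negative_points(zero, scheme, "general_solid"), 0L)
})

test_that("sweetened beverages receive extra unfavourable points", {
  rec <- make_records(2, food_group = "soft_drinks")
  n <- negative_points(rec, scheme, "beverage", has_sweetener = c(FALSE, TRUE))
  expect_equal(n[2] - n[1],
    as.integer(scheme$categories$beverage$sweetener_points))
})

test_that("fats/oils records need total fat and are scored on the SFA ratio", {
  rec <- make_records(1, food_group = "fats_oils", sfa_g = 30, total_fat_g = NA)
  expect_error(negative_points(rec, scheme, "fats_oils_nuts_seeds"),
    "total_fat_g")

  # ratio 50% scores more ratio points than ratio 12.5%, same absolute SFA
  lo <- make_records(1, food_group = "fats_oils", sfa_g = 10, total_fat_g = 80)
  hi <- make_records(1, food_group = "fats_oils", sfa_g = 10, total_fat_g = 20)
  expect_gt(
    negative_points(hi, scheme, "fats_oils_nuts_seeds"),
    negative_points(lo, scheme, "fats_oils_nuts_seeds")
  )
})

test_that("protein counting follows the negative-sum threshold with cheese exemption", {
  # low negative sum: protein counts
  lo <- make_records(1, protein_g = 20)
  p_lo <- positive_points(lo, negative_sum = 10L, scheme, "general_solid")
  expect_true(p_lo$protein_counted)
  # at the threshold: dropped
  p_hi <- positive_points(lo, negative_sum = 11L, scheme, "general_solid")
  expect_false(p_hi$protein_counted)
  expect_equal(p_lo$positive_sum - p_hi$positive_sum,
    component_points(20, scheme$categories$general_solid$grids$protein))
  # cheese keeps protein whatever the negative sum
  p_cheese <- positive_points(lo, negative_sum = 30L, scheme, "general_solid",
    is_cheese = TRUE)
  expect_true(p_cheese$protein_counted)
  # fats category uses its own (lower) threshold
  fat <- make_records(1, food_group = "fats_oils", protein_g = 20,
    total_fat_g = 10)
  expect_false(
    positive_points(fat, 7L, scheme, "fats_oils_nuts_seeds")$protein_counted
  )
  expect_true(
    positive_points(fat, 6L, scheme, "fats_oils_nuts_seeds")$protein_counted
  )
  # beverages always count protein
  bev <- make_records(1, food_group = "soft_drinks", protein_g = 5)
  expect_true(positive_points(bev, 40L, scheme, "beverage")$protein_counted)
})

test_that("red-meat protein points are capped, so red meat never scores better positives", {
  rec <- make_records(1, protein_g = 25, fibre_g = 0, fvl_pct = 0)
  p_other <- positive_points(rec, 0L, scheme, "general_solid")
  p_red <- positive_points(rec, 0L, scheme, "general_solid", is_red_meat = TRUE)
  cap <- scheme$categories$general_solid$red_meat_protein_cap
  expect_equal(p_red$positive_sum, as.integer(cap))
  expect_lte(p_red$positive_sum, p_other$positive_sum)
  # zero favourable components give zero positive points
  zero <- make_records(1, protein_g = 0, fibre_g = 0, fvl_pct = 0)
  expect_equal(positive_points(zero, 0L, scheme, "general_solid")$positive_sum, 0L)
})

test_that("score_records composes points, sums and classes deterministically", {
  set.seed(31)
  rec <- random_records(40)
  scored <- score_records(rec, scheme, tax)
  expect_equal(scored$final_sum, scored$negative_sum - scored$positive_sum)
  expect_equal(
    scored$nutri_class,
    classify_sum(scored$final_sum, "general_solid", scheme)
  )
  # purity: identical call, identical result
  expect_identical(scored, score_records(rec, scheme, tax))
  # mixed categories keep row order
  mix <- dplyr::bind_rows(
    make_records(2, food_group = "soft_drinks"),
    make_records(2, food_group = "breakfast_cereals"),
    make_records(2, food_group = "fats_oils", total_fat_g = 30, sfa_g = 10)
  )
  mixed <- score_records(mix, scheme, tax)
  expect_equal(mixed$ean, mix$ean)
  expect_equal(mixed$category, rep(
    c("beverage", "general_solid", "fats_oils_nuts_seeds"), each = 2
  ))
})

test_that("only water-flagged beverages can reach class A", {
  rec <- dplyr::bind_rows(
    make_records(3,
      food_group = "soft_drinks", is_water = TRUE,
      energy_kj = 0, sugars_g = 0, sfa_g = 0, salt_g = 0, protein_g = 0,
      fibre_g = 0, fvl_pct = 0
    ),
    make_records(20,
      food_group = "soft_drinks",
      energy_kj = seq(0, 400, length.out = 20),
      sugars_g = seq(0, 12, length.out = 20),
      sfa_g = 0, salt_g = 0.02, protein_g = 0, fibre_g = 0, fvl_pct = 0
    )
  )
  scored <- score_records(rec, scheme, tax)
  expect_equal(scored$nutri_class[scored$is_water], rep("A", 3))
  expect_true(all(scored$nutri_class[!scored$is_water] %in% c("B", "C", "D", "E")))
})

test_that("a general solid with final sum 2 classifies as B", {
  # energy 670 kJ -> 2 points (inclusive), all else zero
  rec <- make_records(1,
    energy_kj = 670, sugars_g = 0, sfa_g = 0, salt_g = 0,
    protein_g = 0, fibre_g = 0, fvl_pct = 0
  )
  res <- score_record(rec, scheme, tax)
  expect_equal(res$final_sum, 2L)
  expect_equal(res$nutri_class, "B")
})

test_that("scoring requires preprocessed records", {
  expect_error(score_records(make_records(1, protein_g = NA), scheme, tax),
    "protein_g")
  expect_error(score_records(make_records(1, fibre_g = NA), scheme, tax),
    "impute_fibre")
  expect_error(score_records(make_records(1, fvl_pct = NA), scheme, tax),
    "assign_fvl")
})

test_that("unfavourable increases never improve, favourable increases never worsen the class", {
  set.seed(41)
  n <- 250
  base <- random_records(n)
  groups <- sample(c("breakfast_cereals", "sweets_sweet_goods", "soft_drinks"),
    n, replace = TRUE)
  base$food_group <- groups
  scored0 <- score_records(base, scheme, tax)
  rank0 <- match(scored0$nutri_class, LETTERS)

  worsen <- list(
    sugars_g = 5, sfa_g = 2, salt_g = 0.7, energy_kj = 400
  )
  for (col in names(worsen)) {
    bumped <- base
    bumped[[col]] <- pmin(bumped[[col]] + worsen[[col]],
      if (col == "sugars_g") 100 else Inf)
    r <- match(score_records(bumped, scheme, tax)$nutri_class, LETTERS)
    expect_true(all(r >= rank0), info = col)
  }
  improve <- list(protein_g = 4, fibre_g = 2, fvl_pct = 25)
  for (col in names(improve)) {
    bumped <- base
    bumped[[col]] <- pmin(bumped[[col]] + improve[[col]],
      if (col == "fvl_pct") 100 else Inf)
    r <- match(score_records(bumped, scheme, tax)$nutri_class, LETTERS)
    expect_true(all(r <= rank0), info = col)
  }
})
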