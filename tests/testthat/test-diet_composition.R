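test_that("residual fibre by difference matches the published table rows", {
  expect_equal(residual_fiber(983, 113, 24, 19, starch = 670), 157)  # wheat
  expect_equal(residual_fiber(946, 88, 16, 59, starch = 0), 783)     # beet pulp
  expect_equal(residual_fiber(100, 40, 10, 20, starch = 30), 0)
  expect_error(residual_fiber(100, 80, 10, 20, starch = 30), "negative")
  expect_warning(r <- residual_fiber(100, 80, 10, 20, starch = 30,
                                     clamp = TRUE), "clamped")
  expect_equal(r, 0)
})

test_that("as-fed to DM conversion handles identity and symmetry", {
  tb <- toy_table()
  a <- asfed_to_dm_proportions(toy_diet(p_a = 1), tb)
  expect_equal(unname(a[["a"]]), 1)
  a <- asfed_to_dm_proportions(toy_diet(0.5), tb)   # equal dm, equal incl
  expect_equal(as.numeric(a), c(0.5, 0.5))
  expect_equal(sum(a), 1)
  bad <- diet_spec("bad", data.frame(ingredient = "nope",
                                     proportion_asfed = 1), 1, "weaned")
  expect_error(asfed_to_dm_proportions(bad, tb), "nope")
})

test_that("single-ingredient diet reproduces the ingredient row", {
  d <- diet_spec("pure_wheat",
                 data.frame(ingredient = "wheat", proportion_asfed = 1),
                 1.12, "weaned")
  co <- mix_composition(d, ftab)
  wheat <- ftab$ingredients[ftab$ingredients$name == "wheat", ]
  for (col in c("om", "cp", "cf", "starch", "sugar", "rf", "indf",
                "snsp")) {
    expect_equal(co[[col]], wheat[[col]], info = col)
  }
  expect_equal(co$dm, wheat$dm)
})

test_that("a 50/50 DM blend of wheat and barley averages the nutrients", {
  # equal DM proportions require as-fed inclusions inversely weighted by dm
  w <- 1 / c(856, 854)
  d <- diet_spec("blend", data.frame(ingredient = c("wheat", "barley"),
                                     proportion_asfed = w / sum(w)),
                 1.1, "grower_finisher")
  co <- mix_composition(d, ftab)
  expect_equal(co$cp, (113 + 109) / 2, tolerance = 1e-9)
  expect_equal(co$rf, (157 + 214) / 2, tolerance = 1e-9)
})

test_that("computed diet DM matches the published column within 1 g/kg", {
  printed <- c(weaned = 869, grower_finisher = 865, gestating_sow = 861,
               lactating_sow = 865)
  for (cat in categories) {
    co <- mix_composition(danish_diet(cat), ftab)
    expect_lt(abs(co$dm - printed[[cat]]), 1.05, )
  }
})

test_that("mixing is linear in the DM weights", {
  tb <- toy_table()
  co_a <- mix_composition(toy_diet(1), tb)
  co_b <- mix_composition(toy_diet(0), tb)
  for (w in c(0, 0.25, 0.5, 1)) {
    # equal ingredient dm in the toy table, so as-fed weight = DM weight
    co <- mix_composition(toy_diet(w), tb)
    for (col in c("om", "cp", "rf", "starch", "snsp")) {
      expect_equal(co[[col]], w * co_a[[col]] + (1 - w) * co_b[[col]],
                   tolerance = 1e-12, info = paste(col, w))
    }
  }
})

test_that("substituting wheat by beet pulp raises diet residual fibre", {
  base <- danish_diet("grower_finisher")
  sub <- substitute_ingredient(base, "wheat", "sugar_beet_pulp", 5,
                               fu_per_kg_asfed = 1.035)
  expect_gt(mix_composition(sub, ftab)$rf,
            mix_composition(base, ftab)$rf)
  expect_equal(sum(sub$items$proportion_asfed), 1, tolerance = 1e-12)
  expect_error(substitute_ingredient(base, "sugar_beet_pulp", "wheat", 5,
                                     1.1), "not in diet")
  expect_error(substitute_ingredient(base, "wheat", "oats", 50, 1.1),
               "contains only")
})

test_that("the two residual-fibre routes agree up to table rounding", {
  for (cat in categories) {
    co <- mix_composition(danish_diet(cat), ftab)
    expect_lt(abs(co$rf - co$rf_by_difference), 2)
  }
})
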