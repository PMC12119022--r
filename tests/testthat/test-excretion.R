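test_that("digestion splits intake into digested and excreted exactly", {
  tb <- toy_table(d_om = c(0.9, 0.7))
  # equal dm and equal inclusion: 50/50 DM split
  ik <- nutrient_intake(toy_diet(0.5), tb)
  dig <- digest_nutrients(ik, tb)
  per <- dig$per_ingredient
  # hand oracle on OM: with 100 g/d of OM each at 0.9 and 0.7,
  # digested = 160, excreted = 40; here scale by actual OM intakes
  expect_equal(per$om_digested, per$om_intake * c(0.9, 0.7))
  expect_equal(dig$digested[["om"]] + dig$excreted[["om"]],
               sum(per$om_intake), tolerance = 1e-12)
  for (n in c("om", "cp", "cf", "ss")) {
    expect_equal(dig$digested[[n]] + dig$excreted[[n]],
                 sum(per[[paste0(n, "_intake")]]), tolerance = 1e-12)
  }
  expect_equal(dig$d_om_diet, 0.8, tolerance = 1e-12)

  all1 <- toy_table(d_om = c(1, 1))
  all1$digestibility[, c("d_cp", "d_cf", "d_starch_sugar")] <- 1
  d1 <- digest_nutrients(nutrient_intake(toy_diet(0.5), all1), all1)
  expect_equal(unname(d1$excreted), rep(0, 4))
  all0 <- toy_table(d_om = c(0, 0))
  all0$digestibility[, c("d_cp", "d_cf", "d_starch_sugar")] <- 0
  d0 <- digest_nutrients(nutrient_intake(toy_diet(0.5), all0), all0)
  expect_equal(d0$excreted, d0$digested + d0$excreted)
})

test_that("digested residual fibre and fermentable fibre arithmetic", {
  expect_equal(digested_rf(800, 150, 30, 500), 120)
  expect_equal(digested_rf(0, 0, 0, 0), 0)
  expect_warning(x <- digested_rf(100, 80, 30, 20), "clamped")
  expect_equal(x, 0)
  expect_equal(fermentable_fiber(850, 160, 30, 520), 140)
  expect_equal(fermentable_fiber(0, 0, 0, 0), 0)
})

test_that("fermentable fibre never exceeds diet residual fibre", {
  for (cat in categories) {
    for (d in danish_diets(cat)) {
      ex <- excreta_profile(nutrient_intake(d, ftab), ftab)
      rf <- mix_composition(d, ftab)$rf
      expect_lte(ex$ff, rf + 1e-9)
      expect_gte(ex$ff, 0)
    }
  }
})

test_that("degradable residual fibre partition", {
  expect_equal(degradable_rf(358, 143), 215)
  expect_equal(degradable_rf(100, 100), 0)
  expect_warning(x <- degradable_rf(50, 60), "clamped")
  expect_equal(x, 0)
})

test_that("urine nitrogen prediction and balance", {
  expect_equal(urine_nitrogen(181, 2.141),
               -21.20 + 0.134 * 181 + 10.15 * 2.141, tolerance = 1e-12)
  expect_equal(urine_nitrogen(181, 2.141), 24.78, tolerance = 5e-4)
  expect_error(urine_nitrogen(0, 1e-9), "balance")
  # linear in DM intake with slope 10.15
  expect_equal(urine_nitrogen(181, 3.141) - urine_nitrogen(181, 2.141),
               10.15, tolerance = 1e-12)
  expect_equal(urine_nitrogen_balance(20, 5, 8), 7)
  expect_equal(urine_nitrogen_balance(10, 10, 0), 0)
  expect_error(urine_nitrogen_balance(5, 4, 3), "infeasible")
})

test_that("faeces mass predictions", {
  expect_equal(feces_mass(0.85, 2.141),
               5.405 - 6.31 * 0.85 + 0.505 * 2.141, tolerance = 1e-12)
  expect_equal(round(feces_mass(0.85, 2.141), 3), 1.123)
  expect_error(feces_mass(0.857, 0), "nonpositive")
  expect_gt(feces_mass(0.80, 2), feces_mass(0.85, 2))  # monotone in d_om
  expect_equal(feces_mass_weaned(81, 0.25), 324)
  expect_equal(feces_mass_weaned(0), 0)
  expect_equal(feces_mass_weaned(100, 0.5), 200)
})

test_that("urine volume follows the category constants", {
  expect_equal(urine_volume(2.1409, "grower_finisher"), 4.2818)
  expect_equal(urine_volume(0, "weaned"), 0)
  expect_equal(urine_volume(5.522, "lactating_sow"), 13.805)
  expect_equal(urine_volume(1, "gestating_sow"), 2.5)
})

test_that("excreta profiles are internally consistent on all diets", {
  for (cat in categories) {
    ex <- excreta_profile(nutrient_intake(danish_diet(cat), ftab), ftab)
    expect_lte(ex$feces_dm, ex$intake$dmi)
    expect_equal(ex$urea_n, 0.75 * ex$urine_n)
    expect_equal(ex$fecal_vfa, 2.87 * ex$feces_mass / 1000)
    fc <- ex$feces_composition
    expect_lte(fc[["cp"]] + fc[["cf"]] + fc[["rf"]] +
                 fc[["starch_sugar"]] + fc[["ash"]], 1000 + 1e-6)
    expect_equal(fc[["degradable_rf"]],
                 max(fc[["rf"]] - fc[["indf"]], 0), tolerance = 1e-9)
  }
})

test_that("faecal DM excretion orders the grower diets as published", {
  diets <- danish_diets("grower_finisher")
  fdm <- vapply(diets, function(d)
    excreta_profile(nutrient_intake(d, ftab), ftab)$feces_dm, numeric(1))
  expect_lt(fdm[["wheat"]], fdm[["average"]])
  expect_lt(fdm[["average"]], fdm[["sugar_beet_pulp"]])
  expect_lt(fdm[["sugar_beet_pulp"]], fdm[["wheat_bran"]])
  expect_lt(fdm[["wheat_bran"]], fdm[["oats"]])
})
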