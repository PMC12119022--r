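test_that("packaged feedstuff table loads with the published values", {
  expect_s3_class(ftab, "feed_table")
  ing <- ftab$ingredients
  expect_gte(nrow(ing), 12)
  wheat <- ing[ing$name == "wheat", ]
  expect_equal(wheat$rf, 157)
  expect_equal(wheat$dm, 856)
  expect_equal(ing$rf[ing$name == "barley"], 214)
  expect_equal(ing$rf[ing$name == "sugar_beet_pulp"], 783)
})

test_that("loader rejects empty and malformed files", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,dm,om,cp,cf,starch,sugar,rf,indf,nsp,snsp,ash", empty)
  dig <- system.file("extdata", "digestibility.csv", package = "pigch4")
  expect_error(load_feed_table(empty, dig), "no ingredients")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,dm,om,cp,cf,starch,sugar,rf,indf,nsp,snsp,ash",
               "weird,900,950,100,50,500,50,250,50,200,60,150"), bad)
  expect_error(load_feed_table(bad, dig), "weird.*om \\+ ash")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,dm,om", "x,900,950"), nocol)
  expect_error(load_feed_table(nocol, dig), "missing column")
})

test_that("ingredient validation separates errors from rounding warnings", {
  barley <- as.list(ftab$ingredients[ftab$ingredients$name == "barley", ])
  expect_length(validate_ingredient(barley), 0)

  oats <- as.list(ftab$ingredients[ftab$ingredients$name == "oats", ])
  f <- validate_ingredient(oats)   # printed 313 vs recomputed 312
  expect_length(f, 1)
  expect_equal(f[[1]]$severity, "warning")

  # a clamped negative residual (protein-rich feeds) is a warning too
  fish <- as.list(ftab$ingredients[ftab$ingredients$name == "fish_meal", ])
  f <- validate_ingredient(fish)
  expect_true(all(vapply(f, `[[`, "", "severity") == "warning"))

  broken <- barley
  broken$rf <- 500                 # recomputation gives 214
  f <- validate_ingredient(broken)
  expect_true(any(vapply(f, `[[`, "", "severity") == "error"))
})

test_that("every packaged ingredient passes with at most rounding warnings", {
  for (i in seq_len(nrow(ftab$ingredients))) {
    f <- validate_ingredient(ftab$ingredients[i, ])
    sev <- vapply(f, `[[`, "", "severity")
    expect_true(all(sev == "warning"),
                info = ftab$ingredients$name[i])
  }
})

test_that("feed table round-trips through CSV field-for-field", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feed_table(ftab, f1, f2)
  back <- load_feed_table(f1, f2)
  expect_equal(back$ingredients, ftab$ingredients)
  expect_equal(back$digestibility, ftab$digestibility)
})

test_that("published diet formulations load and (re)normalise", {
  for (cat in categories) {
    d <- danish_diet(cat)
    expect_equal(sum(d$items$proportion_asfed), 1, tolerance = 1e-12)
  }
  # raw column sums of the printed formulations are within 0.002 of 1
  for (cat in categories) {
    file <- system.file("extdata", paste0(
      "diet_", sub("_sow$", "_sow", cat), ".csv"), package = "pigch4")
    raw <- read.csv(file)
    expect_lt(abs(sum(raw$proportion_asfed) - 1), 0.002)
  }
})

test_that("diet and config validation reject bad inputs", {
  expect_error(diet_spec("x", data.frame(ingredient = "wheat",
                                         proportion_asfed = 0.9),
                         1.1, "weaned"), "sum to")
  expect_error(diet_spec("x", data.frame(ingredient = "wheat",
                                         proportion_asfed = 1),
                         0, "weaned"), "fu_per_kg")
  expect_error(pig_category_config("weaned", urine_per_dmi = 2.5),
               "urine_per_dmi")
  expect_error(pig_category_config("weaned", empty_days = 60),
               "empty_days")
  expect_error(storage_config(removal_schedule =
                                data.frame(day = c(200, 100),
                                           fraction = c(0.5, 0.5))),
               "sorted")
  expect_error(storage_config(removal_schedule =
                                data.frame(day = 100, fraction = 1.5)),
               "fraction")
  expect_error(storage_config(monthly_temps = 1:5), "12")
})

test_that("digestibility lookups fail loudly for missing records", {
  tb <- toy_table()
  tb$digestibility <- tb$digestibility[tb$digestibility$ingredient != "b" |
                                         tb$digestibility$animal_class !=
                                         "growing", ]
  ik <- nutrient_intake(toy_diet(), tb,
                        pig_category_config("grower_finisher"))
  expect_error(digest_nutrients(ik, tb), "missing growing.*b")
})
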