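test_that("hydrolysis rate constants order and scale with temperature", {
  p <- kinetic_params()
  expect_gt(hydrolysis_rate("ss", 20, p), hydrolysis_rate("rf", 20, p))
  expect_gt(hydrolysis_rate("ss", 20, p), hydrolysis_rate("cp", 20, p))
  expect_gt(hydrolysis_rate("rf", 20, p), hydrolysis_rate("rf", 10, p))
  # closed form of the exponential response
  expect_equal(hydrolysis_rate("rf", 18.6, p) / hydrolysis_rate("rf", 20, p),
               exp(p$theta_hyd * (18.6 - 20)), tolerance = 1e-12)
  expect_error(hydrolysis_rate("rf", 60, p))
  expect_error(kinetic_params(nonsense = 1), "unknown")
})

test_that("empty system emits nothing", {
  s <- manure_state(mass = 1, biomass = c(0, 0, 0))
  zero_infl <- structure(rep(0, 8), class = "influent_stream")
  for (i in 1:50) {
    st <- step_manure(s, zero_infl, 20)
    expect_equal(st$ch4_cod, 0)
    s <- st$state
  }
  expect_equal(unname(s[1:9]), rep(0, 9))
})

test_that("a starch spike drives VFA up and the inhibition factor down", {
  s <- manure_state(mass = 20, biomass = c(0.05, 0.05, 0.05))
  s[["ss"]] <- 2000                      # one-day spillage spike, g COD
  zero_infl <- structure(rep(0, 8), class = "influent_stream")
  inh <- numeric(60); vfa <- numeric(60)
  for (i in 1:60) {
    st <- step_manure(s, zero_infl, 20)
    s <- st$state
    inh[i] <- st$inhibition
    vfa[i] <- s[["vfa"]]
  }
  expect_gt(max(vfa), 100)
  expect_lt(min(inh), 0.9)               # inhibition engaged (1 = none)
})

test_that("long-run COD conversion approaches 1 minus the biomass yield", {
  # constant degradable influent, no respiration, no biomass decay:
  # cumulative CH4-COD / cumulative influent COD -> 1 - yield * 1.42
  p <- kinetic_params(resp20 = 0, decay = 0)
  days <- 800
  st <- manure_state(mass = 0)
  st[["ss"]] <- 100                      # g COD added per day
  st[["mass"]] <- 5                      # kg water per day
  adds <- lapply(seq_len(days), function(d) list(day = d, state = st))
  sim <- simulate_storage(
    adds,
    storage_config(monthly_temps = rep(35, 12),
                   removal_schedule = data.frame(day = 364,
                                                 fraction = 1e-9)),
    p, horizon = days, init = manure_state(mass = 1))
  ratio <- sim$acc[["ch4_cod"]] / sim$acc[["in_cod"]]
  expect_equal(ratio, 1 - p$yield * p$cod_biomass, tolerance = 0.02)
  expect_lt(cod_balance(sim), 1e-3)
})

test_that("influent mapping covers spillage, linearity and guards", {
  ex <- excreta_profile(nutrient_intake(danish_diet("grower_finisher"),
                                        ftab), ftab)
  i0 <- excreta_to_influent(ex, 0)
  i2 <- excreta_to_influent(ex, 0.02)
  # 2% of the published grower intake is ~49.5 g feed/day into the pit
  spilled_dm <- 0.02 * ex$intake$feed_asfed *
    ex$intake$composition$dm / 1e6
  expect_equal(i2[["solids"]] - i0[["solids"]], spilled_dm,
               tolerance = 1e-9)
  expect_equal(0.02 * ex$intake$feed_asfed, 49.5, tolerance = 0.01)
  # spillage adds fast-pool COD most of all
  expect_gt(i2[["ss"]] - i0[["ss"]], i2[["rf"]] - i0[["rf"]])
  expect_true(all(i2[1:8] >= i0[1:8]))
  expect_error(excreta_to_influent(ex, 0.5), "spillage_fraction")

  # doubling excretion doubles every COD pool
  ex2 <- ex
  for (f in c("feces_dm", "feces_mass", "urine_volume", "fecal_vfa"))
    ex2[[f]] <- 2 * ex[[f]]
  ex2$excreted <- 2 * ex$excreted
  i_dbl <- excreta_to_influent(ex2, 0)
  expect_equal(unname(i_dbl[1:6]), unname(2 * i0[1:6]), tolerance = 1e-12)
})

test_that("daily full removal suppresses barn methanogenesis", {
  infl <- quick_influent()
  slow <- pig_category_config("grower_finisher", removal_interval = 1,
                              residual_fraction = 0)
  weekly <- pig_category_config("grower_finisher")
  e_daily <- sum(simulate_barn(slow, infl, horizon = 90)$ledger$ch4_g)
  e_weekly <- sum(simulate_barn(weekly, infl, horizon = 90)$ledger$ch4_g)
  expect_lt(e_daily, 0.3 * e_weekly)
})

test_that("longer pit retention shifts emission into the barn", {
  infl <- quick_influent()
  c7 <- pig_category_config("grower_finisher", removal_interval = 7)
  c36 <- pig_category_config("grower_finisher", removal_interval = 36)
  b7 <- simulate_barn(c7, infl, horizon = 365)
  b36 <- simulate_barn(c36, infl, horizon = 365)
  expect_gt(sum(b36$ledger$ch4_g), sum(b7$ledger$ch4_g))
  expect_lt(cod_balance(b7), 1e-3)
  expect_lt(cod_balance(b36), 1e-3)
})

test_that("barn emission increases with in-barn temperature", {
  infl <- quick_influent()
  e <- vapply(c(15, 18.6, 20, 22), function(T) {
    cfg <- pig_category_config("grower_finisher", manure_temp_barn = T)
    sum(simulate_barn(cfg, infl, horizon = 180)$ledger$ch4_g)
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("cold storage stays nearly silent until warming", {
  infl <- quick_influent()
  cfg <- pig_category_config("grower_finisher")
  b <- simulate_barn(cfg, infl, horizon = 365)
  cold <- simulate_storage(b$batches,
                           storage_config(monthly_temps = rep(0.5, 12)),
                           horizon = 365)
  warm <- simulate_storage(b$batches, storage_config(), horizon = 365)
  expect_lt(sum(cold$ledger$ch4_g), 0.25 * sum(warm$ledger$ch4_g))
})

test_that("emission rate drops after the spring emptying", {
  infl <- quick_influent()
  cfg <- pig_category_config("grower_finisher")
  b <- simulate_barn(cfg, infl, horizon = 730)
  st <- simulate_storage(b$batches, storage_config(), horizon = 730)
  spring2 <- 365 + 105
  before <- mean(st$ledger$ch4_g[(spring2 - 5):(spring2 - 1)])
  after <- mean(st$ledger$ch4_g[(spring2 + 2):(spring2 + 6)])
  expect_lt(after, before)
  expect_lt(cod_balance(st), 1e-3)
})
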