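# Shared fixtures, loaded once per test run. The packaged Danish table and
# diets are small, but repeated CSV parsing adds up across files.
ftab <- danish_feed_table()
categories <- c("weaned", "grower_finisher", "gestating_sow",
                "lactating_sow")

# a tiny two-ingredient table with round numbers for hand-checkable oracles
toy_table <- function(d_om = c(0.9, 0.7)) {
  ing <- data.frame(
    name = c("a", "b"), dm = c(900, 900),
    om = c(950, 950), cp = c(100, 100), cf = c(50, 50),
    starch = c(500, 300), sugar = c(50, 50), rf = c(250, 450),
    indf = c(50, 150), nsp = c(200, 400), snsp = c(60, 100),
    ash = c(50, 50))
  dig <- do.call(rbind, lapply(c("growing", "sow"), function(cl)
    data.frame(ingredient = c("a", "b"), animal_class = cl,
               d_om = d_om, d_cp = c(0.85, 0.85), d_cf = c(0.5, 0.5),
               d_starch_sugar = c(0.99, 0.99))))
  feed_table(ing, dig)
}

toy_diet <- function(p_a = 0.5, category = "grower_finisher", fu = 1.0) {
  diet_spec("toy", data.frame(ingredient = c("a", "b"),
                              proportion_asfed = c(p_a, 1 - p_a)),
            fu_per_kg_asfed = fu, category = category)
}

# short barn-only run used by several property tests
quick_influent <- function(category = "grower_finisher", spillage = 0.02,
                           table = ftab) {
  d <- danish_diet(category)
  ex <- excreta_profile(nutrient_intake(d, table), table)
  excreta_to_influent(ex, spillage)
}
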