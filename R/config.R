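#' Animal, barn and management configuration for a pig category
#'
#' Bundles the housing and management characteristics that drive manure
#' production and barn emissions: in-barn manure temperature, pit removal
#' interval, production-cycle length and empty (washing) days, washing
#' water, the urine-per-DM-intake constant, and the feed-intake parameters
#' (batch gain and feed efficiency for growing pigs, annual feed-unit stages
#' and feeding days for sows).
#'
#' Calling it with just `category` returns the built-in default for that
#' category (Danish commercial conditions); any field can be overridden.
#'
#' @param category one of `"weaned"`, `"grower_finisher"`,
#'   `"gestating_sow"`, `"lactating_sow"`.
#' @param ... overrides for the default fields, e.g. `manure_temp_barn = 20`.
#' @return object of class `pig_config`.
#' @export
pig_category_config <- function(category, ...) {
  category <- match.arg(category, .PIG_CATEGORIES)
  defaults <- list(
    weaned = list(
      body_weight = 18.9, manure_temp_barn = 22, removal_interval = 27,
      floor_area = 0.3, pit_area = 0.18, cycle_period = 59, empty_days = 5,
      wash_water = 15, urine_per_dmi = 2.0,
      intake_params = list(gain_per_cycle = 21, feed_efficiency = 2.09,
                           feeding_days_per_cycle = 54)),
    grower_finisher = list(
      body_weight = 73, manure_temp_barn = 18.6, removal_interval = 7,
      floor_area = 0.65, pit_area = 0.715, cycle_period = 89, empty_days = 5,
      wash_water = 75, urine_per_dmi = 2.0,
      intake_params = list(gain_per_cycle = 84, feed_efficiency = 2.648,
                           feeding_days_per_cycle = 84)),
    gestating_sow = list(
      body_weight = 245, manure_temp_barn = 18.6, removal_interval = 30,
      floor_area = 2.14, pit_area = 1.05, cycle_period = 119, empty_days = 0,
      wash_water = 0, urine_per_dmi = 2.5,
      intake_params = list(fu_stages = c(gilts = 104, pre_gestation = 58.8,
                                         gestation_section = 208,
                                         pregnancy = 582, boar = 20.4),
                           feeding_days = 285)),
    lactating_sow = list(
      body_weight = 245, manure_temp_barn = 20, removal_interval = 36,
      floor_area = 4.9, pit_area = 2.94, cycle_period = 40, empty_days = 4,
      wash_water = 340, urine_per_dmi = 2.5,
      intake_params = list(fu_stages = c(pre_farrowing = 39.1,
                                         lactation = 499.3),
                           feeding_days = 80)))
  cfg <- defaults[[category]]
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "residual_fraction"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$category <- category
  if (is.null(cfg$residual_fraction)) cfg$residual_fraction <- 0.05
  with(cfg, {
    stopifnot(empty_days < cycle_period,
              urine_per_dmi %in% c(2.0, 2.5),
              body_weight > 0, removal_interval > 0, cycle_period > 0,
              wash_water >= 0, floor_area > 0, pit_area > 0)
  })
  if (is_growing_class(category) != (cfg$urine_per_dmi == 2.0))
    stop("urine_per_dmi must be 2.0 for growing classes and 2.5 for sows")
  structure(cfg, class = "pig_config")
}

#' @export
print.pig_config <- function(x, ...) {
  cat("<pig_config> ", x$category, ": barn ", x$manure_temp_barn,
      " degC, removal every ", x$removal_interval, " d, cycle ",
      x$cycle_period, " d (", x$empty_days, " empty)\n", sep = "")
  invisible(x)
}

#' Outdoor slurry storage configuration
#'
#' Default geometry is a covered tank 5.5 m high and 36 m in diameter; the
#' cover means no rain intake and no evaporation, so stored mass changes
#' only through transfers in and removals out. Removal for field
#' application defaults to the Danish pattern: most manure removed in
#' spring (80% on day 105) and a smaller amount in autumn (20% on day 288),
#' giving a mean retention of about 4.5 months.
#'
#' @param height,diameter tank geometry, m.
#' @param monthly_temps 12 monthly mean slurry temperatures, degrees C.
#'   Default is the packaged synthetic Danish-seasonality series.
#' @param removal_schedule data.frame with columns `day` (day of year) and
#'   `fraction` (fraction of stored mass removed, in (0, 1]).
#' @param covered logical flag.
#' @return object of class `storage_config`.
#' @export
storage_config <- function(height = 5.5, diameter = 36,
                           monthly_temps = default_storage_temperatures(),
                           removal_schedule = data.frame(
                             day = c(105, 288), fraction = c(0.8, 0.2)),
                           covered = TRUE) {
  stopifnot(height > 0, diameter > 0, length(monthly_temps) == 12,
            all(is.finite(monthly_temps)),
            is.data.frame(removal_schedule),
            all(c("day", "fraction") %in% names(removal_schedule)))
  rs <- removal_schedule
  if (any(rs$fraction <= 0 | rs$fraction > 1))
    stop("removal fractions must be in (0, 1]")
  if (is.unsorted(rs$day, strictly = TRUE))
    stop("removal schedule must be strictly sorted by day of year")
  if (any(rs$day < 1 | rs$day > 365))
    stop("removal days must be within 1..365")
  structure(list(height = height, diameter = diameter,
                 monthly_temps = as.numeric(monthly_temps),
                 removal_schedule = rs, covered = covered),
            class = "storage_config")
}

#' Default monthly slurry temperatures in the outdoor store
#'
#' A synthetic 12-value series shaped like Danish outdoor slurry-tank
#' temperatures (winter minimum just under 2 degC, late-summer maximum just
#' over 17 degC). Shipped as
#' `inst/extdata/storage_temperature_synthetic.csv`; it is a documented
#' stand-in, not a measured series.
#'
#' @return numeric vector of length 12 (degC, January first).
#' @export
default_storage_temperatures <- function() {
  path <- system.file("extdata", "storage_temperature_synthetic.csv",
                      package = "pigch4", mustWork = TRUE)
  utils::read.csv(path)$temp_c
}

#' Expand a monthly series to daily values
#' @param monthly numeric vector of 12 monthly values.
#' @param days simulation days (day 1 = 1 January).
#' @return numeric vector of length `days`.
#' @keywords internal
monthly_to_daily <- function(monthly, days) {
  mlen <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of_doy <- rep(seq_len(12), mlen)
  doy <- ((seq_len(days) - 1L) %% 365L) + 1L
  monthly[month_of_doy[doy]]
}

# fu_per_kg for the average Danish diets (published FUsv/FUso per 100 kg
# as-fed) and for the substituted variants. Variant energy densities are
# not printed anywhere; they are fixture values calibrated once so that
# equal-FU intake reproduces the published variant feed intakes (see the
# methods vignette), stored to three decimals.
.DANISH_FU <- list(
  weaned = c(average = 1.12, sugar_beet_pulp = 1.087, wheat_bran = 1.096,
             oats = 1.094, wheat = 1.129),
  grower_finisher = c(average = 1.07, sugar_beet_pulp = 1.035,
                      wheat_bran = 1.044, oats = 1.040, wheat = 1.078),
  gestating_sow = c(average = 0.99, sugar_beet_pulp = 0.944,
                    wheat_bran = 0.950, oats = 0.958, wheat = 0.998,
                    soy_hulls = 0.814),
  lactating_sow = c(average = 1.05, sugar_beet_pulp = 1.028,
                    wheat_bran = 1.029, oats = 1.032, wheat = 1.055))

# substitution recipe per category: percentage points moved out of wheat
# into the fibre source (or out of barley into wheat for the low-fibre diet)
.DANISH_SUBST <- list(
  weaned = c(sugar_beet_pulp = 5, wheat_bran = 5, oats = 10, wheat = 10),
  grower_finisher = c(sugar_beet_pulp = 5, wheat_bran = 5, oats = 10,
                      wheat = 10),
  gestating_sow = c(sugar_beet_pulp = 10, wheat_bran = 10, oats = 10,
                    wheat = 10, soy_hulls = 10),
  lactating_sow = c(sugar_beet_pulp = 5, wheat_bran = 5, oats = 10,
                    wheat = 10))

#' Built-in Danish feedstuff table
#'
#' The packaged fixture: the twelve feedstuffs of the published Danish
#' table plus the mineral, premix and crystalline amino-acid ingredients
#' needed to close the formulations (amino-acid crude-protein equivalents
#' use N x 6.25 from the molecular formula times declared purity; their
#' non-protein mass is assigned to the ash closure term so they contribute
#' no fibre). Digestibility coefficients are documented plausible values,
#' not sourced normative tables.
#'
#' @return a [feed_table()].
#' @export
danish_feed_table <- function() {
  load_feed_table(
    system.file("extdata", "feedstuffs.csv", package = "pigch4",
                mustWork = TRUE),
    system.file("extdata", "digestibility.csv", package = "pigch4",
                mustWork = TRUE))
}

#' Average Danish diet for a pig category
#'
#' @param category pig category.
#' @return a [diet_spec()] read from the packaged formulation CSV.
#' @export
danish_diet <- function(category) {
  category <- match.arg(category, .PIG_CATEGORIES)
  file <- c(weaned = "diet_weaned.csv",
            grower_finisher = "diet_grower_finisher.csv",
            gestating_sow = "diet_gestating_sow.csv",
            lactating_sow = "diet_lactating_sow.csv")[[category]]
  load_diet(system.file("extdata", file, package = "pigch4",
                        mustWork = TRUE),
            fu_per_kg_asfed = .DANISH_FU[[category]][["average"]],
            category = category,
            name = paste0(category, "_average"))
}

#' Average diet plus its fibre-substitution variants
#'
#' Builds the published diet set for a category: the average Danish diet,
#' the sugar beet pulp / wheat bran / oat substitutions of wheat, the
#' low-fibre diet with barley replaced by wheat, and (gestating sows only)
#' the soy-hull substitution.
#'
#' @param category pig category.
#' @return named list of [diet_spec()] objects; first element `average`.
#' @export
danish_diets <- function(category) {
  category <- match.arg(category, .PIG_CATEGORIES)
  base <- danish_diet(category)
  fu <- .DANISH_FU[[category]]
  sub <- .DANISH_SUBST[[category]]
  out <- list(average = base)
  for (v in names(sub)) {
    from <- if (v == "wheat") "barley" else "wheat"
    out[[v]] <- substitute_ingredient(
      base, from = from, to = v, points = sub[[v]],
      fu_per_kg_asfed = fu[[v]],
      name = paste0(category, "_", v))
  }
  out
}
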