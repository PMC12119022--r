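#' Digested and excreted nutrients per ingredient
#'
#' Applies the apparent total-tract digestibility coefficient of each
#' nutrient fraction to the amount of that fraction supplied by each
#' ingredient: `digested = intake x coefficient`,
#' `excreted = intake - digested`. Starch and sugar are treated as one pool
#' with one shared coefficient. Diet totals are sums over ingredients, so
#' mass balance `intake = digested + excreted` holds exactly per nutrient.
#'
#' @param intake an [nutrient_intake()] result.
#' @param table a [feed_table()].
#' @param class digestibility class, `"growing"` or `"sow"`; defaults to
#'   the class implied by the intake's category.
#' @return list with data.frame `per_ingredient` (g/day intakes, digested
#'   and excreted amounts of om, cp, cf and starch+sugar), vector totals
#'   `digested` and `excreted` (g/day), and `d_om_diet`, the intake-weighted
#'   whole-diet OM digestibility coefficient.
#' @export
digest_nutrients <- function(intake, table,
                             class = animal_class(intake$category)) {
  stopifnot(inherits(intake, "intake_result"), inherits(table, "feed_table"))
  a <- intake$dm_proportions
  ing <- table$ingredients
  idx <- match(names(a), ing$name)
  co <- digestibility_for(table, names(a), class)
  g <- function(col) intake$dmi * a * ing[[col]][idx] / 1000
  om_in <- g("om"); cp_in <- g("cp"); cf_in <- g("cf")
  ss_in <- g("starch") + g("sugar")
  per <- data.frame(
    ingredient = names(a),
    om_intake = om_in, cp_intake = cp_in, cf_intake = cf_in,
    ss_intake = ss_in,
    om_digested = om_in * co$d_om, cp_digested = cp_in * co$d_cp,
    cf_digested = cf_in * co$d_cf, ss_digested = ss_in * co$d_starch_sugar,
    stringsAsFactors = FALSE, row.names = NULL)
  per$om_excreted <- per$om_intake - per$om_digested
  per$cp_excreted <- per$cp_intake - per$cp_digested
  per$cf_excreted <- per$cf_intake - per$cf_digested
  per$ss_excreted <- per$ss_intake - per$ss_digested
  digested <- c(om = sum(per$om_digested), cp = sum(per$cp_digested),
                cf = sum(per$cf_digested), ss = sum(per$ss_digested))
  excreted <- c(om = sum(per$om_excreted), cp = sum(per$cp_excreted),
                cf = sum(per$cf_excreted), ss = sum(per$ss_excreted))
  d_om_diet <- if (sum(per$om_intake) > 0)
    digested[["om"]] / sum(per$om_intake) else 0
  list(per_ingredient = per, digested = digested, excreted = excreted,
       d_om_diet = d_om_diet)
}

#' Digested residual fibre by difference
#'
#' `digested RF = digested OM - digested CP - digested CF - digested
#' starch+sugar`, all in g/kg diet DM (or g/day at diet level). Negative
#' results are clamped to 0 with a warning.
#'
#' @param d_om,d_cp,d_cf,d_ss digested amounts.
#' @return digested residual fibre on the same basis as the inputs.
#' @export
digested_rf <- function(d_om, d_cp, d_cf, d_ss) {
  x <- d_om - d_cp - d_cf - d_ss
  if (any(x < 0)) {
    warning("negative digested residual fibre clamped to 0")
    x <- pmax(x, 0)
  }
  x
}

#' Fermentable fibre of a diet
#'
#' Fermentable fibre (FF) is the digested organic matter not explained by
#' digested protein, fat, starch and sugar -- the substrate term of the sow
#' enteric methane regression. Same arithmetic as [digested_rf()], defined
#' per kg DM of feed.
#'
#' @inheritParams digested_rf
#' @return fermentable fibre, g/kg DM of feed (or g/day).
#' @export
fermentable_fiber <- function(d_om, d_cp, d_cf, d_ss) {
  digested_rf(d_om, d_cp, d_cf, d_ss)
}

#' Potentially degradable residual fibre
#'
#' Splits residual fibre into a fully undegradable part (iNDF, which passes
#' both the animal and the slurry untouched) and the potentially degradable
#' remainder that feeds the manure model: `max(rf - indf, 0)`.
#'
#' @param rf residual fibre, g/kg DM (vectorised).
#' @param indf indigestible NDF, g/kg DM.
#' @return degradable residual fibre, g/kg DM.
#' @export
degradable_rf <- function(rf, indf) {
  stopifnot(all(rf >= 0), all(indf >= 0))
  x <- rf - indf
  if (any(x < 0)) {
    warning("indf exceeds rf; degradable residual fibre clamped to 0")
    x <- pmax(x, 0)
  }
  x
}

#' Urine nitrogen from dietary protein and DM intake
#'
#' Linear prediction used for grower-finisher pigs and sows:
#' `urine N (g/d) = -21.20 + 0.134 x dietary CP (g/kg DM) + 10.15 x DMI (kg/d)`.
#'
#' @param cp_diet dietary crude protein, g/kg DM.
#' @param dmi dry matter intake, kg/day.
#' @return g N/day.
#' @export
urine_nitrogen <- function(cp_diet, dmi) {
  stopifnot(dmi > 0)
  n <- -21.20 + 0.134 * cp_diet + 10.15 * dmi
  if (n <= 0)
    stop("urine nitrogen prediction is nonpositive (", round(n, 2),
         " g/d); use the nitrogen-balance route (urine_nitrogen_balance)")
  n
}

#' Urine nitrogen by nitrogen balance (weaned pigs)
#'
#' The linear prediction overestimates urine N in weaned pigs; for them
#' urine N is intake N minus faecal N minus N retained in gain.
#'
#' @param n_intake,n_feces,n_retained g N/day, all nonnegative.
#' @return g N/day.
#' @export
urine_nitrogen_balance <- function(n_intake, n_feces, n_retained) {
  stopifnot(n_intake >= 0, n_feces >= 0, n_retained >= 0)
  n <- n_intake - n_feces - n_retained
  if (n < 0)
    stop("infeasible nitrogen balance: intake ", n_intake,
         " < feces ", n_feces, " + retained ", n_retained)
  n
}

#' Fresh faeces mass from OM digestibility and DM intake
#'
#' `feces mass (kg/d) = 5.405 - 6.31 x d_OM + 0.505 x DMI (kg/d)`, where
#' `d_OM` is the whole-diet apparent OM digestibility coefficient. Mass
#' decreases strictly with digestibility.
#'
#' @param d_om_coeff whole-diet OM digestibility, fraction in \[0, 1\].
#' @param dmi dry matter intake, kg/day.
#' @return kg fresh faeces/day.
#' @export
feces_mass <- function(d_om_coeff, dmi) {
  stopifnot(d_om_coeff >= 0, d_om_coeff <= 1, dmi >= 0)
  m <- 5.405 - 6.31 * d_om_coeff + 0.505 * dmi
  if (m <= 0)
    stop("predicted feces mass is nonpositive (", round(m, 3), " kg/d)")
  m
}

#' Fresh faeces mass of weaned pigs from a constant faecal DM fraction
#'
#' The regression for older pigs does not fit weaned pigs; their fresh mass
#' is excreted faecal DM divided by a constant DM fraction (default 25%).
#'
#' @param feces_dm excreted faecal dry matter, g/day.
#' @param dm_fraction faecal DM content, fraction in (0, 1); default 0.25.
#' @return g fresh faeces/day.
#' @export
feces_mass_weaned <- function(feces_dm, dm_fraction = 0.25) {
  stopifnot(feces_dm >= 0, dm_fraction > 0, dm_fraction < 1)
  feces_dm / dm_fraction
}

#' Urine volume from DM intake
#'
#' 2.0 kg urine per kg DM intake for weaned and grower-finisher pigs,
#' 2.5 kg per kg DM intake for gestating and lactating sows.
#'
#' @param dmi dry matter intake, kg/day.
#' @param category pig category.
#' @return kg urine/day.
#' @export
urine_volume <- function(dmi, category) {
  stopifnot(dmi >= 0)
  ratio <- if (is_growing_class(category)) 2.0 else 2.5
  ratio * dmi
}

#' Full excreta profile for a category on a diet
#'
#' Runs the digestibility chain and assembles everything the enteric and
#' manure models need: faecal DM and fresh mass, urine volume and nitrogen
#' (urea fraction 0.75 of urine N), faecal composition per kg faecal DM
#' including the degradable residual-fibre fraction, diet-level fermentable
#' fibre, and faecal VFA (2.87 g per kg fresh faeces). Faecal ash is the
#' unabsorbed fraction of ash intake (default absorption 0.45) and closes
#' faecal DM as `excreted OM + excreted ash`.
#'
#' @param intake an [nutrient_intake()] result.
#' @param table a [feed_table()].
#' @param config a [pig_category_config()].
#' @param urea_fraction fraction of urine N present as urea (default 0.75).
#' @param ash_absorption apparent mineral absorption, fraction (default 0.45).
#' @param body_n_per_gain g body N per kg gain, used in the weaned-pig
#'   nitrogen balance (default 25.6, i.e. 16% body protein).
#' @param fecal_vfa_per_kg g VFA per kg fresh faeces (default 2.87).
#' @param weaned_dm_fraction faecal DM fraction for weaned pigs (default 0.25).
#' @return object of class `excreta_profile`.
#' @export
excreta_profile <- function(intake, table,
                            config = pig_category_config(intake$category),
                            urea_fraction = 0.75, ash_absorption = 0.45,
                            body_n_per_gain = 25.6,
                            fecal_vfa_per_kg = 2.87,
                            weaned_dm_fraction = 0.25) {
  stopifnot(inherits(intake, "intake_result"), inherits(config, "pig_config"))
  category <- intake$category
  if (intake$dmi == 0) {           # empty place: nothing eaten, nothing excreted
    zero <- c(om = 0, cp = 0, cf = 0, ss = 0, rf = 0, indf = 0,
              degradable_rf = 0, ash = 0)
    return(structure(list(
      category = category, feces_dm = 0, feces_mass = 0,
      urine_volume = 0, urine_n = 0, urea_n = 0, fecal_vfa = 0,
      excreted = zero,
      feces_composition = c(cp = 0, cf = 0, rf = 0, indf = 0,
                            starch_sugar = 0, degradable_rf = 0, ash = 0),
      ff = 0, ff_intake = 0, d_om_diet = 0,
      digested = c(om = 0, cp = 0, cf = 0, ss = 0),
      intake = intake), class = "excreta_profile"))
  }
  dig <- digest_nutrients(intake, table)
  comp <- intake$composition
  exc <- dig$excreted                    # g/day: om, cp, cf, ss
  dmi_kg <- intake$dmi / 1000

  # excreted residual fibre is the unexplained excreted OM; iNDF passes
  # through the animal untouched
  rf_exc <- max(exc[["om"]] - exc[["cp"]] - exc[["cf"]] - exc[["ss"]], 0)
  indf_exc <- intake$nutrients[["indf"]]
  deg_rf_exc <- max(rf_exc - indf_exc, 0)
  ash_exc <- intake$nutrients[["ash"]] * (1 - ash_absorption)
  feces_dm <- exc[["om"]] + ash_exc
  if (feces_dm > intake$dmi)
    stop("excreted faecal DM exceeds DM intake; check digestibility inputs")

  feces_mass_g <- if (category == "weaned") {
    feces_mass_weaned(feces_dm, weaned_dm_fraction)
  } else {
    feces_mass(dig$d_om_diet, dmi_kg) * 1000
  }

  urine_kg <- urine_volume(dmi_kg, category)
  n_intake <- intake$nutrients[["cp"]] / 6.25
  n_feces <- exc[["cp"]] / 6.25
  urine_n <- if (category == "weaned") {
    ip <- config$intake_params
    gain_per_day <- ip$gain_per_cycle / ip$feeding_days_per_cycle
    urine_nitrogen_balance(n_intake, n_feces,
                           body_n_per_gain * gain_per_day)
  } else {
    urine_nitrogen(comp$cp, dmi_kg)
  }

  # diet-level fermentable fibre (per kg DM of feed and per day)
  ff_conc <- fermentable_fiber(
    sum(dig$per_ingredient$om_digested),
    sum(dig$per_ingredient$cp_digested),
    sum(dig$per_ingredient$cf_digested),
    sum(dig$per_ingredient$ss_digested)) / dmi_kg
  ff_intake <- ff_conc * dmi_kg

  per_kg_dm <- function(x) if (feces_dm > 0) 1000 * x / feces_dm else 0
  structure(list(
    category = category,
    feces_dm = feces_dm, feces_mass = feces_mass_g,
    urine_volume = urine_kg * 1000, urine_n = urine_n,
    urea_n = urea_fraction * urine_n,
    fecal_vfa = fecal_vfa_per_kg * feces_mass_g / 1000,
    excreted = c(exc, rf = rf_exc, indf = indf_exc,
                 degradable_rf = deg_rf_exc, ash = ash_exc),
    feces_composition = c(cp = per_kg_dm(exc[["cp"]]),
                          cf = per_kg_dm(exc[["cf"]]),
                          rf = per_kg_dm(rf_exc),
                          indf = per_kg_dm(indf_exc),
                          starch_sugar = per_kg_dm(exc[["ss"]]),
                          degradable_rf = per_kg_dm(deg_rf_exc),
                          ash = per_kg_dm(ash_exc)),
    ff = ff_conc, ff_intake = ff_intake,
    d_om_diet = dig$d_om_diet,
    digested = dig$digested,
    intake = intake),
    class = "excreta_profile")
}

#' @export
print.excreta_profile <- function(x, ...) {
  cat("<excreta_profile> ", x$category, ": feces ", round(x$feces_dm),
      " g DM/d (", round(x$feces_mass), " g/d fresh), urine ",
      round(x$urine_volume), " g/d carrying ", round(x$urine_n, 1),
      " g N/d\n", sep = "")
  invisible(x)
}
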