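#' Enteric methane of growing pigs from sNSP intake and body weight
#'
#' `CH4 (L/d) = -0.62 + 0.032 x sNSP intake (g/d) + 0.025 x body weight (kg)`,
#' clamped at 0 with a warning (the regression intercept is negative, so
#' tiny pigs on fibre-free diets predict below zero).
#'
#' @param snsp_intake soluble non-starch polysaccharide intake, g/day.
#' @param body_weight kg.
#' @return litres CH4/day.
#' @export
enteric_ch4_growing <- function(snsp_intake, body_weight) {
  stopifnot(snsp_intake >= 0, body_weight >= 0)
  l <- -0.62 + 0.032 * snsp_intake + 0.025 * body_weight
  if (l < 0) {
    warning("negative enteric CH4 prediction clamped to 0")
    l <- 0
  }
  l
}

#' Enteric methane of sows from fermentable-fibre intake
#'
#' `CH4 (L/d) = 0.440 + 0.0206 x FF intake (g/d)`.
#'
#' @param ff_intake fermentable fibre intake, g/day.
#' @return litres CH4/day.
#' @export
enteric_ch4_sow <- function(ff_intake) {
  stopifnot(ff_intake >= 0)
  0.440 + 0.0206 * ff_intake
}

#' Convert a CH4 volume flow to a mass flow
#'
#' @param l_d litres/day.
#' @param density gas density, g/L. 0.716 g/L is CH4 at 0 degC and 1 atm;
#'   0.654 g/L at 25 degC.
#' @return g/day.
#' @export
litres_to_grams <- function(l_d, density = 0.716) {
  stopifnot(density > 0)
  l_d * density
}

#' Emission intensity per kg of feed
#' @param g_d emission, g/day.
#' @param feed_asfed feed intake, g/day (> 0).
#' @return g per kg as-fed feed.
#' @export
per_kg_feed <- function(g_d, feed_asfed) {
  stopifnot(feed_asfed > 0)
  g_d / (feed_asfed / 1000)
}

#' Annualise a daily emission per animal place
#'
#' Multiplies by 365 days without an empty-day correction; an animal place
#' is assumed occupied year-round for the enteric term.
#'
#' @param g_d emission, g/day.
#' @return kg/year/animal place.
#' @export
annualize_enteric <- function(g_d) {
  stopifnot(g_d >= 0)
  g_d * 365 / 1000
}

#' Enteric methane emission for a category on a diet
#'
#' Dispatches to the growing-pig regression (driver: sNSP intake and body
#' weight) or the sow regression (driver: fermentable-fibre intake) and
#' attaches the derived reporting quantities.
#'
#' @param excreta an [excreta_profile()] (carries ff intake and the intake).
#' @param config a [pig_category_config()] (body weight).
#' @param gas_density CH4 density used for L to g conversion, g/L.
#' @return object of class `enteric_result` with fields `ch4_l_d`,
#'   `ch4_g_d`, `ch4_g_per_kg_feed`, `ch4_kg_yr` and `gas_density`.
#' @export
enteric_emission <- function(excreta,
                             config = pig_category_config(excreta$category),
                             gas_density = 0.716) {
  stopifnot(inherits(excreta, "excreta_profile"))
  intake <- excreta$intake
  if (intake$dmi == 0)
    return(structure(list(ch4_l_d = 0, ch4_g_d = 0, ch4_g_per_kg_feed = 0,
                          ch4_kg_yr = 0, gas_density = gas_density,
                          category = excreta$category),
                     class = "enteric_result"))
  l_d <- if (is_growing_class(excreta$category)) {
    enteric_ch4_growing(intake$nutrients[["snsp"]], config$body_weight)
  } else {
    enteric_ch4_sow(excreta$ff_intake)
  }
  g_d <- litres_to_grams(l_d, gas_density)
  structure(list(ch4_l_d = l_d, ch4_g_d = g_d,
                 ch4_g_per_kg_feed = per_kg_feed(g_d, intake$feed_asfed),
                 ch4_kg_yr = annualize_enteric(g_d),
                 gas_density = gas_density,
                 category = excreta$category),
            class = "enteric_result")
}

#' @export
print.enteric_result <- function(x, ...) {
  cat("<enteric_result> ", x$category, ": ", round(x$ch4_g_d, 2),
      " g CH4/d (", round(x$ch4_kg_yr, 2), " kg/yr/place, ",
      round(x$ch4_g_per_kg_feed, 2), " g/kg feed)\n", sep = "")
  invisible(x)
}
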