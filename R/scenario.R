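#' Run the full estimation chain for one category and diet
#'
#' Composes every stage: diet mixing, feed and nutrient intake, digestion
#' and excretion, enteric methane, and the dynamic barn-pit plus
#' outdoor-storage slurry simulation. The simulation runs `years` calendar
#' years and reports the final year, so the first year acts as spin-up for
#' methanogen biomass and storage filling. Deterministic: the same inputs
#' give the same result.
#'
#' @param diet a [diet_spec()].
#' @param table a [feed_table()]; default [danish_feed_table()].
#' @param config a [pig_category_config()]; default for the diet category.
#' @param storage a [storage_config()].
#' @param params a [kinetic_params()].
#' @param spillage_fraction fraction of feed intake spilled into the pit
#'   (default 0.02, the baseline production condition).
#' @param years simulated years (final year reported), default 2.
#' @param gas_density CH4 density for the enteric L-to-g conversion, g/L.
#' @return object of class `scenario_result`: all intermediates plus
#'   `summary`, a one-row data.frame with enteric, barn and storage methane
#'   in kg/year/animal place, their total, and percentage shares.
#' @export
run_scenario <- function(diet, table = danish_feed_table(),
                         config = pig_category_config(diet$category),
                         storage = storage_config(),
                         params = kinetic_params(),
                         spillage_fraction = 0.02, years = 2,
                         gas_density = 0.716) {
  stopifnot(years >= 1)
  intake <- nutrient_intake(diet, table, config)
  excreta <- excreta_profile(intake, table, config)
  enteric <- enteric_emission(excreta, config, gas_density)
  influent <- excreta_to_influent(excreta, spillage_fraction)

  horizon <- as.integer(365 * years)
  barn <- simulate_barn(config, influent, params, horizon = horizon)
  store <- simulate_storage(barn$batches, storage, params,
                            horizon = horizon)
  last_year <- (horizon - 364):horizon
  barn_kg <- sum(barn$ledger$ch4_g[last_year]) / 1000
  store_kg <- sum(store$ledger$ch4_g[last_year]) / 1000

  shares <- summarize_shares(enteric$ch4_kg_yr, barn_kg, store_kg)
  summary <- data.frame(
    diet = diet$name, category = diet$category,
    enteric_kg_yr = enteric$ch4_kg_yr, barn_kg_yr = barn_kg,
    storage_kg_yr = store_kg,
    total_kg_yr = enteric$ch4_kg_yr + barn_kg + store_kg,
    enteric_share = shares$exact[["enteric"]],
    barn_share = shares$exact[["barn"]],
    storage_share = shares$exact[["storage"]],
    stringsAsFactors = FALSE)
  structure(list(diet = diet, config = config,
                 composition = intake$composition, intake = intake,
                 excreta = excreta, enteric = enteric,
                 influent = influent, barn = barn, storage = store,
                 shares = shares, summary = summary),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat("<scenario_result> '", s$diet, "' (", s$category, ")\n",
      "  enteric ", round(s$enteric_kg_yr, 2),
      " + barn ", round(s$barn_kg_yr, 2),
      " + storage ", round(s$storage_kg_yr, 2),
      " = ", round(s$total_kg_yr, 2), " kg CH4/yr/animal place\n",
      sep = "")
  invisible(x)
}

#' Percentage shares of enteric, barn and storage methane
#'
#' @param enteric,barn,storage emissions, kg/year/animal place; total must
#'   be positive.
#' @return list with `exact` (named percentages) and `rounded` (integers
#'   as printed in reports; `manure` is the barn+storage share).
#' @export
summarize_shares <- function(enteric, barn, storage) {
  total <- enteric + barn + storage
  if (total <= 0) stop("total emission must be > 0")
  exact <- c(enteric = enteric, barn = barn, storage = storage) /
    total * 100
  list(exact = exact,
       rounded = c(round(exact), manure = round(exact[["barn"]] +
                                                  exact[["storage"]])))
}

#' Feed-spillage sweep
#'
#' Re-runs the full barn+storage simulation of a base scenario for each
#' spillage fraction and reports emissions and the relative change versus
#' the 0% baseline.
#'
#' @param diet,table,config,storage,params,years as in [run_scenario()].
#' @param fractions spillage fractions; default the published sweep
#'   `c(0, 0.02, 0.04, 0.06, 0.08)`.
#' @return data.frame with one row per fraction: barn and storage
#'   kg/yr/animal place, relative changes vs 0%, and the minimum daily
#'   mean inhibition factor seen in the barn.
#' @export
spillage_sweep <- function(diet, table = danish_feed_table(),
                           config = pig_category_config(diet$category),
                           storage = storage_config(),
                           params = kinetic_params(),
                           fractions = c(0, 0.02, 0.04, 0.06, 0.08),
                           years = 2) {
  stopifnot(all(fractions >= 0), all(fractions <= 0.2))
  rows <- lapply(fractions, function(f) {
    sc <- run_scenario(diet, table, config, storage, params,
                       spillage_fraction = f, years = years)
    data.frame(spillage = f,
               barn_kg_yr = sc$summary$barn_kg_yr,
               storage_kg_yr = sc$summary$storage_kg_yr,
               min_inhibition = min(sc$barn$ledger$inhibition_mean))
  })
  out <- do.call(rbind, rows)
  base <- out[out$spillage == min(out$spillage), ]
  out$barn_change_pct <- 100 * (out$barn_kg_yr / base$barn_kg_yr - 1)
  out$storage_change_pct <-
    100 * (out$storage_kg_yr / base$storage_kg_yr - 1)
  out
}

#' Report tables for a set of scenario results
#'
#' Binds the per-diet rows of a category into report tables mirroring the
#' published layout: feed intake and diet composition, faeces composition
#' and excretion, and the three emission columns. Report cells are rounded
#' to printed precision (integers for intake/excreta, two decimals for
#' kg/yr); internal values stay full precision in the scenario objects.
#'
#' @param scenarios list of [run_scenario()] results.
#' @return list of data.frames `intake`, `excreta`, `emission`.
#' @export
scenario_report <- function(scenarios) {
  stopifnot(length(scenarios) > 0)
  intk <- do.call(rbind, lapply(scenarios, function(s) {
    co <- s$composition
    data.frame(diet = s$summary$diet,
               feed_intake_g_d = round(s$intake$feed_asfed),
               dm_g_kg = round(co$dm), cp = round(co$cp),
               cf = round(co$cf), starch = round(co$starch),
               sugar = round(co$sugar), snsp = round(co$snsp),
               rf = round(co$rf), indf = round(co$indf),
               ash = round(co$ash), stringsAsFactors = FALSE)
  }))
  excr <- do.call(rbind, lapply(scenarios, function(s) {
    e <- s$excreta
    fc <- e$feces_composition
    data.frame(diet = s$summary$diet,
               feces_cp = round(fc[["cp"]]), feces_cf = round(fc[["cf"]]),
               feces_rf = round(fc[["rf"]]),
               feces_indf = round(fc[["indf"]]),
               feces_starch = round(fc[["starch_sugar"]], 1),
               ff = round(e$ff),
               feces_dm_g_d = round(e$feces_dm),
               feces_mass_g_d = round(e$feces_mass),
               urine_g_d = round(e$urine_volume),
               stringsAsFactors = FALSE)
  }))
  emis <- do.call(rbind, lapply(scenarios, function(s) {
    data.frame(diet = s$summary$diet,
               enteric_g_d = round(s$enteric$ch4_g_d, 2),
               enteric_g_kg_feed = round(s$enteric$ch4_g_per_kg_feed, 2),
               enteric_kg_yr = round(s$summary$enteric_kg_yr, 2),
               barn_kg_yr = round(s$summary$barn_kg_yr, 2),
               storage_kg_yr = round(s$summary$storage_kg_yr, 2),
               stringsAsFactors = FALSE)
  }))
  list(intake = intk, excreta = excr, emission = emis)
}
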