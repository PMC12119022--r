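#' Daily feed intake of growing pigs (batch-cycle basis)
#'
#' Growing pigs (weaned and grower-finisher) are fed to achieve the average
#' gain per batch cycle at a given feed efficiency, so
#' `intake = gain x efficiency x (1 / fu_per_kg) / cycle_days`.
#'
#' @param gain_per_cycle kg live-weight gain per pig per batch cycle.
#' @param feed_efficiency feed units (FUsv) per kg gain.
#' @param fu_per_kg FUsv per kg as-fed feed.
#' @param cycle_days feeding days in the batch cycle.
#' @return kg as-fed feed per day.
#' @export
growing_feed_intake <- function(gain_per_cycle, feed_efficiency, fu_per_kg,
                                cycle_days) {
  if (gain_per_cycle <= 0 || fu_per_kg <= 0 || cycle_days <= 0 ||
      feed_efficiency < 0)
    stop("growing_feed_intake: inputs must be positive ",
         "(feed_efficiency may be zero)")
  gain_per_cycle * feed_efficiency / fu_per_kg / cycle_days
}

#' Daily feed intake of sows (annual feed-unit budget basis)
#'
#' The annual feed-unit budget of a sow is split over production stages;
#' daily intake while the sow is actually in the section is the stage sum
#' divided by the feeding days it covers:
#' `intake = sum(fu_stages) / feeding_days / fu_per_kg`.
#' The denominator is the feeding days (285 d/year in the gestation
#' section, 80 d/year in the farrowing section), not 365: only then do the
#' published daily intakes follow from the published stage budgets.
#'
#' @param fu_stages numeric vector of stage budgets, FUso/year/sow.
#' @param feeding_days days per year the sow is fed in the section, (0, 365].
#' @param fu_per_kg FUso per kg as-fed feed.
#' @return kg as-fed feed per day.
#' @export
sow_feed_intake <- function(fu_stages, feeding_days, fu_per_kg) {
  if (length(fu_stages) == 0L) stop("fu_stages must not be empty")
  stopifnot(all(fu_stages >= 0), fu_per_kg > 0)
  if (feeding_days <= 0 || feeding_days > 365)
    stop("feeding_days must be in (0, 365]")
  sum(fu_stages) / feeding_days / fu_per_kg
}

#' Daily feed and nutrient intake for a category on a diet
#'
#' Combines the category's intake parameters with the diet composition:
#' as-fed intake from [growing_feed_intake()] or [sow_feed_intake()], DM
#' intake as `feed_asfed x dm / 1000`, and per-nutrient intakes as
#' `dmi x concentration / 1000`.
#'
#' @param diet a [diet_spec()].
#' @param table a [feed_table()].
#' @param config a [pig_category_config()]; defaults to the built-in config
#'   for the diet's category.
#' @return object of class `intake_result`: `feed_asfed` and `dmi` (g/day),
#'   a named vector `nutrients` of g/day intakes, the `composition`, and
#'   the DM proportions used.
#' @export
nutrient_intake <- function(diet, table,
                            config = pig_category_config(diet$category)) {
  stopifnot(inherits(config, "pig_config"))
  comp <- mix_composition(diet, table)
  ip <- config$intake_params
  kg_asfed <- if (is_growing_class(diet$category)) {
    growing_feed_intake(ip$gain_per_cycle, ip$feed_efficiency,
                        diet$fu_per_kg_asfed, ip$feeding_days_per_cycle)
  } else {
    sow_feed_intake(ip$fu_stages, ip$feeding_days, diet$fu_per_kg_asfed)
  }
  feed_asfed <- kg_asfed * 1000
  dmi <- feed_asfed * comp$dm / 1000
  nut <- vapply(.NUTRIENT_COLS, function(n) dmi * comp[[n]] / 1000,
                numeric(1))
  structure(list(feed_asfed = feed_asfed, dmi = dmi, nutrients = nut,
                 composition = comp,
                 dm_proportions = comp$dm_proportions,
                 category = diet$category),
            class = "intake_result")
}

#' @export
print.intake_result <- function(x, ...) {
  cat("<intake_result> ", x$category, ": ", round(x$feed_asfed),
      " g as-fed/d, ", round(x$dmi), " g DM/d\n", sep = "")
  invisible(x)
}
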