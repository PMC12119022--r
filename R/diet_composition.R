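#' Residual fibre by difference
#'
#' Residual fibre (RF, g/kg DM) is the carbohydrate fraction not accounted
#' for by protein, fat, starch and sugar:
#' `RF = OM - CP - CF - starch - sugar`. For real feeds the result should be
#' nonnegative; a negative value signals inconsistent inputs.
#'
#' @param om,cp,cf,sugar,starch concentrations in g/kg DM (vectorised).
#' @param clamp if `TRUE`, clamp negative results to 0 with a warning
#'   instead of erroring.
#' @return residual fibre, g/kg DM.
#' @examples
#' residual_fiber(983, 113, 24, 19, starch = 670)  # wheat: 157
#' @export
residual_fiber <- function(om, cp, cf, sugar, starch, clamp = FALSE) {
  stopifnot(all(om >= 0), all(cp >= 0), all(cf >= 0),
            all(starch >= 0), all(sugar >= 0))
  rf <- om - cp - cf - starch - sugar
  if (any(rf < 0)) {
    if (!clamp)
      stop("residual fibre is negative (", paste(round(rf[rf < 0], 2),
           collapse = ", "), "); om is smaller than cp + cf + starch + sugar")
    warning("negative residual fibre clamped to 0")
    rf <- pmax(rf, 0)
  }
  rf
}

#' Convert as-fed inclusions to dry-matter proportions
#'
#' The mixing equation works on a DM basis: the DM proportion of ingredient
#' j is `a_j = (incl_j * dm_j) / sum_k(incl_k * dm_k)`. The denominator
#' (over the as-fed inclusion sum) is the whole-diet DM in g/kg as-fed.
#'
#' @param diet a [diet_spec()].
#' @param table a [feed_table()].
#' @return named numeric vector of DM proportions (sums to 1), with the
#'   whole-diet `dm` (g/kg as-fed) attached as attribute `"dm"`.
#' @export
asfed_to_dm_proportions <- function(diet, table) {
  stopifnot(inherits(diet, "diet_spec"), inherits(table, "feed_table"))
  ing <- table$ingredients
  idx <- match(diet$items$ingredient, ing$name)
  if (anyNA(idx))
    stop("diet '", diet$name, "' refers to unknown ingredient(s): ",
         paste(diet$items$ingredient[is.na(idx)], collapse = ", "))
  dm <- ing$dm[idx]
  if (any(dm <= 0)) stop("ingredient dm values must be > 0")
  w <- diet$items$proportion_asfed * dm
  a <- w / sum(w)
  names(a) <- diet$items$ingredient
  attr(a, "dm") <- sum(w) / sum(diet$items$proportion_asfed)
  a
}

#' Whole-diet nutrient composition from ingredient inclusions
#'
#' Every nutrient concentration of the mixed diet is the DM-proportion
#' weighted sum of the ingredient concentrations; whole-diet DM (g/kg
#' as-fed) is the as-fed weighted mean of ingredient DM. The diet-level
#' residual fibre is computed both by mixing the ingredient rf values
#' (canonical, reported as `rf`) and by difference on the mixed
#' om/cp/cf/starch/sugar (`rf_by_difference`); the two differ only through
#' printed-table rounding of ingredient rf.
#'
#' @param diet a [diet_spec()].
#' @param table a [feed_table()].
#' @return object of class `diet_composition`: list with `dm` (g/kg as-fed),
#'   nutrient concentrations (g/kg DM), `rf_by_difference`, and
#'   `dm_proportions`.
#' @export
mix_composition <- function(diet, table) {
  a <- asfed_to_dm_proportions(diet, table)
  ing <- table$ingredients
  idx <- match(names(a), ing$name)
  conc <- lapply(.NUTRIENT_COLS, function(col) sum(a * ing[[col]][idx]))
  names(conc) <- .NUTRIENT_COLS
  out <- c(list(name = diet$name, category = diet$category,
                dm = attr(a, "dm")),
           conc,
           list(rf_by_difference = conc$om - conc$cp - conc$cf -
                  conc$starch - conc$sugar,
                dm_proportions = as.numeric(a)))
  names(out$dm_proportions) <- names(a)
  structure(out, class = "diet_composition")
}

#' @export
print.diet_composition <- function(x, digits = 1, ...) {
  cat("<diet_composition> '", x$name, "' (", x$category, ")\n", sep = "")
  v <- unlist(x[c("dm", .NUTRIENT_COLS)])
  print(round(v, digits))
  invisible(x)
}

#' Substitute one ingredient by another (percentage points as-fed)
#'
#' Emulates the fibre-substitution scheme used to build diet variants:
#' `points` as-fed percentage points are moved from ingredient `from` to
#' ingredient `to`.
#'
#' @param diet a [diet_spec()].
#' @param from,to ingredient names.
#' @param points percentage points of the as-fed formulation to move.
#' @param fu_per_kg_asfed energy density of the resulting diet (fibre
#'   substitutions dilute net energy, so it must be given).
#' @param name label for the new diet.
#' @return a new [diet_spec()].
#' @export
substitute_ingredient <- function(diet, from, to, points, fu_per_kg_asfed,
                                  name = paste0(diet$name, "_", to)) {
  stopifnot(inherits(diet, "diet_spec"), points >= 0)
  items <- diet$items
  i <- match(from, items$ingredient)
  if (is.na(i)) stop("ingredient '", from, "' not in diet '", diet$name, "'")
  frac <- points / 100
  if (items$proportion_asfed[i] < frac)
    stop("diet '", diet$name, "' contains only ",
         round(100 * items$proportion_asfed[i], 2), "% of '", from,
         "', cannot remove ", points, " points")
  items$proportion_asfed[i] <- items$proportion_asfed[i] - frac
  j <- match(to, items$ingredient)
  if (is.na(j)) {
    items <- rbind(items, data.frame(ingredient = to,
                                     proportion_asfed = frac))
  } else {
    items$proportion_asfed[j] <- items$proportion_asfed[j] + frac
  }
  diet_spec(name, items, fu_per_kg_asfed, diet$category)
}
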