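#' @keywords internal
"_PACKAGE"

# Column layout shared by readers/writers; nutrient columns are g/kg DM,
# dm is g DM/kg as-fed.
.NUTRIENT_COLS <- c("om", "cp", "cf", "starch", "sugar", "rf", "indf",
                    "nsp", "snsp", "ash")
.FEED_COLS <- c("name", "dm", .NUTRIENT_COLS)
.DIG_COLS  <- c("ingredient", "animal_class", "d_om", "d_cp", "d_cf",
                "d_starch_sugar")

.PIG_CATEGORIES <- c("weaned", "grower_finisher", "gestating_sow",
                     "lactating_sow")

#' Is a pig category a growing class (weaned / grower-finisher)?
#' @param category pig category string.
#' @return logical scalar.
#' @keywords internal
is_growing_class <- function(category) {
  category <- match.arg(category, .PIG_CATEGORIES)
  category %in% c("weaned", "grower_finisher")
}

#' Digestibility class ("growing" or "sow") for a pig category
#'
#' Growing-class coefficients apply to weaned and grower-finisher pigs,
#' sow-class coefficients to gestating and lactating sows.
#'
#' @param category one of `"weaned"`, `"grower_finisher"`, `"gestating_sow"`,
#'   `"lactating_sow"`.
#' @return `"growing"` or `"sow"`.
#' @export
animal_class <- function(category) {
  if (is_growing_class(category)) "growing" else "sow"
}

#' Construct a feed table
#'
#' A feed table bundles per-ingredient nutrient concentrations (g/kg DM; `dm`
#' in g/kg as-fed) with apparent total-tract digestibility coefficients per
#' animal class. All diet and excretion computations resolve ingredients
#' against it.
#'
#' @param ingredients data.frame with columns
#'   `name, dm, om, cp, cf, starch, sugar, rf, indf, nsp, snsp, ash`.
#' @param digestibility data.frame with columns
#'   `ingredient, animal_class, d_om, d_cp, d_cf, d_starch_sugar`;
#'   coefficients are fractions in \[0, 1\].
#' @param validate validate invariants (default `TRUE`).
#' @return object of class `feed_table`.
#' @export
feed_table <- function(ingredients, digestibility, validate = TRUE) {
  stopifnot(is.data.frame(ingredients), is.data.frame(digestibility))
  missing <- setdiff(.FEED_COLS, names(ingredients))
  if (length(missing))
    stop("feedstuff table is missing column(s): ",
         paste(missing, collapse = ", "))
  missing <- setdiff(.DIG_COLS, names(digestibility))
  if (length(missing))
    stop("digestibility table is missing column(s): ",
         paste(missing, collapse = ", "))
  ingredients <- ingredients[, .FEED_COLS]
  digestibility <- digestibility[, .DIG_COLS]
  ft <- structure(list(ingredients = ingredients,
                       digestibility = digestibility),
                  class = "feed_table")
  if (validate) {
    if (nrow(ingredients) == 0L) stop("no ingredients in feed table")
    if (anyDuplicated(ingredients$name))
      stop("duplicate ingredient name(s): ",
           paste(unique(ingredients$name[duplicated(ingredients$name)]),
                 collapse = ", "))
    for (i in seq_len(nrow(ingredients))) {
      f <- validate_ingredient(as.list(ingredients[i, ]))
      errs <- f[vapply(f, function(x) x$severity == "error", logical(1))]
      if (length(errs))
        stop("ingredient '", ingredients$name[i], "' (row ", i, "): ",
             paste(vapply(errs, `[[`, "", "message"), collapse = "; "))
    }
    dc <- digestibility
    bad <- !dc$animal_class %in% c("growing", "sow")
    if (any(bad))
      stop("digestibility rows with unknown animal_class: ",
           paste(unique(dc$animal_class[bad]), collapse = ", "))
    co <- as.matrix(dc[, c("d_om", "d_cp", "d_cf", "d_starch_sugar")])
    if (any(!is.finite(co)) || any(co < 0) || any(co > 1))
      stop("digestibility coefficients must be fractions in [0, 1]")
    unk <- setdiff(dc$ingredient, ingredients$name)
    if (length(unk))
      stop("digestibility refers to unknown ingredient(s): ",
           paste(unk, collapse = ", "))
  }
  ft
}

#' Validate one feed ingredient record
#'
#' Checks the record's internal consistency: all concentrations nonnegative,
#' `dm <= 1000`, `om + ash = 1000 +/- 2`, `indf <= rf`, `snsp <= nsp`, and the
#' printed residual fibre against its by-difference recomputation
#' `om - cp - cf - starch - sugar`. A discrepancy of at most 2 g/kg DM (or a
#' negative recomputed value clamped to a printed 0, as happens for pure
#' protein feeds) is reported as a rounding-level warning; anything larger is
#' an error.
#'
#' @param ing a list or one-row data.frame with fields
#'   `name, dm, om, cp, cf, starch, sugar, rf, indf, nsp, snsp, ash`.
#' @return list of findings, each `list(severity, field, message)` with
#'   severity `"error"` or `"warning"`; empty when all invariants hold.
#' @export
validate_ingredient <- function(ing) {
  ing <- as.list(ing)
  findings <- list()
  say <- function(severity, field, message)
    findings[[length(findings) + 1L]] <<-
      list(severity = severity, field = field, message = message)

  num <- setdiff(.FEED_COLS, "name")
  for (f in num) {
    v <- ing[[f]]
    if (is.null(v) || !is.finite(v)) {
      say("error", f, paste0(f, " is missing or non-finite"))
      return(findings)
    }
    if (v < 0) say("error", f, paste0(f, " is negative (", v, ")"))
  }
  if (ing$dm > 1000)
    say("error", "dm", paste0("dm exceeds 1000 g/kg (", ing$dm, ")"))
  if (abs(ing$om + ing$ash - 1000) > 2)
    say("error", "ash", paste0("om + ash = ", ing$om + ing$ash,
                               ", expected 1000 +/- 2"))
  raw <- ing$om - ing$cp - ing$cf - ing$starch - ing$sugar
  rf2 <- max(raw, 0)
  dev <- abs(ing$rf - rf2)
  if (raw < 0 && ing$rf == 0) {
    say("warning", "rf",
        paste0("by-difference residual fibre is negative (", raw,
               "); printed value clamped to 0"))
  } else if (dev > 2) {
    say("error", "rf",
        paste0("rf = ", ing$rf, " but om - cp - cf - starch - sugar = ",
               raw, " (|diff| = ", dev, " > 2 g/kg DM)"))
  } else if (dev > 0) {
    say("warning", "rf",
        paste0("rf = ", ing$rf, " differs from recomputed ", raw,
               " by ", dev, " g/kg DM (table rounding)"))
  }
  if (ing$indf > ing$rf)
    say("error", "indf", paste0("indf (", ing$indf, ") exceeds rf (",
                                ing$rf, ")"))
  if (ing$snsp > ing$nsp)
    say("error", "snsp", paste0("snsp (", ing$snsp, ") exceeds nsp (",
                                ing$nsp, ")"))
  findings
}

#' Load a feed table from CSV files
#'
#' Files are comma-separated UTF-8 with a mandatory header row and decimal
#' points. See [feed_table()] for the required columns.
#'
#' @param feedstuffs path to the feedstuff nutrient CSV.
#' @param digestibility path to the digestibility-coefficient CSV.
#' @return validated [feed_table()].
#' @export
load_feed_table <- function(feedstuffs, digestibility) {
  ing <- utils::read.csv(feedstuffs, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (nrow(ing) == 0L) stop("no ingredients in '", feedstuffs, "'")
  dig <- utils::read.csv(digestibility, stringsAsFactors = FALSE,
                         comment.char = "#")
  feed_table(ing, dig)
}

#' Write a feed table back to CSV files
#' @param table a [feed_table()].
#' @param feedstuffs,digestibility output paths.
#' @return `table`, invisibly.
#' @export
write_feed_table <- function(table, feedstuffs, digestibility) {
  stopifnot(inherits(table, "feed_table"))
  utils::write.csv(table$ingredients, feedstuffs, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(table$digestibility, digestibility, row.names = FALSE,
                   quote = FALSE)
  invisible(table)
}

#' @export
print.feed_table <- function(x, ...) {
  cat("<feed_table> ", nrow(x$ingredients), " ingredients, ",
      nrow(x$digestibility), " digestibility records\n", sep = "")
  invisible(x)
}

#' Construct a diet specification
#'
#' Inclusion proportions are as-fed mass fractions (kg ingredient per kg
#' feed). They must sum to 1 within 0.002 (printed formulation tables round
#' to two decimals of a percent and can be a few parts per thousand off);
#' proportions are renormalised to sum exactly to 1.
#'
#' @param name diet label.
#' @param items data.frame with columns `ingredient`, `proportion_asfed`.
#' @param fu_per_kg_asfed net-energy density, Danish feed units (FUsv for
#'   growing pigs, FUso for sows) per kg as-fed feed.
#' @param category pig category the diet is fed to.
#' @return object of class `diet_spec`.
#' @export
diet_spec <- function(name, items, fu_per_kg_asfed, category) {
  category <- match.arg(category, .PIG_CATEGORIES)
  stopifnot(is.data.frame(items),
            all(c("ingredient", "proportion_asfed") %in% names(items)))
  p <- items$proportion_asfed
  if (any(!is.finite(p)) || any(p < 0))
    stop("diet '", name, "': inclusion proportions must be finite and >= 0")
  s <- sum(p)
  if (abs(s - 1) > 0.002)
    stop("diet '", name, "': inclusion proportions sum to ", round(s, 4),
         ", expected 1 +/- 0.002")
  if (!is.finite(fu_per_kg_asfed) || fu_per_kg_asfed <= 0)
    stop("diet '", name, "': fu_per_kg_asfed must be > 0")
  items <- data.frame(ingredient = as.character(items$ingredient),
                      proportion_asfed = p / s,
                      stringsAsFactors = FALSE)
  structure(list(name = name, items = items,
                 fu_per_kg_asfed = fu_per_kg_asfed,
                 category = category),
            class = "diet_spec")
}

#' Load a diet specification from CSV
#'
#' @param path CSV with columns `ingredient`, `proportion_asfed`.
#' @inheritParams diet_spec
#' @return [diet_spec()].
#' @export
load_diet <- function(path, fu_per_kg_asfed, category,
                      name = sub("\\.csv$", "", basename(path))) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  diet_spec(name, items, fu_per_kg_asfed, category)
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("<diet_spec> '", x$name, "' (", x$category, "), ",
      nrow(x$items), " ingredients, ", x$fu_per_kg_asfed,
      " FU/kg as-fed\n", sep = "")
  invisible(x)
}

#' Look up digestibility coefficients for a set of ingredients
#'
#' @param table a [feed_table()].
#' @param ingredients character vector of ingredient names.
#' @param class `"growing"` or `"sow"`.
#' @param require_for names for which a missing record is an error; by
#'   default ingredients carrying no organic matter (pure minerals) are
#'   exempt and get coefficients of 0.
#' @return data.frame of coefficients aligned with `ingredients`.
#' @keywords internal
digestibility_for <- function(table, ingredients, class,
                              require_for = NULL) {
  dc <- table$digestibility
  dc <- dc[dc$animal_class == class, , drop = FALSE]
  idx <- match(ingredients, dc$ingredient)
  out <- data.frame(ingredient = ingredients,
                    d_om = dc$d_om[idx], d_cp = dc$d_cp[idx],
                    d_cf = dc$d_cf[idx],
                    d_starch_sugar = dc$d_starch_sugar[idx],
                    stringsAsFactors = FALSE)
  om <- table$ingredients$om[match(ingredients, table$ingredients$name)]
  needs <- if (is.null(require_for)) ingredients[om > 0] else require_for
  miss <- needs[is.na(idx[match(needs, ingredients)])]
  if (length(miss))
    stop("missing ", class, "-class digestibility record(s) for: ",
         paste(miss, collapse = ", "))
  out[is.na(out$d_om), c("d_om", "d_cp", "d_cf", "d_starch_sugar")] <- 0
  out
}
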