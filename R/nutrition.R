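#' Load and validate a nutrient table
#'
#' Nutrient tables map fine food categories to a density (for the
#' volume-to-weight conversion), energy and macronutrients per 100 g, and a
#' standard serving volume (the fallback when the reference card is
#' unavailable). A single CSV schema replaces live database access: network
#' nutrient services are not a reproducible surface, but the primary ->
#' secondary fallback order is preserved as behaviour. Two fixture tables
#' are bundled (`nutrients_primary.csv`, `nutrients_secondary.csv`).
#'
#' @param path CSV with columns `fine_category`, `density_g_per_mL`,
#'   `kcal_per_100g`, `cho_g_per_100g`, `protein_g_per_100g`,
#'   `fat_g_per_100g`, `serving_volume_mL`.
#' @return A validated `nutrient_table` tibble keyed by `fine_category`.
#' @export
load_nutrient_table <- function(path = system.file("extdata",
                                                   "nutrients_primary.csv",
                                                   package = "mealmetry")) {
  cols <- c("fine_category", "density_g_per_mL", "kcal_per_100g",
            "cho_g_per_100g", "protein_g_per_100g", "fat_g_per_100g",
            "serving_volume_mL")
  tab <- readr::read_csv(path, col_types = "cdddddd")
  if (!all(cols %in% names(tab))) {
    abort(sprintf("nutrient table must have columns: %s",
                  paste(cols, collapse = ", ")))
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    line <- i + 1  # header is line 1
    if (is.na(r$density_g_per_mL) || r$density_g_per_mL <= 0) {
      abort(sprintf("line %d (%s): density must be > 0", line,
                    r$fine_category))
    }
    nut <- c(r$kcal_per_100g, r$cho_g_per_100g, r$protein_g_per_100g,
             r$fat_g_per_100g, r$serving_volume_mL)
    if (anyNA(nut) || any(nut < 0)) {
      abort(sprintf("line %d (%s): nutrient fields must be >= 0", line,
                    r$fine_category))
    }
    if (any(c(r$cho_g_per_100g, r$protein_g_per_100g, r$fat_g_per_100g) > 100)) {
      abort(sprintf("line %d (%s): macros per 100 g cannot exceed 100", line,
                    r$fine_category))
    }
  }
  dup <- tab |> count(fine_category) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate categories: %s", paste(dup$fine_category,
                                                    collapse = ", ")))
  }
  class(tab) <- c("nutrient_table", class(tab))
  tab
}

#' Look a category up with primary/secondary fallback
#'
#' The primary table wins; the secondary table is consulted only for
#' categories the primary is missing, and such records are flagged so the
#' provenance survives into reports.
#'
#' @param category Fine category name.
#' @param primary,secondary `nutrient_table`s (secondary may be `NULL`).
#' @return One-row tibble: the record plus a `source` column
#'   (`"primary"`/`"secondary"`).
#' @export
nutrient_lookup <- function(category, primary, secondary = NULL) {
  hit <- primary[primary$fine_category == category, ]
  if (nrow(hit) > 0) return(mutate(hit[1, ], source = "primary"))
  if (!is.null(secondary)) {
    hit <- secondary[secondary$fine_category == category, ]
    if (nrow(hit) > 0) return(mutate(hit[1, ], source = "secondary"))
  }
  abort(sprintf("category '%s' missing from all nutrient tables", category),
        class = "mealmetry_missing_nutrient")
}

#' Convert an item volume to weight and nutrients
#'
#' `weight = volume x density`; each nutrient is `weight x per-100g / 100`.
#'
#' @param volume_mL Item volume (>= 0).
#' @param record One row of a `nutrient_table`.
#' @return One-row tibble: `weight_g`, `kcal`, `cho_g`, `protein_g`,
#'   `fat_g`.
#' @export
item_nutrition <- function(volume_mL, record) {
  stopifnot(volume_mL >= 0)
  w <- volume_mL * record$density_g_per_mL
  tibble(weight_g = w,
         kcal = w * record$kcal_per_100g / 100,
         cho_g = w * record$cho_g_per_100g / 100,
         protein_g = w * record$protein_g_per_100g / 100,
         fat_g = w * record$fat_g_per_100g / 100)
}

#' EAN-13 checksum validation
#'
#' @param barcode Digit string of length 13.
#' @return `TRUE` when the check digit is consistent.
#' @export
ean13_valid <- function(barcode) {
  if (!grepl("^[0-9]{13}$", barcode)) return(FALSE)
  d <- as.integer(strsplit(barcode, "")[[1]])
  s <- sum(d[1:12] * rep(c(1, 3), 6))
  (10 - s %% 10) %% 10 == d[13]
}

#' Declare a consumed packaged product
#'
#' Packaged products bypass volume estimation: their per-package nutrients
#' are known (from a barcode database) and the user declares the fraction
#' consumed.
#'
#' @param barcode EAN-13 digit string (checksum validated).
#' @param kcal,cho_g,protein_g,fat_g Per-package nutrient content.
#' @param fraction_consumed Fraction of the package eaten, in `(0, 1]`.
#' @param name Optional display name.
#' @return A `packaged_product`.
#' @export
packaged_product <- function(barcode, kcal, cho_g, protein_g, fat_g,
                             fraction_consumed, name = NA_character_) {
  if (!ean13_valid(barcode)) {
    abort(sprintf("invalid EAN-13 barcode '%s'", barcode),
          class = "mealmetry_invalid_barcode")
  }
  if (!is.numeric(fraction_consumed) || fraction_consumed <= 0 ||
      fraction_consumed > 1) {
    abort("fraction_consumed must be in (0, 1]")
  }
  stopifnot(kcal >= 0, cho_g >= 0, protein_g >= 0, fat_g >= 0)
  structure(list(barcode = barcode, kcal = kcal, cho_g = cho_g,
                 protein_g = protein_g, fat_g = fat_g,
                 fraction_consumed = fraction_consumed, name = name),
            class = "packaged_product")
}

#' Nutrients contributed by a packaged product
#'
#' @param product A [packaged_product()].
#' @return One-row tibble: `weight_g` (NA, unknown for packages), `kcal`,
#'   `cho_g`, `protein_g`, `fat_g`, each per-package value scaled by the
#'   fraction consumed.
#' @export
packaged_nutrition <- function(product) {
  stopifnot(inherits(product, "packaged_product"))
  f <- product$fraction_consumed
  tibble(weight_g = NA_real_, kcal = product$kcal * f,
         cho_g = product$cho_g * f, protein_g = product$protein_g * f,
         fat_g = product$fat_g * f)
}

nutrient_cols <- c("kcal", "cho_g", "protein_g", "fat_g")

#' Aggregate items into a meal report
#'
#' @param items Tibble with one row per item; must contain the nutrient
#'   columns `kcal`, `cho_g`, `protein_g`, `fat_g` (plus whatever per-item
#'   detail is available: category, volume, weight, flags).
#' @param meal_label One of snack, breakfast, lunch, dinner, drink.
#' @return A `meal_report`: `items`, per-nutrient `totals`, `meal_label`.
#' @export
aggregate_meal <- function(items, meal_label = c("snack", "breakfast",
                                                 "lunch", "dinner", "drink")) {
  meal_label <- arg_match(meal_label)
  items <- as_tibble(items)
  totals <- map_dbl(nutrient_cols, function(cn) {
    if (cn %in% names(items)) sum(items[[cn]], na.rm = TRUE) else 0
  })
  names(totals) <- nutrient_cols
  structure(list(items = items, totals = as_tibble(as.list(totals)),
                 meal_label = meal_label),
            class = "meal_report")
}

#' @export
print.meal_report <- function(x, ...) {
  cat(sprintf("<meal_report> %s: %d item(s), %.0f kcal (CHO %.1f g, protein %.1f g, fat %.1f g)\n",
              x$meal_label, nrow(x$items), x$totals$kcal, x$totals$cho_g,
              x$totals$protein_g, x$totals$fat_g))
  invisible(x)
}

#' Aggregate meal reports into day totals
#'
#' Day totals are plain element-wise sums, so they are invariant to how
#' items are grouped into meals.
#'
#' @param meal_reports List of `meal_report`s.
#' @return One-row tibble of day totals (`kcal`, `cho_g`, `protein_g`,
#'   `fat_g`).
#' @export
aggregate_day <- function(meal_reports) {
  if (length(meal_reports) == 0) {
    return(as_tibble(setNames(as.list(rep(0, 4)), nutrient_cols)))
  }
  map(meal_reports, ~.x$totals) |> bind_rows() |>
    summarise(across(dplyr::everything(), sum))
}
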