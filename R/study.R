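#' Default meal-scene catalogue
#'
#' A small catalogue of tabletop meal scenes (each a [scene_spec()] whose
#' solids carry fine taxonomy categories) used by [generate_study()] and the
#' demo fixtures. Geometry is kept inside the default camera frustum and
#' item heights inside the 5 cm card-plane band, emulating typical
#' single-plate meals photographed at about 40 cm.
#'
#' @return Named list of `scene_spec`s with a `meal_label` attribute each.
#' @export
default_meal_catalogue <- function() {
  tpl <- function(spec, label) {
    attr(spec, "meal_label") <- label
    spec
  }
  list(
    breakfast_bread = tpl(scene_spec(solids = list(
      solid_cuboid(90, 70, 18, x = 60, y = 40, category = "bread white"),
      solid_cylinder(32, 45, x = 40, y = -70, category = "milk coffee")
    )), "breakfast"),
    lunch_rice = tpl(scene_spec(solids = list(
      solid_spherical_cap(70, 35, x = 70, y = 30, category = "white rice"),
      solid_cuboid(80, 50, 25, x = -50, y = 80, category = "chicken breast")
    )), "lunch"),
    dinner_pasta = tpl(scene_spec(solids = list(
      solid_spherical_cap(75, 30, x = 60, y = 30, category = "spaghetti"),
      solid_spherical_cap(25, 22, x = -45, y = 90, category = "meatball"),
      solid_cylinder(30, 48, x = 30, y = -75, category = "water")
    )), "dinner"),
    dinner_steak = tpl(scene_spec(solids = list(
      solid_cuboid(90, 60, 35, x = 65, y = 25, category = "french fries"),
      solid_cuboid(85, 55, 22, x = -45, y = 85, category = "beef steak"),
      solid_cylinder(31, 46, x = 25, y = -80, category = "cola")
    )), "dinner"),
    snack_fruit = tpl(scene_spec(solids = list(
      solid_spherical_cap(40, 38, x = 45, y = 40, category = "apple"),
      solid_cuboid(60, 45, 35, x = -40, y = 75, category = "chocolate cake")
    )), "snack"),
    drink_juice = tpl(scene_spec(solids = list(
      solid_cylinder(31, 46, x = 50, y = 0, category = "orange juice")
    )), "drink")
  )
}

scene_truth_nutrients <- function(spec, table, secondary = NULL) {
  scene <- make_scene(spec)
  rows <- imap(scene$spec$solids, function(s, i) {
    rec <- nutrient_lookup(s$category, table, secondary)
    dplyr::bind_cols(tibble(fine_category = s$category,
                            volume_mL = scene$analytic_volume_mL[i]),
                     item_nutrition(scene$analytic_volume_mL[i], rec))
  })
  bind_rows(rows)
}

#' Generate a synthetic multi-participant study
#'
#' Emulates a one-day feasibility study: each participant eats
#' `meals_per_day` meals drawn from the scene catalogue; daily truth is the
#' sum of analytic-volume nutrient content over those meals; the "dietitian
#' recall" reference is the truth times multiplicative log-normal noise with
#' coefficient of variation `noise_cv` (drawn independently per participant
#' and nutrient, unit mean). Regenerating with the same seed is
#' bit-identical.
#'
#' @param n_participants Number of participants (>= 1).
#' @param meals_per_day Meals drawn per participant.
#' @param noise_cv Coefficient of variation of the recall noise (0 =
#'   perfect recall).
#' @param seed Integer seed.
#' @param catalogue Scene catalogue; defaults to
#'   [default_meal_catalogue()].
#' @param nutrient_table A `nutrient_table`; defaults to the bundled
#'   primary fixture.
#' @return A `synthetic_study`: `daily` (long tibble `participant_id`,
#'   `nutrient`, `truth`, `reference`), `meals` (tibble `participant_id`,
#'   `meal`, `template`, `meal_label`), `catalogue`, `seed`.
#' @export
generate_study <- function(n_participants, meals_per_day = 3,
                           noise_cv = 0.10, seed = 1L,
                           catalogue = default_meal_catalogue(),
                           nutrient_table = load_nutrient_table()) {
  stopifnot(n_participants >= 1, meals_per_day >= 1, noise_cv >= 0)
  if (length(catalogue) == 0) abort("meal catalogue is empty")
  truth_per_template <- map(catalogue, function(spec) {
    scene_truth_nutrients(spec, nutrient_table) |>
      summarise(across(c("kcal", "cho_g", "protein_g", "fat_g"), sum))
  })
  sigma <- sqrt(log(1 + noise_cv^2))
  withr::with_seed(as.integer(seed), {
    meals <- bind_rows(map(seq_len(n_participants), function(p) {
      draw <- sample(length(catalogue), meals_per_day, replace = TRUE)
      tibble(participant_id = sprintf("P%03d", p), meal = seq_len(meals_per_day),
             template = names(catalogue)[draw],
             meal_label = map_chr(catalogue[draw],
                                  ~attr(.x, "meal_label") %||% "lunch"))
    }))
    daily <- meals |>
      left_join(bind_rows(truth_per_template, .id = "template"),
                by = "template") |>
      group_by(.data$participant_id) |>
      summarise(across(c("kcal", "cho_g", "protein_g", "fat_g"), sum),
                .groups = "drop") |>
      tidyr::pivot_longer(c("kcal", "cho_g", "protein_g", "fat_g"),
                          names_to = "nutrient", values_to = "truth")
    noise <- if (noise_cv == 0) {
      rep(1, nrow(daily))
    } else {
      exp(rnorm(nrow(daily), mean = -sigma^2 / 2, sd = sigma))
    }
    daily$reference <- daily$truth * noise
  })
  structure(list(daily = daily, meals = meals, catalogue = catalogue,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants, %d meals, seed %d\n",
              dplyr::n_distinct(x$meals$participant_id), nrow(x$meals),
              x$seed))
  invisible(x)
}
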