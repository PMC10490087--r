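#' Process one meal capture into a meal report
#'
#' Binds the modules into the two pipeline variants. In `provider` mode the
#' depth map comes from any single-image depth provider (possibly in
#' arbitrary units) and is made metric through the card. In `stereo` mode
#' depth is computed from a two-view pair by rectification, block matching
#' and disparity conversion. Either way the chain continues: card detection
#' and pose, per-item volume with the height rules and the cup cap, the
#' top-5 user-selection rule when rankings are supplied, and nutrient
#' mapping with primary/secondary fallback. A missing card degrades every
#' item to its standard serving (with a structured log line), never an
#' error.
#'
#' @param intensity Intensity image of the reference view (card detection).
#' @param masks List of logical item masks in the reference view.
#' @param camera [camera_model()] of the reference view.
#' @param depth A [depth_map()] (provider mode).
#' @param stereo A list like [render_stereo()]'s output (stereo mode).
#' @param camera_b Second-view camera (stereo mode).
#' @param labels Character fine labels per item, or `NULL` when
#'   `predictions` are given.
#' @param predictions List of `prediction` rankings per item (then
#'   `gt_labels` drives the top-5 selection rule).
#' @param gt_labels Ground-truth labels for the selection rule.
#' @param packaged List of [packaged_product()]s consumed with this meal.
#' @param mode `"provider"` or `"stereo"`.
#' @param card A [card_spec()].
#' @param rules A [volume_rules()].
#' @param primary,secondary Nutrient tables.
#' @param meal_label Meal slot label.
#' @return A `meal_report` whose `items` carry per-item volume, weight,
#'   nutrients and provenance flags; totals are item sums.
#' @export
process_meal <- function(intensity, masks, camera,
                         depth = NULL, stereo = NULL, camera_b = NULL,
                         labels = NULL, predictions = NULL, gt_labels = NULL,
                         packaged = list(),
                         mode = c("provider", "stereo"),
                         card = card_spec(), rules = volume_rules(),
                         primary = load_nutrient_table(), secondary = NULL,
                         meal_label = "lunch") {
  mode <- arg_match(mode)
  if (mode == "provider" && is.null(depth) && length(masks) > 0) {
    abort("provider mode needs a depth map")
  }
  if (mode == "stereo" && length(masks) > 0) {
    if (is.null(stereo) || is.null(camera_b)) {
      abort("stereo mode needs the stereo pair and second camera")
    }
    depth <- stereo_depth_map(stereo, camera, camera_b, spec = card)
  }

  if (is.null(labels)) {
    stopifnot(!is.null(predictions), !is.null(gt_labels))
    labels <- map2_chr(predictions, gt_labels, top5_select)
  }
  stopifnot(length(labels) == length(masks))

  card_pose <- tryCatch({
    det <- detect_card(intensity)
    estimate_pose(det, card, camera)
  }, mealmetry_card_not_found = function(e) {
    log_event("card_missing", "reference card absent or undetected")
    NULL
  })

  aligned <- depth
  if (!is.null(card_pose) && !is.null(depth)) {
    card_px <- card_pixels(card_pose, card, camera, dim(depth$values))
    al <- tryCatch(metric_align(depth, card_pose, card_px),
                   mealmetry_alignment_impossible = function(e) NULL)
    if (is.null(al)) {
      log_event("card_missing", "no valid depth on card; treating card as undetected")
      card_pose <- NULL
    } else {
      aligned <- al$aligned
    }
  }

  items <- imap(masks, function(mask, i) {
    est <- estimate_item_volume(aligned, mask, card_pose, labels[[i]],
                                primary, rules, camera)
    if (est$capped) {
      log_event("capped", sprintf("item %d (%s) clipped to %.0f mL", i,
                                  labels[[i]], rules$cap_mL))
    }
    if (est$fallback_serving) {
      log_event("fallback_serving",
                sprintf("item %d (%s) used standard serving", i, labels[[i]]))
    }
    rec <- nutrient_lookup(labels[[i]], primary, secondary)
    if (rec$source == "secondary") {
      log_event("secondary_lookup",
                sprintf("item %d (%s) resolved from secondary table", i,
                        labels[[i]]))
    }
    dplyr::bind_cols(est, item_nutrition(est$volume_mL, rec),
                     tibble(source = rec$source))
  })
  pk <- map(packaged, function(p) {
    dplyr::bind_cols(
      tibble(fine_category = p$name %|% paste0("barcode:", p$barcode),
             volume_mL = NA_real_, card_found = NA, capped = FALSE,
             fallback_serving = FALSE, outliers_removed = NA_integer_),
      packaged_nutrition(p), tibble(source = "packaged"))
  })
  aggregate_meal(bind_rows(c(items, pk)), meal_label)
}

# rasterise the card quadrilateral predicted by the pose (for alignment)
card_pixels <- function(pose, spec, camera, dims) {
  W <- spec$width_mm; Hc <- spec$height_mm
  corners_card <- rbind(c(0, 0, 0), c(W, 0, 0), c(W, Hc, 0), c(0, Hc, 0))
  cc <- corners_card %*% t(pose$rotation) +
    matrix(pose$translation, 4, 3, byrow = TRUE)
  u <- camera$fx * cc[, 1] / cc[, 3] + camera$cx
  v <- camera$fy * cc[, 2] / cc[, 3] + camera$cy
  mask <- matrix(FALSE, dims[1], dims[2])
  U <- rep(0:(dims[2] - 1), each = dims[1])
  V <- rep(0:(dims[1] - 1), times = dims[2])
  mask[point_in_quad(U, V, cbind(u, v))] <- TRUE
  mask
}

# convex quadrilateral containment: point is inside when the edge cross
# products all share one sign
point_in_quad <- function(px, py, quad) {
  pos <- rep(TRUE, length(px)); neg <- rep(TRUE, length(px))
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[(i %% 4) + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    pos <- pos & cr >= 0
    neg <- neg & cr <= 0
  }
  pos | neg
}

log_event <- function(event, detail) {
  inform(sprintf("[mealmetry] event=%s %s", event, detail),
         class = "mealmetry_log")
}

#' Serialise a meal report to JSON
#'
#' Versioned schema; numbers are serialised with 6 significant digits so
#' reruns with the same seed produce byte-identical reports.
#'
#' @param report A `meal_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_meal_report <- function(report, path) {
  stopifnot(inherits(report, "meal_report"))
  sig <- function(df) {
    df |> mutate(across(dplyr::where(is.numeric), ~signif(.x, 6)))
  }
  jsonlite::write_json(
    list(schema = "mealmetry/report/v1",
         meal_label = report$meal_label,
         items = sig(report$items),
         totals = sig(report$totals)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Evaluate estimated against reference daily intakes
#'
#' Joins two per-participant tables of daily nutrient totals, then runs the
#' study-level statistics per nutrient: mean absolute percentage error and
#' Bland-Altman agreement.
#'
#' @param estimates,reference Tibbles with columns `participant_id`,
#'   `kcal`, `cho_g`, `protein_g`, `fat_g`.
#' @return A `daily_evaluation`: `mape` (tibble), `agreement` (named list
#'   of `bland_altman`), `days` (the long-form joined data).
#' @export
evaluate_daily <- function(estimates, reference) {
  estimates <- as_tibble(estimates); reference <- as_tibble(reference)
  orphans <- c(setdiff(estimates$participant_id, reference$participant_id),
               setdiff(reference$participant_id, estimates$participant_id))
  if (length(orphans) > 0) {
    abort(sprintf("participants present in only one file: %s",
                  paste(unique(orphans), collapse = ", ")))
  }
  long <- function(df, what) {
    tidyr::pivot_longer(df, c("kcal", "cho_g", "protein_g", "fat_g"),
                        names_to = "nutrient", values_to = what)
  }
  days <- left_join(long(estimates, "estimated"), long(reference, "reference"),
                    by = c("participant_id", "nutrient"))
  ba <- map(setNames(nm = unique(days$nutrient)),
            ~bland_altman(days, .x))
  structure(list(mape = mape(days), agreement = ba, days = days),
            class = "daily_evaluation")
}

#' @export
print.daily_evaluation <- function(x, ...) {
  cat("<daily_evaluation>\n")
  print(x$mape)
  invisible(x)
}

#' @export
tidy.daily_evaluation <- function(x, ...) x$mape

#' @export
glance.daily_evaluation <- function(x, ...) {
  bind_rows(map(x$agreement, glance))
}

#' Write the demo fixture set
#'
#' Emits everything needed to replay the pipeline from disk: a demo scene
#' (depth raster + sidecar, masks, intensity, scene JSON), the taxonomy and
#' nutrient tables, a synthetic study (estimated and reference daily CSVs),
#' and a manifest. Fully seeded; reruns are byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_participants Study size.
#' @return Character vector of written files (the manifest), invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1L, n_participants = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) abort(sprintf("cannot write to '%s'", dir))
  out <- character(0)
  put <- function(p) { out <<- c(out, p); p }

  catalogue <- default_meal_catalogue()
  spec <- catalogue$dinner_pasta
  scene <- make_scene(spec)
  cam <- camera_at(distance_mm = 400, elevation_deg = 90)
  r <- render_depth(scene, cam)
  write_depth(r$depth, put(file.path(dir, "demo_depth.tif")), camera = cam)
  put(file.path(dir, "demo_depth.tif.json"))
  write_mask(r$index, put(file.path(dir, "demo_masks.tif")))
  tiff::writeTIFF(r$intensity, put(file.path(dir, "demo_intensity.tif")),
                  bits.per.sample = 16)
  jsonlite::write_json(
    list(schema = "mealmetry/scene/v1",
         card_pose = spec$card_pose, card_size = spec$card_size,
         table_extent = spec$table_extent,
         labels = map_chr(spec$solids, "category"),
         analytic_volume_mL = scene$analytic_volume_mL,
         card_corners_px = unname(r$card_corners_px)),
    put(file.path(dir, "demo_scene.json")), auto_unbox = TRUE, digits = NA)

  file.copy(system.file("extdata", "taxonomy_mini.tsv", package = "mealmetry"),
            put(file.path(dir, "taxonomy.tsv")), overwrite = TRUE)
  file.copy(system.file("extdata", "nutrients_primary.csv",
                        package = "mealmetry"),
            put(file.path(dir, "nutrients_primary.csv")), overwrite = TRUE)
  file.copy(system.file("extdata", "nutrients_secondary.csv",
                        package = "mealmetry"),
            put(file.path(dir, "nutrients_secondary.csv")), overwrite = TRUE)

  study <- generate_study(n_participants, seed = seed)
  wide <- function(col) {
    study$daily |>
      select("participant_id", "nutrient", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "nutrient",
                         values_from = dplyr::all_of(col))
  }
  readr::write_csv(wide("truth"), put(file.path(dir, "study_estimated.csv")))
  readr::write_csv(wide("reference"), put(file.path(dir, "study_reference.csv")))

  manifest <- file.path(dir, "MANIFEST")
  writeLines(sort(basename(out)), manifest)
  invisible(c(out, manifest))
}

#' Read a pipeline configuration file
#'
#' YAML configuration binding the pieces for the command-line interface:
#' card size, volume-rule constants, nutrient table paths, depth back-end
#' selection and seed. Missing fields take package defaults.
#'
#' @param path YAML file.
#' @return A list: `card` ([card_spec()]), `rules` ([volume_rules()]),
#'   `backend`, `seed`, `primary_table`, `secondary_table`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  backend <- cfg$backend %||% "provider"
  if (!backend %in% c("provider", "stereo")) {
    abort(sprintf("unknown depth back-end '%s'", backend))
  }
  vr <- cfg$volume %||% list()
  primary <- cfg$primary_table %||%
    system.file("extdata", "nutrients_primary.csv", package = "mealmetry")
  secondary <- cfg$secondary_table %||%
    system.file("extdata", "nutrients_secondary.csv", package = "mealmetry")
  for (p in c(primary, secondary)) {
    if (!file.exists(p)) abort(sprintf("configured file does not exist: %s", p))
  }
  list(
    card = card_spec(cfg$card$width_mm %||% 85.6,
                     cfg$card$height_mm %||% 54.0),
    rules = volume_rules(
      bottom_tol_mm = vr$bottom_tol_mm %||% 5,
      top_max_mm = vr$top_max_mm %||% 50,
      cup_mL = vr$cup_mL %||% 240,
      max_cups = vr$max_cups %||% 2.5,
      grid_cell_mm = vr$grid_cell_mm %||% 2),
    backend = backend,
    seed = cfg$seed %||% 1L,
    primary_table = primary,
    secondary_table = secondary
  )
}
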