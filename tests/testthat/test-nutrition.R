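test_that("the bundled nutrient tables load and malformed tables are
          rejected with the offending line", {
  tab <- load_nutrient_table()
  expect_s3_class(tab, "nutrient_table")
  expect_identical(nrow(tab), 20L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "fine_category,density_g_per_mL,kcal_per_100g,cho_g_per_100g,protein_g_per_100g,fat_g_per_100g,serving_volume_mL",
    "water,1.0,0,0,0,0,250",
    "void,0,10,1,1,1,100"), bad)
  expect_error(load_nutrient_table(bad), "line 3")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "fine_category,density_g_per_mL,kcal_per_100g,cho_g_per_100g,protein_g_per_100g,fat_g_per_100g,serving_volume_mL",
    "water,1.0,0,0,0,0,250",
    "water,1.0,0,0,0,0,200"), dup)
  expect_error(load_nutrient_table(dup), "duplicate")
})

test_that("lookup prefers the primary table and flags secondary fallback", {
  prim <- load_nutrient_table()
  sec <- secondary_table()
  rice <- nutrient_lookup("white rice", prim, sec)
  expect_identical(rice$source, "primary")
  expect_equal(rice$kcal_per_100g, 130)   # not the secondary 135
  pie <- nutrient_lookup("apple pie", prim, sec)
  expect_identical(pie$source, "secondary")
  expect_error(nutrient_lookup("unicorn stew", prim, sec),
               class = "mealmetry_missing_nutrient")
})

test_that("50 g of olive oil maps to 400 kcal and 45 g of fat", {
  rec <- nutrient_lookup("olive oil", load_nutrient_table())
  vol <- 50 / rec$density_g_per_mL
  nut <- item_nutrition(vol, rec)
  expect_equal(nut$weight_g, 50)
  expect_equal(nut$kcal, 400)
  expect_equal(nut$fat_g, 45)
})

test_that("zero volume and zero-energy drinks behave", {
  rec <- nutrient_lookup("olive oil", load_nutrient_table())
  z <- item_nutrition(0, rec)
  expect_true(all(as.numeric(z) == 0))
  water <- nutrient_lookup("water", load_nutrient_table())
  nut <- item_nutrition(200, water)
  expect_equal(nut$weight_g, 200)
  expect_equal(nut$kcal, 0)
})

test_that("fixture records are Atwater-consistent within 15%", {
  tab <- load_nutrient_table()
  on <- tab$kcal_per_100g > 0
  atwater <- 4 * tab$cho_g_per_100g + 4 * tab$protein_g_per_100g +
    9 * tab$fat_g_per_100g
  rel <- abs(tab$kcal_per_100g - atwater) / tab$kcal_per_100g
  expect_true(all(rel[on] < 0.15))
})

test_that("EAN-13 checksums gate packaged products", {
  expect_true(ean13_valid("4006381333931"))
  expect_false(ean13_valid("4006381333932"))
  expect_false(ean13_valid("40063813339"))
  p <- packaged_product("4006381333931", kcal = 250, cho_g = 30,
                        protein_g = 5, fat_g = 10, fraction_consumed = 0.5)
  nut <- packaged_nutrition(p)
  expect_equal(nut$kcal, 125)
  expect_equal(nut$fat_g, 5)
  full <- packaged_product("4006381333931", 250, 30, 5, 10, 1)
  expect_equal(packaged_nutrition(full)$kcal, 250)
  expect_error(packaged_product("4006381333932", 250, 30, 5, 10, 0.5),
               class = "mealmetry_invalid_barcode")
  expect_error(packaged_product("4006381333931", 250, 30, 5, 10, 0))
  expect_error(packaged_product("4006381333931", 250, 30, 5, 10, 1.2))
})

test_that("meal and day aggregation conserve nutrients under regrouping", {
  items <- tibble::tibble(
    fine_category = c("white rice", "meatball", "water"),
    kcal = c(200, 150, 0), cho_g = c(43, 4, 0),
    protein_g = c(4, 10, 0), fat_g = c(0.5, 10, 0))
  meal <- aggregate_meal(items, "lunch")
  expect_equal(meal$totals$kcal, 350)
  expect_equal(meal$totals$protein_g, 14)

  empty <- aggregate_meal(items[0, ], "snack")
  expect_true(all(as.numeric(empty$totals) == 0))

  perm <- aggregate_meal(items[c(3, 1, 2), ], "lunch")
  expect_equal(perm$totals, meal$totals)

  # regrouping items over meals leaves day totals bit-identical
  day_a <- aggregate_day(list(aggregate_meal(items[1, ], "breakfast"),
                              aggregate_meal(items[2:3, ], "dinner")))
  day_b <- aggregate_day(list(aggregate_meal(items, "lunch")))
  expect_equal(day_a, day_b, tolerance = 1e-12)
})

test_that("nutrient totals are exactly homogeneous in volume", {
  tab <- load_nutrient_table()
  vols <- c(120, 80, 250)
  cats <- c("white rice", "meatball", "orange juice")
  nut1 <- dplyr::bind_rows(lapply(seq_along(cats), function(i) {
    item_nutrition(vols[i], nutrient_lookup(cats[i], tab))
  }))
  nut3 <- dplyr::bind_rows(lapply(seq_along(cats), function(i) {
    item_nutrition(3 * vols[i], nutrient_lookup(cats[i], tab))
  }))
  expect_equal(colSums(nut3[, c("kcal", "cho_g", "protein_g", "fat_g")]),
               3 * colSums(nut1[, c("kcal", "cho_g", "protein_g", "fat_g")]))
})
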