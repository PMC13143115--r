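targets <- fixture_targets()
map <- fixture_map(targets)

test_that("sugar wins over calorie; hierarchy sets at most one of the two", {
  # a dessert matching both a sugar and a calorie rule keeps only sugar
  both_map <- category_map(tibble::tibble(
    programme = c("sugar", "calorie"),
    category_name = c("Desserts", "Mains"),
    subcategory = c("Desserts", "Desserts")), targets)
  dessert <- complete_items(make_items(
    item_row(subcategory = "Desserts", sugar_100g = 20, kcal_serv = 300,
             salt_serv = 0.2, serving_size = 100)))
  a <- assign_targets(dessert, both_map, targets)
  expect_equal(a$sugar_target, "sugar_desserts")
  expect_true(is.na(a$calorie_target))

  salad <- complete_items(make_items(
    item_row(subcategory = "Salads", kcal_serv = 200, serving_size = 250)))
  a <- assign_targets(salad, map, targets)
  expect_true(is.na(a$sugar_target))
  expect_equal(a$calorie_target, "calorie_mains")

  # sauces match no sugar/calorie rule in this map
  sauce <- complete_items(make_items(
    item_row(subcategory = "Sauces", salt_100g = 2, kcal_100g = 300)))
  a <- assign_targets(sauce, map, targets)
  expect_true(is.na(a$sugar_target) && is.na(a$calorie_target))
})

test_that("salt assignment tries OOH first, then retailer/manufacturer", {
  burger <- complete_items(make_items(
    item_row(subcategory = "Burgers", salt_serv = 1.0, kcal_serv = 400,
             serving_size = 200)))
  a <- assign_targets(burger, map, targets)
  expect_equal(a$salt_sector, "ooh")
  expect_equal(a$salt_target, "saltooh_mains")

  sauce <- complete_items(make_items(
    item_row(subcategory = "Sauces", salt_100g = 2)))
  a <- assign_targets(sauce, map, targets)
  expect_equal(a$salt_sector, "rm")

  # an item matching rules in both sectors goes OOH
  dual_targets <- validate_target_table(dplyr::bind_rows(
    fixture_targets(),
    tibble::tibble(target_id = "saltrm_mains", programme = "salt_rm",
                   category_name = "MainsRM", nutrient = "salt",
                   basis = "per100g", value = 1.0, value_kind = "average")))
  dual_map <- category_map(dplyr::bind_rows(
    fixture_map(),
    tibble::tibble(programme = "salt_rm", category_name = "MainsRM",
                   subcategory = "Burgers", label = NA_character_)),
    dual_targets)
  a <- assign_targets(burger, dual_map, dual_targets)
  expect_equal(a$salt_sector, "ooh")
})

test_that("pizza serving counts follow declared, style, label, diameter", {
  items <- make_items(
    item_row(item_name = "declared", subcategory = "Pizzas",
             pizza_style = "takeaway", pizza_size_label = "medium",
             declared_servings = 2, kcal_serv = 2000, serving_size = 800),
    item_row(item_name = "italian", subcategory = "Pizzas",
             pizza_style = "italian", kcal_serv = 900, serving_size = 400),
    item_row(item_name = "large", subcategory = "Pizzas",
             pizza_style = "takeaway", pizza_size_label = "large",
             kcal_serv = 2400, serving_size = 900),
    item_row(item_name = "xl", subcategory = "Pizzas",
             pizza_style = "takeaway", pizza_size_label = "extra-large",
             kcal_serv = 3000, serving_size = 1100),
    item_row(item_name = "diam", subcategory = "Pizzas",
             pizza_style = "takeaway", pizza_diameter = 13.8,
             kcal_serv = 2400, serving_size = 900),
    item_row(item_name = "unknown", subcategory = "Pizzas",
             pizza_style = "takeaway", kcal_serv = 2400,
             serving_size = 900),
    item_row(item_name = "burger", subcategory = "Burgers",
             kcal_serv = 500, serving_size = 250))
  s <- pizza_servings(items)
  expect_equal(s, c(2, 1, 3, 4, 3, NA, 1))
})

test_that("sharing pizzas are large-and-above or 11.5 inches and above", {
  items <- make_items(
    item_row(item_name = "a", subcategory = "Pizzas",
             pizza_size_label = "large"),
    item_row(item_name = "b", subcategory = "Pizzas", pizza_diameter = 11.5),
    item_row(item_name = "c", subcategory = "Pizzas", pizza_diameter = 11.4,
             pizza_size_label = "medium"),
    item_row(item_name = "d", subcategory = "Burgers"))
  expect_equal(is_sharing_pizza(items), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("unassignable pizzas leave the calorie denominator only", {
  pz_targets <- validate_target_table(tibble::tibble(
    target_id = c("calorie_pizzas", "saltooh_pizzas"),
    programme = c("calorie", "salt_ooh"),
    category_name = "Pizzas", nutrient = c("kcal", "salt"),
    basis = c("per_serving", "per_serving"), value = c(600, 1.8),
    value_kind = "average"))
  pz_map <- category_map(tibble::tibble(
    programme = c("calorie", "salt_ooh"), category_name = "Pizzas",
    subcategory = "Pizzas"), pz_targets)
  items <- complete_items(make_items(
    item_row(subcategory = "Pizzas", pizza_style = "takeaway",
             kcal_serv = 2000, salt_serv = 1.0, serving_size = 800)))
  a <- assign_targets(items, pz_map, pz_targets)
  expect_true(a$calorie_unassignable)
  expect_true(is.na(a$calorie_target))
  expect_equal(a$salt_target, "saltooh_pizzas")
  rec <- evaluate_adherence(items, a, pz_targets)
  expect_false(rec$calorie_eligible)
  expect_true(rec$salt_eligible)
  expect_match(rec$audit, "unassignable")
})

test_that("all four eligibility states arise and are mutually consistent", {
  items <- complete_items(make_items(
    item_row(item_name = "none", subcategory = "Breakfast Items",
             kcal_100g = 100),
    item_row(item_name = "cal_only", subcategory = "Salads",
             kcal_serv = 300, serving_size = 300),
    item_row(item_name = "salt_cal", subcategory = "Burgers",
             kcal_serv = 400, salt_serv = 1.2, serving_size = 200),
    item_row(item_name = "salt_sugar", subcategory = "Desserts",
             sugar_100g = 25, salt_100g = 0.4, kcal_100g = 350),
    item_row(item_name = "salt_only", subcategory = "Sauces",
             salt_100g = 2.5),
    item_row(item_name = "sugar_only", subcategory = "Desserts",
             sugar_100g = 10)))
  salt_rm_desserts <- tibble::tibble(
    target_id = "saltrm_desserts", programme = "salt_rm",
    category_name = "DessertsRM", nutrient = "salt", basis = "per100g",
    value = 0.5, value_kind = "average")
  tt <- validate_target_table(dplyr::bind_rows(fixture_targets(),
                                               salt_rm_desserts))
  mm <- category_map(dplyr::bind_rows(
    fixture_map(),
    tibble::tibble(programme = "salt_rm", category_name = "DessertsRM",
                   subcategory = "Desserts", label = NA_character_)), tt)
  a <- assign_targets(items, mm, tt)
  rec <- evaluate_adherence(items, a, tt)
  # the dessert with no salt value is salt-ineligible: sugar-only state
  states <- c("none", "one_programme", "salt_and_calorie", "salt_and_sugar",
              "one_programme", "salt_and_sugar")
  expect_equal(a$eligibility_state, states)
  expect_false(rec$salt_eligible[6])
  expect_true(rec$sugar_eligible[6])

  # partition property: sugar and calorie are never both present
  expect_false(any(!is.na(a$sugar_target) & !is.na(a$calorie_target)))
})

test_that("an empty target table leaves every item unassigned", {
  items <- complete_items(make_items(
    item_row(subcategory = "Burgers", kcal_serv = 400, serving_size = 200)))
  empty <- validate_target_table(fixture_targets()[0, ])
  a <- assign_targets(items, fixture_map()[0, ], empty)
  expect_equal(a$eligibility_state, "none")
})

test_that("config lint catches orphan rules, shadowing, and map gaps", {
  bad_map <- tibble::tibble(programme = "sugar", category_name = "Nope",
                            subcategory = "Desserts")
  expect_error(category_map(bad_map, targets), "unknown target category")

  v <- lint_config(targets, bad_map)
  expect_true(any(v$kind == "category_map"))

  shadowed <- dplyr::bind_rows(fixture_map(), fixture_map()[1, ])
  v <- lint_config(targets, shadowed)
  expect_true(any(grepl("shadowed", v$detail)))

  items <- make_items(item_row(restaurant = "R9", kcal_100g = 1))
  v <- lint_config(targets, fixture_map(), fixture_groups(), items)
  expect_true(any(grepl("R9", v$detail)))

  v <- lint_config(targets, fixture_map(), fixture_groups(),
                   make_items(item_row(restaurant = "R1", kcal_100g = 1)))
  expect_equal(nrow(v), 0)
})
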