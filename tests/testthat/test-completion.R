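test_that("energy completion applies the kJ/kcal conversion exactly", {
  items <- make_items(item_row(kj_100g = 4184))
  out <- complete_energy(items, "100g")
  expect_identical(out$kcal_100g, 4184 / 4.184)
  expect_equal(out$kcal_100g, 1000)
  expect_equal(out$src_kcal_100g, "derived")

  items <- make_items(item_row(kcal_serv = 250))
  out <- complete_energy(items, "serv")
  expect_identical(out$kj_serv, 250 * 4.184)
})

test_that("macro-energy rule is a fallback that never overrides kJ", {
  items <- make_items(item_row(protein_100g = 10, fat_100g = 5,
                               carb_100g = 20))
  out <- complete_energy(items, "100g")
  expect_identical(out$kcal_100g, 4 * 10 + 9 * 5 + 3.75 * 20)
  expect_equal(out$kcal_100g, 160)

  # kJ present: the unit conversion wins over the macro rule
  items <- make_items(item_row(kj_100g = 4184, protein_100g = 10,
                               fat_100g = 5, carb_100g = 20))
  out <- complete_energy(items, "100g")
  expect_equal(out$kcal_100g, 1000)
})

test_that("reported energy values are never overwritten", {
  items <- make_items(item_row(kcal_100g = 300, kj_100g = 1100))
  out <- complete_items(items)
  expect_equal(out$kcal_100g, 300)
  expect_equal(out$kj_100g, 1100)
  expect_equal(out$src_kcal_100g, "reported")
})

test_that("salt/sodium completion applies the printed conversion exactly", {
  items <- make_items(item_row(salt_100g = 2.5))
  out <- complete_salt_sodium(items, "100g")
  expect_identical(out$sodium_100g, 2.5 * 1000 / 2.5)
  expect_equal(out$sodium_100g, 1000)

  items <- make_items(item_row(sodium_serv = 400))
  out <- complete_salt_sodium(items, "serv")
  expect_identical(out$salt_serv, 400 * 2.5 / 1000)
  expect_equal(out$salt_serv, 1.0)

  items <- make_items(item_row(salt_100g = 0))
  out <- complete_salt_sodium(items, "100g")
  expect_equal(out$sodium_100g, 0)
})

test_that("basis scaling and serving-size derivation follow the formulas", {
  items <- make_items(item_row(salt_serv = 2.0, serving_size = 250))
  out <- complete_items(items)
  expect_equal(out$salt_100g, 2.0 / 2.5)
  expect_equal(out$src_salt_100g, "derived")

  items <- make_items(item_row(kcal_100g = 200, kcal_serv = 450))
  out <- complete_items(items)
  expect_identical(out$serving_size, 100 * 450 / 200)
  expect_equal(out$serving_size, 225)
  expect_equal(out$src_serving_size, "derived")
})

test_that("serving-size derivation uses the kcal-first priority order", {
  # kcal implies 225 g; salt implies 250 g: kcal wins
  items <- make_items(item_row(kcal_100g = 200, kcal_serv = 450,
                               salt_100g = 1, salt_serv = 2.5))
  out <- suppressWarnings(complete_items(items))
  expect_equal(out$serving_size, 225)
})

test_that("cross-basis disagreement >5% warns and keeps reported values", {
  items <- make_items(item_row(kcal_100g = 200, kcal_serv = 500,
                               salt_100g = 1, salt_serv = 1.0,
                               serving_size = 250))
  # salt on both bases implies 2.5 g per serving but reports 1.0: >5% off
  expect_warning(out <- complete_items(items), "salt")
  expect_equal(out$salt_serv, 1.0)
  expect_equal(out$salt_100g, 1)
})

test_that("items with all three nutrients of interest underivable are excluded", {
  unusable1 <- item_row(item_name = "u1", fibre_100g = 2, protein_100g = 10)
  kept_kj <- item_row(item_name = "k1", kj_serv = 1000)
  res <- exclude_unusable(make_items(unusable1, kept_kj))
  expect_equal(nrow(res$items), 1)
  expect_equal(res$items$item_name, "k1")
  expect_equal(res$report$n_excluded_all_missing, 1)

  # macro panel counts as kcal-derivable
  macro <- make_items(item_row(protein_100g = 5, fat_100g = 5, carb_100g = 5))
  expect_equal(nrow(exclude_unusable(macro)$items), 1)

  rows <- c(lapply(1:8, function(i) item_row(item_name = paste0("ok", i),
                                             kcal_100g = 100 + i)),
            lapply(1:2, function(i) item_row(item_name = paste0("bad", i),
                                             fibre_100g = 1)))
  res <- exclude_unusable(do.call(make_items, rows))
  expect_equal(nrow(res$items), 8)
  expect_equal(res$report$n_excluded_all_missing, 2)
})

test_that("serving statistics use reported/derived sizes and type-7 quartiles", {
  items <- make_items(
    item_row(item_name = "a", serving_size = 100, kcal_100g = 1),
    item_row(item_name = "b", serving_size = 200, kcal_100g = 1),
    item_row(item_name = "c", serving_size = 300, kcal_100g = 1))
  st <- serving_stats(items)
  expect_equal(st$mean, 200)
  expect_equal(st$median, 200)

  items <- make_items(
    item_row(item_name = "a", serving_size = 100, kcal_100g = 1),
    item_row(item_name = "b", serving_size = 100, kcal_100g = 1),
    item_row(item_name = "c", serving_size = 400, kcal_100g = 1))
  st <- serving_stats(items)
  expect_equal(st$mean, 200)
  expect_equal(st$median, 100)

  items <- make_items(
    item_row(item_name = "a", serving_size = 10, kcal_100g = 1),
    item_row(item_name = "b", serving_size = 20, kcal_100g = 1),
    item_row(item_name = "c", serving_size = 30, kcal_100g = 1),
    item_row(item_name = "d", serving_size = 40, kcal_100g = 1))
  st <- serving_stats(items)
  expect_equal(st$lq, 17.5)
  expect_equal(st$uq, 32.5)

  # imputed sizes never feed back into the statistics
  items <- make_items(
    item_row(item_name = "a", serving_size = 100, kcal_100g = 2),
    item_row(item_name = "b", serving_size = 300, kcal_100g = 2),
    item_row(item_name = "c", kcal_100g = 2))
  imp <- impute_serving_size(items, "mean")
  expect_equal(serving_stats(imp)$n_known, 2)
  expect_equal(serving_stats(imp)$mean, 200)
})

test_that("serving-size imputation fills only missing sizes and re-scales", {
  items <- make_items(
    item_row(item_name = "a", serving_size = 100, kcal_100g = 2),
    item_row(item_name = "b", serving_size = 200, kcal_100g = 2),
    item_row(item_name = "c", kcal_100g = 2))
  out <- impute_serving_size(items, "mean")
  expect_equal(out$serving_size[3], 150)
  expect_equal(out$src_serving_size[3], "subcategory_imputed")
  expect_equal(out$kcal_serv[3], 2 * 150 / 100)
  expect_equal(out$serving_size[1:2], c(100, 200))
  expect_equal(out$src_serving_size[1:2], c("reported", "reported"))

  for (s in c("mean", "lq", "uq")) {
    out <- impute_serving_size(items, s)
    expect_equal(out$serving_size[1:2], c(100, 200))
  }
})

test_that("switching imputation strategy only moves values through imputed sizes", {
  items <- make_items(
    item_row(item_name = "a", subcategory = "Salads", serving_size = 100,
             kcal_100g = 2),
    item_row(item_name = "b", subcategory = "Salads", serving_size = 300,
             kcal_100g = 2),
    item_row(item_name = "c", subcategory = "Salads", kcal_100g = 2),
    item_row(item_name = "d", subcategory = "Salads", kcal_serv = 6))
  st <- serving_stats(complete_items(items))
  mean_run <- impute_serving_size(complete_items(items), "mean", st)
  uq_run <- impute_serving_size(complete_items(items), "uq", st)
  # per-serving changes only for the per-100g-only item c
  expect_equal(mean_run$kcal_serv[1:2], uq_run$kcal_serv[1:2])
  expect_false(mean_run$kcal_serv[3] == uq_run$kcal_serv[3])
  # per-100g changes only for the per-serving-only item d
  expect_equal(mean_run$kcal_100g[1:3], uq_run$kcal_100g[1:3])
  expect_false(mean_run$kcal_100g[4] == uq_run$kcal_100g[4])
})

test_that("completion is idempotent and never touches reported values", {
  for (seed in c(1, 2, 3)) {
    items <- random_fixture(seed)
    once <- complete_items(items)
    twice <- complete_items(once)
    expect_identical(once, twice)
    # monotone missingness: no reported value changed, none deleted
    for (col in c(paste0(nutrient_fields(), "_100g"),
                  paste0(nutrient_fields(), "_serv"), "serving_size")) {
      was_reported <- !is.na(items[[col]])
      expect_identical(once[[col]][was_reported], items[[col]][was_reported])
      expect_false(any(is.na(once[[col]]) & !is.na(items[[col]])))
    }
  }
})

test_that("completion satisfies unit-pair and round-trip invariants", {
  items <- complete_items(random_fixture(7))
  rel_ok <- function(a, b) {
    i <- !is.na(a) & !is.na(b) & b != 0
    all(abs(a[i] - b[i]) / abs(b[i]) < 1e-6)
  }
  expect_true(rel_ok(items$kj_100g, items$kcal_100g * 4.184))
  expect_true(rel_ok(items$kj_serv, items$kcal_serv * 4.184))
  expect_true(rel_ok(items$sodium_100g, items$salt_100g * 400))
  expect_true(rel_ok(items$sodium_serv, items$salt_serv * 400))
  for (nut in nutrient_fields()) {
    g <- items[[paste0(nut, "_100g")]]
    s <- items[[paste0(nut, "_serv")]]
    i <- !is.na(g) & !is.na(s) & !is.na(items$serving_size) & g > 0 &
      items$src_serving_size %in% c("reported", "derived")
    expect_true(rel_ok(s[i], g[i] * items$serving_size[i] / 100))
  }
})

test_that("the engine matches a straight-line per-item completion oracle", {
  vals <- c(paste0(nutrient_fields(), "_100g"),
            paste0(nutrient_fields(), "_serv"), "serving_size")
  for (seed in c(11, 12, 13)) {
    items <- random_fixture(seed, n = 20)
    engine <- complete_items(items)
    oracle <- oracle_complete(items)
    for (col in vals) {
      expect_identical(engine[[col]], oracle[[col]],
                       label = paste("column", col, "seed", seed))
    }
  }
})
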