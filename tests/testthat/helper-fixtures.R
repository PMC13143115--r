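# Fixture builders and independent straight-line oracles. The oracles are
# deliberately naive per-item loops, written without reference to the
# engine's vectorised code paths.

item_row <- function(restaurant = "R1", item_name = "item", subcategory = "Burgers",
                     ...) {
  tibble::tibble(restaurant = restaurant, item_name = item_name,
                 subcategory = subcategory, ...)
}

make_items <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) {
    if (!"item_name" %in% names(rows[[i]]) || rows[[i]]$item_name == "item") {
      rows[[i]]$item_name <- paste0("item", i)
    }
  }
  as_menu_table(dplyr::bind_rows(rows))
}

# --- completion oracle: repeated per-item rule application until stable ----

oracle_complete_one <- function(it) {
  repeat {
    before <- it
    for (b in c("_100g", "_serv")) {
      kcal <- paste0("kcal", b); kj <- paste0("kj", b)
      if (is.na(it[[kcal]]) && !is.na(it[[kj]])) it[[kcal]] <- it[[kj]] / 4.184
      if (is.na(it[[kj]]) && !is.na(it[[kcal]])) it[[kj]] <- it[[kcal]] * 4.184
      p <- it[[paste0("protein", b)]]; fa <- it[[paste0("fat", b)]]
      cb <- it[[paste0("carb", b)]]
      if (is.na(it[[kcal]]) && !is.na(p) && !is.na(fa) && !is.na(cb)) {
        it[[kcal]] <- 4 * p + 9 * fa + 3.75 * cb
        it[[kj]] <- it[[kcal]] * 4.184
      }
      salt <- paste0("salt", b); sodium <- paste0("sodium", b)
      if (is.na(it[[sodium]]) && !is.na(it[[salt]])) {
        it[[sodium]] <- it[[salt]] * 1000 / 2.5
      }
      if (is.na(it[[salt]]) && !is.na(it[[sodium]])) {
        it[[salt]] <- it[[sodium]] * 2.5 / 1000
      }
    }
    if (is.na(it$serving_size)) {
      for (nut in c("kcal", "salt", "sugar", "carb", "fat", "protein")) {
        g <- it[[paste0(nut, "_100g")]]; s <- it[[paste0(nut, "_serv")]]
        if (!is.na(g) && !is.na(s) && g > 0) {
          it$serving_size <- 100 * s / g
          break
        }
      }
    }
    if (!is.na(it$serving_size)) {
      for (nut in menutargets::nutrient_fields()) {
        g <- paste0(nut, "_100g"); s <- paste0(nut, "_serv")
        if (is.na(it[[s]]) && !is.na(it[[g]])) {
          it[[s]] <- it[[g]] * (it$serving_size / 100)
        }
        if (is.na(it[[g]]) && !is.na(it[[s]])) {
          it[[g]] <- it[[s]] / (it$serving_size / 100)
        }
      }
    }
    if (identical(it, before)) return(it)
  }
}

oracle_complete <- function(items) {
  vals <- c(paste0(menutargets::nutrient_fields(), "_100g"),
            paste0(menutargets::nutrient_fields(), "_serv"), "serving_size")
  for (i in seq_len(nrow(items))) {
    done <- oracle_complete_one(items[i, vals])
    for (col in vals) items[[col]][i] <- done[[col]]
  }
  items
}

# --- adherence counting oracle: plain loops over records ------------------

oracle_adherence_counts <- function(records) {
  out <- list()
  for (p in c("sugar", "salt", "calorie")) {
    elig <- met <- 0L
    for (i in seq_len(nrow(records))) {
      if (isTRUE(records[[paste0(p, "_eligible")]][i])) {
        elig <- elig + 1L
        if (isTRUE(records[[paste0(p, "_met")]][i])) met <- met + 1L
      }
    }
    out[[p]] <- c(n_eligible = elig, n_met = met)
  }
  elig <- met <- 0L
  for (i in seq_len(nrow(records))) {
    progs <- c("sugar", "salt", "calorie")
    e <- vapply(progs, function(p) isTRUE(records[[paste0(p, "_eligible")]][i]),
                logical(1))
    if (any(e)) {
      elig <- elig + 1L
      ok <- TRUE
      for (p in progs[e]) if (!isTRUE(records[[paste0(p, "_met")]][i])) ok <- FALSE
      if (ok) met <- met + 1L
    }
  }
  out$all_applicable <- c(n_eligible = elig, n_met = met)
  out
}

# --- summary oracle: first-principles mean/median/sd ----------------------

oracle_summary <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  sv <- sort(v)
  med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  s <- if (n < 2) 0 else sqrt(sum((v - m)^2) / (n - 1))
  c(n = n, mean = m, median = med, sd = s)
}

# elementwise equality that treats NA == NA as equal
identical_na <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

# a small randomised completed corpus with one target per programme
random_fixture <- function(seed, n = 20) {
  set.seed(seed)
  subs <- c("Burgers", "Desserts", "Salads", "Sauces")
  rows <- lapply(seq_len(n), function(i) {
    sub <- sample(subs, 1)
    r <- item_row(restaurant = sample(c("R1", "R2"), 1),
                  item_name = paste0("it", i), subcategory = sub)
    # random single- or dual-basis reporting
    mode <- sample(c("both", "g100", "serv"), 1)
    ss <- round(runif(1, 80, 400), 1)
    kcal <- round(runif(1, 80, 400), 2)
    salt <- round(runif(1, 0.1, 3), 3)
    sugar <- round(runif(1, 0.5, 40), 2)
    fat <- round(runif(1, 1, 25), 2)
    if (mode %in% c("both", "g100")) {
      r$kcal_100g <- kcal; r$salt_100g <- salt; r$sugar_100g <- sugar
      r$fat_100g <- fat
    }
    if (mode %in% c("both", "serv")) {
      r$kcal_serv <- kcal * ss / 100; r$salt_serv <- salt * ss / 100
      r$sugar_serv <- sugar * ss / 100; r$fat_serv <- fat * ss / 100
    }
    if (mode == "both" || runif(1) < 0.6) r$serving_size <- ss
    r
  })
  as_menu_table(dplyr::bind_rows(rows))
}

fixture_targets <- function() {
  validate_target_table(tibble::tibble(
    target_id = c("sugar_desserts", "calorie_mains", "saltooh_mains",
                  "saltrm_sauces"),
    programme = c("sugar", "calorie", "salt_ooh", "salt_rm"),
    category_name = c("Desserts", "Mains", "Mains", "Sauces"),
    nutrient = c("sugar", "kcal", "salt", "salt"),
    basis = c("per100g", "per_serving", "per_serving", "per100g"),
    value = c(15, 500, 1.8, 1.5),
    value_kind = "average"))
}

# Salads are deliberately calorie-only so the fixture covers the
# one-programme eligibility state.
fixture_map <- function(targets = fixture_targets()) {
  category_map(tibble::tibble(
    programme = c("sugar", "calorie", "calorie", "salt_ooh", "salt_rm"),
    category_name = c("Desserts", "Mains", "Mains", "Mains", "Sauces"),
    subcategory = c("Desserts", "Burgers", "Salads", "Burgers", "Sauces")),
    targets)
}

fixture_groups <- function() {
  group_map(restaurant_type = c(R1 = "Burger", R2 = "Other Main"))
}
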