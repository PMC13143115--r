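#' Synthetic corpus configuration
#'
#' Builds the configuration for the seeded synthetic menu-corpus
#' generator. Defaults describe a "paper-shaped" corpus: 21 restaurants
#' across the five restaurant types, roughly 3,000 menu items with
#' heterogeneous subcategory mixes, log-normal per-100g nutrient densities
#' with macronutrient panels consistent with energy, truncated-normal
#' serving sizes, and the observed missingness structure in which roughly
#' half of all items report a single nutrient basis with no serving size
#' and must have it imputed from subcategory statistics.
#'
#' @param seed Integer seed; every draw is reproducible given it.
#' @param n_restaurants Number of restaurants.
#' @param mean_items Mean number of menu items per restaurant.
#' @param item_range Min/max items per restaurant.
#' @param missingness Named list of rates in \[0, 1\]:
#'   `per100g_only` (item reports the per-100g panel only),
#'   `per_serving_only` (per-serving panel only),
#'   `serving_size_absent` (serving size withheld),
#'   `kj_only` (energy reported as kJ with kcal withheld),
#'   `sodium_only` (salt reported as sodium only),
#'   `unusable` (all three nutrients of interest withheld, exercising the
#'   exclusion rule).
#' @param adherence_design Named fractions in \[0, 1\] per programme
#'   (`sugar`, `calorie`, `salt`): targets are placed so the realised met
#'   fraction among eligible items equals the design (up to per-category
#'   integer rounding), making adherence a sharp ground truth rather than
#'   a statistical one.
#' @param limited_time_rate Fraction of items flagged limited-time offers.
#' @param pizza_fraction_italian Fraction of pizzas that are Italian-style
#'   (single-serving convention) rather than takeaway-style.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_restaurants = 21L,
                             mean_items = 148,
                             item_range = c(40L, 330L),
                             missingness = list(
                               per100g_only = 0.32,
                               per_serving_only = 0.28,
                               serving_size_absent = 0.88,
                               kj_only = 0.10,
                               sodium_only = 0.10,
                               unusable = 0.005),
                             adherence_design = c(sugar = 0.36,
                                                  calorie = 0.61,
                                                  salt = 0.58),
                             limited_time_rate = 0.012,
                             pizza_fraction_italian = 0.15) {
  defaults <- list(per100g_only = 0.32, per_serving_only = 0.28,
                   serving_size_absent = 0.88, kj_only = 0.10,
                   sodium_only = 0.10, unusable = 0.005)
  missingness <- utils::modifyList(defaults, missingness)
  rates <- unlist(missingness)
  if (any(rates < 0 | rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if (missingness$per100g_only + missingness$per_serving_only > 1) {
    stop("per100g_only + per_serving_only must not exceed 1", call. = FALSE)
  }
  if (any(adherence_design < 0 | adherence_design > 1) ||
      !all(c("sugar", "calorie", "salt") %in% names(adherence_design))) {
    stop("adherence_design must give sugar, calorie, salt fractions in [0, 1]",
         call. = FALSE)
  }
  if (limited_time_rate < 0 || limited_time_rate > 1 ||
      pizza_fraction_italian < 0 || pizza_fraction_italian > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_restaurants < 1 || mean_items < 1) {
    stop("need at least one restaurant and one item", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_restaurants = n_restaurants,
                 mean_items = mean_items, item_range = item_range,
                 missingness = missingness,
                 adherence_design = adherence_design,
                 limited_time_rate = limited_time_rate,
                 pizza_fraction_italian = pizza_fraction_italian),
            class = "synthetic_config")
}

# Stylised per-100g nutrient density and serving-size parameters per
# subcategory. Macronutrients are drawn log-normally; energy is then the
# exact 4/9/3.75 consequence, so macro-implied kcal always matches. Sugar
# is a Beta-distributed share of carbohydrate (sweet categories high).
subcategory_params <- function() {
  tibble::tribble(
    ~subcategory,       ~prot, ~fat, ~carb, ~salt, ~sug_a, ~sug_b, ~serv_mean, ~serv_sd, ~serv_min,
    "Pizzas",            11,    10,   28,    1.30,  2,      18,     440,        120,      150,
    "Burgers",           14,    13,   20,    1.10,  2,      18,     250,         60,       80,
    "Chicken",           18,    12,   12,    1.00,  1.5,    20,     180,         50,       60,
    "Other Mains",        9,     9,   15,    0.80,  2,      14,     400,        100,      120,
    "Children's Meals",   8,     8,   18,    0.60,  2,      12,     250,         60,       80,
    "Salads",             5,     5,    6,    0.50,  2,      10,     250,         70,       60,
    "Sandwiches",        10,     9,   22,    1.00,  2,      14,     200,         50,       70,
    "Potato Sides",       3.5,   8,   25,    0.70,  1.5,    25,     150,         40,       50,
    "Other Sides",        6,    10,   20,    0.90,  2,      16,     120,         35,       40,
    "Breakfast Items",    9,    11,   22,    1.00,  3,      10,     220,         60,       60,
    "Desserts",           4,    15,   45,    0.35,  12,      6,     130,         40,       40,
    "Sauces",             2,    20,   12,    2.20,  3,       8,      40,         15,       15)
}

# Menu-profile weights over the 12 subcategories for each restaurant type.
type_profiles <- function() {
  subs <- menu_subcategories()
  w <- rbind(
    Burger       = c(0.02, 0.34, 0.06, 0.02, 0.08, 0.03, 0.04, 0.12, 0.08, 0.06, 0.10, 0.05),
    Chicken      = c(0.01, 0.14, 0.30, 0.04, 0.08, 0.04, 0.08, 0.10, 0.07, 0.02, 0.07, 0.05),
    Pizza        = c(0.48, 0.01, 0.05, 0.06, 0.04, 0.04, 0.01, 0.06, 0.08, 0.00, 0.11, 0.06),
    Sandwich     = c(0.00, 0.02, 0.02, 0.06, 0.03, 0.08, 0.38, 0.04, 0.08, 0.14, 0.13, 0.02),
    `Other Main` = c(0.03, 0.08, 0.08, 0.30, 0.08, 0.06, 0.06, 0.08, 0.08, 0.06, 0.07, 0.02))
  colnames(w) <- subs
  w
}

# draw from a normal truncated below at `lo`
rtnorm_min <- function(n, mean, sd, lo) {
  p_lo <- stats::pnorm(lo, mean, sd)
  u <- runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

rlnorm_med <- function(n, med, sdlog = 0.30) {
  stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
}

generate_truth_items <- function(config) {
  subs <- menu_subcategories()
  params <- subcategory_params()
  profiles <- type_profiles()

  mix <- c(Burger = 3, Chicken = 2, Pizza = 5, Sandwich = 6,
           `Other Main` = 5)
  types <- rep(names(mix), mix)
  types <- rep_len(types, config$n_restaurants)
  restaurants <- sprintf("Restaurant%02d", seq_len(config$n_restaurants))

  lo <- config$item_range[1]; hi <- config$item_range[2]
  # log-normal menu sizes, clipped to the observed range; the -0.10 offset
  # keeps the post-clipping mean at mean_items
  n_items <- pmin(pmax(round(stats::rlnorm(
    config$n_restaurants, meanlog = log(config$mean_items) - 0.10,
    sdlog = 0.5)), lo), hi)

  rows <- list()
  for (r in seq_len(config$n_restaurants)) {
    n <- n_items[r]
    sub <- sample(subs, n, replace = TRUE, prob = profiles[types[r], ])
    p <- params[match(sub, params$subcategory), ]

    prot <- rlnorm_med(n, p$prot)
    fat <- rlnorm_med(n, p$fat)
    carb <- rlnorm_med(n, p$carb)
    kcal <- 4 * prot + 9 * fat + 3.75 * carb
    sugar <- carb * stats::rbeta(n, p$sug_a, p$sug_b)
    salt <- rlnorm_med(n, p$salt)
    satfat <- fat * runif(n, 0.2, 0.6)
    fibre <- rlnorm_med(n, 2, 0.4)
    ss <- rtnorm_min(n, p$serv_mean, p$serv_sd, p$serv_min)

    pizza_style <- rep(NA_character_, n)
    pizza_size_label <- rep(NA_character_, n)
    pizza_diameter <- rep(NA_real_, n)
    declared_servings <- rep(NA_real_, n)
    pz <- which(sub == "Pizzas")
    if (length(pz) > 0) {
      italian <- runif(length(pz)) < config$pizza_fraction_italian
      pizza_style[pz] <- ifelse(italian, "italian", "takeaway")
      take <- pz[!italian]
      labels <- sample(c("small", "medium", "large", "extra-large"),
                       length(take), replace = TRUE,
                       prob = c(0.15, 0.35, 0.35, 0.15))
      pizza_size_label[take] <- labels
      base_d <- c(small = 9.5, medium = 11.5, large = 13.5,
                  `extra-large` = 15.5)
      pizza_diameter[take] <- base_d[labels] + runif(length(take), -0.3, 0.3)
      pizza_diameter[pz[italian]] <- runif(sum(italian), 11, 12.8)
      size_factor <- c(small = 0.7, medium = 1, large = 1.3,
                       `extra-large` = 1.6)
      ss[take] <- ss[take] * size_factor[labels]
      ss[pz[italian]] <- ss[pz[italian]] * 0.85
      declared <- runif(length(take)) < 0.5
      std_serv <- c(small = 1, medium = 2, large = 3, `extra-large` = 4)
      declared_servings[take[declared]] <- std_serv[labels[declared]]
    }

    rows[[r]] <- tibble::tibble(
      restaurant = restaurants[r], restaurant_type = types[r],
      item_name = sprintf("%s item %03d", restaurants[r], seq_len(n)),
      subcategory = sub,
      limited_time = runif(n) < config$limited_time_rate,
      pizza_style = pizza_style, pizza_size_label = pizza_size_label,
      pizza_diameter = pizza_diameter,
      declared_servings = declared_servings,
      serving_size = ss,
      kcal_100g = kcal, kj_100g = kcal * KJ_PER_KCAL,
      fat_100g = fat, satfat_100g = satfat, carb_100g = carb,
      sugar_100g = sugar, protein_100g = prot, fibre_100g = fibre,
      salt_100g = salt, sodium_100g = salt * SODIUM_MG_PER_G_SALT)
  }
  truth <- dplyr::bind_rows(rows)
  truth$item_id <- seq_len(nrow(truth))

  f <- truth$serving_size / 100
  for (nut in nutrient_fields()) {
    truth[[paste0(nut, "_serv")]] <- truth[[paste0(nut, "_100g")]] * f
  }
  truth
}

# Programme design: which subcategories carry which targets. Covers all
# four eligibility states: most mains are salt+calorie, Desserts are
# salt+sugar, Salads calorie-only, Sauces salt-only, Other Sides none.
programme_design <- function() {
  list(
    sugar = "Desserts",
    calorie = c("Pizzas", "Burgers", "Chicken", "Other Mains",
                "Children's Meals", "Salads", "Sandwiches", "Potato Sides",
                "Breakfast Items"),
    salt_ooh = c("Pizzas", "Burgers", "Chicken", "Other Mains",
                 "Children's Meals", "Sandwiches", "Potato Sides",
                 "Breakfast Items"),
    salt_rm = c("Desserts", "Sauces"))
}

# Place one target so that exactly k of the n eligible values meet it.
# The target sits midway between the k-th and (k+1)-th order statistics,
# so the realised count is robust to round-trip floating error in the
# completion formulas.
place_target <- function(values, fraction) {
  v <- sort(values)
  n <- length(v)
  k <- round(fraction * n)
  if (k <= 0) return(v[1] / 2)
  if (k >= n) return(v[n] * 1.01)
  (v[k] + v[k + 1]) / 2
}

build_targets <- function(truth, usable, config) {
  design <- programme_design()
  f <- config$adherence_design
  servings <- pizza_servings(truth)

  rows <- list()
  add <- function(programme, subcat, nutrient, basis, values) {
    if (length(values) == 0) return()
    frac <- switch(programme, sugar = f[["sugar"]],
                   calorie = f[["calorie"]], f[["salt"]])
    rows[[length(rows) + 1]] <<- tibble::tibble(
      target_id = paste0(programme, "_", gsub("[^A-Za-z]", "_",
                                              tolower(subcat))),
      programme = programme, category_name = subcat, nutrient = nutrient,
      basis = basis, value = place_target(values, frac),
      value_kind = "average")
  }

  for (s in design$sugar) {
    idx <- usable & truth$subcategory == s
    add("sugar", s, "sugar", "per100g", truth$sugar_100g[idx])
  }
  for (s in design$calorie) {
    idx <- usable & truth$subcategory == s & !is.na(servings)
    add("calorie", s, "kcal", "per_serving",
        (truth$kcal_serv / servings)[idx])
  }
  for (s in design$salt_ooh) {
    idx <- usable & truth$subcategory == s
    add("salt_ooh", s, "salt", "per_serving", truth$salt_serv[idx])
  }
  for (s in design$salt_rm) {
    idx <- usable & truth$subcategory == s
    add("salt_rm", s, "salt", "per100g", truth$salt_100g[idx])
  }
  validate_target_table(dplyr::bind_rows(rows))
}

build_category_map <- function(targets) {
  category_map(tibble::tibble(programme = targets$programme,
                              category_name = targets$category_name,
                              subcategory = targets$category_name),
               targets)
}

#' Mask a ground-truth panel into an observed menu item table
#'
#' Applies the missingness mechanism: each usable item reports either the
#' per-100g panel only, the per-serving panel only, or both (emulating
#' single-format nutrition disclosures); serving size is withheld at the
#' configured rate; a fraction of items report energy as kJ only or salt
#' as sodium only; and a small fraction are emitted unusable (all three
#' nutrients of interest withheld). Uses the current RNG state.
#'
#' @param truth Ground-truth item tibble from the generator.
#' @param missingness Missingness rate list (see [synthetic_config()]).
#' @return List: `menu` (masked menu-table tibble), `unusable` (logical
#'   vector flagging items emitted unusable).
#' @export
mask_items <- function(truth, missingness) {
  n <- nrow(truth)
  m <- missingness
  menu <- truth

  u <- runif(n)
  pattern <- ifelse(u < m$per100g_only, "per100g_only",
                    ifelse(u < m$per100g_only + m$per_serving_only,
                           "per_serving_only", "both"))
  unusable <- runif(n) < m$unusable
  ss_absent <- runif(n) < m$serving_size_absent
  kj_only <- runif(n) < m$kj_only
  sodium_only <- runif(n) < m$sodium_only

  for (nut in nutrient_fields()) {
    menu[[paste0(nut, "_serv")]][pattern == "per100g_only"] <- NA_real_
    menu[[paste0(nut, "_100g")]][pattern == "per_serving_only"] <- NA_real_
  }
  menu$serving_size[ss_absent] <- NA_real_

  for (b in c("100g", "serv")) {
    menu[[paste0("kcal_", b)]][kj_only] <- NA_real_
    menu[[paste0("salt_", b)]][sodium_only] <- NA_real_
  }
  # unusable items must stay unusable: withhold the macronutrients too so
  # energy cannot be reconstructed from the macro formula
  for (b in c("100g", "serv")) {
    for (nut in c("kcal", "kj", "sugar", "salt", "sodium", "fat", "carb")) {
      menu[[paste0(nut, "_", b)]][unusable] <- NA_real_
    }
  }

  menu$restaurant_type <- NULL
  list(menu = as_menu_table(menu), unusable = unusable)
}

truth_adherence <- function(truth, usable, targets, map) {
  assignments <- assign_targets(truth, map, targets)
  records <- evaluate_adherence(truth, assignments, targets)
  records$sugar_eligible[!usable] <- FALSE
  records$salt_eligible[!usable] <- FALSE
  records$calorie_eligible[!usable] <- FALSE
  records$sugar_met[!usable] <- NA
  records$salt_met[!usable] <- NA
  records$calorie_met[!usable] <- NA
  records$all_applicable <- all_applicable(records)
  records
}

#' Generate a synthetic menu corpus with known ground truth
#'
#' Draws a complete, internally consistent ground-truth corpus (full
#' nutrient panels on both bases, serving sizes, pizza conventions),
#' places reduction targets at the order statistics of the generated
#' compared-value distributions so the designed met fractions are realised
#' exactly, then masks fields per the missingness mechanism to produce the
#' observed corpus the pipeline analyses.
#'
#' @param config A [synthetic_config()].
#' @return List: `menu` (masked menu table), `targets` (target table),
#'   `map` (category map), `groups` (group map), `truth` (list with
#'   `items` — the unmasked panels — `records` — per-item adherence truth
#'   — `adherence` — overall truth counts per programme — and `unusable`),
#'   `config`.
#' @export
generate_menus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  truth_raw <- generate_truth_items(config)
  groups <- group_map(
    restaurant_type = setNames(
      truth_raw$restaurant_type[!duplicated(truth_raw$restaurant)],
      truth_raw$restaurant[!duplicated(truth_raw$restaurant)]))
  truth_items <- as_menu_table(
    truth_raw[setdiff(names(truth_raw), "restaurant_type")])

  masked <- mask_items(truth_raw, config$missingness)
  usable <- !masked$unusable

  targets <- build_targets(truth_items, usable, config)
  map <- build_category_map(targets)

  records <- truth_adherence(truth_items, usable, targets, map)
  adh <- aggregate_adherence(records, "overall")

  list(menu = masked$menu, targets = targets, map = map, groups = groups,
       truth = list(items = truth_items, records = records, adherence = adh,
                    unusable = masked$unusable),
       config = config)
}
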