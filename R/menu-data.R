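#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang .data :=
#' @importFrom stats median quantile rnorm runif rbinom sd setNames
#' @importFrom utils head
## usethis namespace: end
NULL

#' Nutrient fields carried on each basis
#'
#' The ten nutrient fields a menu-item nutrient panel may report: energy in
#' kcal and kJ, fat, saturated fat, carbohydrate, sugar, protein, fibre and
#' salt in grams, and sodium in milligrams. Each exists on two bases,
#' per 100 g (`_100g` columns) and per serving (`_serv` columns), and every
#' field is optional: an empty cell is missing, which is distinct from zero.
#'
#' @return Character vector of nutrient field names.
#' @export
nutrient_fields <- function() {
  c("kcal", "kj", "fat", "satfat", "carb", "sugar",
    "protein", "fibre", "salt", "sodium")
}

#' The twelve menu-item subcategories
#'
#' Cross-restaurant food groupings used for nutrient summaries and
#' serving-size imputation.
#'
#' @return Character vector of the 12 admissible subcategory labels.
#' @export
menu_subcategories <- function() {
  c("Pizzas", "Burgers", "Chicken", "Other Mains", "Children's Meals",
    "Salads", "Sandwiches", "Potato Sides", "Other Sides",
    "Breakfast Items", "Desserts", "Sauces")
}

#' The five restaurant types
#'
#' Restaurants are grouped by their predominant main-meal subcategory.
#'
#' @return Character vector of the 5 restaurant-type labels.
#' @export
restaurant_types <- function() {
  c("Burger", "Chicken", "Pizza", "Sandwich", "Other Main")
}

#' Meal classes for the twelve subcategories
#'
#' Default division of subcategories into Mains, Sides/Extras, and Desserts.
#'
#' @return Named character vector mapping subcategory to meal class.
#' @export
default_meal_class <- function() {
  c("Pizzas" = "Mains", "Burgers" = "Mains", "Chicken" = "Mains",
    "Other Mains" = "Mains", "Children's Meals" = "Mains",
    "Salads" = "Mains", "Sandwiches" = "Mains", "Breakfast Items" = "Mains",
    "Potato Sides" = "Sides/Extras", "Other Sides" = "Sides/Extras",
    "Sauces" = "Sides/Extras", "Desserts" = "Desserts")
}

# kJ per kcal and mg sodium per g salt; fixed by the completion formulas
KJ_PER_KCAL <- 4.184
SODIUM_MG_PER_G_SALT <- 1000 / 2.5

# Provenance codes for per-field provenance tracking
PROVENANCE_LEVELS <- c("reported", "derived", "subcategory_imputed")

value_columns <- function() {
  c(paste0(nutrient_fields(), "_100g"),
    paste0(nutrient_fields(), "_serv"),
    "serving_size")
}

src_columns <- function() paste0("src_", value_columns())

descriptor_columns <- function() {
  c("item_id", "restaurant", "item_name", "subcategory", "limited_time",
    "pizza_style", "pizza_size_label", "pizza_diameter",
    "declared_servings", "target_label")
}

menu_column_order <- function() {
  c(descriptor_columns(), value_columns(), src_columns())
}

#' Construct / validate a menu table
#'
#' Coerces a data frame of menu items into the canonical menu-table layout:
#' one row per item, descriptor columns, `<nutrient>_100g` / `<nutrient>_serv`
#' value columns plus `serving_size`, and parallel `src_*` provenance columns
#' (`reported`, `derived`, or `subcategory_imputed`). Missing optional
#' columns are added; provenance defaults to `reported` wherever a value is
#' present. Validation enforces the 12-label subcategory enum, non-negative
#' nutrient values, and positive serving sizes.
#'
#' @param df Data frame with at least `restaurant`, `item_name`,
#'   `subcategory` columns; nutrient columns as available.
#' @return A tibble in canonical menu-table layout.
#' @export
as_menu_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("restaurant", "item_name", "subcategory")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("menu table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  bad <- which(!df$subcategory %in% menu_subcategories())
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown subcategory '%s'",
                 bad[1], df$subcategory[bad[1]]), call. = FALSE)
  }

  if (!"item_id" %in% names(df)) df$item_id <- seq_len(nrow(df))
  if (!"limited_time" %in% names(df)) df$limited_time <- FALSE
  df$limited_time[is.na(df$limited_time)] <- FALSE
  for (col in c("pizza_style", "pizza_size_label", "target_label")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  for (col in c("pizza_diameter", "declared_servings")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  for (col in value_columns()) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }

  for (col in setdiff(value_columns(), "serving_size")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("row %d: negative value in '%s' (%g)",
                   bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    }
  }
  bad <- which(!is.na(df$serving_size) & df$serving_size <= 0)
  if (length(bad) > 0) {
    stop(sprintf("row %d: serving_size must be positive (%g)",
                 bad[1], df$serving_size[bad[1]]), call. = FALSE)
  }

  for (col in value_columns()) {
    scol <- paste0("src_", col)
    if (!scol %in% names(df)) df[[scol]] <- NA_character_
    df[[scol]] <- as.character(df[[scol]])
    df[[scol]][!is.na(df[[col]]) & is.na(df[[scol]])] <- "reported"
    df[[scol]][is.na(df[[col]])] <- NA_character_
    known <- df[[scol]][!is.na(df[[scol]])]
    if (!all(known %in% PROVENANCE_LEVELS)) {
      stop("unknown provenance code in ", scol, call. = FALSE)
    }
  }

  dup <- duplicated(df[c("restaurant", "item_name")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (restaurant, item_name) pair(s) kept",
                    sum(dup)), call. = FALSE)
  }

  df[menu_column_order()]
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a menu table from delimited text
#'
#' Reads a CSV or TSV export (delimiter auto-detected from the header line)
#' into the canonical menu-table layout. A `dialect` mapping adapts
#' heterogeneous exports without code changes: a named character vector
#' whose names are canonical column names and whose values are the headers
#' used in the file. Empty cells become missing values, never zero, and all
#' values read from file get provenance `reported` unless the file itself
#' carries `src_*` columns (as written by [write_menu_table()]).
#'
#' @param path Path to a delimited text file.
#' @param dialect Optional named character vector, canonical name -> file
#'   header.
#' @return A menu-table tibble (see [as_menu_table()]).
#' @export
read_menu_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_delim(path, delim = detect_delim(path),
                          col_types = readr::cols(.default = readr::col_character()),
                          na = c("", "NA"), show_col_types = FALSE,
                          progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  numeric_cols <- intersect(c(value_columns(), "pizza_diameter",
                              "declared_servings"), names(df))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("row %d: cannot parse '%s' value '%s' as a number",
                   bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  if ("limited_time" %in% names(df)) {
    df$limited_time <- tolower(trimws(df$limited_time)) %in%
      c("true", "t", "1", "yes")
  }
  if ("item_id" %in% names(df)) df$item_id <- as.integer(df$item_id)
  as_menu_table(df)
}

#' Write a menu table to CSV
#'
#' Writes the canonical column order, including provenance columns, so that
#' `read_menu_table(write_menu_table(x))` round-trips losslessly.
#'
#' @param x Menu-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_menu_table <- function(x, path) {
  x <- x[menu_column_order()]
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a reduction-target table
#'
#' Reads target rows from CSV or YAML (by extension). Each row defines one
#' target: `target_id`, `programme` (`sugar`, `calorie`, `salt_ooh`,
#' `salt_rm`), `category_name`, `nutrient` (`sugar`, `salt`, `kcal`),
#' `basis` (`per100g`, `per_serving`), `value` (> 0), and `value_kind`
#' (`average` or `maximum`). Programme-level invariants are enforced:
#' sugar targets are per 100 g for sugar, calorie targets per serving for
#' kcal, and salt targets are for salt on either basis.
#'
#' @param path Path to a CSV or YAML file.
#' @return Tibble of validated target specifications.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  }
  if (nrow(df) == 0 || ncol(df) == 0) {
    warning("target table is empty: ", path, call. = FALSE)
    return(empty_target_table())
  }
  validate_target_table(df)
}

empty_target_table <- function() {
  tibble::tibble(target_id = character(), programme = character(),
                 category_name = character(), nutrient = character(),
                 basis = character(), value = numeric(),
                 value_kind = character())
}

#' Validate a target table
#'
#' @param df Data frame of candidate target rows.
#' @return Validated tibble of target specifications.
#' @export
validate_target_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("target_id", "programme", "category_name", "nutrient",
                "basis", "value")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("target table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"value_kind" %in% names(df)) df$value_kind <- "average"
  df$value <- as.numeric(df$value)

  check_row <- function(i, ok, msg) {
    if (!ok) stop(sprintf("target table row %d: %s", i, msg), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    p <- df$programme[i]
    check_row(i, p %in% c("sugar", "calorie", "salt_ooh", "salt_rm"),
              paste0("unknown programme '", p, "'"))
    check_row(i, df$basis[i] %in% c("per100g", "per_serving"),
              paste0("unknown basis '", df$basis[i], "'"))
    check_row(i, df$nutrient[i] %in% c("sugar", "salt", "kcal"),
              paste0("unknown nutrient '", df$nutrient[i], "'"))
    check_row(i, !is.na(df$value[i]) && df$value[i] > 0,
              "target value must be positive")
    check_row(i, df$value_kind[i] %in% c("average", "maximum"),
              paste0("unknown value_kind '", df$value_kind[i], "'"))
    if (p == "sugar") {
      check_row(i, df$nutrient[i] == "sugar" && df$basis[i] == "per100g",
                "sugar targets must be for sugar per 100 g")
    } else if (p == "calorie") {
      check_row(i, df$nutrient[i] == "kcal" && df$basis[i] == "per_serving",
                "calorie targets must be for kcal per serving")
    } else {
      check_row(i, df$nutrient[i] == "salt",
                "salt targets must be for salt")
    }
  }
  if (anyDuplicated(df$target_id) > 0) {
    stop("duplicate target_id in target table", call. = FALSE)
  }
  df[c("target_id", "programme", "category_name", "nutrient", "basis",
       "value", "value_kind")]
}

#' Read a group map (restaurant types and meal classes)
#'
#' A group map carries two mappings: `restaurant_type` (restaurant -> one of
#' the 5 restaurant types) and `meal_class` (subcategory -> Mains,
#' Sides/Extras, or Desserts). Accepts a YAML file with those two named
#' blocks, or constructs one from named vectors via [group_map()].
#'
#' @param path Path to a YAML file.
#' @return A group-map list with elements `restaurant_type`, `meal_class`.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  group_map(restaurant_type = unlist(raw$restaurant_type),
            meal_class = unlist(raw$meal_class))
}

#' Construct a group map
#'
#' @param restaurant_type Named character vector, restaurant -> type.
#' @param meal_class Named character vector, subcategory -> meal class;
#'   defaults to [default_meal_class()].
#' @return A group-map list.
#' @export
group_map <- function(restaurant_type, meal_class = default_meal_class()) {
  bad <- setdiff(unique(restaurant_type), restaurant_types())
  if (length(bad) > 0) {
    stop("unknown restaurant type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(meal_class), menu_subcategories())
  if (length(bad) > 0) {
    stop("unknown subcategory in meal_class map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(restaurant_type = restaurant_type,
                 meal_class = meal_class),
            class = "group_map")
}

#' Write result tables and run metadata
#'
#' Writes one CSV per named table (stable column order as given) plus a
#' `run_metadata.yaml` file recording the seed, a hash of the configuration,
#' and the write timestamp. Refuses to overwrite existing files unless
#' `overwrite = TRUE`.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Overwrite existing files?
#' @param seed Optional seed to record in metadata.
#' @param config Optional configuration object; hashed into metadata.
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(tables, out_dir, overwrite = FALSE, seed = NULL,
                          config = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(tables), ".csv"))
  clash <- paths[file.exists(paths)]
  if (length(clash) > 0 && !overwrite) {
    stop("output file(s) already exist (use overwrite = TRUE): ",
         paste(basename(clash), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(tables)) {
    readr::write_csv(tibble::as_tibble(tables[[i]]), paths[i], na = "",
                     progress = FALSE)
  }
  meta <- list(
    seed = if (is.null(seed)) NA else seed,
    config_hash = config_hash(config),
    tables = names(tables),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(paths, meta_path))
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  txt <- paste(deparse(config), collapse = "\n")
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
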