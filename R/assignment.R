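#' Construct a category map
#'
#' A category map is an ordered rule list matching menu items to
#' reduction-target categories. Each rule carries a `programme` (`sugar`,
#' `calorie`, `salt_ooh`, `salt_rm`), the `category_name` of the target it
#' points at, and a predicate over item fields: a `subcategory` to match
#' (NA = any) and/or an explicit per-item `label` matched against the
#' item's `target_label` column (NA = any). Within a programme the first
#' matching rule wins.
#'
#' Category assignment to the government's food categories was a manual
#' judgement in the underlying study design; here the judgement is encoded
#' as configuration while the hierarchy logic stays mechanical.
#'
#' @param rules Data frame with columns `programme`, `category_name`, and
#'   optionally `subcategory`, `label`.
#' @param targets Target table; every rule must reference a category that
#'   exists for its programme.
#' @return Validated category-map tibble (rule order preserved).
#' @export
category_map <- function(rules, targets = NULL) {
  rules <- tibble::as_tibble(rules)
  required <- c("programme", "category_name")
  miss <- setdiff(required, names(rules))
  if (length(miss) > 0) {
    stop("category map missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"subcategory" %in% names(rules)) rules$subcategory <- NA_character_
  if (!"label" %in% names(rules)) rules$label <- NA_character_
  bad <- setdiff(unique(rules$programme),
                 c("sugar", "calorie", "salt_ooh", "salt_rm"))
  if (length(bad) > 0) {
    stop("unknown programme in category map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_sub <- setdiff(stats::na.omit(unique(rules$subcategory)),
                     menu_subcategories())
  if (length(bad_sub) > 0) {
    stop("unknown subcategory in category map: ",
         paste(bad_sub, collapse = ", "), call. = FALSE)
  }
  if (!is.null(targets)) {
    key <- paste(rules$programme, rules$category_name)
    have <- paste(targets$programme, targets$category_name)
    orphan <- which(!key %in% have)
    if (length(orphan) > 0) {
      stop(sprintf(
        "category map rule %d references unknown target category '%s' (programme %s)",
        orphan[1], rules$category_name[orphan[1]],
        rules$programme[orphan[1]]), call. = FALSE)
    }
  }
  rules[c("programme", "category_name", "subcategory", "label")]
}

#' Read a category map from YAML or CSV
#'
#' @param path File path; YAML files hold a list of rule mappings, CSV a
#'   rule table.
#' @param targets Optional target table for referential validation.
#' @return Category-map tibble.
#' @export
read_category_map <- function(path, targets = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(raw, function(r) {
      tibble::tibble(
        programme = r$programme, category_name = r$category_name,
        subcategory = r$subcategory %||% NA_character_,
        label = r$label %||% NA_character_)
    }))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = c("", "NA"))
  }
  category_map(df, targets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First-match-wins category per item for one programme; vectorised over
# items, iterating over the (few) rules in declaration order.
first_match <- function(items, rules, programme) {
  prules <- rules[rules$programme == programme, ]
  out <- rep(NA_character_, nrow(items))
  for (j in seq_len(nrow(prules))) {
    sub_ok <- if (is.na(prules$subcategory[j])) TRUE else
      items$subcategory == prules$subcategory[j]
    lab_ok <- if (is.na(prules$label[j])) TRUE else
      !is.na(items$target_label) & items$target_label == prules$label[j]
    hit <- is.na(out) & sub_ok & lab_ok
    out[hit] <- prules$category_name[j]
  }
  out
}

#' Is a pizza a sharing pizza?
#'
#' Sharing pizzas are defined disjunctively: size label large or above, or
#' diameter of 11.5 inches or more. Either condition suffices.
#'
#' @param items Menu-table tibble.
#' @return Logical vector (FALSE for non-pizzas).
#' @export
is_sharing_pizza <- function(items) {
  lbl <- tolower(items$pizza_size_label)
  items$subcategory == "Pizzas" &
    ((!is.na(lbl) & lbl %in% c("large", "extra-large", "extra large", "xl")) |
       (!is.na(items$pizza_diameter) & items$pizza_diameter >= 11.5))
}

#' Serving count for a pizza's calorie-target comparison
#'
#' Returns, per item, the number of servings a whole pizza is assumed to
#' contain: the restaurant's declared serving count when present (e.g., a
#' medium pizza shared between two people counts as two servings);
#' otherwise 1 for Italian-style pizzas; otherwise a size-label rule
#' (small 1, medium 2, large 3, extra-large 4 — large and extra-large as
#' per the guidance assumptions); otherwise a diameter rule at the same
#' breakpoints (<10.5" = 1, <12.5" = 2, <14.5" = 3, else 4). A takeaway
#' pizza with no declared servings, no size label, and no diameter is
#' unassignable: NA is returned and the item is excluded from the calorie
#' denominator by [assign_targets()]. Non-pizza rows get 1.
#'
#' @param items Menu-table tibble.
#' @return Numeric vector of serving counts (NA where unassignable).
#' @export
pizza_servings <- function(items) {
  n <- nrow(items)
  out <- rep(1, n)
  pz <- items$subcategory == "Pizzas"
  if (!any(pz)) return(out)

  declared <- items$declared_servings
  lbl <- tolower(items$pizza_size_label)
  lbl_servings <- c("small" = 1, "medium" = 2, "large" = 3,
                    "extra-large" = 4, "extra large" = 4, "xl" = 4)
  diam <- items$pizza_diameter

  for (i in which(pz)) {
    if (!is.na(declared[i])) {
      out[i] <- declared[i]
    } else if (!is.na(items$pizza_style[i]) &&
               items$pizza_style[i] == "italian") {
      out[i] <- 1
    } else if (!is.na(lbl[i]) && lbl[i] %in% names(lbl_servings)) {
      out[i] <- unname(lbl_servings[lbl[i]])
    } else if (!is.na(diam[i])) {
      out[i] <- if (diam[i] < 10.5) 1 else if (diam[i] < 12.5) 2
      else if (diam[i] < 14.5) 3 else 4
    } else {
      out[i] <- NA_real_
    }
  }
  out
}

#' Assign menu items to reduction targets under the programme hierarchy
#'
#' For each item: sugar rules are evaluated first and calorie rules only
#' for items with no sugar match, so no item ever holds both a sugar and a
#' calorie target (the two programmes are non-overlapping by guidance).
#' Salt rules are evaluated OOH-sector first, then retailer/manufacturer
#' rules for the remainder; the matched sector is recorded. Sharing pizzas
#' whose serving count cannot be established are flagged and excluded from
#' the calorie denominator only.
#'
#' @param items Completed menu-table tibble.
#' @param map Category map (see [category_map()]).
#' @param targets Target table (see [read_target_table()]).
#' @return Assignment tibble: `item_id`, one target id per programme
#'   (`sugar_target`, `calorie_target`, `salt_target`), `salt_sector`,
#'   `servings_for_calorie`, `calorie_unassignable`, and
#'   `eligibility_state` (`none`, `one_programme`, `salt_and_calorie`,
#'   `salt_and_sugar`).
#' @export
assign_targets <- function(items, map, targets) {
  map <- category_map(map, targets)
  target_key <- paste(targets$programme, targets$category_name)
  lookup_target <- function(programme, category) {
    if (is.na(category)) return(NA_character_)
    hit <- which(target_key == paste(programme, category))
    targets$target_id[hit[1]]
  }

  n <- nrow(items)
  servings <- pizza_servings(items)
  id_of <- function(programme, cats) {
    vapply(cats, function(cat) lookup_target(programme, cat),
           character(1), USE.NAMES = FALSE)
  }

  # sugar first; calorie only for items with no sugar match
  cat_sugar <- first_match(items, map, "sugar")
  sugar_t <- id_of("sugar", cat_sugar)
  cat_cal <- first_match(items, map, "calorie")
  cat_cal[!is.na(cat_sugar)] <- NA_character_
  unassignable <- !is.na(cat_cal) & is.na(servings)
  cat_cal[unassignable] <- NA_character_
  calorie_t <- id_of("calorie", cat_cal)

  # salt: OOH sector first, retailer/manufacturer for the remainder
  cat_ooh <- first_match(items, map, "salt_ooh")
  cat_rm <- first_match(items, map, "salt_rm")
  cat_rm[!is.na(cat_ooh)] <- NA_character_
  salt_t <- ifelse(!is.na(cat_ooh), id_of("salt_ooh", cat_ooh),
                   id_of("salt_rm", cat_rm))
  sector <- ifelse(!is.na(cat_ooh), "ooh",
                   ifelse(!is.na(cat_rm), "rm", NA_character_))

  state <- dplyr::case_when(
    !is.na(salt_t) & !is.na(calorie_t) ~ "salt_and_calorie",
    !is.na(salt_t) & !is.na(sugar_t) ~ "salt_and_sugar",
    !is.na(salt_t) | !is.na(calorie_t) | !is.na(sugar_t) ~ "one_programme",
    TRUE ~ "none")

  tibble::tibble(
    item_id = items$item_id,
    sugar_target = sugar_t,
    calorie_target = calorie_t,
    salt_target = salt_t,
    salt_sector = sector,
    servings_for_calorie = servings,
    calorie_unassignable = unassignable,
    eligibility_state = state)
}

#' Lint a configuration
#'
#' Validates the target table, category-map referential integrity and
#' within-programme exclusivity (rules shadowed by an earlier rule with the
#' same predicate scope are flagged), and group-map coverage of the
#' restaurants and subcategories present in the data.
#'
#' @param targets Target table.
#' @param map Category map.
#' @param groups Group map.
#' @param items Optional menu table whose restaurants/subcategories must be
#'   covered.
#' @return Tibble of violations (zero rows when clean).
#' @export
lint_config <- function(targets, map, groups = NULL, items = NULL) {
  violations <- list()
  note <- function(kind, detail) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(kind = kind, detail = detail)
  }

  tryCatch(validate_target_table(targets),
           error = function(e) note("target_table", conditionMessage(e)))
  tryCatch(category_map(map, targets),
           error = function(e) note("category_map", conditionMessage(e)))

  m <- tryCatch(category_map(map), error = function(e) NULL)
  if (!is.null(m)) {
    key <- paste(m$programme, m$subcategory, m$label)
    dup <- which(duplicated(key))
    for (i in dup) {
      note("category_map",
           sprintf("rule %d (%s, %s) is shadowed by an earlier rule with the same predicate",
                   i, m$programme[i], m$category_name[i]))
    }
  }

  if (!is.null(items) && !is.null(groups)) {
    missing_r <- setdiff(unique(items$restaurant),
                         names(groups$restaurant_type))
    for (r in missing_r) note("group_map", paste0("restaurant not mapped: ", r))
    missing_s <- setdiff(unique(items$subcategory), names(groups$meal_class))
    for (s in missing_s) note("group_map", paste0("subcategory not mapped: ", s))
  }

  if (length(violations) == 0) {
    tibble::tibble(kind = character(), detail = character())
  } else {
    dplyr::bind_rows(violations)
  }
}
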