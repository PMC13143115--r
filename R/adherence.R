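#' Evaluate target adherence per item
#'
#' For each item and each programme it is assigned to, the compared value
#' is taken on the target's own basis: sugar per 100 g, calories per
#' serving (dividing whole-pizza energy by the pizza's serving count), and
#' salt on the basis carried by the matched salt target (OOH rows typically
#' per serving, retailer/manufacturer rows per 100 g). A target is met when
#' the compared value is less than or equal to the target value (boundary
#' inclusive). An item whose required basis value is still missing after
#' completion is dropped from that programme's denominator with an audit
#' note, but stays in the other programmes' denominators.
#'
#' @param items Completed menu-table tibble.
#' @param assignments Assignment tibble from [assign_targets()].
#' @param targets Target table.
#' @return Adherence-record tibble, one row per item: per programme an
#'   `*_eligible` flag, `*_met` (NA when ineligible), `*_value`,
#'   `*_target_value`, `*_basis`; an `audit` note column; and
#'   `all_applicable` (TRUE iff every eligible programme is met; NA when
#'   eligible for none).
#' @export
evaluate_adherence <- function(items, assignments, targets) {
  stopifnot(identical(items$item_id, assignments$item_id))
  tgt <- targets
  tval <- setNames(tgt$value, tgt$target_id)
  tbasis <- setNames(tgt$basis, tgt$target_id)

  n <- nrow(items)
  rec <- tibble::tibble(
    item_id = items$item_id,
    restaurant = items$restaurant,
    subcategory = items$subcategory,
    sugar_eligible = FALSE, sugar_met = NA,
    sugar_value = NA_real_, sugar_target_value = NA_real_,
    calorie_eligible = FALSE, calorie_met = NA,
    calorie_value = NA_real_, calorie_target_value = NA_real_,
    salt_eligible = FALSE, salt_met = NA,
    salt_value = NA_real_, salt_target_value = NA_real_,
    salt_basis = NA_character_,
    audit = NA_character_)

  add_audit <- function(old, msg) ifelse(is.na(old), msg, paste(old, msg, sep = "; "))

  # sugar: always per 100 g
  has_sugar_t <- !is.na(assignments$sugar_target)
  v <- items$sugar_100g
  ok <- has_sugar_t & !is.na(v)
  rec$sugar_eligible <- ok
  rec$sugar_value[ok] <- v[ok]
  rec$sugar_target_value[ok] <- unname(tval[assignments$sugar_target[ok]])
  rec$sugar_met[ok] <- rec$sugar_value[ok] <= rec$sugar_target_value[ok]
  dropped <- has_sugar_t & is.na(v)
  rec$audit[dropped] <- add_audit(rec$audit[dropped],
                                  "sugar value missing: dropped from sugar denominator")

  # calorie: per serving, whole-pizza energy divided by serving count
  has_cal_t <- !is.na(assignments$calorie_target)
  v <- items$kcal_serv / assignments$servings_for_calorie
  ok <- has_cal_t & !is.na(v)
  rec$calorie_eligible <- ok
  rec$calorie_value[ok] <- v[ok]
  rec$calorie_target_value[ok] <- unname(tval[assignments$calorie_target[ok]])
  rec$calorie_met[ok] <- rec$calorie_value[ok] <= rec$calorie_target_value[ok]
  dropped <- has_cal_t & is.na(v)
  rec$audit[dropped] <- add_audit(rec$audit[dropped],
                                  "kcal per serving missing: dropped from calorie denominator")
  unas <- assignments$calorie_unassignable
  rec$audit[unas] <- add_audit(rec$audit[unas],
                               "pizza serving count unassignable: dropped from calorie denominator")

  # salt: basis travels with the matched target
  has_salt_t <- !is.na(assignments$salt_target)
  basis <- unname(tbasis[assignments$salt_target])
  v <- ifelse(!is.na(basis) & basis == "per100g",
              items$salt_100g, items$salt_serv)
  ok <- has_salt_t & !is.na(v)
  rec$salt_eligible <- ok
  rec$salt_value[ok] <- v[ok]
  rec$salt_target_value[ok] <- unname(tval[assignments$salt_target[ok]])
  rec$salt_basis[ok] <- basis[ok]
  rec$salt_met[ok] <- rec$salt_value[ok] <= rec$salt_target_value[ok]
  dropped <- has_salt_t & is.na(v)
  rec$audit[dropped] <- add_audit(rec$audit[dropped],
                                  "salt value missing on target basis: dropped from salt denominator")

  rec$all_applicable <- all_applicable(rec)
  rec
}

#' Meets-all-applicable-targets flag
#'
#' TRUE iff the item met every programme for which it is eligible; NA for
#' items eligible for no programme (such items are excluded from the
#' all-applicable denominator).
#'
#' @param records Adherence-record tibble (the `all_applicable` column is
#'   recomputed, not read).
#' @return Logical vector.
#' @export
all_applicable <- function(records) {
  n_elig <- records$sugar_eligible + records$calorie_eligible +
    records$salt_eligible
  met_all <-
    (!records$sugar_eligible | records$sugar_met %in% TRUE) &
    (!records$calorie_eligible | records$calorie_met %in% TRUE) &
    (!records$salt_eligible | records$salt_met %in% TRUE)
  ifelse(n_elig == 0, NA, met_all)
}

grouping_labels <- function(records, grouping, groups = NULL) {
  switch(grouping,
    overall = rep("All", nrow(records)),
    restaurant = records$restaurant,
    subcategory = records$subcategory,
    restaurant_type = {
      if (is.null(groups)) stop("grouping 'restaurant_type' needs a group map",
                                call. = FALSE)
      unmapped <- setdiff(unique(records$restaurant),
                          names(groups$restaurant_type))
      if (length(unmapped) > 0) {
        stop("restaurant(s) not in group map: ",
             paste(unmapped, collapse = ", "), call. = FALSE)
      }
      unname(groups$restaurant_type[records$restaurant])
    },
    stop("unknown grouping: ", grouping, call. = FALSE))
}

#' Aggregate adherence records into group proportions
#'
#' Counts eligible and met items per group for each programme and for
#' all-applicable, with the proportion met. Counts are exact integers;
#' percentages are for reporting and rounded only at report time.
#'
#' @param records Adherence-record tibble from [evaluate_adherence()].
#' @param grouping One of `"overall"`, `"restaurant"`, `"subcategory"`,
#'   `"restaurant_type"`.
#' @param groups Group map (needed for `restaurant_type`).
#' @return Tibble: `grouping`, `label`, `programme` (sugar, salt, calorie,
#'   all_applicable), `n_eligible`, `n_met`, `proportion`.
#' @export
aggregate_adherence <- function(records,
                                grouping = c("overall", "restaurant",
                                             "subcategory",
                                             "restaurant_type"),
                                groups = NULL) {
  grouping <- match.arg(grouping)
  label <- grouping_labels(records, grouping, groups)

  one_prog <- function(elig, met, programme) {
    df <- tibble::tibble(label = label, elig = elig, met = met)
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$label),
      n_eligible = sum(.data$elig, na.rm = TRUE),
      n_met = sum(.data$met %in% TRUE & .data$elig, na.rm = TRUE),
      .groups = "drop")
    out$programme <- programme
    out
  }

  res <- dplyr::bind_rows(
    one_prog(records$sugar_eligible, records$sugar_met, "sugar"),
    one_prog(records$salt_eligible, records$salt_met, "salt"),
    one_prog(records$calorie_eligible, records$calorie_met, "calorie"),
    one_prog(!is.na(records$all_applicable), records$all_applicable,
             "all_applicable"))
  res$proportion <- ifelse(res$n_eligible > 0,
                           res$n_met / res$n_eligible, NA_real_)
  res$grouping <- grouping
  res[c("grouping", "label", "programme", "n_eligible", "n_met",
        "proportion")]
}

#' Format an adherence summary for reporting
#'
#' Adds a whole-number percentage column (configurable precision); the
#' underlying counts stay exact.
#'
#' @param summary Tibble from [aggregate_adherence()].
#' @param digits Decimal places for the percentage (default 0, whole
#'   percents).
#' @return The tibble with a `percent` column.
#' @export
format_adherence <- function(summary, digits = 0) {
  summary$percent <- round(100 * summary$proportion, digits)
  summary
}
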