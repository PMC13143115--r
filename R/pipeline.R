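#' Run the full menu-nutrition adherence analysis
#'
#' Orchestrates the stages in order: exclude unusable items (all three
#' nutrients of interest missing and underivable), deterministic completion
#' (unit conversions, serving-size derivation, basis scaling), serving-size
#' statistics, subcategory serving-size imputation, target assignment under
#' the programme hierarchy, per-item adherence evaluation, and aggregation
#' of adherence and nutrient summaries over all four groupings.
#'
#' @param menu Menu-table tibble (or path readable by
#'   [read_menu_table()]).
#' @param targets Target table (or path).
#' @param map Category map (or path).
#' @param groups Group map (or path to YAML).
#' @param strategy Serving-size imputation strategy: `"mean"` (primary),
#'   `"lq"`, `"uq"`.
#' @param stats Serving statistics to use for imputation; computed from
#'   the completed items when omitted. Sensitivity runs pass the primary
#'   run's statistics.
#' @param exclude_limited_time Drop limited-time-offer items before the
#'   analysis?
#' @return A results bundle (list): `items` (completed), `serving_stats`,
#'   `assignments`, `records`, `adherence` (list of summaries by
#'   grouping), `summaries` (nutrient summaries by grouping), and
#'   `report` (stage accounting: exclusions, imputations, eligible counts).
#' @export
run_pipeline <- function(menu, targets, map, groups,
                         strategy = c("mean", "lq", "uq"),
                         stats = NULL, exclude_limited_time = FALSE) {
  strategy <- match.arg(strategy)
  if (is.character(menu)) menu <- read_menu_table(menu)
  if (is.character(targets)) targets <- read_target_table(targets)
  if (is.character(map)) map <- read_category_map(map, targets)
  if (is.character(groups)) groups <- read_group_map(groups)
  if (nrow(menu) == 0) stop("menu table is empty", call. = FALSE)

  n_lto_excluded <- 0L
  if (exclude_limited_time) {
    n_lto_excluded <- sum(menu$limited_time)
    menu <- menu[!menu$limited_time, ]
  }

  excl <- exclude_unusable(menu)
  items <- complete_items(excl$items)
  if (is.null(stats)) stats <- serving_stats(items)
  items <- impute_serving_size(items, strategy = strategy, stats = stats)

  assignments <- assign_targets(items, map, targets)
  records <- evaluate_adherence(items, assignments, targets)

  groupings <- c("overall", "restaurant", "subcategory", "restaurant_type")
  adherence <- lapply(groupings, function(g) {
    format_adherence(aggregate_adherence(records, g, groups))
  })
  names(adherence) <- groupings
  check_denominator_conservation(adherence)

  summaries <- lapply(groupings, function(g) {
    summarize_nutrients(items, g, groups = groups, stats = stats)
  })
  names(summaries) <- groupings

  report <- tibble::tibble(
    n_input = nrow(menu) + n_lto_excluded,
    n_limited_time_excluded = n_lto_excluded,
    n_excluded_all_missing = excl$report$n_excluded_all_missing,
    n_analysed = nrow(items),
    n_serving_size_imputed = n_serving_imputed(items),
    n_sugar_eligible = sum(records$sugar_eligible),
    n_salt_eligible = sum(records$salt_eligible),
    n_calorie_eligible = sum(records$calorie_eligible),
    n_any_eligible = sum(!is.na(records$all_applicable)),
    strategy = strategy)

  list(items = items, serving_stats = stats, assignments = assignments,
       records = records, adherence = adherence, summaries = summaries,
       report = report)
}

# Every grouping must partition the corpus: its per-group eligible and met
# counts must sum to the overall counts, per programme.
check_denominator_conservation <- function(adherence) {
  overall <- adherence$overall
  for (g in setdiff(names(adherence), "overall")) {
    tab <- adherence[[g]]
    for (p in unique(overall$programme)) {
      n_g <- sum(tab$n_eligible[tab$programme == p])
      n_o <- overall$n_eligible[overall$programme == p]
      if (n_g != n_o) {
        stop(sprintf(
          "denominator conservation violated: grouping '%s', programme '%s' (%d vs %d)",
          g, p, n_g, n_o), call. = FALSE)
      }
      m_g <- sum(tab$n_met[tab$programme == p])
      m_o <- overall$n_met[overall$programme == p]
      if (m_g != m_o) {
        stop(sprintf(
          "met-count conservation violated: grouping '%s', programme '%s'",
          g, p), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Collect a results bundle into flat output tables
#'
#' @param results Results bundle from [run_pipeline()].
#' @return Named list of tibbles suitable for [write_outputs()].
#' @export
result_tables <- function(results) {
  list(
    items_completed = results$items,
    serving_stats = results$serving_stats,
    assignments = results$assignments,
    adherence_records = results$records,
    adherence_overall = results$adherence$overall,
    adherence_by_restaurant = results$adherence$restaurant,
    adherence_by_subcategory = results$adherence$subcategory,
    adherence_by_restaurant_type = results$adherence$restaurant_type,
    nutrient_summaries_overall = results$summaries$overall,
    nutrient_summaries_by_restaurant = results$summaries$restaurant,
    nutrient_summaries_by_subcategory = results$summaries$subcategory,
    nutrient_summaries_by_restaurant_type = results$summaries$restaurant_type,
    run_report = results$report)
}
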