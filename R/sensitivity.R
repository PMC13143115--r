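#' Re-run the analysis under a sensitivity specification
#'
#' Three sensitivity specifications are supported, each a single
#' perturbation of the primary analysis:
#' * `exclude_lto` — limited-time-offer items are removed before any
#'   stage runs;
#' * `serving_lq` / `serving_uq` — missing serving sizes are imputed with
#'   the subcategory lower/upper quartile instead of the mean. The
#'   quartiles come from the primary run's serving-size statistics
#'   (computed before imputation), so the strategies perturb imputation,
#'   never the statistics themselves.
#'
#' @param menu Raw menu-table tibble (the same input the primary run used).
#' @param spec `"exclude_lto"`, `"serving_lq"`, or `"serving_uq"`.
#' @param targets,map,groups As in [run_pipeline()].
#' @param primary Primary results bundle from [run_pipeline()]; supplies
#'   the shared serving statistics and the baseline for the diff tables.
#' @return List: `results` (the sensitivity run's bundle), `diff_summary`
#'   (per overall summary cell: primary vs sensitivity value and delta),
#'   `diff_adherence` (same for overall adherence proportions).
#' @export
run_sensitivity <- function(menu, spec, targets, map, groups, primary) {
  if (!spec %in% c("exclude_lto", "serving_lq", "serving_uq")) {
    stop("unknown sensitivity spec: ", spec, call. = FALSE)
  }
  res <- switch(spec,
    exclude_lto = run_pipeline(menu, targets, map, groups,
                               strategy = "mean",
                               stats = primary$serving_stats,
                               exclude_limited_time = TRUE),
    serving_lq = run_pipeline(menu, targets, map, groups, strategy = "lq",
                              stats = primary$serving_stats),
    serving_uq = run_pipeline(menu, targets, map, groups, strategy = "uq",
                              stats = primary$serving_stats))

  key <- c("grouping", "label", "nutrient", "basis")
  ds <- dplyr::inner_join(primary$summaries$overall,
                          res$summaries$overall,
                          by = key, suffix = c("_primary", "_sensitivity"))
  ds$delta_mean <- ds$mean_sensitivity - ds$mean_primary
  diff_summary <- ds[c(key, "mean_primary", "mean_sensitivity",
                       "delta_mean")]

  da <- dplyr::inner_join(primary$adherence$overall, res$adherence$overall,
                          by = c("grouping", "label", "programme"),
                          suffix = c("_primary", "_sensitivity"))
  da$delta_proportion <- da$proportion_sensitivity - da$proportion_primary
  diff_adherence <- da[c("grouping", "label", "programme",
                         "n_eligible_primary", "n_met_primary",
                         "proportion_primary", "n_eligible_sensitivity",
                         "n_met_sensitivity", "proportion_sensitivity",
                         "delta_proportion")]

  list(spec = spec, results = res, diff_summary = diff_summary,
       diff_adherence = diff_adherence)
}

#' Three-strategy serving-size comparison tables
#'
#' Runs the lower- and upper-quartile imputation sensitivities and lays
#' out the comparison the way the robustness analysis reports it: one
#' table of average nutrient content (kcal, salt, sugar on per-100g and
#' reported-serving bases) and one of target adherence (calorie, salt,
#' sugar, all-applicable), each with columns for the average, lower
#' quartile, and upper quartile strategies.
#'
#' @param menu Raw menu-table tibble.
#' @param targets,map,groups As in [run_pipeline()].
#' @param primary Primary results bundle (mean strategy).
#' @return List of two tibbles: `nutrient_content`, `adherence`.
#' @export
serving_strategy_comparison <- function(menu, targets, map, groups,
                                        primary) {
  lq <- run_sensitivity(menu, "serving_lq", targets, map, groups, primary)
  uq <- run_sensitivity(menu, "serving_uq", targets, map, groups, primary)

  pick_means <- function(bundle) {
    s <- bundle$summaries$overall
    s <- s[s$nutrient %in% c("kcal", "salt", "sugar") &
             s$basis %in% c("per100g", "reported_serving"), ]
    s[order(match(s$basis, c("per100g", "reported_serving")),
            match(s$nutrient, c("kcal", "salt", "sugar"))), ]
  }
  p <- pick_means(primary)
  nutrient_content <- tibble::tibble(
    nutrient = p$nutrient, basis = p$basis,
    using_average = p$mean,
    using_lower_quartile = pick_means(lq$results)$mean,
    using_upper_quartile = pick_means(uq$results)$mean)

  pick_adh <- function(bundle) {
    a <- bundle$adherence$overall
    a[match(c("calorie", "salt", "sugar", "all_applicable"), a$programme), ]
  }
  p <- pick_adh(primary)
  adherence <- tibble::tibble(
    target = p$programme,
    using_average = p$proportion,
    using_lower_quartile = pick_adh(lq$results)$proportion,
    using_upper_quartile = pick_adh(uq$results)$proportion)

  list(nutrient_content = nutrient_content, adherence = adherence)
}
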