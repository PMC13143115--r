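#!/usr/bin/env Rscript

# Step 4: descriptive nutrient summaries.
#
# Mean/median/SD for kcal, salt, sugar, and fat on three serving bases
# (per 100 g, per reported serving, per subcategory-average serving), for
# every grouping, plus the five-number distribution tables behind the
# box-plot figures.

suppressPackageStartupMessages(library(menutargets))

res <- run_pipeline("results/data/menu_corpus.csv",
                    "results/data/target_table.csv",
                    "results/data/category_map.csv",
                    "results/data/group_map.yaml")

tables <- result_tables(res)[c(
  "nutrient_summaries_overall", "nutrient_summaries_by_restaurant",
  "nutrient_summaries_by_subcategory",
  "nutrient_summaries_by_restaurant_type")]

dists <- list()
for (g in c("subcategory", "restaurant")) {
  for (nut in c("kcal", "salt", "sugar")) {
    for (b in c("per100g", "reported_serving")) {
      dists[[length(dists) + 1]] <-
        distribution_export(res$items, g, nut, b, groups = NULL,
                            stats = res$serving_stats)
    }
  }
}
tables$nutrient_distributions <- dplyr::bind_rows(dists)

write_outputs(tables, "results", overwrite = TRUE)

ov <- res$summaries$overall
line <- function(nut, basis) {
  r <- ov[ov$nutrient == nut & ov$basis == basis, ]
  sprintf("%.1f", r$mean)
}
cat(sprintf(
  "Per 100 g, mean content across all menu items: %s kcal, %s g salt, %s g sugar.\n",
  line("kcal", "per100g"), line("salt", "per100g"),
  line("sugar", "per100g")))
cat(sprintf(
  "Per reported serving: %s kcal, %s g salt, %s g sugar.\n",
  line("kcal", "reported_serving"), line("salt", "reported_serving"),
  line("sugar", "reported_serving")))
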