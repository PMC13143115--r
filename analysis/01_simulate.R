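#!/usr/bin/env Rscript

# Step 1: generate the synthetic menu corpus the analysis runs on.
#
# The generator emulates the structure of a multi-restaurant UK menu
# audit: 21 restaurants across five types, ~3,000 menu items in 12
# subcategories, log-normal nutrient densities, and the observed
# missingness pattern in which roughly half of all items report a single
# nutrient basis with no serving size. Reduction targets are placed at
# order statistics of the generated distributions so the designed
# adherence fractions (61% calorie, 58% salt, 36% sugar) are the exact
# ground truth.

suppressPackageStartupMessages(library(menutargets))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

sim <- generate_menus(synthetic_config(seed = seed))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
write_menu_table(sim$menu, "results/data/menu_corpus.csv")
readr::write_csv(sim$targets, "results/data/target_table.csv")
readr::write_csv(sim$map, "results/data/category_map.csv", na = "")
yaml::write_yaml(list(restaurant_type = as.list(sim$groups$restaurant_type),
                      meal_class = as.list(sim$groups$meal_class)),
                 "results/data/group_map.yaml")
readr::write_csv(sim$truth$items, "results/data/ground_truth_items.csv",
                 na = "")
readr::write_csv(sim$truth$records, "results/data/ground_truth_records.csv",
                 na = "")
yaml::write_yaml(list(seed = seed), "results/data/simulation_meta.yaml")

cat(sprintf(
  "Simulated %d menu items from %d restaurants (seed %d).\n",
  nrow(sim$menu), length(unique(sim$menu$restaurant)), seed))
cat(sprintf(
  "%d targets across programmes: %s.\n", nrow(sim$targets),
  paste(unique(sim$targets$programme), collapse = ", ")))
cat(sprintf(
  "Ground-truth overall adherence: %s.\n",
  paste(sprintf("%s %d/%d", sim$truth$adherence$programme,
                sim$truth$adherence$n_met,
                sim$truth$adherence$n_eligible), collapse = "; ")))
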