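#!/usr/bin/env Rscript
# Paired-cohort campaign: several MVO settings, each run under both infusion
# protocols plus a clean-chip control, summarized as the cohort table
# (quartiles/means of c_max and D_final per setting), occlusivity and
# contact fraction tables, balloon-vs-no-balloon comparisons, and the
# thrombus occurrence heatmap.
#
# Writes results/cohort_summary.csv, results/fraction_tables.csv,
#        results/comparison.json, results/heatmap_counts.csv

suppressMessages(library(mvochip))

seeds <- 201:203   # small demonstration campaign; the test suite runs 10
layout <- build_symmetric_tree()
maps <- rasterize_layout(layout)

message("Paired campaign over seeds ", paste(seeds, collapse = ", "), " ...")
tab <- run_paired_campaign(seeds, n_thrombi = 14, layout = layout, maps = maps,
                           include_control = TRUE, analyze = TRUE)

summary_tab <- summarize_cohort(tab)
write.csv(summary_tab, "results/cohort_summary.csv", row.names = FALSE)
message("Cohort summary (quartiles / means):")
print(summary_tab, digits = 3)

mvo <- tab[tab$setting != "no_balloon/no_MVO", ]
ft <- fraction_tables(mvo)
frac_out <- rbind(cbind(kind = "occlusivity", stats::setNames(ft$occlusivity,
                    c("case", "class1", "class2", "class3"))),
                  cbind(kind = "contact", stats::setNames(ft$contact,
                    c("case", "class1", "class2", "class3"))))
write.csv(frac_out, "results/fraction_tables.csv", row.names = FALSE)
message("Occlusivity fractions per case:"); print(ft$occlusivity, digits = 2)
message("Contact fractions per case:"); print(ft$contact, digits = 2)

cmp_mvo <- compare_settings(tab, reference = "no_balloon/MVO",
                            treatment = "balloon/MVO")
cmp_ctl <- compare_settings(tab, reference = "no_balloon/no_MVO",
                            treatment = "no_balloon/MVO")
jsonlite::write_json(list(balloon_vs_no_balloon = cmp_mvo,
                          mvo_vs_control = cmp_ctl),
                     "results/comparison.json", auto_unbox = TRUE, digits = NA)
message("Balloon vs no-balloon (MVO settings):")
print(cmp_mvo[, c("metric", "mean_ratio", "mean_percent", "median_ratio")], digits = 3)
message("MVO vs control (no-balloon):")
print(cmp_ctl[, c("metric", "mean_ratio", "mean_percent")], digits = 3)

# occurrence heatmap from the generator's footprints across the campaign
heat <- matrix(0L, maps$image_shape[1], maps$image_shape[2])
for (s in seeds) {
  th <- place_microthrombi(layout, maps, n = 14, rng_seed = s)
  for (t in th) heat[t$footprint] <- heat[t$footprint] + 1L
}
hc <- which(heat > 0, arr.ind = TRUE)
write.csv(data.frame(row = hc[, 1], col = hc[, 2], count = heat[hc]),
          "results/heatmap_counts.csv", row.names = FALSE)
png::writePNG(heat / max(max(heat), 1), "scratch/heatmap.png")
message("Wrote results/cohort_summary.csv, fraction_tables.csv, comparison.json, heatmap_counts.csv")
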