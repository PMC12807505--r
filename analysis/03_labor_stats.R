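#!/usr/bin/env Rscript
# Group-level labor statistics on the animal-summary table produced by
# 02_detect_peaks.R: Kruskal-Wallis across the four arms for inter-pup
# interval and mean peak pressure, Mann-Whitney for control vs combined
# knockout, and Fisher's exact test for the onset-after-ZT3 dichotomy
# (control vs pooled knockouts). Writes results/labor_stats.csv.

library(partolab)

summ <- utils::read.csv(file.path("results", "run", "animal_summaries.csv"))
grp <- factor(summ$group, levels = unique(summ$group))

rows <- list()
note <- function(test, variable, statistic, p, n)
  rows[[length(rows) + 1L]] <<- data.frame(test, variable, statistic,
                                           p_value = p, n)

for (v in c("mean_interpup_interval", "mean_peak_pressure")) {
  gs <- split(summ[[v]][!is.na(summ[[v]])], grp[!is.na(summ[[v]])])
  kw <- kruskal_wallis(gs)
  note("kruskal_wallis", v, kw$H, kw$p_value, sum(lengths(gs)))
  mw <- mann_whitney(gs$control, gs$combined_ko)
  note("mann_whitney_control_vs_combined", v, mw$U, mw$p_value,
       length(gs$control) + length(gs$combined_ko))
}

ctrl <- grp == "control"
late <- summ$onset_after_zt3 == "TRUE" | summ$onset_after_zt3 == TRUE
tab <- matrix(c(sum(ctrl & !late), sum(ctrl & late),
                sum(!ctrl & !late), sum(!ctrl & late)), 2, byrow = TRUE)
fe <- fisher_exact_2x2(tab)
note("fisher_exact_onset_after_zt3", "control_vs_knockout", fe$odds_ratio,
     fe$p_value, nrow(summ))

out <- do.call(rbind, rows)
utils::write.csv(out, file.path("results", "labor_stats.csv"),
                 row.names = FALSE)
cat("onset-after-ZT3 table (rows control/knockout, cols before/after):\n")
print(tab)
cat("\n")
print(out, row.names = FALSE, digits = 4)
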