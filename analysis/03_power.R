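#!/usr/bin/env Rscript
# Step 3: Monte-Carlo comparison of the two analysis routes.
#
# Three experiments, each re-simulating the study many times:
#   (a) null calibration - no injected effects; the Sidak families should
#       reject at no more than the nominal 5% familywise rate;
#   (b) broad right-horn deficit (45% at OE/NOE/MD/NCE) - both routes detect
#       it, and the litter-mean percent decrease is diluted to ~19%;
#   (c) localized deficit (45% at the right middle only) - the regime where
#       litter averaging masks the effect (<10% decrease, reduced t-test
#       power) while the positional contrast still rejects essentially
#       always.
# 200 replicates per experiment keep this step under ~1 minute; the
# acceptance script reruns (a) and (b) at 1000 and 500 replicates.

library(iupos)

reps <- 200L
dir.create("results", showWarnings = FALSE)

run <- function(tag, cfg, seed) {
  pw <- power_experiment(cfg, reps, seed = seed)
  out <- merge(pw$positional,
               pw$traditional[, c("group_label", "rejection_rate", "mean_pct_decrease")],
               by = "group_label", suffixes = c("_positional", "_traditional"))
  out$experiment <- tag
  out
}

null_cfg <- simulation_config(n_dams = c(control = 20L, exposed = 7L))
broad_cfg <- scenario_gd4_like()
local_cfg <- simulation_config(
  n_dams = c(control = 20L, GD4 = 6L),
  effects = data.frame(group_label = "GD4", horn_side = "R", position = "MD",
                       reduction = 0.45, stringsAsFactors = FALSE)
)

tab <- rbind(
  run("null", null_cfg, seed = 101),
  run("broad_right_horn", broad_cfg, seed = 102),
  run("rmd_only", local_cfg, seed = 103)
)
write.csv(tab, "results/power_table.csv", row.names = FALSE)

pick <- function(tag, side, pos) {
  tab[tab$experiment == tag & tab$horn_side == side & tab$position == pos, ]
}

null_fam <- power_experiment(null_cfg, reps, seed = 101)$familywise
cat(sprintf("Null familywise Sidak rejection: %s (nominal 0.05)\n",
            paste(sprintf("%s horn %.3f", null_fam$horn_side,
                          null_fam$familywise_rate), collapse = ", ")))

b <- pick("broad_right_horn", "R", "MD")
cat(sprintf(paste0(
  "Broad right-horn deficit: positional RMD power %.2f, traditional power %.2f,\n",
  "  litter-mean decrease %.1f%% - a deficit this wide is visible to both routes.\n"),
  b$rejection_rate_positional, b$rejection_rate_traditional, b$mean_pct_decrease))

l <- pick("rmd_only", "R", "MD")
cat(sprintf(paste0(
  "Localized RMD deficit: positional power %.2f vs traditional %.2f,\n",
  "  litter-mean decrease %.1f%% - litter averaging dilutes a one-position\n",
  "  effect below its detection threshold while the positional contrast keeps\n",
  "  near-certain power.\n"),
  l$rejection_rate_positional, l$rejection_rate_traditional, l$mean_pct_decrease))
cat("Wrote results/power_table.csv.\n")
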