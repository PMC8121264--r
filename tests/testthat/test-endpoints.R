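test_that("normalization equals fetal weight times horn count over maternal weight", {
  expect_equal(normalize_fetal_weight(2.62, 262, 6), 0.06)
  expect_equal(normalize_fetal_weight(1, 7, 7), 1.0)
  # homogeneity: doubling maternal weight halves it, doubling horn count doubles it
  base <- normalize_fetal_weight(2.5, 330, 6)
  expect_equal(normalize_fetal_weight(2.5, 660, 6), base / 2)
  expect_equal(normalize_fetal_weight(2.5, 330, 12), base * 2)
  # joint unit rescaling cancels
  expect_equal(normalize_fetal_weight(2500, 330000, 6), base)
  expect_error(normalize_fetal_weight(-1, 330, 6), "positive")
})

test_that("placental efficiency is the fetal/placental ratio on the reported scale", {
  expect_equal(placental_efficiency(2.62, 0.524), 5.0)
  expect_equal(placental_efficiency(0.7, 0.7), 1.0)
  expect_equal(placental_efficiency(2.87, 0.5), 5.74)
  expect_true(is.na(placental_efficiency(2.5, NA)))
  expect_error(placental_efficiency(2.5, -0.5), "positive")
})

test_that("percent decrease reproduces the printed summary-table convention", {
  expect_identical(percent_decrease(2.62, 2.49), 5L)
  expect_identical(percent_decrease(2.62, 2.57), 2L)
  expect_identical(percent_decrease(2.62, 2.62), 0L)
  expect_identical(percent_decrease(2.62, 2.63), 0L) # increases floor at 0
  expect_identical(percent_decrease(2.0, 1.99), 1L)  # 0.5% rounds away from zero
  # monotone in the group mean for fixed control
  g <- seq(2.0, 2.7, by = 0.05)
  expect_true(all(diff(percent_decrease(2.62, g)) <= 0))
})

test_that("traditional summary averages by litter then by group", {
  df <- rbind(
    dam_rows("d1", "control", 300, r_fetal = c(2.0, 2.0, 3.0), l_fetal = c(1.0, 2.0)),
    dam_rows("d2", "control", 300, r_fetal = rep(3.0, 3), l_fetal = rep(3.0, 2)),
    dam_rows("d3", "dosed", 300, r_fetal = rep(2.0, 3), l_fetal = rep(2.0, 2)),
    dam_rows("d4", "dosed", 300, r_fetal = rep(2.5, 2), l_fetal = rep(2.5, 3)),
    dam_rows("d5", "dosed", 300, r_fetal = c(2.2, 2.3), l_fetal = c(2.1, 2.2)) # 4 feti: dropped
  )
  trad <- traditional_summary(as_study_data(df))
  expect_equal(trad$per_dam$dam_mean_fetal_weight_g[trad$per_dam$dam_id == "d1"], 2.0)
  expect_false("d5" %in% trad$per_dam$dam_id)

  pg <- trad$per_group
  ctl <- pg[pg$group_label == "control", ]
  expect_equal(ctl$mean, 2.5)
  expect_equal(ctl$sem, 0.5) # two dams at 2.0 and 3.0: sd/sqrt(2)
  expect_equal(ctl$n_dams, 2L)
  dosed <- pg[pg$group_label == "dosed", ]
  expect_equal(dosed$mean, 2.25)
  expect_identical(dosed$pct_decrease, 10L)
  expect_true(is.na(ctl$pct_decrease))
})

test_that("undersized horns still feed the litter mean (litter rule only)", {
  df <- dam_rows("d1", "control", 300, r_fetal = rep(3.0, 5), l_fetal = rep(1.0, 3))
  trad <- traditional_summary(as_study_data(df))
  expect_equal(trad$per_dam$dam_mean_fetal_weight_g, (5 * 3 + 3 * 1) / 8)
  expect_equal(trad$per_dam$n_feti, 8L)
  # a single-dam group has undefined SEM, flagged
  expect_false(trad$per_group$sem_defined)
  expect_true(is.na(trad$per_group$sem))
})

test_that("group mean recovers the simulated control mean (Monte-Carlo consistency)", {
  cfg <- simulation_config(
    n_dams = c(control = 20L),
    horn_multipliers = c(R = 1, L = 1),
    position_multipliers = c(OE = 1, NOE = 1, MD = 1, NCE = 1, CE = 1)
  )
  ds <- simulate_study(cfg, seed = 2024)
  trad <- traditional_summary(ds)
  ctl <- trad$per_group[trad$per_group$group_label == "control", ]
  expect_lt(abs(ctl$mean - 2.62), 2 * ctl$sem + 0.02)
})

test_that("endpoint tables have one value per horn-position, minus missing placentas", {
  fw <- c(2.0, 2.1, 2.2, 2.3, 2.4)
  ds <- as_study_data(rbind(
    dam_rows("d1", "control", 300, r_fetal = rep(2.0, 5), l_fetal = fw,
             r_placental = rep(0.5, 5)), # left placentas all missing
    dam_rows("d2", "control", 310, r_fetal = fw, l_fetal = fw,
             r_placental = rep(0.5, 5), l_placental = c(0.5, NA, 0.5, 0.5, 0.5))
  ))
  obs <- collapse_positions(ds)

  norm <- compute_endpoint_table(obs, "normalized_fetal_weight")
  expect_equal(nrow(norm), 5L * 4L)
  # identical feti in a horn give five equal normalized values
  d1r <- norm$value[norm$dam_id == "d1" & norm$horn_side == "R"]
  expect_equal(d1r, rep(2.0 * 5 / 300, 5L))

  plac <- compute_endpoint_table(obs, "raw_placental_weight")
  expect_equal(nrow(plac), 5L * 4L - 5L - 1L) # d1 L horn gone; d2 L NOE gone
  expect_false(any(plac$dam_id == "d1" & plac$horn_side == "L"))

  eff <- compute_endpoint_table(obs, "placental_efficiency")
  expect_equal(nrow(eff), nrow(plac))
  expect_equal(eff$value[eff$dam_id == "d1" & eff$horn_side == "R"],
               rep(2.0 / 0.5, 5L))
})

test_that("cell summaries report mean, SEM and dam count per cell", {
  ds <- tiny_study(3, 3)
  tab <- compute_endpoint_table(collapse_positions(ds), "normalized_fetal_weight")
  sm <- summarize_cells(tab)
  expect_equal(nrow(sm), 2L * 2L * 5L) # group x side x position
  expect_equal(unique(sm$n), 3L)
  one <- sm[sm$group_label == "control" & sm$horn_side == "R" & sm$position == "OE", ]
  v <- tab$value[tab$group_label == "control" & tab$horn_side == "R" & tab$position == "OE"]
  expect_equal(one$mean, mean(v))
  expect_equal(one$sem, sd(v) / sqrt(3))
})
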