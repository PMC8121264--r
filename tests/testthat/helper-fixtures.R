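# In-code fixtures: small study tables built programmatically.

# One horn's worth of rows.
horn_rows <- function(dam_id, group, maternal, side, fetal, placental = NULL) {
  n <- length(fetal)
  if (is.null(placental)) placental <- rep(NA_real_, n)
  if (n == 0L) {
    return(data.frame(
      dam_id = character(), group_label = character(),
      maternal_gd20_weight_g = numeric(), horn_side = character(),
      fetus_index = integer(), fetal_weight_g = numeric(),
      placental_weight_g = numeric(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    dam_id = dam_id, group_label = group, maternal_gd20_weight_g = maternal,
    horn_side = side, fetus_index = seq_len(n), fetal_weight_g = fetal,
    placental_weight_g = placental, stringsAsFactors = FALSE
  )
}

# A dam with given per-horn fetal weight vectors (R then L).
dam_rows <- function(dam_id, group, maternal, r_fetal, l_fetal,
                     r_placental = NULL, l_placental = NULL) {
  rbind(
    horn_rows(dam_id, group, maternal, "R", r_fetal, r_placental),
    horn_rows(dam_id, group, maternal, "L", l_fetal, l_placental)
  )
}

# Two-group study with regular 5-feti horns; enough structure for the full
# pipeline to run.
tiny_study <- function(n_control = 3L, n_exposed = 3L, seed = 1L) {
  set.seed(seed)
  mk <- function(g, i) {
    dam_rows(sprintf("%s_%02d", g, i), g, 300,
             r_fetal = round(stats::rnorm(5, 2.6, 0.1), 3),
             l_fetal = round(stats::rnorm(5, 2.5, 0.1), 3),
             r_placental = round(stats::rnorm(5, 0.52, 0.03), 3),
             l_placental = round(stats::rnorm(5, 0.52, 0.03), 3))
  }
  df <- rbind(
    do.call(rbind, lapply(seq_len(n_control), function(i) mk("control", i))),
    do.call(rbind, lapply(seq_len(n_exposed), function(i) mk("dosed", i)))
  )
  as_study_data(df, control_label = "control")
}
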