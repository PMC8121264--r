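# Study endpoints: normalized fetal weight, raw placental weight, placental
# efficiency, traditional litter-mean summaries and percent decrease.

#' Normalize fetal weight by maternal weight and horn occupancy
#'
#' `fetal_weight / (maternal_weight / n_feti_in_horn)`, i.e. fetal weight
#' relative to the maternal grams "available" per fetus in that horn. The
#' quantity is dimensionally grams per (gram/fetus); study tables
#' conventionally print it in "g" (control values near 0.05-0.06).
#'
#' @param fetal_weight_g fetal wet weight (g), possibly a middle-position mean.
#' @param maternal_gd20_weight_g maternal body weight at GD 20 necropsy (g).
#' @param n_feti_in_horn number of feti in the fetus's horn before middle
#'   collapsing.
#' @return Normalized fetal weight (vectorised).
#' @export
normalize_fetal_weight <- function(fetal_weight_g, maternal_gd20_weight_g,
                                   n_feti_in_horn) {
  if (any(fetal_weight_g <= 0, na.rm = TRUE) ||
      any(maternal_gd20_weight_g <= 0, na.rm = TRUE) ||
      any(n_feti_in_horn <= 0, na.rm = TRUE)) {
    stop("normalize_fetal_weight() requires positive inputs")
  }
  fetal_weight_g * n_feti_in_horn / maternal_gd20_weight_g
}

#' Placental efficiency
#'
#' Ratio of raw fetal weight to raw placental weight, a proxy for placental
#' function; near-term rat values are around 5-6. Returns `NA` where the
#' placental weight is missing, so such feti drop out of placental endpoints
#' without affecting fetal-weight endpoints.
#'
#' @param fetal_weight_g fetal wet weight (g).
#' @param placental_weight_g placental wet weight (g), `NA` allowed.
#' @return Dimensionless efficiency (vectorised).
#' @export
placental_efficiency <- function(fetal_weight_g, placental_weight_g) {
  if (any(fetal_weight_g <= 0, na.rm = TRUE) ||
      any(placental_weight_g <= 0, na.rm = TRUE)) {
    stop("placental_efficiency() requires positive weights")
  }
  fetal_weight_g / placental_weight_g
}

# round() halves to even; summary tables use the conventional half-away-from-
# zero rule.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent decrease relative to control, as printed in summary tables
#'
#' `100 * (control - group) / control`, rounded to the nearest integer (halves
#' away from zero) and floored at 0: a group mean above control prints as a
#' 0% decrease, never a negative one.
#'
#' @param control_mean control group mean (> 0).
#' @param group_mean treated group mean.
#' @return Integer percent decrease.
#' @export
percent_decrease <- function(control_mean, group_mean) {
  stopifnot(all(control_mean > 0))
  pct <- 100 * (control_mean - group_mean) / control_mean
  as.integer(pmax(0, round_half_away(pct)))
}

#' Traditional litter-mean analysis of raw fetal weight
#'
#' The classical DART summary: average raw fetal weight per litter, then per
#' treatment group. Only the litter-size rule applies here (litters with fewer
#' than five feti are dropped); undersized horns still contribute their feti
#' to the litter mean, since this summary predates any positional
#' organisation.
#'
#' @param x a `study_data` object.
#' @param control_label control group label; defaults to the attribute on `x`.
#' @return List with `per_dam` (dam-level means) and `per_group` (group mean,
#'   SEM, n dams, and integer percent decrease vs control; SEM is `NA` and
#'   flagged when a group has fewer than two dams).
#' @export
traditional_summary <- function(x, control_label = attr(x, "control_label")) {
  stopifnot(is.data.frame(x))
  if (is.null(control_label)) control_label <- "control"
  df <- as.data.frame(x)
  litter_sizes <- tapply(df$fetal_weight_g, df$dam_id, length)
  keep_dams <- names(litter_sizes)[litter_sizes >= 5L]
  df <- df[df$dam_id %in% keep_dams, , drop = FALSE]

  per_dam <- do.call(rbind, lapply(split(df, df$dam_id), function(dd) {
    data.frame(dam_id = dd$dam_id[1L], group_label = dd$group_label[1L],
               n_feti = nrow(dd), dam_mean_fetal_weight_g = mean(dd$fetal_weight_g),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_dam)) {
    per_dam <- data.frame(dam_id = character(), group_label = character(),
                          n_feti = integer(), dam_mean_fetal_weight_g = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(per_dam) <- NULL

  per_group <- do.call(rbind, lapply(split(per_dam, per_dam$group_label), function(g) {
    n <- nrow(g)
    m <- mean(g$dam_mean_fetal_weight_g)
    sem <- if (n >= 2L) stats::sd(g$dam_mean_fetal_weight_g) / sqrt(n) else NA_real_
    data.frame(group_label = g$group_label[1L], mean = m, sem = sem, n_dams = n,
               sem_defined = n >= 2L, stringsAsFactors = FALSE)
  }))
  if (is.null(per_group)) {
    per_group <- data.frame(group_label = character(), mean = numeric(),
                            sem = numeric(), n_dams = integer(),
                            sem_defined = logical(), stringsAsFactors = FALSE)
  }
  rownames(per_group) <- NULL
  if (control_label %in% per_group$group_label) {
    cm <- per_group$mean[per_group$group_label == control_label]
    per_group$pct_decrease <- percent_decrease(cm, per_group$mean)
    per_group$pct_decrease[per_group$group_label == control_label] <- NA_integer_
  } else {
    per_group$pct_decrease <- NA_integer_
  }
  list(per_dam = per_dam, per_group = per_group, control_label = control_label)
}

ENDPOINTS <- c("normalized_fetal_weight", "raw_placental_weight", "placental_efficiency")

#' Tidy endpoint table from positional observations
#'
#' Produces one value per dam x horn side x position for a chosen endpoint:
#' the maternal/litter-normalized fetal weight, the raw placental weight, or
#' the placental efficiency (all from the collapsed positional observations of
#' [collapse_positions()]). Placental endpoints drop observations whose
#' placental data are entirely missing.
#'
#' @param obs positional observation table from [collapse_positions()].
#' @param endpoint one of `"normalized_fetal_weight"`,
#'   `"raw_placental_weight"`, `"placental_efficiency"`.
#' @return Data frame `dam_id, group_label, horn_side, position, endpoint,
#'   value, n_feti_in_horn`.
#' @export
compute_endpoint_table <- function(obs, endpoint = ENDPOINTS) {
  endpoint <- match.arg(endpoint)
  value <- switch(endpoint,
    normalized_fetal_weight = normalize_fetal_weight(
      obs$raw_fetal_weight_g, obs$maternal_gd20_weight_g, obs$n_feti_in_horn
    ),
    raw_placental_weight = obs$raw_placental_weight_g,
    placental_efficiency = obs$raw_efficiency
  )
  out <- data.frame(
    dam_id = obs$dam_id, group_label = obs$group_label,
    horn_side = obs$horn_side, position = obs$position,
    endpoint = rep(endpoint, nrow(obs)), value = value,
    n_feti_in_horn = obs$n_feti_in_horn, stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean and SEM per analysis cell
#'
#' Summarises an endpoint table as mean, SEM and n across the dams
#' contributing to each group x horn side x position cell, the form in which
#' positional results are reported (mean +/- SEM).
#'
#' @param tab endpoint table, typically after [screen_endpoint_table()].
#' @return Data frame with one row per cell.
#' @export
summarize_cells <- function(tab) {
  if (nrow(tab) == 0L) {
    return(data.frame(group_label = character(), horn_side = character(),
                      position = character(), mean = numeric(), sem = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  cells <- split(tab, paste(tab$group_label, tab$horn_side, tab$position, sep = "\r"))
  out <- do.call(rbind, lapply(cells, function(cc) {
    n <- nrow(cc)
    data.frame(
      group_label = cc$group_label[1L], horn_side = cc$horn_side[1L],
      position = cc$position[1L], mean = mean(cc$value),
      sem = if (n >= 2L) stats::sd(cc$value) / sqrt(n) else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$group_label, out$horn_side,
                   match(out$position, position_levels())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
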