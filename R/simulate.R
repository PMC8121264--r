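# Synthetic litter generator and Monte-Carlo power experiments.

#' Configuration for the synthetic-litter generator
#'
#' Defines the full data-generating law for a simulated study: group sizes,
#' maternal weight law, per-horn litter-size law, baseline fetal weight,
#' horn- and position-specific multipliers, a (group, side, position) effect
#' matrix of fractional reductions, noise levels, a placental weight law and
#' the maternal/litter coupling of raw fetal weight.
#'
#' Defaults emulate a near-term Sprague-Dawley study: 20 control and 7
#' exposed dams, maternal GD 20 weight 330 +/- 20 g, per-horn litter sizes
#' uniform on 4..8, baseline fetal weight 2.62 g with 0.15 g fetus-level
#' noise, a slight right-horn advantage (R 1.02 vs L 0.98) and an elevated
#' middle position (MD 1.05), and placental weights 0.52 +/- 0.05 g so that
#' placental efficiency sits near 5.
#'
#' `maternal_litter_coupling` (kappa) scales raw fetal weight by
#' `((M / n_horn) / E[M / n_horn])^kappa`, a mean-preserving factor that makes
#' heavier dams and emptier horns produce heavier feti - the structure the
#' maternal/litter normalization is designed to remove. `kappa = 1` is the
#' exact proportional model implied by the normalization; `kappa = 0` switches
#' the coupling off. The default 0.35 reproduces a between-dam SD of litter
#' mean weight near 0.18 g, the dispersion implied by a control SEM of 0.04 g
#' over 20 dams.
#'
#' @param n_dams named integer vector of dams per group; must include
#'   `control_label`.
#' @param control_label reference group label.
#' @param maternal_mean_g,maternal_sd_g maternal GD 20 weight law (normal).
#' @param litter_sizes integer support of per-horn litter sizes.
#' @param litter_probs sampling probabilities over `litter_sizes` (uniform by
#'   default).
#' @param baseline_fetal_mean_g baseline fetal weight (g).
#' @param horn_multipliers named multipliers for sides `R` and `L`.
#' @param position_multipliers named multipliers for the five positions.
#' @param effects data frame `group_label, horn_side, position, reduction`
#'   with fractional reductions in `[0, 1)`; empty by default.
#' @param fetal_noise_sd_g fetus-level normal noise sd (g).
#' @param min_fetal_weight_g truncation floor preventing nonphysical weights.
#' @param placental_mean_g,placental_sd_g placental weight law (normal,
#'   floored at 0.1 g).
#' @param placenta_fetal_corr correlation between fetal and placental noise
#'   (default 0: independent, matching the observation that placental weight
#'   was unaffected where fetal weight fell).
#' @param missing_placenta_prob probability a placental weight is unrecorded.
#' @param maternal_litter_coupling exponent kappa described above.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_dams = c(control = 20L, exposed = 7L),
                              control_label = "control",
                              maternal_mean_g = 330, maternal_sd_g = 20,
                              litter_sizes = 4:8, litter_probs = NULL,
                              baseline_fetal_mean_g = 2.62,
                              horn_multipliers = c(R = 1.02, L = 0.98),
                              position_multipliers = c(OE = 0.98, NOE = 0.99,
                                                       MD = 1.05, NCE = 1.00,
                                                       CE = 0.99),
                              effects = NULL,
                              fetal_noise_sd_g = 0.15,
                              min_fetal_weight_g = 0.5,
                              placental_mean_g = 0.52, placental_sd_g = 0.05,
                              placenta_fetal_corr = 0,
                              missing_placenta_prob = 0,
                              maternal_litter_coupling = 0.35) {
  if (is.null(litter_probs)) litter_probs <- rep(1 / length(litter_sizes), length(litter_sizes))
  if (is.null(effects)) {
    effects <- data.frame(group_label = character(), horn_side = character(),
                          position = character(), reduction = numeric(),
                          stringsAsFactors = FALSE)
  }
  cfg <- structure(list(
    n_dams = n_dams, control_label = control_label,
    maternal_mean_g = maternal_mean_g, maternal_sd_g = maternal_sd_g,
    litter_sizes = as.integer(litter_sizes), litter_probs = litter_probs,
    baseline_fetal_mean_g = baseline_fetal_mean_g,
    horn_multipliers = horn_multipliers,
    position_multipliers = position_multipliers,
    effects = effects,
    fetal_noise_sd_g = fetal_noise_sd_g,
    min_fetal_weight_g = min_fetal_weight_g,
    placental_mean_g = placental_mean_g, placental_sd_g = placental_sd_g,
    placenta_fetal_corr = placenta_fetal_corr,
    missing_placenta_prob = missing_placenta_prob,
    maternal_litter_coupling = maternal_litter_coupling
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly; errors on any violated constraint.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg)
  if (is.null(names(cfg$n_dams)) || any(names(cfg$n_dams) == "")) fail("n_dams must be named by group")
  if (!(cfg$control_label %in% names(cfg$n_dams))) fail("control_label must appear in n_dams")
  if (any(cfg$n_dams < 0)) fail("n_dams must be >= 0")
  if (!all(is.finite(c(cfg$maternal_mean_g, cfg$maternal_sd_g))) ||
      cfg$maternal_mean_g <= 0 || cfg$maternal_sd_g < 0) fail("maternal weight law")
  if (length(cfg$litter_sizes) == 0L || any(cfg$litter_sizes < 1L)) fail("litter sizes must be >= 1")
  if (length(cfg$litter_probs) != length(cfg$litter_sizes) ||
      any(cfg$litter_probs < 0) || sum(cfg$litter_probs) <= 0) fail("litter size probabilities")
  if (cfg$baseline_fetal_mean_g <= 0) fail("baseline fetal weight must be > 0")
  if (!all(HORN_SIDES %in% names(cfg$horn_multipliers)) ||
      any(cfg$horn_multipliers <= 0)) fail("horn multipliers must be > 0 for L and R")
  if (!all(position_levels() %in% names(cfg$position_multipliers)) ||
      any(cfg$position_multipliers <= 0)) fail("position multipliers must be > 0 for all 5 positions")
  ef <- cfg$effects
  if (!all(c("group_label", "horn_side", "position", "reduction") %in% names(ef))) {
    fail("effects must have columns group_label, horn_side, position, reduction")
  }
  if (nrow(ef) > 0L) {
    if (any(!(ef$horn_side %in% HORN_SIDES))) fail("effects horn_side")
    if (any(!(ef$position %in% position_levels()))) fail("effects position")
    if (any(ef$reduction < 0 | ef$reduction >= 1)) fail("reductions must be in [0, 1)")
  }
  if (cfg$fetal_noise_sd_g < 0 || cfg$placental_sd_g < 0) fail("noise sds must be >= 0")
  if (cfg$min_fetal_weight_g < 0) fail("min fetal weight")
  if (abs(cfg$placenta_fetal_corr) > 1) fail("placenta_fetal_corr must be in [-1, 1]")
  if (cfg$missing_placenta_prob < 0 || cfg$missing_placenta_prob > 1) fail("missing_placenta_prob")
  if (cfg$maternal_litter_coupling < 0) fail("maternal_litter_coupling must be >= 0")
  invisible(cfg)
}

#' Scenario with a broad right-horn growth deficit in one exposed group
#'
#' Returns a configuration whose effect matrix imposes a fractional reduction
#' (default 0.45) at the right-horn `OE`, `NOE`, `MD` and `NCE` positions of
#' one exposed group and nothing elsewhere - the pattern of an early-gestation
#' exposure that spares only the right cervical end and the whole left horn.
#' Group sizes default to 6 exposed vs 20 control dams.
#'
#' @param config base configuration to modify.
#' @param group label of the affected exposed group.
#' @param reduction fractional reduction in `[0, 1)` applied at the four
#'   right-horn positions.
#' @return A `sim_config`.
#' @export
scenario_gd4_like <- function(config = NULL, group = "GD4", reduction = 0.45) {
  if (is.null(config)) {
    config <- simulation_config(n_dams = stats::setNames(c(20L, 6L), c("control", group)))
  }
  if (!(group %in% names(config$n_dams))) {
    config$n_dams <- c(config$n_dams, stats::setNames(6L, group))
  }
  config$effects <- data.frame(
    group_label = group, horn_side = "R",
    position = c("OE", "NOE", "MD", "NCE"),
    reduction = reduction, stringsAsFactors = FALSE
  )
  validate_sim_config(config)
  config
}

# E[1/n] under the configured litter-size law; used to centre the
# maternal/litter coupling factor so that it is mean-preserving.
mean_inverse_litter <- function(cfg) {
  p <- cfg$litter_probs / sum(cfg$litter_probs)
  sum(p / cfg$litter_sizes)
}

#' Simulate a study dataset
#'
#' Draws a full per-fetus necropsy table under a [simulation_config()]: per
#' dam a maternal weight and two per-horn litter sizes; per fetus a position
#' (via the positional mapping run in reverse), a fetal weight
#' `baseline x horn x position x (1 - reduction) x coupling + noise`
#' (truncated below at the configured floor) and a placental weight drawn
#' around the placental mean with optional correlation to the fetal noise.
#' Deterministic for a fixed seed.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return A validated `study_data` object.
#' @export
simulate_study <- function(config, seed) {
  validate_sim_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))

  draw_litter <- function(k) {
    if (length(config$litter_sizes) == 1L) rep(config$litter_sizes, k)
    else sample(config$litter_sizes, k, replace = TRUE, prob = config$litter_probs)
  }
  ef_key <- with(config$effects, paste(group_label, horn_side, position, sep = "\r"))
  kappa <- config$maternal_litter_coupling
  couple_scale <- config$maternal_mean_g * mean_inverse_litter(config)

  rho <- config$placenta_fetal_corr
  acc <- list(dam_id = list(), group_label = list(), M = list(), side = list(),
              idx = list(), fw = list(), pw = list())
  k <- 0L
  for (g in names(config$n_dams)) {
    ng <- config$n_dams[[g]]
    if (ng == 0L) next
    for (i in seq_len(ng)) {
      dam <- sprintf("%s_d%02d", g, i)
      M <- max(50, stats::rnorm(1L, config$maternal_mean_g, config$maternal_sd_g))
      n_horn <- draw_litter(2L)
      for (si in seq_along(HORN_SIDES)) {
        s <- HORN_SIDES[[si]]
        n <- n_horn[[si]]
        idx <- seq_len(n)
        pos <- position_of_index(idx, n)
        red <- config$effects$reduction[match(paste(g, s, pos, sep = "\r"), ef_key)]
        red[is.na(red)] <- 0
        couple <- if (kappa == 0) 1 else ((M / n) / couple_scale)^kappa
        mu <- config$baseline_fetal_mean_g * config$horn_multipliers[[s]] *
          config$position_multipliers[pos] * (1 - red) * couple
        z_f <- stats::rnorm(n)
        fw <- pmax(config$min_fetal_weight_g, mu + config$fetal_noise_sd_g * z_f)
        z_p <- rho * z_f + sqrt(1 - rho^2) * stats::rnorm(n)
        pw <- pmax(0.1, config$placental_mean_g + config$placental_sd_g * z_p)
        if (config$missing_placenta_prob > 0) {
          pw[stats::runif(n) < config$missing_placenta_prob] <- NA_real_
        }
        k <- k + 1L
        acc$dam_id[[k]] <- rep(dam, n); acc$group_label[[k]] <- rep(g, n)
        acc$M[[k]] <- rep(M, n); acc$side[[k]] <- rep(s, n)
        acc$idx[[k]] <- idx; acc$fw[[k]] <- unname(fw); acc$pw[[k]] <- unname(pw)
      }
    }
  }
  if (k == 0L) {
    df <- data.frame(dam_id = character(), group_label = character(),
                     maternal_gd20_weight_g = numeric(), horn_side = character(),
                     fetus_index = integer(), fetal_weight_g = numeric(),
                     placental_weight_g = numeric(), stringsAsFactors = FALSE)
    out <- structure(df, control_label = config$control_label,
                     class = c("study_data", "data.frame"))
    return(out)
  }
  df <- data.frame(
    dam_id = unlist(acc$dam_id), group_label = unlist(acc$group_label),
    maternal_gd20_weight_g = unlist(acc$M), horn_side = unlist(acc$side),
    fetus_index = unlist(acc$idx), fetal_weight_g = unlist(acc$fw),
    placental_weight_g = unlist(acc$pw), stringsAsFactors = FALSE
  )
  as_study_data(df, control_label = config$control_label)
}

# One simulated replicate pushed through both analysis routes. Returns the
# traditional per-group test and the positional exposed-vs-control Sidak
# contrasts on the normalized fetal-weight endpoint.
replicate_comparison <- function(config, seed, alpha = 0.05) {
  ds <- simulate_study(config, seed)
  control <- config$control_label

  trad <- traditional_summary(ds, control_label = control)
  groups <- setdiff(names(config$n_dams), control)
  ctl_means <- trad$per_dam$dam_mean_fetal_weight_g[trad$per_dam$group_label == control]
  trad_rows <- do.call(rbind, lapply(groups, function(g) {
    gm <- trad$per_dam$dam_mean_fetal_weight_g[trad$per_dam$group_label == g]
    scr_c <- grubbs_screen(ctl_means, alpha)$values
    scr_g <- grubbs_screen(gm, alpha)$values
    if (length(scr_g) < 2L || length(scr_c) < 2L) {
      return(data.frame(group_label = g, p = NA_real_, pct_decrease = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    tt <- students_t_test(scr_g, scr_c)
    data.frame(group_label = g, p = tt$p_value,
               pct_decrease = percent_decrease(mean(scr_c), mean(scr_g)),
               stringsAsFactors = FALSE)
  }))

  inc <- apply_inclusion_criteria(ds)
  obs <- collapse_positions(inc$data)
  tab <- compute_endpoint_table(obs, "normalized_fetal_weight")
  tab <- screen_endpoint_table(tab, alpha)$data

  pos_rows <- list()
  for (g in groups) {
    for (s in HORN_SIDES) {
      sub <- tab[tab$group_label %in% c(g, control) & tab$horn_side == s, , drop = FALSE]
      res <- tryCatch({
        sub$group_label <- factor(sub$group_label, levels = c(g, control))
        fit <- two_way_anova(sub, "value", "group_label", "position")
        sidak_pairwise(fit, "group_label", "position", alpha)
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(res) || nrow(res) == 0L) next
      res$group_label <- g
      res$horn_side <- s
      pos_rows[[length(pos_rows) + 1L]] <- res
    }
  }
  positional <- if (length(pos_rows) > 0L) do.call(rbind, pos_rows) else NULL
  list(traditional = trad_rows, positional = positional)
}

#' Monte-Carlo power experiment: positional vs traditional analysis
#'
#' Repeatedly simulates a study under `config`, runs the traditional
#' litter-mean Student's t-test and the positional pipeline (inclusion
#' criteria, position collapse, normalization, per-cell Grubbs, exposed vs
#' control x position ANOVA with Sidak contrasts), and tabulates rejection
#' frequencies at `alpha`.
#'
#' @param config a `sim_config`.
#' @param n_replicates number of simulated studies (`>= 1`).
#' @param seed integer seed; per-replicate seeds are derived from it, so the
#'   whole table is reproducible.
#' @param alpha significance level.
#' @return List with `traditional` (per exposed group: rejection rate and mean
#'   percent decrease), `positional` (per group x horn side x position:
#'   rejection rate, mean Sidak p, mean cell means), `familywise` (per
#'   group x side: frequency of any Sidak contrast in the family rejecting)
#'   and `n_replicates`.
#' @export
power_experiment <- function(config, n_replicates, seed, alpha = 0.05) {
  stopifnot(n_replicates >= 1L)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  trad_all <- list(); pos_all <- list()
  for (r in seq_len(n_replicates)) {
    rep_res <- replicate_comparison(config, seeds[[r]], alpha)
    tr <- rep_res$traditional; tr$replicate <- r
    trad_all[[r]] <- tr
    if (!is.null(rep_res$positional)) {
      po <- rep_res$positional; po$replicate <- r
      pos_all[[length(pos_all) + 1L]] <- po
    }
  }
  trad <- do.call(rbind, trad_all)
  pos <- if (length(pos_all) > 0L) do.call(rbind, pos_all) else NULL

  traditional <- do.call(rbind, lapply(split(trad, trad$group_label), function(g) {
    ok <- !is.na(g$p)
    data.frame(group_label = g$group_label[1L],
               rejection_rate = mean(g$p[ok] < alpha),
               mean_pct_decrease = mean(g$pct_decrease[ok]),
               n_effective = sum(ok), n_reps = n_replicates,
               stringsAsFactors = FALSE)
  }))
  rownames(traditional) <- NULL

  positional <- NULL
  familywise <- NULL
  if (!is.null(pos)) {
    key <- paste(pos$group_label, pos$horn_side, pos$within_level, sep = "\r")
    positional <- do.call(rbind, lapply(split(pos, key), function(cc) {
      ok <- !is.na(cc$sidak_p)
      data.frame(group_label = cc$group_label[1L], horn_side = cc$horn_side[1L],
                 position = cc$within_level[1L],
                 rejection_rate = mean(cc$sidak_p[ok] < alpha),
                 mean_sidak_p = mean(cc$sidak_p[ok]),
                 mean_exposed = mean(cc$mean_1[ok]), mean_control = mean(cc$mean_2[ok]),
                 n_effective = sum(ok), n_reps = n_replicates,
                 stringsAsFactors = FALSE)
    }))
    rownames(positional) <- NULL
    positional <- positional[order(positional$group_label, positional$horn_side,
                                   match(positional$position, position_levels())), ,
                             drop = FALSE]
    rownames(positional) <- NULL

    fam_key <- paste(pos$group_label, pos$horn_side, pos$replicate, sep = "\r")
    fam_min <- do.call(rbind, lapply(split(pos, fam_key), function(ff) {
      data.frame(group_label = ff$group_label[1L], horn_side = ff$horn_side[1L],
                 any_reject = any(ff$sidak_p < alpha, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    familywise <- do.call(rbind, lapply(
      split(fam_min, paste(fam_min$group_label, fam_min$horn_side, sep = "\r")),
      function(ff) data.frame(group_label = ff$group_label[1L],
                              horn_side = ff$horn_side[1L],
                              familywise_rate = mean(ff$any_reject),
                              n_families = nrow(ff), stringsAsFactors = FALSE)
    ))
    rownames(familywise) <- NULL
  }

  list(traditional = traditional, positional = positional,
       familywise = familywise, n_replicates = n_replicates, alpha = alpha,
       details = list(traditional = trad, positional = pos))
}
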