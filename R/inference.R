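# Statistical comparisons: pooled-variance t-test, Type-III two-factor ANOVA,
# Sidak-adjusted pairwise contrasts, Cohen's d.

#' Pooled-variance (classic Student) two-sample t-test
#'
#' Two-sided Student's t-test with pooled variance and
#' `df = n_a + n_b - 2`, the test used for the traditional litter-mean
#' comparison of each exposed group against control.
#'
#' @param sample_a,sample_b numeric vectors, each with at least two values.
#' @return List with `t_statistic`, `df`, `p_value`, `mean_difference`
#'   (`mean(a) - mean(b)`) and the two group means.
#' @export
students_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("students_t_test() requires at least 2 observations per sample")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  list(
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_difference = mean(sample_a) - mean(sample_b),
    mean_a = mean(sample_a), mean_b = mean(sample_b),
    n_a = length(sample_a), n_b = length(sample_b)
  )
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pooled`, pooling the sample variances with
#' `n - 1` weights. Positive `d` means sample A exceeds sample B.
#'
#' @param sample_a,sample_b numeric vectors, each with at least two values.
#' @return List with `cohens_d` (NA with a flag if the pooled sd is zero) and
#'   the pooled sd.
#' @export
cohens_d <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) stop("cohens_d() requires at least 2 observations per sample")
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) / (na + nb - 2)
  sp <- sqrt(sp2)
  if (sp == 0) {
    return(list(cohens_d = NA_real_, pooled_sd = 0, defined = FALSE))
  }
  list(cohens_d = (mean(sample_a) - mean(sample_b)) / sp, pooled_sd = sp, defined = TRUE)
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons.
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m family size (positive integer).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  1 - (1 - p)^m
}

#' Two-factor ANOVA with Type-III sums of squares
#'
#' Fits the cell-means model `value ~ A * B` and computes Type-III sums of
#' squares by model comparison: each term's SS is the increase in residual SS
#' when that term's columns are dropped from the full sum-to-zero-coded design
#' matrix. For balanced data this coincides with the textbook two-way
#' decomposition; for unbalanced data it matches the Type-III convention of
#' standard graphing/statistics software. `F = MS_term / MS_residual` with p
#' from the F distribution.
#'
#' @param data data frame containing the response and both factors.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (each `>= 2`
#'   levels; every cell must be non-empty and the residual df positive).
#' @return A `two_way_anova` object: `table` (source, df, ss, ms, f, p),
#'   `cell_means`, `ms_residual`, `df_residual`, level sets, and a
#'   `no_variance` flag for the degenerate all-constant input, in which case F
#'   and p are `NA`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  y <- data[[response]]
  stopifnot(is.numeric(y), !anyNA(y))
  A <- droplevels(factor(data[[factor_a]]))
  B <- droplevels(factor(data[[factor_b]]))
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2L || b < 2L) stop("two_way_anova() requires >= 2 levels per factor")
  counts <- table(A, B)
  if (any(counts == 0L)) {
    empty <- which(counts == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: ", levels(A)[empty[1L]], " x ", levels(B)[empty[2L]])
  }
  N <- length(y)
  df_resid <- N - a * b
  if (df_resid < 1L) stop("residual degrees of freedom must be >= 1")

  d <- data.frame(y = y, A = A, B = B)
  X <- stats::model.matrix(~ A * B, d,
                           contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  asgn <- attr(X, "assign") # 0 = intercept, 1 = A, 2 = B, 3 = A:B
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  rss_full <- rss(X)
  ss_term <- vapply(1:3, function(k) rss(X[, asgn != k, drop = FALSE]) - rss_full,
                    numeric(1L))
  ss_term <- pmax(ss_term, 0) # guard tiny negative values from round-off
  ss_total <- sum((y - mean(y))^2)
  no_variance <- ss_total < 1e-12

  dfs <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L), df_resid)
  ss <- c(ss_term, rss_full)
  ms <- ss / dfs
  if (no_variance) {
    f <- rep(NA_real_, 3L); p <- rep(NA_real_, 3L)
  } else {
    f <- ms[1:3] / ms[4L]
    p <- stats::pf(f, dfs[1:3], df_resid, lower.tail = FALSE)
  }
  tab <- data.frame(
    source = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residual"),
    df = dfs, ss = ss, ms = ms, f = c(f, NA_real_), p = c(p, NA_real_),
    stringsAsFactors = FALSE
  )

  agg_mean <- tapply(y, list(A, B), mean)
  agg_n <- table(A, B)
  cell_means <- do.call(rbind, lapply(levels(A), function(la) {
    data.frame(a = la, b = levels(B), mean = agg_mean[la, levels(B)],
               n = as.integer(agg_n[la, levels(B)]), stringsAsFactors = FALSE)
  }))
  names(cell_means)[1:2] <- c(factor_a, factor_b)
  rownames(cell_means) <- NULL

  structure(list(
    table = tab, cell_means = cell_means,
    ms_residual = ms[4L], df_residual = df_resid,
    factor_a = factor_a, factor_b = factor_b,
    levels_a = levels(A), levels_b = levels(B),
    n = N, no_variance = no_variance, ss_total = ss_total
  ), class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat(sprintf("Two-factor ANOVA (Type III): %s x %s, N = %d\n",
              x$factor_a, x$factor_b, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sidak-adjusted pairwise contrasts from a two-factor ANOVA
#'
#' For each level of `within_factor`, compares the two levels of
#' `compare_factor` with
#' `t = (m1 - m2) / sqrt(MS_residual * (1/n1 + 1/n2))` on the ANOVA's residual
#' degrees of freedom; raw two-sided p-values are Sidak-adjusted with family
#' size `m` equal to the number of `within_factor` levels (one family per
#' ANOVA). A contrast with an empty cell is skipped with a warning; on a
#' no-variance fit all p-values are `NA`.
#'
#' @param fit a `two_way_anova` object.
#' @param compare_factor name of the factor with exactly two levels to compare.
#' @param within_factor name of the factor whose levels index the family.
#' @param alpha significance level for the `significant` flag.
#' @return Data frame with one row per within-factor level: means, ns,
#'   `mean_diff` (first minus second compare level), `t`, `df`, `raw_p`,
#'   `sidak_p`, `significant`.
#' @export
sidak_pairwise <- function(fit, compare_factor, within_factor, alpha = 0.05) {
  stopifnot(inherits(fit, "two_way_anova"))
  stopifnot(compare_factor %in% c(fit$factor_a, fit$factor_b),
            within_factor %in% c(fit$factor_a, fit$factor_b),
            compare_factor != within_factor)
  cmp_levels <- if (compare_factor == fit$factor_a) fit$levels_a else fit$levels_b
  win_levels <- if (within_factor == fit$factor_a) fit$levels_a else fit$levels_b
  if (length(cmp_levels) != 2L) {
    stop("sidak_pairwise() requires the compare factor to have exactly 2 levels")
  }
  m <- length(win_levels)
  cm <- fit$cell_means
  rows <- lapply(win_levels, function(w) {
    c1 <- cm[cm[[compare_factor]] == cmp_levels[1L] & cm[[within_factor]] == w, ]
    c2 <- cm[cm[[compare_factor]] == cmp_levels[2L] & cm[[within_factor]] == w, ]
    if (nrow(c1) == 0L || c1$n == 0L || nrow(c2) == 0L || c2$n == 0L) {
      warning("contrast skipped at ", within_factor, " = ", w, ": empty cell")
      return(NULL)
    }
    diff <- c1$mean - c2$mean
    if (fit$no_variance || fit$ms_residual <= 0) {
      t <- NA_real_; raw_p <- NA_real_; sid <- NA_real_
    } else {
      se <- sqrt(fit$ms_residual * (1 / c1$n + 1 / c2$n))
      t <- diff / se
      raw_p <- 2 * stats::pt(abs(t), fit$df_residual, lower.tail = FALSE)
      sid <- sidak_adjust(raw_p, m)
    }
    data.frame(
      within_level = w, level_1 = cmp_levels[1L], level_2 = cmp_levels[2L],
      mean_1 = c1$mean, mean_2 = c2$mean, n_1 = c1$n, n_2 = c2$n,
      mean_diff = diff, t = t, df = fit$df_residual,
      raw_p = raw_p, sidak_p = sid, m = m,
      significant = !is.na(sid) & sid < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(within_level = character(), level_1 = character(),
                      level_2 = character(), mean_1 = numeric(), mean_2 = numeric(),
                      n_1 = integer(), n_2 = integer(), mean_diff = numeric(),
                      t = numeric(), df = numeric(), raw_p = numeric(),
                      sidak_p = numeric(), m = integer(), significant = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Layered positional comparisons for one endpoint
#'
#' Reproduces the layered analysis structure on a screened endpoint table:
#' (a) within each group, a horn side x position ANOVA with Sidak contrasts of
#' right vs left at each position, plus the marginal horn-side effect and an
#' alternative pooled t-test of all right vs left values; (b) for each exposed
#' group and each horn side, a group-vs-control x position ANOVA with Sidak
#' contrasts of exposed vs control at each position; (c) Cohen's d for every
#' contrast.
#'
#' @param tab endpoint table (post-Grubbs), from [compute_endpoint_table()]
#'   and [screen_endpoint_table()].
#' @param control_label label of the reference group in `tab`.
#' @param alpha significance level.
#' @return List with `within_group` (per group: `anova`, `contrasts`,
#'   `horn_side_p`, `horn_t_test`), `vs_control` (per exposed group, per side:
#'   `anova`, `contrasts`), and `contrast_table`, a tidy data frame of all
#'   pairwise contrasts with effect sizes.
#' @export
run_positional_analyses <- function(tab, control_label, alpha = 0.05) {
  stopifnot(control_label %in% tab$group_label)
  groups <- unique(tab$group_label)
  exposed <- setdiff(groups, control_label)

  safe <- function(expr) tryCatch(expr, error = function(e) e)
  add_d <- function(contrasts, sub, compare_factor, within_factor) {
    if (nrow(contrasts) == 0L) return(contrasts)
    contrasts$cohens_d <- vapply(seq_len(nrow(contrasts)), function(i) {
      v1 <- sub$value[sub[[compare_factor]] == contrasts$level_1[i] &
                        sub[[within_factor]] == contrasts$within_level[i]]
      v2 <- sub$value[sub[[compare_factor]] == contrasts$level_2[i] &
                        sub[[within_factor]] == contrasts$within_level[i]]
      if (length(v1) < 2L || length(v2) < 2L) return(NA_real_)
      cohens_d(v1, v2)$cohens_d
    }, numeric(1L))
    contrasts
  }

  within_group <- list()
  for (g in groups) {
    sub <- tab[tab$group_label == g, , drop = FALSE]
    fit <- safe(two_way_anova(sub, "value", "horn_side", "position"))
    if (inherits(fit, "error")) {
      within_group[[g]] <- list(anova = NULL, contrasts = NULL,
                                horn_side_p = NA_real_, horn_t_test = NULL,
                                error = conditionMessage(fit))
      next
    }
    ctr <- add_d(sidak_pairwise(fit, "horn_side", "position", alpha), sub,
                 "horn_side", "position")
    r <- sub$value[sub$horn_side == "R"]
    l <- sub$value[sub$horn_side == "L"]
    tt <- if (length(r) >= 2L && length(l) >= 2L) students_t_test(r, l) else NULL
    within_group[[g]] <- list(
      anova = fit, contrasts = ctr,
      horn_side_p = fit$table$p[fit$table$source == "horn_side"],
      horn_t_test = tt
    )
  }

  vs_control <- list()
  for (g in exposed) {
    per_side <- list()
    for (s in HORN_SIDES) {
      sub <- tab[tab$group_label %in% c(g, control_label) & tab$horn_side == s, ,
                 drop = FALSE]
      # order factor levels exposed-first so mean_diff = exposed - control
      fit <- safe({
        sub2 <- sub
        sub2$group_label <- factor(sub2$group_label, levels = c(g, control_label))
        two_way_anova(sub2, "value", "group_label", "position")
      })
      if (inherits(fit, "error")) {
        per_side[[s]] <- list(anova = NULL, contrasts = NULL,
                              error = conditionMessage(fit))
        next
      }
      ctr <- add_d(sidak_pairwise(fit, "group_label", "position", alpha), sub,
                   "group_label", "position")
      per_side[[s]] <- list(anova = fit, contrasts = ctr)
    }
    vs_control[[g]] <- per_side
  }

  rows <- list()
  for (g in names(within_group)) {
    ctr <- within_group[[g]]$contrasts
    if (!is.null(ctr) && nrow(ctr) > 0L) {
      ctr$analysis <- "horn_within_group"; ctr$group_label <- g; ctr$horn_side <- NA_character_
      ctr$position <- ctr$within_level
      rows[[length(rows) + 1L]] <- ctr
    }
  }
  for (g in names(vs_control)) {
    for (s in names(vs_control[[g]])) {
      ctr <- vs_control[[g]][[s]]$contrasts
      if (!is.null(ctr) && nrow(ctr) > 0L) {
        ctr$analysis <- "group_vs_control"; ctr$group_label <- g; ctr$horn_side <- s
        ctr$position <- ctr$within_level
        rows[[length(rows) + 1L]] <- ctr
      }
    }
  }
  contrast_table <- if (length(rows) > 0L) do.call(rbind, rows) else NULL

  list(within_group = within_group, vs_control = vs_control,
       contrast_table = contrast_table, alpha = alpha,
       control_label = control_label)
}
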