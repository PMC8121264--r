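# Inclusion criteria and Grubbs outlier screening.

#' Apply litter and horn inclusion criteria
#'
#' A litter with fewer than five feti in total is excluded entirely; within
#' retained litters, any uterine horn with fewer than five feti is excluded
#' individually (a horn absent from the records counts as a horn of zero
#' feti). An auditable per-group report is returned in the `k/N` format used
#' for study summary tables, with the number of dams in the group as the
#' denominator.
#'
#' @param x a `study_data` object.
#' @return List with elements `data` (the filtered `study_data`), `report`
#'   (per-group data frame of litters/right horns/left horns excluded) and
#'   `horn_log` (one row per dam x side with feti count and exclusion reason,
#'   `""` if retained). The operation is idempotent.
#' @export
apply_inclusion_criteria <- function(x) {
  stopifnot(is.data.frame(x))
  control_label <- attr(x, "control_label")
  df <- as.data.frame(x)
  dam_ids <- unique(df$dam_id)

  horn_log <- do.call(rbind, lapply(dam_ids, function(d) {
    dd <- df[df$dam_id == d, , drop = FALSE]
    counts <- vapply(HORN_SIDES, function(s) sum(dd$horn_side == s), integer(1L))
    litter <- sum(counts)
    reason <- vapply(HORN_SIDES, function(s) {
      if (litter < 5L) "litter <5 feti"
      else if (counts[[s]] < 5L) "horn <5 feti"
      else ""
    }, character(1L))
    data.frame(
      dam_id = d, group_label = dd$group_label[1L], horn_side = HORN_SIDES,
      n_feti = unname(counts), litter_size = litter, excluded = reason != "",
      reason = reason, stringsAsFactors = FALSE
    )
  }))

  if (is.null(horn_log)) {
    horn_log <- data.frame(dam_id = character(), group_label = character(),
                           horn_side = character(), n_feti = integer(),
                           litter_size = integer(), excluded = logical(),
                           reason = character(), stringsAsFactors = FALSE)
  }

  groups <- unique(df$group_label)
  report <- do.call(rbind, lapply(groups, function(g) {
    gl <- horn_log[horn_log$group_label == g, , drop = FALSE]
    n_dams <- length(unique(gl$dam_id))
    litters_excluded <- length(unique(gl$dam_id[gl$reason == "litter <5 feti"]))
    cnt <- function(side) sum(gl$horn_side == side & gl$excluded)
    data.frame(
      group_label = g,
      n_dams = n_dams,
      litters_excluded = litters_excluded,
      right_horns_excluded = cnt("R"),
      left_horns_excluded = cnt("L"),
      litters_display = sprintf("%d/%d", litters_excluded, n_dams),
      right_horns_display = sprintf("%d/%d", cnt("R"), n_dams),
      left_horns_display = sprintf("%d/%d", cnt("L"), n_dams),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(report)) {
    report <- data.frame(group_label = character(), n_dams = integer(),
                         litters_excluded = integer(), right_horns_excluded = integer(),
                         left_horns_excluded = integer(), litters_display = character(),
                         right_horns_display = character(), left_horns_display = character(),
                         stringsAsFactors = FALSE)
  }

  kept_key <- with(horn_log[!horn_log$excluded, , drop = FALSE],
                   paste(dam_id, horn_side, sep = "\r"))
  keep <- paste(df$dam_id, df$horn_side, sep = "\r") %in% kept_key
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("inclusion criteria excluded every horn")
  attr(out, "control_label") <- control_label
  class(out) <- c("study_data", "data.frame")
  list(data = out, report = report, horn_log = horn_log)
}

#' Two-sided Grubbs critical value
#'
#' Critical value for the two-sided single-outlier Grubbs statistic at
#' significance level `alpha`:
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n - 2 + t^2}}}
#' where `t` is the upper `alpha/(2n)` quantile of Student's t with `n - 2`
#' degrees of freedom.
#'
#' @param n sample size (`>= 3`).
#' @param alpha significance level in (0, 1).
#' @return The critical value (vectorised over `n`).
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("Grubbs critical value requires n >= 3")
  stopifnot(alpha > 0, alpha < 1)
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

# Single pass of the two-sided Grubbs test. Returns the test summary; the
# outlier index is NA when nothing exceeds the critical value (or sd is 0).
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  stopifnot(n >= 3L)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(n = n, g_statistic = 0, g_critical = grubbs_critical(n, alpha),
                outlier_index = NA_integer_, alpha = alpha))
  }
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  crit <- grubbs_critical(n, alpha)
  list(
    n = n, g_statistic = g, g_critical = crit,
    outlier_index = if (g > crit) which.max(dev) else NA_integer_,
    alpha = alpha
  )
}

#' Iterative two-sided Grubbs outlier screening
#'
#' Repeatedly applies the two-sided Grubbs test (`G = max |x_i - mean| / sd`,
#' sample sd), removing the single most deviant point whenever `G` exceeds the
#' critical value, until no outlier is found or fewer than three points
#' remain. Constant samples (sd = 0) and samples with `n < 3` are returned
#' unchanged.
#'
#' @param values numeric vector.
#' @param alpha significance level per pass (default 0.05).
#' @return List with `values` (kept values, a subsequence of the input),
#'   `removed` (values removed, in removal order), `removed_index` (their
#'   positions in the original input) and `tests` (one summary per pass).
#' @export
grubbs_screen <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  keep <- values
  orig_pos <- seq_along(values)
  removed <- numeric(0)
  removed_index <- integer(0)
  tests <- list()
  while (length(keep) >= 3L) {
    res <- grubbs_test(keep, alpha)
    tests[[length(tests) + 1L]] <- res
    if (is.na(res$outlier_index)) break
    removed <- c(removed, keep[res$outlier_index])
    removed_index <- c(removed_index, orig_pos[res$outlier_index])
    keep <- keep[-res$outlier_index]
    orig_pos <- orig_pos[-res$outlier_index]
  }
  list(values = keep, removed = removed, removed_index = removed_index, tests = tests)
}

#' Screen an endpoint table for outliers within each analysis cell
#'
#' Applies [grubbs_screen()] separately within every
#' group x horn side x position cell of a tidy endpoint table, so that
#' treatment effects are never confounded with outlier removal. Cells with
#' fewer than three observations are left untouched.
#'
#' @param tab endpoint table from [compute_endpoint_table()] (columns
#'   `group_label`, `horn_side`, `position`, `value`, ...).
#' @param alpha significance level per Grubbs pass.
#' @return List with `data` (the screened table) and `outliers` (log of
#'   removed observations: cell, dam, value, G statistic and critical value).
#' @export
screen_endpoint_table <- function(tab, alpha = 0.05) {
  stopifnot(all(c("group_label", "horn_side", "position", "value") %in% names(tab)))
  if (nrow(tab) == 0L) {
    return(list(data = tab, outliers = data.frame(
      group_label = character(), horn_side = character(), position = character(),
      dam_id = character(), value = numeric(), g_statistic = numeric(),
      g_critical = numeric(), stringsAsFactors = FALSE
    )))
  }
  cell <- paste(tab$group_label, tab$horn_side, tab$position, sep = "\r")
  drop_rows <- integer(0)
  logs <- list()
  for (cl in unique(cell)) {
    rows <- which(cell == cl)
    if (length(rows) < 3L) next
    scr <- grubbs_screen(tab$value[rows], alpha)
    if (length(scr$removed_index) > 0L) {
      rem <- rows[scr$removed_index]
      drop_rows <- c(drop_rows, rem)
      g <- vapply(scr$tests[seq_along(rem)], `[[`, numeric(1L), "g_statistic")
      gc <- vapply(scr$tests[seq_along(rem)], `[[`, numeric(1L), "g_critical")
      logs[[length(logs) + 1L]] <- data.frame(
        group_label = tab$group_label[rem], horn_side = tab$horn_side[rem],
        position = tab$position[rem],
        dam_id = if ("dam_id" %in% names(tab)) tab$dam_id[rem] else NA_character_,
        value = tab$value[rem], g_statistic = g, g_critical = gc,
        stringsAsFactors = FALSE
      )
    }
  }
  outliers <- if (length(logs) > 0L) do.call(rbind, logs) else data.frame(
    group_label = character(), horn_side = character(), position = character(),
    dam_id = character(), value = numeric(), g_statistic = numeric(),
    g_critical = numeric(), stringsAsFactors = FALSE
  )
  data <- if (length(drop_rows) > 0L) tab[-drop_rows, , drop = FALSE] else tab
  rownames(data) <- NULL
  list(data = data, outliers = outliers)
}
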