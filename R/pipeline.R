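# End-to-end analysis of one study table, with optional CSV export of every
# intermediate so exclusion and outlier decisions stay auditable.

#' Run the full positional analysis pipeline
#'
#' Executes the complete workflow on a per-fetus study table: read/validate,
#' inclusion filtering (litter and horn rules), position collapse,
#' traditional litter-mean summary with percent decrease, endpoint
#' computation (normalized fetal weight, raw placental weight, placental
#' efficiency), per-cell Grubbs screening, and the layered comparisons
#' (within-group horn x position ANOVA; exposed vs control x position ANOVA
#' per horn; Sidak contrasts; Cohen's d). Any stage failure is reported with
#' the stage named.
#'
#' @param x a `study_data` object or a path to a study CSV.
#' @param control_label reference group label (used when `x` is a path or has
#'   no control attribute).
#' @param alpha significance level (default 0.05, marked `*` in reports).
#' @param outdir optional directory; when given, every table in the report is
#'   also written there as CSV.
#' @return A run report: list with `exclusions` (`report`, `horn_log`),
#'   `traditional` (per-dam and per-group summaries), `endpoints` (per
#'   endpoint: screened `table`, `outliers`, cell `summary`, `analyses` from
#'   [run_positional_analyses()]), `alpha` and `control_label`.
#' @export
analyze_study <- function(x, control_label = "control", alpha = 0.05,
                          outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("read", {
    if (is.character(x)) read_study_table(x, control_label = control_label)
    else as_study_data(as.data.frame(x),
                       control_label = attr(x, "control_label") %||% control_label)
  })
  control_label <- attr(ds, "control_label")

  inc <- stage("inclusion_criteria", apply_inclusion_criteria(ds))
  trad <- stage("traditional_summary", traditional_summary(ds, control_label))
  obs <- stage("position_collapse", collapse_positions(inc$data))

  endpoints <- list()
  for (ep in ENDPOINTS) {
    tab <- stage(paste0("endpoint_", ep), compute_endpoint_table(obs, ep))
    scr <- stage(paste0("grubbs_", ep), screen_endpoint_table(tab, alpha))
    analyses <- if (nrow(scr$data) > 0L && control_label %in% scr$data$group_label) {
      stage(paste0("inference_", ep),
            run_positional_analyses(scr$data, control_label, alpha))
    } else NULL
    endpoints[[ep]] <- list(
      table = scr$data, outliers = scr$outliers,
      summary = summarize_cells(scr$data), analyses = analyses
    )
  }

  report <- list(
    exclusions = inc[c("report", "horn_log")],
    traditional = trad,
    endpoints = endpoints,
    positional_observations = obs,
    alpha = alpha, control_label = control_label
  )
  if (!is.null(outdir)) stage("export", write_run_report(report, outdir))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a run report as CSV tables
#'
#' Writes the exclusion report and horn log, the traditional per-dam and
#' per-group summaries, and per endpoint the screened table, the outlier log,
#' the cell summary and the tidy contrast table (with a `*` marker at
#' significant contrasts).
#'
#' @param report output of [analyze_study()].
#' @param outdir directory to write into (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(outdir, paste0(name, ".csv")), row.names = FALSE)
    }
  }
  wr(report$exclusions$report, "exclusion_report")
  wr(report$exclusions$horn_log, "horn_log")
  wr(report$traditional$per_dam, "traditional_per_dam")
  wr(report$traditional$per_group, "traditional_per_group")
  for (ep in names(report$endpoints)) {
    e <- report$endpoints[[ep]]
    wr(e$table, paste0(ep, "_values"))
    wr(e$outliers, paste0(ep, "_outliers"))
    wr(e$summary, paste0(ep, "_cell_summary"))
    if (!is.null(e$analyses$contrast_table)) {
      ct <- e$analyses$contrast_table
      ct$marker <- ifelse(ct$significant, "*", "")
      wr(ct, paste0(ep, "_contrasts"))
    }
  }
  invisible(outdir)
}
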