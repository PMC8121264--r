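#' @keywords internal
"_PACKAGE"

# Canonical column order of the flat per-fetus study table.
STUDY_COLUMNS <- c(
  "dam_id", "group_label", "maternal_gd20_weight_g",
  "horn_side", "fetus_index", "fetal_weight_g", "placental_weight_g"
)

HORN_SIDES <- c("L", "R")

#' Construct a validated study dataset from a per-fetus table
#'
#' A study dataset is a flat data frame with one row per fetus recorded at
#' GD 20 necropsy: dam identity, treatment group, maternal body weight,
#' uterine horn side, 1-based fetus index counted from the ovarian end,
#' fetal wet weight and (optionally missing) placental wet weight.
#'
#' @param df data frame holding the columns `dam_id`, `group_label`,
#'   `maternal_gd20_weight_g`, `horn_side` (`"L"`/`"R"`), `fetus_index`
#'   (integer, 1 = ovarian end), `fetal_weight_g`, `placental_weight_g`
#'   (`NA` allowed).
#' @param control_label group label designating the reference group.
#' @return A `study_data` object: the validated data frame, sorted by
#'   `(dam_id, horn_side, fetus_index)`, with the control label attached as an
#'   attribute.
#' @export
as_study_data <- function(df, control_label = "control") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[STUDY_COLUMNS]
  df$dam_id <- as.character(df$dam_id)
  df$group_label <- as.character(df$group_label)
  df$horn_side <- as.character(df$horn_side)
  df$fetus_index <- as.integer(df$fetus_index)
  df$maternal_gd20_weight_g <- as.numeric(df$maternal_gd20_weight_g)
  df$fetal_weight_g <- as.numeric(df$fetal_weight_g)
  df$placental_weight_g <- as.numeric(df$placental_weight_g)
  df <- df[order(df$dam_id, df$horn_side, df$fetus_index), , drop = FALSE]
  rownames(df) <- NULL
  x <- structure(df,
    control_label = control_label,
    class = c("study_data", "data.frame")
  )
  validate_study_data(x)
  x
}

#' Validate study-dataset invariants
#'
#' Checks the row-level and dam-level invariants of the per-fetus table:
#' positive weights, horn sides in `L`/`R`, fetus indices forming a gap-free
#' 1..n sequence within each `(dam, horn)`, a single group label and maternal
#' weight per dam, maternal weight exceeding the summed fetal weight of the
#' litter, and presence of the control label (for non-empty data).
#'
#' @param x a `study_data` object (or data frame with the same columns).
#' @param control_label control group label; defaults to the attribute on `x`.
#' @return `x`, invisibly. Errors describe the offending row or dam.
#' @export
validate_study_data <- function(x, control_label = attr(x, "control_label")) {
  if (is.null(control_label)) control_label <- "control"
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      stop("validation error: ", what, " (row ", paste(utils::head(i, 5L), collapse = ", "), ")")
    }
  }
  if (nrow(x) == 0L) return(invisible(x))

  bad(is.na(x$dam_id) | x$dam_id == "", "missing dam_id")
  bad(!(x$horn_side %in% HORN_SIDES), "horn_side must be 'L' or 'R'")
  bad(is.na(x$fetus_index) | x$fetus_index < 1L, "fetus_index must be an integer >= 1")
  bad(is.na(x$fetal_weight_g) | x$fetal_weight_g <= 0, "fetal_weight_g must be > 0")
  bad(!is.na(x$placental_weight_g) & x$placental_weight_g <= 0,
      "placental_weight_g must be > 0 when present")
  bad(is.na(x$maternal_gd20_weight_g) | x$maternal_gd20_weight_g <= 0,
      "maternal_gd20_weight_g must be > 0")

  key <- paste(x$dam_id, x$horn_side, x$fetus_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("integrity error: duplicate (dam_id, horn_side, fetus_index): ",
         gsub("\r", "/", d))
  }
  # gap-free 1..n indices per horn
  horns <- split(x$fetus_index, paste(x$dam_id, x$horn_side, sep = "/"))
  for (h in names(horns)) {
    idx <- sort(horns[[h]])
    if (!identical(idx, seq_len(length(idx)))) {
      stop("integrity error: fetus_index sequence has gaps or does not start at 1 for horn ", h)
    }
  }
  # dam-level consistency
  dams <- split(x, x$dam_id)
  for (d in names(dams)) {
    dd <- dams[[d]]
    if (length(unique(dd$group_label)) != 1L) {
      stop("integrity error: dam ", d, " appears under multiple group labels")
    }
    if (length(unique(dd$maternal_gd20_weight_g)) != 1L) {
      stop("integrity error: dam ", d, " has inconsistent maternal_gd20_weight_g")
    }
    if (dd$maternal_gd20_weight_g[1L] <= sum(dd$fetal_weight_g)) {
      stop("validation error: maternal weight of dam ", d,
           " does not exceed the summed fetal weight of its litter")
    }
  }
  if (!(control_label %in% x$group_label)) {
    stop("validation error: control label '", control_label,
         "' not present among group labels")
  }
  invisible(x)
}

#' Read a per-fetus study table from CSV
#'
#' The expected schema is the seven-column flat table written by
#' [write_study_table()]: `dam_id, group_label, maternal_gd20_weight_g,
#' horn_side, fetus_index, fetal_weight_g, placental_weight_g` (UTF-8, `.`
#' decimal separator, empty cell = missing placental weight).
#'
#' @inheritParams as_study_data
#' @param path path to a CSV file.
#' @return A validated `study_data` object with deterministic row ordering.
#' @export
read_study_table <- function(path, control_label = "control") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$placental_weight_g[df$placental_weight_g %in% c("", "NA")] <- NA
  num <- function(v) suppressWarnings(as.numeric(v))
  df$maternal_gd20_weight_g <- num(df$maternal_gd20_weight_g)
  df$fetus_index <- num(df$fetus_index)
  df$fetal_weight_g <- num(df$fetal_weight_g)
  df$placental_weight_g <- num(df$placental_weight_g)
  as_study_data(df, control_label = control_label)
}

#' Write a study dataset to CSV
#'
#' Writes the canonical seven-column schema; missing placental weights become
#' empty cells. Full double precision is preserved so that
#' `read_study_table(write_study_table(x))` round-trips exactly.
#'
#' @param x a `study_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(x)[, STUDY_COLUMNS, drop = FALSE]
  fmt <- function(v) {
    out <- vapply(v, function(z) if (is.na(z)) "" else format(z, digits = 17, scientific = FALSE),
                  character(1L))
    out
  }
  df$maternal_gd20_weight_g <- fmt(df$maternal_gd20_weight_g)
  df$fetal_weight_g <- fmt(df$fetal_weight_g)
  df$placental_weight_g <- fmt(df$placental_weight_g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf(
    "Study dataset: %d feti, %d dams, %d groups (control = '%s')\n",
    nrow(x), length(unique(x$dam_id)), length(unique(x$group_label)),
    attr(x, "control_label")
  ))
  NextMethod()
}

# Keep the study_data class and control label through [ subsetting.
#' @export
`[.study_data` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "control_label") <- attr(x, "control_label")
    class(out) <- c("study_data", "data.frame")
  }
  out
}
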