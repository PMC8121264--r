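# Anatomical position categories within a uterine horn, ovarian end first.

#' The five intrauterine position categories
#'
#' Ordered from the ovarian end: `OE` (ovarian end), `NOE` (next-to-ovarian
#' end), `MD` (middle, possibly several feti), `NCE` (next-to-cervical end),
#' `CE` (cervical end).
#'
#' @return Character vector of length 5.
#' @export
position_levels <- function() c("OE", "NOE", "MD", "NCE", "CE")

#' Partition the ordered feti of a horn into position categories
#'
#' For a horn of `n >= 5` feti numbered 1..n from the ovarian end, position
#' `OE` is fetus 1, `NOE` fetus 2, `CE` fetus `n`, `NCE` fetus `n - 1`, and
#' `MD` the `n - 4` feti in between (indices `3..n-2`). The partition is
#' exhaustive and disjoint; horns with more than five feti contribute several
#' feti to `MD`, which downstream are averaged into one middle value.
#'
#' @param n number of feti in the horn (must be `>= 5`).
#' @return Named list mapping each position to the integer fetus indices it
#'   contains.
#' @export
assign_positions <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 5L) {
    stop("assign_positions() requires a horn with at least 5 feti (got ", n, ")")
  }
  list(
    OE  = 1L,
    NOE = 2L,
    MD  = 3:(n - 2L),
    NCE = n - 1L,
    CE  = n
  )
}

# Position of fetus i in a horn of n feti, defined for any n >= 1. For n >= 5
# this inverts assign_positions(); undersized horns (which the inclusion
# criteria exclude from analysis) fall back to end-first labels so that the
# simulator can still attach position multipliers to every fetus.
position_of_index <- function(i, n) {
  stopifnot(all(i >= 1L), all(i <= n))
  if (n >= 5L) {
    out <- rep("MD", length(i))
    out[i == 1L] <- "OE"
    out[i == 2L] <- "NOE"
    out[i == n - 1L] <- "NCE"
    out[i == n] <- "CE"
    return(out)
  }
  labels <- switch(as.character(n),
    "1" = "OE",
    "2" = c("OE", "CE"),
    "3" = c("OE", "MD", "CE"),
    "4" = c("OE", "NOE", "NCE", "CE")
  )
  labels[i]
}

#' Collapse horns to one observation per position
#'
#' Converts a filtered study dataset (every remaining horn has at least five
#' feti) into the positional analysis unit: one observation per
#' dam x horn side x position. End positions carry the single fetus value; the
#' middle (`MD`) value is the arithmetic mean over the middle feti. Placental
#' averaging mirrors fetal averaging but uses only feti with a recorded
#' placental weight; placental efficiency (fetal/placental weight) is computed
#' per fetus before averaging, over the same feti.
#'
#' @param x a `study_data` object whose horns all have `>= 5` feti (apply
#'   [apply_inclusion_criteria()] first).
#' @return Data frame with columns `dam_id`, `group_label`, `horn_side`,
#'   `position`, `raw_fetal_weight_g`, `raw_placental_weight_g`,
#'   `raw_efficiency`, `n_feti_in_horn`, `maternal_gd20_weight_g`.
#' @export
collapse_positions <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) {
    return(data.frame(
      dam_id = character(), group_label = character(), horn_side = character(),
      position = character(), raw_fetal_weight_g = numeric(),
      raw_placental_weight_g = numeric(), raw_efficiency = numeric(),
      n_feti_in_horn = integer(), maternal_gd20_weight_g = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  df <- as.data.frame(x)
  df <- df[order(df$dam_id, df$horn_side, df$fetus_index), , drop = FALSE]
  horn_key <- paste(df$dam_id, df$horn_side, sep = "\r")
  n_in_horn <- stats::ave(df$fetus_index, horn_key, FUN = length)
  if (any(n_in_horn < 5L)) {
    small <- unique(horn_key[n_in_horn < 5L])[1L]
    stop("collapse_positions() requires horns with at least 5 feti; got horn ",
         gsub("\r", "/", small), " (apply inclusion criteria first)")
  }
  # vectorised position rule: ends by index, everything else is middle
  pos <- rep("MD", nrow(df))
  pos[df$fetus_index == 1L] <- "OE"
  pos[df$fetus_index == 2L] <- "NOE"
  pos[df$fetus_index == n_in_horn - 1L] <- "NCE"
  pos[df$fetus_index == n_in_horn] <- "CE"

  cell <- paste(horn_key, pos, sep = "\r")
  first <- !duplicated(cell)
  fw_sum <- rowsum(df$fetal_weight_g, cell)
  fw_n <- rowsum(rep(1, nrow(df)), cell)
  has_pw <- !is.na(df$placental_weight_g)
  pw_sum <- rowsum(ifelse(has_pw, df$placental_weight_g, 0), cell)
  pw_n <- rowsum(as.numeric(has_pw), cell)
  eff_sum <- rowsum(ifelse(has_pw, df$fetal_weight_g / df$placental_weight_g, 0),
                    cell)

  key <- cell[first]
  out <- data.frame(
    dam_id = df$dam_id[first], group_label = df$group_label[first],
    horn_side = df$horn_side[first], position = pos[first],
    raw_fetal_weight_g = fw_sum[key, 1L] / fw_n[key, 1L],
    raw_placental_weight_g = ifelse(pw_n[key, 1L] > 0, pw_sum[key, 1L] / pw_n[key, 1L], NA_real_),
    raw_efficiency = ifelse(pw_n[key, 1L] > 0, eff_sum[key, 1L] / pw_n[key, 1L], NA_real_),
    n_feti_in_horn = as.integer(n_in_horn[first]),
    maternal_gd20_weight_g = df$maternal_gd20_weight_g[first],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$dam_id, out$horn_side,
                   match(out$position, position_levels())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
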